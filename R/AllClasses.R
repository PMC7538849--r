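#' TumorVolume: a multi-slice binary tumor segmentation
#'
#' An ordered stack of 2D binary slices describing one tumor. Each slice
#' carries two aligned images: the *solid* image `A`, whose active pixels are
#' the radio-dense (solid) tumor pixels, and the *mask* image `B`, equal to
#' `A` with every internal hole filled (8-connected foreground, 4-connected
#' background). The set difference `B & !A` is the radiolucent (non-solid)
#' component of the tumor: cavities, cysts, reticulation or air bronchograms.
#'
#' @slot solid list of logical matrices, the per-slice solid images `A`.
#' @slot mask list of logical matrices, the per-slice filled masks `B`.
#' @slot spacing numeric(1), in-plane pixel size in mm (1 = pixel units).
#'
#' @seealso [TumorVolume()] for construction, [computeIBM()] for feature
#'   extraction.
#' @name TumorVolume-class
#' @rdname TumorVolume-class
#' @exportClass TumorVolume
setClass("TumorVolume",
  representation(solid = "list", mask = "list", spacing = "numeric"))

setValidity("TumorVolume", function(object) {
  msgs <- character()
  if (length(object@solid) == 0L)
    msgs <- c(msgs, "volume has no slices")
  if (length(object@solid) != length(object@mask))
    msgs <- c(msgs, "solid and mask slice counts differ")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msgs <- c(msgs, "spacing must be a single positive number")
  dims <- lapply(object@solid, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L)
    msgs <- c(msgs, "slice dimensions are inconsistent")
  for (i in seq_along(object@solid)) {
    A <- object@solid[[i]]; B <- object@mask[[i]]
    if (!is.logical(A) || !is.logical(B))
      msgs <- c(msgs, sprintf("slice %d is not logical", i))
    else {
      if (!identical(dim(A), dim(B)))
        msgs <- c(msgs, sprintf("slice %d: A and B dimensions differ", i))
      else if (any(A & !B))
        msgs <- c(msgs, sprintf("slice %d: solid pixels outside the mask", i))
    }
  }
  if (length(msgs) == 0L &&
      !any(vapply(object@mask, any, logical(1))))
    msgs <- c(msgs, "volume has no tumor pixels in any slice")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TumorVolume from binary slices
#'
#' The filled mask `B` of each slice is derived from the solid image `A` by
#' morphological hole filling: background regions of `A` not 4-connected to
#' the image border are set active. Slices may be supplied as a list of
#' matrices or a 3D array (rows x cols x slices); any nonzero value counts as
#' solid.
#'
#' @param slices list of binary matrices, or a 3D numeric/logical array.
#' @param spacing in-plane pixel size in mm; a length-2 vector of anisotropic
#'   spacings is averaged with a warning.
#' @return A [TumorVolume-class] object.
#' @examples
#' A <- matrix(1, 7, 7); A[3:5, 3:5] <- 0   # block with a 3x3 cavity
#' vol <- TumorVolume(list(A))
#' nLucentSlices(vol)
#' @export
TumorVolume <- function(slices, spacing = 1) {
  if (is.array(slices) && length(dim(slices)) == 3L)
    slices <- lapply(seq_len(dim(slices)[3]), function(k) slices[, , k])
  if (is.matrix(slices)) slices <- list(slices)
  if (!is.list(slices) || length(slices) == 0L)
    stop("'slices' must be a non-empty list of matrices or a 3D array")
  if (length(spacing) == 2L) {
    if (abs(diff(spacing)) > sqrt(.Machine$double.eps))
      warning("anisotropic in-plane spacing; using the mean of row/column spacing")
    spacing <- mean(spacing)
  }
  solid <- lapply(slices, function(s) {
    if (is.null(dim(s)) || length(dim(s)) != 2L)
      stop("each slice must be a 2D matrix")
    s <- s != 0
    storage.mode(s) <- "logical"
    s
  })
  mask <- lapply(solid, fillMask)
  methods::new("TumorVolume", solid = solid, mask = mask,
               spacing = as.numeric(spacing))
}
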