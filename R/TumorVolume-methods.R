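#' Accessors for TumorVolume
#'
#' @param x a [TumorVolume-class] object
#' @return `solidSlices`/`maskSlices`: lists of logical matrices.
#'   `pixelSpacing`: numeric(1) mm per pixel. `nSlices`: total slice count.
#'   `nTumorSlices`: slices with a nonempty mask. `nLucentSlices`: slices
#'   with at least one internal hole.
#' @name TumorVolume-accessors
#' @aliases solidSlices maskSlices pixelSpacing nSlices nTumorSlices
#'   nLucentSlices
NULL

#' @rdname TumorVolume-accessors
#' @export
setMethod("solidSlices", "TumorVolume", function(x) x@solid)

#' @rdname TumorVolume-accessors
#' @export
setMethod("maskSlices", "TumorVolume", function(x) x@mask)

#' @rdname TumorVolume-accessors
#' @export
setMethod("pixelSpacing", "TumorVolume", function(x) x@spacing)

#' @rdname TumorVolume-accessors
#' @export
setMethod("nSlices", "TumorVolume", function(x) length(x@solid))

#' @rdname TumorVolume-accessors
#' @export
setMethod("nTumorSlices", "TumorVolume", function(x)
  sum(vapply(x@mask, any, logical(1))))

#' @rdname TumorVolume-accessors
#' @export
setMethod("nLucentSlices", "TumorVolume", function(x)
  sum(vapply(seq_along(x@solid),
             function(i) any(x@mask[[i]] & !x@solid[[i]]), logical(1))))

setMethod("show", "TumorVolume", function(object) {
  d <- dim(object@solid[[1]])
  cat("TumorVolume:", length(object@solid), "slice(s) of",
      d[1], "x", d[2], "pixels\n")
  cat("  tumor-bearing slices: ", nTumorSlices(object),
      ", lucency-bearing: ", nLucentSlices(object), "\n", sep = "")
  cat("  pixel spacing:", object@spacing, "mm\n")
  invisible(NULL)
})

#' Per-slice pixel counts
#'
#' Counts of active pixels in the solid image `A`, the filled mask `B`, and
#' their intersection, for one slice of a volume. Because `A` is a subset of
#' `B` by construction, `PBiA` always equals `PA`.
#'
#' @param volume a [TumorVolume-class]
#' @param i slice index
#' @return named numeric: `PA`, `PB`, `PBiA`.
#' @examples
#' A <- matrix(1, 3, 3); A[2, 2] <- 0
#' pixelCounts(TumorVolume(list(A)), 1)
#' @export
pixelCounts <- function(volume, i = 1L) {
  stopifnot(methods::is(volume, "TumorVolume"))
  if (i < 1L || i > length(volume@solid)) stop("slice index out of range")
  A <- volume@solid[[i]]; B <- volume@mask[[i]]
  c(PA = sum(A), PB = sum(B), PBiA = sum(A & B))
}
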