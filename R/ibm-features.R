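#' Fill internal holes of a binary slice
#'
#' Returns the tumor mask `B`: the input solid image `A` with every
#' background region not 4-connected to the image border set active
#' (equivalently, 8-connected foreground with 4-connected background).
#'
#' @param A binary matrix (nonzero = solid pixel)
#' @return logical matrix of the same dimensions; `A` is a subset of the
#'   result.
#' @examples
#' A <- matrix(1, 3, 3); A[2, 2] <- 0
#' sum(fillMask(A))  # 9: the interior hole is filled
#' @export
fillMask <- function(A) {
  if (is.null(dim(A)) || length(dim(A)) != 2L || length(A) == 0L)
    stop("empty slice")
  A <- A != 0
  B <- EBImage::fillHull(A + 0) != 0
  matrix(as.logical(B), nrow(A), ncol(A))
}

# indices of tumor-bearing (PB > 0) and lucency-bearing (any hole) slices
.tumorSliceIdx <- function(volume)
  which(vapply(volume@mask, any, logical(1)))
.lucentSliceIdx <- function(volume)
  which(vapply(seq_along(volume@solid),
               function(i) any(volume@mask[[i]] & !volume@solid[[i]]),
               logical(1)))

.perSliceRatio <- function(volume, f) {
  idx <- .tumorSliceIdx(volume)
  if (length(idx) == 0L) stop("volume has no tumor-bearing slices")
  vapply(idx, function(i) {
    PA <- sum(volume@solid[[i]]); PB <- sum(volume@mask[[i]])
    f(PA, PB)
  }, numeric(1))
}

#' @describeIn ibm-generics Radio-dense composition: the mean over
#'   tumor-bearing slices of the solid pixel fraction `PA / PB`. 1 for a
#'   fully solid tumor; values below 1 indicate internal lucency.
#' @export
setMethod("rdc", "TumorVolume", function(volume)
  mean(.perSliceRatio(volume, function(PA, PB) PA / PB)))

#' @describeIn ibm-generics Radio-lucent composition: the mean over
#'   tumor-bearing slices of the lucent fraction `(PB - PA) / PB`;
#'   complements `rdc` so that `rdc + rlc = 1`.
#' @export
setMethod("rlc", "TumorVolume", function(volume)
  mean(.perSliceRatio(volume, function(PA, PB) (PB - PA) / PB)))

#' Difference of composition
#'
#' The absolute difference between the radio-dense and radio-lucent
#' composition scores, `sqrt((rdc - rlc)^2)`. Near 1 when one component
#' dominates, 0 when the tumor is half solid, half lucent.
#'
#' @param rdc,rlc composition scores in \[0, 1\]
#' @return a score in \[0, 1\]
#' @export
doc <- function(rdc, rlc) {
  stopifnot(is.numeric(rdc), is.numeric(rlc))
  sqrt((rdc - rlc)^2)
}

#' @describeIn ibm-generics Air-to-tissue ratio: the mean over tumor-bearing
#'   slices of lucent over solid pixels, `(PB - PA) / P(B & A)`. Unbounded
#'   above; 0 iff the tumor has no holes. A slice with no solid pixels at
#'   all is an error.
#' @export
setMethod("atRatio", "TumorVolume", function(volume) {
  vals <- .perSliceRatio(volume, function(PA, PB) {
    if (PA == 0L) stop("no solid tissue in slice")
    (PB - PA) / PA
  })
  mean(vals)
})

#' @describeIn ibm-generics Span: the maximum over tumor-bearing slices of
#'   the largest pairwise distance between boundary pixel centers of the
#'   mask `B` (max Feret diameter), scaled by the pixel spacing.
#' @export
setMethod("spanDiameter", "TumorVolume", function(volume) {
  idx <- .tumorSliceIdx(volume)
  if (length(idx) == 0L) stop("volume has no tumor-bearing slices")
  max(vapply(idx, function(i)
    .maxFeret(.boundaryCoords(volume@mask[[i]])), numeric(1))) *
    volume@spacing
})

# boundary vertices of each largest hole (all regions tied for maximal
# area, so the result is invariant to relabeling) and of the outer mask;
# NULL when the slice has no hole
.wallVertexSets <- function(A, B) {
  lab <- .labelHoles(A, B)
  if (!any(lab > 0L)) return(NULL)
  areas <- tabulate(lab[lab > 0L])
  biggest <- which(areas == max(areas))
  list(inner = lapply(biggest, function(b) .boundaryCoords(lab == b)),
       outer = .boundaryCoords(B))
}

#' @describeIn ibm-generics Length of solid area: the thickest wall between
#'   a lucent region and the outer tumor boundary. Per lucency-bearing
#'   slice, the largest lucent region is selected (every region when tied
#'   for the maximal area) and for each of its
#'   boundary vertices the minimum distance to the mask boundary vertices is
#'   taken; the slice value is the maximum of these minima and the volume
#'   value the maximum over slices (0 for a hole-free volume).
#'   `method = "maxpair"` instead takes the largest distance over all
#'   (lucent, wall) vertex pairs.
#' @param method `"directed"` (default) or `"maxpair"`, see Details.
#' @export
setMethod("losa", "TumorVolume", function(volume,
                                          method = c("directed", "maxpair")) {
  method <- match.arg(method)
  idx <- .lucentSliceIdx(volume)
  if (length(idx) == 0L) return(0)
  per <- vapply(idx, function(i) {
    vs <- .wallVertexSets(volume@solid[[i]], volume@mask[[i]])
    max(vapply(vs$inner, function(inner) {
      if (method == "directed") .directedMaxMin(inner, vs$outer)
      else .maxPairDist(inner, vs$outer)
    }, numeric(1)))
  }, numeric(1))
  max(per) * volume@spacing
})

#' @describeIn ibm-generics Ratio of `losa` to the span; in \[0, 1\] for the
#'   directed method.
#' @export
setMethod("losaRatio", "TumorVolume", function(volume, ...) {
  sp <- spanDiameter(volume)
  if (sp <= 0) stop("degenerate mask: span is zero")
  losa(volume, ...) / sp
})

#' Inner diameter of the lucent areas of one slice
#'
#' For each lucent connected component (4-connected) of the slice, the
#' diameter of the circle with the same area, `2 * sqrt(area / pi)`; the
#' slice value is the mean over components. Degenerate-safe: a single-pixel
#' hole has diameter `2 / sqrt(pi)`.
#'
#' @param volume a [TumorVolume-class]
#' @param i slice index
#' @return mean equivalent diameter, scaled by the pixel spacing
#' @export
innerDiameter <- function(volume, i = 1L) {
  stopifnot(methods::is(volume, "TumorVolume"))
  lab <- .labelHoles(volume@solid[[i]], volume@mask[[i]])
  if (!any(lab > 0L)) stop("no lucent area in slice")
  areas <- tabulate(lab[lab > 0L])
  mean(2 * sqrt(areas / pi)) * volume@spacing
}

#' @describeIn ibm-generics Length of cavity area: the mean over
#'   lucency-bearing slices of the per-slice mean equivalent hole diameter
#'   ([innerDiameter()]); 0 for a hole-free volume.
#' @export
setMethod("loca", "TumorVolume", function(volume) {
  idx <- .lucentSliceIdx(volume)
  if (length(idx) == 0L) return(0)
  mean(vapply(idx, function(i) innerDiameter(volume, i), numeric(1)))
})

#' @describeIn ibm-generics Ratio of `loca` to the span.
#' @export
setMethod("locaRatio", "TumorVolume", function(volume) {
  sp <- spanDiameter(volume)
  if (sp <= 0) stop("degenerate mask: span is zero")
  loca(volume) / sp
})

#' @describeIn ibm-generics Solidity: the mean over tumor-bearing slices of
#'   solid pixels over the area of the axis-aligned bounding box of the mask
#'   (the measure called "extent" in most shape libraries).
#' @export
setMethod("solidity", "TumorVolume", function(volume) {
  idx <- .tumorSliceIdx(volume)
  if (length(idx) == 0L) stop("volume has no tumor-bearing slices")
  mean(vapply(idx, function(i) {
    B <- volume@mask[[i]]
    rr <- range(which(rowSums(B) > 0))
    cc <- range(which(colSums(B) > 0))
    sum(volume@solid[[i]]) / ((diff(rr) + 1) * (diff(cc) + 1))
  }, numeric(1)))
})

#' @describeIn ibm-generics Compute all nine imaging biomarkers at once.
#'   Returns a named numeric vector with elements `rdc`, `rlc`, `doc`,
#'   `at_r`, `losa`, `losa_r`, `loca`, `loca_r`, `solidity`, plus bookkeeping
#'   counts `n_slices` and `n_lucent_slices`.
#' @export
setMethod("computeIBM", "TumorVolume", function(volume,
                                                method = c("directed",
                                                           "maxpair")) {
  method <- match.arg(method)
  v.rdc <- rdc(volume); v.rlc <- rlc(volume)
  c(rdc = v.rdc, rlc = v.rlc, doc = doc(v.rdc, v.rlc),
    at_r = atRatio(volume),
    losa = losa(volume, method = method),
    losa_r = losaRatio(volume, method = method),
    loca = loca(volume), loca_r = locaRatio(volume),
    solidity = solidity(volume),
    n_slices = nTumorSlices(volume),
    n_lucent_slices = nLucentSlices(volume))
})

#' Imaging-biomarker table for a list of volumes
#'
#' @param volumes named list of [TumorVolume-class] objects (names become
#'   subject ids)
#' @param ... passed to [computeIBM()]
#' @return data.frame with one row per subject: `subject_id`, the nine
#'   biomarkers, `n_slices`, `n_lucent_slices`.
#' @export
computeIBMTable <- function(volumes, ...) {
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(volumes))
  rows <- lapply(volumes, function(v) as.data.frame(as.list(computeIBM(v, ...))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cbind(subject_id = ids, out, stringsAsFactors = FALSE)
}

#' Names of the nine imaging biomarkers
#'
#' @return character vector in canonical order.
#' @export
ibmNames <- function()
  c("rdc", "rlc", "doc", "at_r", "losa", "losa_r", "loca", "loca_r",
    "solidity")

#' Binarize a grayscale CT slice or volume at a HU threshold
#'
#' Pixels above the threshold inside the region of interest are solid. The
#' default threshold of -500 HU sits between air (-1000) and soft tissue.
#'
#' @param ct numeric matrix or 3D array of HU values
#' @param roi binary matrix/array delimiting the tumor region (default: all)
#' @param huThreshold numeric cutoff, default -500
#' @return binary array of the same shape
#' @export
binarizeCT <- function(ct, roi = NULL, huThreshold = -500) {
  out <- ct > huThreshold
  if (!is.null(roi)) out <- out & (roi != 0)
  out
}
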