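#' @name ibm-generics
#' @title Imaging-biomarker generics
#' @description Generics for the nine imaging biomarkers and their helpers,
#'   implemented for [TumorVolume-class]. See [computeIBM()] for the
#'   one-call interface and the package vignette for the definitions.
#' @param volume a [TumorVolume-class] object
#' @param ... further arguments passed to methods
#' @keywords internal
NULL

#' @rdname ibm-generics
#' @export
setGeneric("rdc", function(volume, ...) standardGeneric("rdc"))

#' @rdname ibm-generics
#' @export
setGeneric("rlc", function(volume, ...) standardGeneric("rlc"))

#' @rdname ibm-generics
#' @export
setGeneric("atRatio", function(volume, ...) standardGeneric("atRatio"))

#' @rdname ibm-generics
#' @export
setGeneric("spanDiameter", function(volume, ...) standardGeneric("spanDiameter"))

#' @rdname ibm-generics
#' @export
setGeneric("losa", function(volume, ...) standardGeneric("losa"))

#' @rdname ibm-generics
#' @export
setGeneric("losaRatio", function(volume, ...) standardGeneric("losaRatio"))

#' @rdname ibm-generics
#' @export
setGeneric("loca", function(volume, ...) standardGeneric("loca"))

#' @rdname ibm-generics
#' @export
setGeneric("locaRatio", function(volume, ...) standardGeneric("locaRatio"))

#' @rdname ibm-generics
#' @export
setGeneric("solidity", function(volume, ...) standardGeneric("solidity"))

#' @rdname ibm-generics
#' @export
setGeneric("computeIBM", function(volume, ...) standardGeneric("computeIBM"))

#' @rdname TumorVolume-accessors
#' @export
setGeneric("solidSlices", function(x) standardGeneric("solidSlices"))

#' @rdname TumorVolume-accessors
#' @export
setGeneric("maskSlices", function(x) standardGeneric("maskSlices"))

#' @rdname TumorVolume-accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname TumorVolume-accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname TumorVolume-accessors
#' @export
setGeneric("nTumorSlices", function(x) standardGeneric("nTumorSlices"))

#' @rdname TumorVolume-accessors
#' @export
setGeneric("nLucentSlices", function(x) standardGeneric("nLucentSlices"))
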