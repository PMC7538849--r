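#' Mid-rank empirical CDF normalization
#'
#' Maps values into (0, 1) by `(rank - 0.5) / n` with average ranks for
#' ties; strictly order-preserving on distinct values and invariant to any
#' strictly monotone transform of the input. Used to bring the unbounded
#' biomarkers (air-to-tissue ratio and the two length measures) onto the
#' probability scale before thresholding.
#'
#' @param values numeric vector, length >= 2
#' @return numeric vector in (0, 1)
#' @examples
#' ecdfNormalize(c(10, 20, 30, 40))  # 0.125 0.375 0.625 0.875
#' @export
ecdfNormalize <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to normalize")
  if (any(!is.finite(values))) stop("non-finite values")
  (rank(values, ties.method = "average") - 0.5) / length(values)
}

# which biomarkers are already ratios in [0,1], and which point toward the
# solid (vs lucent) component
.ratioIBMs  <- function() c("rdc", "rlc", "doc", "losa_r", "loca_r", "solidity")
.solidIBMs  <- function() c("rdc", "doc", "losa", "losa_r", "solidity")
.lucentIBMs <- function() c("rlc", "at_r", "loca", "loca_r")

#' Dichotomize a cohort into solid-dominant and non-solid-dominant groups
#'
#' For one biomarker, each subject is assigned to the solid-dominant (SD) or
#' non-solid-dominant (NSD) group at a fixed threshold (default 0.6).
#' Ratio-type biomarkers (`rdc`, `rlc`, `doc`, `losa_r`, `loca_r`,
#' `solidity`) are thresholded on their raw value; the unbounded ones
#' (`at_r`, `losa`, `loca`) are first passed through [ecdfNormalize()].
#' Solid-polarity biomarkers send values at or above the threshold to SD;
#' lucent-polarity biomarkers (which grow with the lucent component) send
#' them to NSD.
#'
#' @param ibmName one of [ibmNames()]
#' @param values numeric vector of that biomarker over the cohort
#' @param threshold group cut point, default 0.6
#' @param subjectId optional ids (defaults to seq_along)
#' @param rlcAsComplement if TRUE, group `rlc` through `1 - rlc` with solid
#'   polarity, which makes the RLC partition identical to the RDC partition.
#' @return data.frame: `subject_id`, `ibm`, `raw`, `normalized`, `group`
#'   (factor SD/NSD)
#' @export
assignGroups <- function(ibmName, values, threshold = 0.6,
                         subjectId = NULL, rlcAsComplement = FALSE) {
  if (!ibmName %in% ibmNames())
    stop("unknown biomarker '", ibmName, "'; expected one of: ",
         paste(ibmNames(), collapse = ", "))
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(subjectId)) subjectId <- seq_along(values)
  raw <- values
  polarity <- if (ibmName %in% .solidIBMs()) "solid" else "lucent"
  if (ibmName == "rlc" && rlcAsComplement) {
    values <- 1 - values
    polarity <- "solid"
  }
  normalized <- if (ibmName %in% .ratioIBMs()) values else ecdfNormalize(values)
  hi <- normalized >= threshold
  group <- if (polarity == "solid") ifelse(hi, "SD", "NSD")
           else ifelse(hi, "NSD", "SD")
  data.frame(subject_id = subjectId, ibm = ibmName, raw = raw,
             normalized = normalized,
             group = factor(group, levels = c("SD", "NSD")),
             stringsAsFactors = FALSE)
}

#' Group assignments for every biomarker of an IBM table
#'
#' @param ibmTable data.frame from [computeIBMTable()] (needs `subject_id`
#'   and the nine biomarker columns)
#' @param threshold,rlcAsComplement see [assignGroups()]
#' @return long data.frame stacking [assignGroups()] over the nine
#'   biomarkers.
#' @export
assignGroupsAll <- function(ibmTable, threshold = 0.6,
                            rlcAsComplement = FALSE) {
  do.call(rbind, lapply(ibmNames(), function(nm)
    assignGroups(nm, ibmTable[[nm]], threshold = threshold,
                 subjectId = ibmTable$subject_id,
                 rlcAsComplement = rlcAsComplement)))
}
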