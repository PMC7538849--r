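#' Encode a two-level nominal covariate as 0/1
#'
#' The first listed category maps to 0, the second to 1 (e.g. Male = 0,
#' Female = 1; Squamous = 0, Non-Squamous = 1).
#'
#' @param value character vector of observed categories
#' @param categories ordered pair of admissible categories
#' @return integer vector of 0/1
#' @export
encodeBinaryNominal <- function(value, categories) {
  stopifnot(length(categories) == 2L)
  bad <- !(value %in% categories)
  if (any(bad))
    stop("unknown category '", value[bad][1], "'; admissible values: ",
         paste(categories, collapse = ", "))
  as.integer(match(value, categories) - 1L)
}

#' Proportion encoding of a categorical staging covariate
#'
#' Each category is replaced by the fraction of the cohort it contains:
#' a stage held by 16 of 68 subjects encodes to 16/68 = 0.235. This keeps
#' staging on a dense numeric scale instead of sparse indicator columns.
#'
#' @param stage vector of categories
#' @param cohortSize denominator; defaults to `length(stage)`
#' @return list with `encoded` (numeric vector, aligned to `stage`) and
#'   `mapping` (named numeric, category to proportion)
#' @examples
#' stageProportionEncoding(rep(c(1, 2), c(16, 52)))$mapping
#' @export
stageProportionEncoding <- function(stage, cohortSize = length(stage)) {
  if (length(stage) == 0L) stop("empty stage column")
  stopifnot(cohortSize >= 1)
  counts <- table(stage)
  mapping <- as.numeric(counts) / cohortSize
  names(mapping) <- names(counts)
  list(encoded = unname(mapping[as.character(stage)]), mapping = mapping)
}

# the nine clinical covariates, in table order
.cbmColumns <- function()
  c("gender", "age", "weight", "smoking_years", "histology",
    "t_stage", "n_stage", "m_stage", "tumor_size")

#' Encode a clinical covariate table for modeling
#'
#' Applies the covariate conversions row-wise: gender and histology become
#' 0/1, T/N/M stages become within-cohort proportions (recomputed from this
#' cohort unless a frozen mapping is supplied), and the continuous
#' covariates (age, weight in lbs, smoking years, tumor size in mm) pass
#' through unchanged. Subjects with a missing value in any of the nine
#' covariates are excluded and reported in the `exclusions` attribute.
#'
#' @param records data.frame with columns `subject_id`, `gender`
#'   (Male/Female), `age`, `weight`, `smoking_years`, `histology`
#'   (Squamous/Non-Squamous), `t_stage`, `n_stage`, `m_stage`, `tumor_size`
#' @param stageEncoding `"recompute"` (default) or a named list of frozen
#'   category-to-value mappings with elements `t_stage`, `n_stage`,
#'   `m_stage`
#' @return data.frame of encoded features, one row per retained subject,
#'   with attributes `exclusions` (data.frame of subject_id + reason) and
#'   `stage_mappings`.
#' @export
encodeClinical <- function(records, stageEncoding = "recompute") {
  need <- c("subject_id", .cbmColumns())
  missingCols <- setdiff(need, names(records))
  if (length(missingCols))
    stop("missing clinical columns: ", paste(missingCols, collapse = ", "))

  has_na <- !stats::complete.cases(records[, .cbmColumns()])
  exclusions <- data.frame(subject_id = records$subject_id[has_na],
                           reason = rep("incomplete record", sum(has_na)),
                           stringsAsFactors = FALSE)
  if (any(has_na))
    message(sum(has_na), " subject(s) excluded for incomplete records")
  kept <- records[!has_na, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no complete clinical records")

  out <- data.frame(subject_id = kept$subject_id, stringsAsFactors = FALSE)
  out$gender <- encodeBinaryNominal(as.character(kept$gender),
                                    c("Male", "Female"))
  out$age <- as.numeric(kept$age)
  out$weight <- as.numeric(kept$weight)
  out$smoking_years <- as.numeric(kept$smoking_years)
  out$histology <- encodeBinaryNominal(as.character(kept$histology),
                                       c("Squamous", "Non-Squamous"))
  mappings <- list()
  for (col in c("t_stage", "n_stage", "m_stage")) {
    if (identical(stageEncoding, "recompute")) {
      enc <- stageProportionEncoding(kept[[col]])
      out[[col]] <- enc$encoded
      mappings[[col]] <- enc$mapping
    } else {
      map <- stageEncoding[[col]]
      if (is.null(map)) stop("frozen stage encoding missing for ", col)
      val <- map[as.character(kept[[col]])]
      val[is.na(val)] <- 0        # category absent from the reference cohort
      out[[col]] <- unname(val)
      mappings[[col]] <- map
    }
  }
  out$tumor_size <- as.numeric(kept$tumor_size)
  attr(out, "exclusions") <- exclusions
  attr(out, "stage_mappings") <- mappings
  out
}

#' Five-year survival endpoint from follow-up data
#'
#' Positive (1) = death observed within `horizon` years of surgery;
#' negative (0) = followed beyond the horizon (alive at the horizon, whatever
#' happens later); `NA` = censored alive before the horizon, where the
#' endpoint is unknowable. NA subjects are excluded from classification but
#' retained for time-to-event analysis.
#'
#' @param time follow-up time in years
#' @param event 1 = death observed, 0 = censored
#' @param horizon endpoint horizon in years, default 5
#' @return integer vector of 1/0/NA
#' @export
fiveYearLabel <- function(time, event, horizon = 5) {
  stopifnot(length(time) == length(event), all(time > 0, na.rm = TRUE))
  out <- ifelse(event == 1 & time <= horizon, 1L,
                ifelse(time > horizon, 0L, NA_integer_))
  as.integer(out)
}
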