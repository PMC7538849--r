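#' Read a tumor mask volume from disk
#'
#' Accepts a NIfTI file (any nonzero voxel = solid tumor pixel) or a
#' directory of per-slice PNG/TIFF images read in filename order. In-plane
#' pixel spacing is taken from the NIfTI header when present; a `spacing`
#' argument overrides it.
#'
#' @param path NIfTI file or slice directory
#' @param spacing optional in-plane spacing (mm); overrides the header
#' @return a [TumorVolume-class]
#' @export
readMaskVolume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("cannot read mask input: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("no PNG/TIFF slices found in ", path)
    slices <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
             else tiff::readTIFF(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img != 0
    })
    dims <- vapply(slices, function(s) paste(dim(s), collapse = "x"),
                   character(1))
    if (length(unique(dims)) > 1L)
      stop("mixed slice dimensions in ", path)
    TumorVolume(slices, spacing = if (is.null(spacing)) 1 else spacing)
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L) stop("expected a 2D or 3D NIfTI: ", path)
    sp <- spacing
    if (is.null(sp)) {
      pd <- RNifti::pixdim(img)
      sp <- if (length(pd) >= 2 && all(pd[1:2] > 0)) pd[1:2] else 1
    }
    TumorVolume(arr, spacing = sp)
  }
}

#' Write a tumor volume as per-slice PNG masks
#'
#' @param volume a [TumorVolume-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
writeMaskVolume <- function(volume, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(solidSlices(volume)), function(i) {
    f <- file.path(dir, sprintf("slice_%03d.png", i))
    png::writePNG(solidSlices(volume)[[i]] * 1, f)
    f
  }, character(1))
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: imaging-biomarker extraction, clinical
#' encoding, SD/NSD grouping, cross-validated five-year survival
#' classification with AUC/IDI, and per-biomarker survival association
#' (log-rank, Cox, Kaplan-Meier summaries). Subjects present in only one
#' input are excluded with a logged reason.
#'
#' @param volumes named list of [TumorVolume-class] objects (names =
#'   subject ids), or a data.frame of precomputed biomarkers with a
#'   `subject_id` column
#' @param clinical data.frame of raw clinical records including
#'   `survival_time` and `event` columns
#' @param threshold SD/NSD cut, default 0.6
#' @param families classifier families for the prediction stage
#' @param folds cross-validation folds, default 10
#' @param seed integer seed for fold assignment and learners
#' @param hbmIBMs imaging biomarkers in the hybrid pool
#' @param rlcAsComplement see [assignGroups()]
#' @param outDir optional directory: all result tables are written as CSV
#' @return list: `ibm`, `encoded`, `groups`, `comparison`, `survival`
#'   (per-biomarker log-rank / univariable Cox / KM summaries +
#'   multivariable selection), `exclusions`, `seed`
#' @export
runPipeline <- function(volumes, clinical, threshold = 0.6,
                        families = c("lr", "rf", "svm", "ann"),
                        folds = 10L, seed = 1L,
                        hbmIBMs = c("rdc", "rlc", "losa_r", "loca_r"),
                        rlcAsComplement = FALSE, outDir = NULL) {
  ibm <- if (is.data.frame(volumes)) volumes else computeIBMTable(volumes)
  stopifnot("subject_id" %in% names(ibm))
  for (col in c("survival_time", "event"))
    if (!col %in% names(clinical))
      stop("clinical table is missing required column '", col, "'")

  onlyImg <- setdiff(ibm$subject_id, clinical$subject_id)
  onlyClin <- setdiff(clinical$subject_id, ibm$subject_id)
  exclusions <- data.frame(
    subject_id = c(onlyImg, onlyClin),
    reason = rep(c("no clinical record", "no imaging"),
                 c(length(onlyImg), length(onlyClin))),
    stringsAsFactors = FALSE)
  if (nrow(exclusions))
    message(nrow(exclusions), " subject(s) excluded: ",
            paste(exclusions$subject_id, collapse = ", "))
  ibm <- ibm[ibm$subject_id %in% clinical$subject_id, , drop = FALSE]
  clinical <- clinical[clinical$subject_id %in% ibm$subject_id, , drop = FALSE]

  encoded <- encodeClinical(clinical)
  exclusions <- rbind(exclusions, attr(encoded, "exclusions"))
  merged <- merge(ibm, encoded, by = "subject_id")
  clinKeep <- clinical[match(merged$subject_id, clinical$subject_id), ]
  merged$survival_time <- clinKeep$survival_time
  merged$event <- clinKeep$event
  merged$five_year_label <- if ("five_year_label" %in% names(clinical))
    clinKeep$five_year_label
  else fiveYearLabel(clinKeep$survival_time, clinKeep$event)

  groups <- assignGroupsAll(merged[, c("subject_id", ibmNames())],
                            threshold = threshold,
                            rlcAsComplement = rlcAsComplement)

  comparison <- compareFeatureSets(
    merged, labelCol = "five_year_label",
    sets = featureSetSpec(hbmIBMs), families = families,
    k = folds, seed = seed)

  survTables <- .survivalStage(merged, groups)

  result <- list(ibm = ibm, encoded = encoded, groups = groups,
                 comparison = comparison, survival = survTables,
                 exclusions = exclusions, seed = seed)
  if (!is.null(outDir)) .writePipelineCSVs(result, outDir)
  result
}

# per-biomarker SD/NSD survival association + multivariable selection over
# the group indicators
.survivalStage <- function(merged, groups) {
  perIBM <- list(); kmRows <- list()
  groupCols <- data.frame(subject_id = merged$subject_id,
                          stringsAsFactors = FALSE)
  for (nm in ibmNames()) {
    g <- groups[groups$ibm == nm, ]
    g <- g[match(merged$subject_id, g$subject_id), ]
    ind <- as.integer(g$group == "NSD")
    groupCols[[paste0(nm, "_nsd")]] <- ind
    row <- data.frame(ibm = nm, n_sd = sum(ind == 0), n_nsd = sum(ind == 1))
    if (length(unique(ind)) == 2L) {
      lr <- logrankTest(merged$survival_time, merged$event, g$group)
      cox <- tryCatch(
        coxFit(cbind(merged, nsd = ind), "nsd",
               timeCol = "survival_time", eventCol = "event"),
        error = function(e) NULL)
      row$logrank_chisq <- lr$chisq; row$logrank_p <- lr$p
      if (!is.null(cox)) {
        row$hr <- cox$table$hr; row$hr_lower <- cox$table$lower
        row$hr_upper <- cox$table$upper; row$cox_p <- cox$table$p
      } else row[c("hr", "hr_lower", "hr_upper", "cox_p")] <- NA
      for (lev in c("SD", "NSD")) {
        sel <- g$group == lev
        if (sum(merged$event[sel]) >= 1) {
          ks <- kmSummary(merged$survival_time[sel], merged$event[sel])
          kmRows[[paste(nm, lev)]] <- cbind(ibm = nm, group = lev, ks)
        }
      }
    } else {
      row[c("logrank_chisq", "logrank_p", "hr", "hr_lower", "hr_upper",
            "cox_p")] <- NA
    }
    perIBM[[nm]] <- row
  }
  uniTab <- do.call(rbind, perIBM)
  rownames(uniTab) <- NULL
  candidates <- paste0(uniTab$ibm[!is.na(uniTab$cox_p)], "_nsd")
  survData <- cbind(groupCols,
                    survival_time = merged$survival_time,
                    event = merged$event)
  screen <- coxScreen(survData, candidates, timeCol = "survival_time",
                      eventCol = "event")
  list(univariable = uniTab,
       km = if (length(kmRows)) do.call(rbind, kmRows) else NULL,
       multivariable = screen)
}

.writePipelineCSVs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(outDir, f),
                                       row.names = FALSE)
  w(result$ibm, "ibm_features.csv")
  w(result$encoded, "cbm_encoded.csv")
  w(result$groups, "grouping.csv")
  w(result$comparison$metrics, "prediction_auc.csv")
  w(result$comparison$idi, "prediction_idi.csv")
  w(result$survival$univariable, "survival_univariable.csv")
  if (!is.null(result$survival$km)) w(result$survival$km, "survival_km.csv")
  if (nrow(result$exclusions)) w(result$exclusions, "exclusions.csv")
  mv <- result$survival$multivariable
  if (!is.null(mv$multivariable$result))
    w(mv$multivariable$result$table, "survival_multivariable.csv")
  writeLines(c(paste("seed:", result$seed),
               paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(outDir, "run_log.txt"))
  invisible(NULL)
}
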