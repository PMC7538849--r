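# run expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched when a seed is given
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Stratified cross-validation folds
#'
#' Subjects are first split into the positive and negative strata; within
#' each stratum the shuffled subjects are dealt round-robin to the `k`
#' folds, so each fold's class counts differ from exact proportionality by
#' at most one subject.
#'
#' @param labels binary vector (0/1)
#' @param k number of folds, default 10
#' @param seed optional integer for reproducible assignment
#' @return integer vector of fold ids (1..k), one per subject
#' @export
stratifiedFolds <- function(labels, k = 10L, seed = NULL) {
  stopifnot(k >= 2L)
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1 without NAs")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k))
    stop("a class has fewer than k = ", k,
         " members; use a smaller number of folds")
  .withSeed(seed, {
    fold <- integer(length(labels))
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# fit one classifier family on standardized training data and return a
# probability-of-positive predictor. Hyperparameters are fixed documented
# defaults: ridge-free glm for LR, 500 trees for RF, RBF kernel with a
# probability model for SVM, one hidden layer of 4 units with weight decay
# for the network.
.fitFamily <- function(x, y, family) {
  y <- as.integer(y)
  switch(family,
    lr = {
      df <- data.frame(x, .y = y)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      function(newx)
        as.numeric(suppressWarnings(
          stats::predict(fit, newdata = data.frame(newx), type = "response")))
    },
    rf = {
      fit <- randomForest::randomForest(x, factor(y, levels = c(0L, 1L)),
                                        ntree = 500)
      function(newx) unname(stats::predict(fit, newx, type = "prob")[, "1"])
    },
    svm = {
      fit <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                        probability = TRUE)
      function(newx) {
        pr <- stats::predict(fit, newx, probability = TRUE)
        unname(attr(pr, "probabilities")[, "1"])
      }
    },
    ann = {
      fit <- nnet::nnet(x, y, size = 4L, decay = 0.01, maxit = 300,
                        entropy = TRUE, trace = FALSE)
      function(newx) as.numeric(stats::predict(fit, newx))
    },
    stop("unknown classifier family '", family,
         "'; expected lr, rf, svm or ann"))
}

#' Pooled out-of-fold class probabilities
#'
#' For each fold, the classifier is trained on the remaining folds --
#' features standardized to the training fold's mean and standard deviation
#' -- and predicts the held-out subjects, so every subject's probability
#' comes from a model that never saw it.
#'
#' @param features numeric matrix or data.frame (subjects x features)
#' @param labels binary 0/1 vector
#' @param family `"lr"`, `"rf"`, `"svm"` or `"ann"`
#' @param folds integer fold vector from [stratifiedFolds()]
#' @return numeric vector of probabilities in \[0, 1\], one per subject
#' @export
crossValProbs <- function(features, labels, family = "lr", folds) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop("non-finite feature value at subject ", bad[1], ", column '",
         colnames(x)[bad[2]], "'")
  }
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x), length(folds) == nrow(x))
  probs <- rep(NA_real_, nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
    predictFun <- .fitFamily(xs[tr, , drop = FALSE], labels[tr], family)
    p <- predictFun(xs[te, , drop = FALSE])
    probs[te] <- pmin(pmax(p, 0), 1)
  }
  probs
}

#' ROC curve and area under it
#'
#' Sweeps every distinct probability as a decision threshold and returns
#' the (FPR, TPR) points with the trapezoidal area. The trapezoid over tied
#' probabilities credits half, so the area equals the Mann-Whitney
#' probability that a random positive outranks a random negative.
#'
#' @param probs predicted probabilities
#' @param labels binary 0/1 outcomes
#' @return list: `points` (data.frame `threshold`, `fpr`, `tpr`) and `auc`
#' @examples
#' rocAuc(c(.9, .2, .8, .1), c(1, 1, 0, 0))$auc  # 0.75
#' @export
rocAuc <- function(probs, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]; y <- labels[ord]
  # cumulative counts at each distinct threshold
  keep <- c(p[-length(p)] != p[-1], TRUE)
  tp <- cumsum(y == 1L)[keep]
  fp <- cumsum(y == 0L)[keep]
  tpr <- c(0, tp / nPos); fpr <- c(0, fp / nNeg)
  auc <- sum((fpr[-1] - fpr[-length(fpr)]) *
             (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(threshold = c(Inf, p[keep]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Integrated discrimination improvement
#'
#' The change in discrimination slope between two risk models:
#' `IDI = (mean p_new among events - mean p_new among non-events) -
#' (mean p_old among events - mean p_old among non-events)`. Significance
#' uses the normal approximation on the per-subject probability differences:
#' `z = IDI / sqrt(se_events^2 + se_nonevents^2)` with each `se` the
#' standard error of the within-group differences.
#'
#' @param probsOld,probsNew probabilities from the reference and candidate
#'   models, same subjects in the same order
#' @param labels binary 0/1 outcomes
#' @return list: `idi`, `z`, `p` (two-tailed)
#' @export
idi <- function(probsOld, probsNew, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probsOld) == length(labels),
            length(probsNew) == length(labels))
  ev <- labels == 1L; ne <- labels == 0L
  if (sum(ev) < 2L || sum(ne) < 2L)
    stop("need at least 2 subjects in each outcome class")
  d <- probsNew - probsOld
  est <- mean(d[ev]) - mean(d[ne])
  se <- sqrt(stats::var(d[ev]) / sum(ev) + stats::var(d[ne]) / sum(ne))
  if (se == 0) {
    z <- if (est == 0) 0 else sign(est) * Inf
  } else z <- est / se
  list(idi = est, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Default feature-set specification
#'
#' The three predictor pools compared: the nine encoded clinical covariates
#' (CBM), the nine imaging biomarkers (IBM), and the hybrid pool (HBM) of
#' all clinical covariates plus the four prognostically informative imaging
#' biomarkers (`rdc`, `rlc`, `losa_r`, `loca_r`).
#'
#' @param hbmIBMs imaging biomarkers appended to the clinical pool for HBM
#' @return named list of column-name vectors
#' @export
featureSetSpec <- function(hbmIBMs = c("rdc", "rlc", "losa_r", "loca_r")) {
  list(CBM = .cbmColumns(),
       IBM = ibmNames(),
       HBM = c(.cbmColumns(), hbmIBMs))
}

#' Compare feature sets across classifier families
#'
#' Runs stratified k-fold cross-validation for every (classifier family,
#' feature set) pair on a common fold assignment, so comparisons within a
#' family are paired subject-by-subject. Reports pooled out-of-fold AUC per
#' pair and the integrated discrimination improvement of each feature set
#' over the first (reference) set.
#'
#' @param data data.frame holding all feature columns plus the label column
#' @param labelCol name of the binary outcome column (default
#'   `"five_year_label"`); rows with NA labels are dropped
#' @param sets named list of feature-column vectors, default
#'   [featureSetSpec()]
#' @param families classifier families to run, default all four
#' @param k folds, default 10
#' @param seed integer seed for the fold assignment and any stochastic
#'   learner
#' @return list of class `ModelComparison`: `metrics` (family, set, auc),
#'   `idi` (family, reference, set, idi, z, p), `roc` (nested list of ROC
#'   point data.frames), `probs`, `folds`, `labels`.
#' @export
compareFeatureSets <- function(data, labelCol = "five_year_label",
                               sets = featureSetSpec(),
                               families = c("lr", "rf", "svm", "ann"),
                               k = 10L, seed = NULL) {
  stopifnot(labelCol %in% names(data))
  keep <- !is.na(data[[labelCol]])
  data <- data[keep, , drop = FALSE]
  labels <- as.integer(data[[labelCol]])
  for (s in names(sets)) {
    missing <- setdiff(sets[[s]], names(data))
    if (length(missing))
      stop("feature set ", s, " needs missing columns: ",
           paste(missing, collapse = ", "))
  }
  folds <- stratifiedFolds(labels, k = k, seed = seed)
  probs <- list(); rocs <- list()
  metrics <- data.frame(); idiTab <- data.frame()
  refSet <- names(sets)[1]
  for (fam in families) {
    probs[[fam]] <- list(); rocs[[fam]] <- list()
    for (s in names(sets)) {
      p <- .withSeed(if (is.null(seed)) NULL else seed + 1L,
                     crossValProbs(data[, sets[[s]], drop = FALSE],
                                   labels, fam, folds))
      probs[[fam]][[s]] <- p
      r <- rocAuc(p, labels)
      rocs[[fam]][[s]] <- r$points
      metrics <- rbind(metrics,
                       data.frame(family = fam, set = s, auc = r$auc))
    }
    for (s in setdiff(names(sets), refSet)) {
      res <- idi(probs[[fam]][[refSet]], probs[[fam]][[s]], labels)
      idiTab <- rbind(idiTab,
                      data.frame(family = fam, reference = refSet, set = s,
                                 idi = res$idi, z = res$z, p = res$p))
    }
  }
  structure(list(metrics = metrics, idi = idiTab, roc = rocs, probs = probs,
                 folds = folds, labels = labels),
            class = "ModelComparison")
}

#' @export
print.ModelComparison <- function(x, ...) {
  cat("ModelComparison:", length(unique(x$metrics$family)), "families x",
      length(unique(x$metrics$set)), "feature sets,",
      length(x$labels), "subjects\n")
  m <- x$metrics
  m$auc <- round(m$auc, 3)
  print(m, row.names = FALSE)
  if (nrow(x$idi)) {
    cat("IDI vs", x$idi$reference[1], "\n")
    i <- x$idi; i$idi <- round(i$idi, 3); i$z <- round(i$z, 2)
    i$p <- signif(i$p, 3)
    print(i[, c("family", "set", "idi", "z", "p")], row.names = FALSE)
  }
  invisible(x)
}
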