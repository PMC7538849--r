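#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] (Greenwood variance, log-log confidence
#' bands) and returns the step function in tidy form.
#'
#' @param time follow-up times (> 0)
#' @param event 1 = event observed, 0 = censored
#' @return list: `fit` (the survfit object) and `curve` (data.frame `time`,
#'   `n_risk`, `n_event`, `surv`, `std_err`, `lower`, `upper`)
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0))
  if (sum(event) < 1) stop("no events observed; cannot estimate survival")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  s <- summary(fit, censored = TRUE)
  list(fit = fit,
       curve = data.frame(time = s$time, n_risk = s$n.risk,
                          n_event = s$n.event, surv = s$surv,
                          std_err = s$std.err, lower = s$lower,
                          upper = s$upper))
}

#' Mean and median survival from the Kaplan-Meier curve
#'
#' The median is the earliest time at which the survival curve drops to 0.5
#' or below, with a 95% confidence interval from log-log transformed
#' Greenwood bands; `NA` when the curve never reaches 0.5 (median not
#' reached). The mean is the area under the curve restricted to the largest
#' observed time, with its standard error.
#'
#' @inheritParams kmEstimate
#' @return data.frame with one row: `mean`, `mean_se`, `mean_lower`,
#'   `mean_upper` (normal-approximation 95% CI), `median`, `median_lower`,
#'   `median_upper`, `rmean_limit` (restriction time)
#' @export
kmSummary <- function(time, event) {
  km <- kmEstimate(time, event)
  limit <- max(time)
  tab <- summary(km$fit, rmean = limit)$table
  m <- unname(tab["rmean"]); mse <- unname(tab["se(rmean)"])
  # earliest-crossing median: first time the curve drops to 0.5 or below
  crossed <- km$curve$surv <= 0.5 + 1e-12
  med <- if (any(crossed)) min(km$curve$time[crossed]) else NA_real_
  data.frame(mean = m, mean_se = mse,
             mean_lower = m - 1.96 * mse, mean_upper = m + 1.96 * mse,
             median = med,
             median_lower = unname(tab["0.95LCL"]),
             median_upper = unname(tab["0.95UCL"]),
             rmean_limit = limit)
}

#' Log-rank test between two survival groups
#'
#' @inheritParams kmEstimate
#' @param group two-level factor or vector
#' @return list: `chisq`, `df`, `p`
#' @export
logrankTest <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L)
    stop("log-rank needs two nonempty groups")
  if (sum(event) < 1) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event times.
#' Reports per-covariate hazard ratios with Wald 95% confidence intervals
#' and p-values, plus the model likelihood-ratio chi-squared against the
#' null model.
#'
#' @param data data.frame with the time/event columns and covariates
#' @param covariates character vector of covariate column names
#' @param timeCol,eventCol column names, defaults `"time"`, `"event"`
#' @return list of class `CoxResult`: `table` (covariate, coef, hr, lower,
#'   upper, p), `lr_chisq`, `df`, `lr_p`, `fit`
#' @export
coxFit <- function(data, covariates, timeCol = "time", eventCol = "event") {
  stopifnot(all(c(timeCol, eventCol, covariates) %in% names(data)))
  if (sum(data[[eventCol]]) < length(covariates) + 1)
    stop("too few events for ", length(covariates), " covariate(s)")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", timeCol, ", ", eventCol, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(survival::coxph(fml, data = data, ties = "efron"))
  beta <- stats::coef(fit)
  # NA = aliased (collinear) covariate; huge |beta| = monotone likelihood
  bad <- !is.finite(beta) | abs(beta) > 15
  if (any(bad)) {
    cond <- structure(
      class = c("lucency_inestimable", "error", "condition"),
      list(message = paste0(
             "Cox coefficient not estimable (collinearity or monotone ",
             "likelihood) for covariate(s): ",
             paste(names(beta)[bad], collapse = ", ")),
           call = sys.call(-1), covariates = names(beta)[bad]))
    stop(cond)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(covariate = names(beta), coef = unname(beta),
                    hr = exp(unname(beta)),
                    lower = exp(unname(beta) - 1.96 * se),
                    upper = exp(unname(beta) + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE)
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  df <- length(beta)
  structure(list(table = tab, lr_chisq = lr, df = df,
                 lr_p = stats::pchisq(lr, df, lower.tail = FALSE),
                 fit = fit),
            class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
  tab <- x$table
  tab$hr <- round(tab$hr, 3); tab$lower <- round(tab$lower, 3)
  tab$upper <- round(tab$upper, 3); tab$p <- signif(tab$p, 3)
  print(tab[, c("covariate", "hr", "lower", "upper", "p")],
        row.names = FALSE)
  cat(sprintf("LR chi-squared(%d) = %.3f, p = %.4g\n",
              x$df, x$lr_chisq, x$lr_p))
  invisible(x)
}

#' Backward elimination on a Cox model
#'
#' Starting from the candidate pool (typically covariates passing a
#' univariable screen), repeatedly drops the covariate with the largest
#' Wald p-value while any p is at or above `alpha`, and refits. Returns the
#' final model on the retained covariates, or an empty result when
#' everything is eliminated.
#'
#' @inheritParams coxFit
#' @param candidates covariate names entering the elimination
#' @param alpha retention threshold, default 0.05
#' @return list: `retained` (character), `result` ([coxFit()] output or
#'   NULL when nothing is retained)
#' @export
backwardSelect <- function(data, candidates, timeCol = "time",
                           eventCol = "event", alpha = 0.05) {
  retained <- candidates
  result <- NULL
  while (length(retained) > 0L) {
    result <- tryCatch(
      coxFit(data, retained, timeCol = timeCol, eventCol = eventCol),
      lucency_inestimable = function(e) e)
    if (inherits(result, "lucency_inestimable")) {
      # drop aliased / separated covariates and refit
      retained <- setdiff(retained, result$covariates)
      result <- NULL
      next
    }
    worst <- which.max(result$table$p)
    if (result$table$p[worst] < alpha) break
    retained <- setdiff(retained, result$table$covariate[worst])
    result <- NULL
  }
  list(retained = retained, result = result)
}

#' Univariable screen followed by multivariable backward elimination
#'
#' Fits one single-covariate Cox model per candidate; those with Wald
#' p below `enterAlpha` (default 0.10) enter [backwardSelect()].
#'
#' @inheritParams backwardSelect
#' @param enterAlpha univariable entry threshold, default 0.10
#' @return list: `univariable` (data.frame of per-covariate results),
#'   `candidates`, `multivariable` (the [backwardSelect()] output)
#' @export
coxScreen <- function(data, candidates, timeCol = "time",
                      eventCol = "event", enterAlpha = 0.10,
                      alpha = 0.05) {
  uni <- do.call(rbind, lapply(candidates, function(cv) {
    res <- tryCatch(coxFit(data, cv, timeCol = timeCol, eventCol = eventCol),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(covariate = cv, coef = NA, hr = NA, lower = NA,
                 upper = NA, p = NA, stringsAsFactors = FALSE)
    else res$table
  }))
  pool <- uni$covariate[!is.na(uni$p) & uni$p < enterAlpha]
  multi <- if (length(pool))
    backwardSelect(data, pool, timeCol = timeCol, eventCol = eventCol,
                   alpha = alpha)
  else list(retained = character(), result = NULL)
  list(univariable = uni, candidates = pool, multivariable = multi)
}
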