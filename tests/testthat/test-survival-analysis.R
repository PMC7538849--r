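test_that("Kaplan-Meier estimate matches the product-limit by hand", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$curve$time, c(1, 2, 3))
  # no censoring: the curve is the empirical survival fraction
  set.seed(3)
  t <- sort(rexp(20))
  km2 <- kmEstimate(t, rep(1, 20))
  expect_equal(km2$curve$surv, (19:0) / 20)
  expect_true(all(diff(km2$curve$surv) <= 0))
  expect_error(kmEstimate(c(1, 2), c(0, 0)), "no events")
})

test_that("KM mean and median summaries follow the curve", {
  s <- kmSummary(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2.5)
  s5 <- kmSummary(rep(5, 8), rep(1, 8))
  expect_equal(s5$mean, 5); expect_equal(s5$median, 5)
  # a curve never dropping to 0.5 reports the median as not reached
  sNR <- kmSummary(c(1, 2, 3, 4, 5), c(1, 0, 0, 0, 0))
  expect_true(is.na(sNR$median))
  expect_equal(sNR$rmean_limit, 5)
})

test_that("log-rank is null on identical groups and invariant to relabeling", {
  t <- c(1, 2, 3, 1, 2, 3); e <- rep(1, 6)
  g <- rep(c("A", "B"), each = 3)
  # identical survival experience: two interleaved copies
  res <- logrankTest(c(1, 1, 2, 2, 3, 3), rep(1, 6),
                     rep(c("A", "B"), 3))
  expect_lt(res$chisq, 1e-10)
  res1 <- logrankTest(t, e, g)
  res2 <- logrankTest(t, e, rev(g))
  expect_equal(res1$chisq, res2$chisq)
  expect_error(logrankTest(t, e, rep("A", 6)), "two nonempty groups")
})

test_that("log-rank p agrees with the exhaustive permutation oracle at n = 6", {
  t <- 1:6; e <- rep(1, 6)
  obs <- logrankTest(t, e, rep(c("A", "B"), each = 3))$chisq
  combs <- utils::combn(6, 3)
  stats <- apply(combs, 2, function(idx) {
    g <- rep("B", 6); g[idx] <- "A"
    logrankTest(t, e, g)$chisq
  })
  permP <- mean(stats >= obs - 1e-12)
  asymP <- logrankTest(t, e, rep(c("A", "B"), each = 3))$p
  # the observed split (earliest three deaths vs latest three) is the most
  # extreme of the 20 assignments
  expect_equal(permP, 2 / 20)
  expect_lt(abs(asymP - permP), 0.15)
})

test_that("Cox fit recovers a wired-in hazard ratio and nulls stay null", {
  set.seed(17)
  reps <- 40
  est <- cover <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- factor(rep(c("SD", "NSD"), each = 150), levels = c("SD", "NSD"))
    d <- simulateSurvival(group = g, logHR = log(2.2), censoringRate = 0.3,
                          seed = 1000 + i)
    d$nsd <- as.integer(g == "NSD")
    fit <- coxFit(d, "nsd", timeCol = "survival_time")
    est[i] <- fit$table$coef
    cover[i] <- fit$table$lower <= 2.2 && 2.2 <= fit$table$upper
  }
  expect_lt(abs(mean(est) - log(2.2)), 0.08)
  expect_gt(mean(cover), 0.85)
})

test_that("duplicating a dataset keeps the HR and shrinks the CI", {
  set.seed(19)
  g <- factor(rep(c("SD", "NSD"), each = 60), levels = c("SD", "NSD"))
  d <- simulateSurvival(group = g, seed = 19)
  d$nsd <- as.integer(g == "NSD")
  f1 <- coxFit(d, "nsd", timeCol = "survival_time")
  d2 <- rbind(d, d)
  f2 <- coxFit(d2, "nsd", timeCol = "survival_time")
  # duplication creates ties, so Efron handling shifts the estimate slightly
  expect_equal(f2$table$hr, f1$table$hr, tolerance = 0.02)
  w1 <- log(f1$table$upper) - log(f1$table$lower)
  w2 <- log(f2$table$upper) - log(f2$table$lower)
  expect_equal(w2 / w1, 1 / sqrt(2), tolerance = 0.05)
})

test_that("Cox HR direction matches the log-rank direction for a binary covariate", {
  set.seed(21)
  for (i in 1:5) {
    g <- factor(sample(rep(c("SD", "NSD"), each = 40)),
                levels = c("SD", "NSD"))
    d <- simulateSurvival(group = g, logHR = log(2.2), seed = 300 + i)
    d$nsd <- as.integer(g == "NSD")
    fit <- coxFit(d, "nsd", timeCol = "survival_time")
    sdiff <- survival::survdiff(
      survival::Surv(survival_time, event) ~ nsd, data = d)
    dirLogrank <- sign(sdiff$obs[2] - sdiff$exp[2])
    expect_equal(sign(fit$table$coef), dirLogrank)
  }
})

test_that("backward elimination drops null covariates and keeps wired ones", {
  set.seed(23)
  n <- 300
  x1 <- rnorm(n)                      # wired into the hazard
  x2 <- rnorm(n); x3 <- rnorm(n)      # pure noise
  rate <- 0.15 * exp(0.8 * x1)
  d <- data.frame(time = rexp(n, rate), event = 1,
                  x1 = x1, x2 = x2, x3 = x3)
  sel <- backwardSelect(d, c("x1", "x2", "x3"))
  expect_true("x1" %in% sel$retained)
  expect_false(all(c("x2", "x3") %in% sel$retained))
  # single significant candidate is retained unchanged
  sel1 <- backwardSelect(d, "x1")
  expect_equal(sel1$retained, "x1")
  # all-null pool: usually everything is eliminated
  dnull <- data.frame(time = rexp(n, 0.2), event = 1,
                      z1 = rnorm(n), z2 = rnorm(n))
  seln <- backwardSelect(dnull, c("z1", "z2"))
  expect_lte(length(seln$retained), 1)
})

test_that("the univariable screen feeds the multivariable model", {
  set.seed(27)
  n <- 250
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(time = rexp(n, 0.15 * exp(0.9 * x1)), event = 1,
                  x1 = x1, x2 = x2)
  sc <- coxScreen(d, c("x1", "x2"))
  expect_equal(nrow(sc$univariable), 2)
  expect_true("x1" %in% sc$candidates)
  expect_true("x1" %in% sc$multivariable$retained)
})

test_that("too few events or inestimable covariates raise errors", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 0, 0), x = c(1, 2, 3))
  expect_error(coxFit(d, "x"), "too few events")
})
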