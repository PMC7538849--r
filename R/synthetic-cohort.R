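# Synthetic study generator: tumor volumes with controlled lucent fraction,
# clinical covariates with cohort-like marginals, and proportional-hazards
# survival outcomes with known effect sizes. Defaults emulate a surgical
# NSCLC cohort with internal lucency: ~68 subjects, ~66% five-year
# mortality, NSD-vs-SD hazard ratio 2.2.

#' Simulate one tumor volume with a controlled lucent fraction
#'
#' Builds an ellipse-based mask per slice (semi-axes tapered along the
#' stack) and carves internal holes until each slice's lucent pixel
#' fraction matches the target, so the volume-level radio-lucent
#' composition lands within `tol` of `targetFraction`. Carving is
#' restricted to the mask interior, guaranteeing every hole is enclosed and
#' hole filling recovers the original mask exactly.
#'
#' Morphologies: `"cavity"` carves one compact hole around the centroid;
#' `"cyst"` carves 2-4 compact holes around random interior seeds;
#' `"reticular"` carves pixels nearest to a random line grid, producing
#' intersecting lucent lines.
#'
#' @param targetFraction desired lucent fraction in \[0, 0.9\]
#' @param nSlices number of slices, default 5
#' @param radius base in-plane radius in pixels, default 14
#' @param morphology hole phenotype, see Details
#' @param spacing pixel size in mm, default 1
#' @param seed optional integer seed
#' @param tol acceptable |realized - target| for the volume-level fraction
#' @return a [TumorVolume-class] with attribute `target_fraction`
#' @export
simulateTumorVolume <- function(targetFraction, nSlices = 5L, radius = 14,
                                morphology = c("cavity", "cyst",
                                               "reticular"),
                                spacing = 1, seed = NULL, tol = 0.02) {
  morphology <- match.arg(morphology)
  stopifnot(targetFraction >= 0, targetFraction <= 0.9, radius >= 6,
            nSlices >= 1)
  .withSeed(seed, {
    side <- 2L * ceiling(radius) + 7L
    ctr <- (side + 1) / 2
    xs <- matrix(rep(seq_len(side), each = side), side)   # column index
    ys <- matrix(rep(seq_len(side), times = side), side)  # row index
    zrel <- if (nSlices == 1L) 0
            else seq(-0.7, 0.7, length.out = nSlices)
    slices <- vector("list", nSlices)
    realized <- numeric(nSlices)
    for (s in seq_len(nSlices)) {
      taper <- sqrt(1 - zrel[s]^2)
      a <- radius * taper * stats::runif(1, 0.95, 1.05)
      b <- radius * taper * stats::runif(1, 0.95, 1.05)
      B <- ((xs - ctr) / a)^2 + ((ys - ctr) / b)^2 <= 1
      PB <- sum(B)
      k <- round(targetFraction * PB)
      interior <- B & !.boundaryMask(B)
      if (k > sum(interior))
        stop("unreachable target lucent fraction ", targetFraction,
             " for radius ", radius)
      if (k > 0L) {
        cand <- which(interior)
        cx <- xs[cand]; cy <- ys[cand]
        score <- switch(morphology,
          cavity = (cx - ctr)^2 + (cy - ctr)^2,
          cyst = {
            m <- sample(2:4, 1L)
            sx <- stats::runif(m, ctr - 0.6 * a, ctr + 0.6 * a)
            sy <- stats::runif(m, ctr - 0.6 * b, ctr + 0.6 * b)
            d2 <- outer(cx, sx, "-")^2 + outer(cy, sy, "-")^2
            apply(d2, 1L, min)
          },
          reticular = {
            p <- stats::runif(1, 4, 6)
            ox <- stats::runif(1, 0, p); oy <- stats::runif(1, 0, p)
            ax <- (cx + ox) %% p; ay <- (cy + oy) %% p
            pmin(ax, p - ax, ay, p - ay)
          })
        carve <- cand[order(score, seq_along(score))[seq_len(k)]]
        A <- B; A[carve] <- FALSE
      } else A <- B
      slices[[s]] <- A
      realized[s] <- k / PB
    }
    if (abs(mean(realized) - targetFraction) > tol)
      stop("could not realize lucent fraction ", targetFraction,
           " within tolerance ", tol)
    vol <- TumorVolume(slices, spacing = spacing)
    attr(vol, "target_fraction") <- targetFraction
    vol
  })
}

#' Simulate a clinical covariate table
#'
#' Draws the nine clinical covariates from marginals loosely matching a
#' surgical NSCLC cohort (71% male, mean age ~68, mostly non-squamous,
#' early T/N stages, rare metastasis). Covariates are independent of
#' imaging and outcome unless wired downstream, so the clinical pool
#' carries no prognostic signal by default.
#'
#' @param n number of subjects
#' @param seed optional integer seed
#' @return data.frame of raw (unencoded) clinical records
#' @export
simulateClinical <- function(n, seed = NULL) {
  .withSeed(seed, {
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      gender = sample(c("Male", "Female"), n, TRUE, prob = c(48, 20)),
      age = round(clip(stats::rnorm(n, 68.5, 9), 42, 87), 1),
      weight = round(clip(stats::rnorm(n, 170, 40), 80, 318), 1),
      smoking_years = round(stats::runif(n, 0, 41), 1),
      histology = sample(c("Squamous", "Non-Squamous"), n, TRUE,
                         prob = c(10, 58)),
      t_stage = sample(1:4, n, TRUE, prob = c(30, 25, 9, 4)),
      n_stage = sample(0:2, n, TRUE, prob = c(56, 4, 8)),
      m_stage = sample(0:1, n, TRUE, prob = c(66, 2)),
      tumor_size = round(clip(stats::rnorm(n, 37, 14), 11.7, 73.9), 1),
      stringsAsFactors = FALSE)
  })
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with hazard
#' `baseHazard * exp(linear predictor)`. The linear predictor is
#' `logHR * I(group == "NSD")` when `group` is given,
#' `betaLucent * (1 - rdc)` when `rdc` is given, and 0 otherwise (null
#' model). Censoring times are uniform on `(0, u)` with `u` solved
#' numerically so the expected censoring proportion equals
#' `censoringRate`.
#'
#' @param n number of subjects (inferred from `group`/`rdc` when supplied)
#' @param group optional SD/NSD factor
#' @param rdc optional radio-dense composition values in (0, 1\]
#' @param baseHazard baseline hazard per year; default 0.15 for the
#'   group/null model (~53% five-year mortality in SD), 0.03 for the
#'   rdc-driven model
#' @param logHR log hazard ratio of NSD vs SD, default `log(2.2)`
#' @param betaLucent log hazard ratio per unit lucent fraction, default 6
#' @param censoringRate target fraction censored, default 0.3
#' @param horizon horizon (years) for the binary endpoint label, default 5
#' @param seed optional integer seed
#' @return data.frame: `survival_time`, `event`, `five_year_label`
#' @export
simulateSurvival <- function(n = NULL, group = NULL, rdc = NULL,
                             baseHazard = NULL, logHR = log(2.2),
                             betaLucent = 6, censoringRate = 0.3,
                             horizon = 5, seed = NULL) {
  if (!is.null(group)) {
    n <- length(group)
    lp <- logHR * (as.character(group) == "NSD")
    if (is.null(baseHazard)) baseHazard <- 0.15
  } else if (!is.null(rdc)) {
    n <- length(rdc)
    lp <- betaLucent * (1 - rdc)
    if (is.null(baseHazard)) baseHazard <- 0.03
  } else {
    stopifnot(!is.null(n))
    lp <- rep(0, n)
    if (is.null(baseHazard)) baseHazard <- 0.15
  }
  rate <- baseHazard * exp(lp)
  .withSeed(seed, {
    tEvent <- stats::rexp(n, rate)
    if (censoringRate > 0) {
      # E[P(C < T)] for C ~ U(0, u): mean over subjects of
      # (1 - exp(-rate*u)) / (rate*u); decreasing in u
      target <- function(u)
        mean((1 - exp(-rate * u)) / (rate * u)) - censoringRate
      u <- stats::uniroot(target, lower = 1e-6, upper = 1e6)$root
      tCens <- stats::runif(n, 0, u)
    } else tCens <- rep(Inf, n)
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
    data.frame(survival_time = time, event = event,
               five_year_label = fiveYearLabel(time, event, horizon))
  })
}

# draw lucent fractions from a two-component truncated normal mixture
.drawLucentFractions <- function(n, mix = list(weights = c(0.5, 0.5),
                                               means = c(0.1, 0.5),
                                               sds = c(0.05, 0.1))) {
  comp <- sample(seq_along(mix$weights), n, TRUE, prob = mix$weights)
  f <- stats::rnorm(n, mix$means[comp], mix$sds[comp])
  pmin(pmax(f, 0), 0.9)
}

# parametric stand-ins for the nine biomarkers of a tumor with per-slice
# lucent fractions fs and base radius r (what rendered ellipse volumes
# yield, without the rasterization)
.parametricIBM <- function(fs, r) {
  v.rlc <- mean(fs); v.rdc <- 1 - v.rlc
  span <- 2 * r * stats::runif(1, 0.97, 1.03)
  if (all(fs == 0)) {
    v.losa <- 0; v.loca <- 0
  } else {
    v.losa <- min(span / 2 * (1 - sqrt(max(fs))) *
                    stats::runif(1, 0.8, 1.2), span)
    v.loca <- min(span * sqrt(v.rlc) * stats::runif(1, 0.8, 1.2), span)
  }
  c(rdc = v.rdc, rlc = v.rlc, doc = abs(v.rdc - v.rlc),
    at_r = mean(fs / (1 - fs)),
    losa = v.losa, losa_r = v.losa / span,
    loca = v.loca, loca_r = v.loca / span,
    solidity = min((pi / 4) * (1 - v.rlc) * stats::runif(1, 0.95, 1.05), 1))
}

#' Simulate a full analysis cohort
#'
#' Generates, per subject: a lucent-fraction target from a bimodal mixture
#' (a mostly-solid and a markedly lucent component, so both the
#' solid-dominant and non-solid-dominant groups are populated at the 0.6
#' threshold), the nine imaging biomarkers, the nine clinical covariates
#' (independent of imaging and outcome), and survival outcomes under the
#' chosen effect model.
#'
#' With `render = TRUE` every subject's tumor volume is rasterized with
#' [simulateTumorVolume()] and the biomarkers measured with
#' [computeIBM()]; the volumes are returned in the `volumes` attribute.
#' With `render = FALSE` (default) the biomarkers are drawn from the
#' parametric model of the same ellipse geometry, which is exact for the
#' composition scores and approximate for the length scores.
#'
#' @param n subjects, default 68
#' @param outcomeModel `"rdc"` (hazard driven by the lucent fraction,
#'   default), `"group"` (NSD vs SD hazard ratio `exp(logHR)`), or
#'   `"none"` (outcome independent of everything)
#' @param render rasterize volumes instead of the parametric biomarker
#'   draw
#' @param lucentMix mixture spec: list of `weights`, `means`, `sds`
#' @param morphology hole phenotype passed to the renderer
#' @param threshold SD/NSD cut on `rdc` used to define the true group
#' @param seed optional integer master seed
#' @inheritParams simulateSurvival
#' @return data.frame with `subject_id`, the nine biomarkers, the raw
#'   clinical covariates, `survival_time`, `event`, `five_year_label`,
#'   `true_fraction`, `true_group`; rendered volumes (if any) in the
#'   `volumes` attribute.
#' @export
simulateCohort <- function(n = 68L, outcomeModel = c("rdc", "group", "none"),
                           render = FALSE,
                           lucentMix = list(weights = c(0.5, 0.5),
                                            means = c(0.1, 0.5),
                                            sds = c(0.05, 0.1)),
                           morphology = "cavity", threshold = 0.6,
                           baseHazard = NULL, logHR = log(2.2),
                           betaLucent = 6, censoringRate = 0.3,
                           seed = NULL) {
  outcomeModel <- match.arg(outcomeModel)
  .withSeed(seed, {
    f <- .drawLucentFractions(n, lucentMix)
    radius <- stats::runif(n, 10, 18)
    nSlices <- sample(3:7, n, TRUE)
    volumes <- NULL
    if (render) {
      volumes <- lapply(seq_len(n), function(i)
        simulateTumorVolume(f[i], nSlices = nSlices[i],
                            radius = radius[i], morphology = morphology))
      names(volumes) <- sprintf("S%03d", seq_len(n))
      ibm <- computeIBMTable(volumes)
      ibm$n_slices <- NULL; ibm$n_lucent_slices <- NULL
    } else {
      rows <- lapply(seq_len(n), function(i) {
        fs <- pmin(pmax(stats::rnorm(nSlices[i], f[i], 0.01), 0), 0.9)
        if (f[i] == 0) fs <- rep(0, nSlices[i])
        as.data.frame(as.list(.parametricIBM(fs, radius[i])))
      })
      ibm <- cbind(subject_id = sprintf("S%03d", seq_len(n)),
                   do.call(rbind, rows), stringsAsFactors = FALSE)
    }
    trueGroup <- factor(ifelse(ibm$rdc >= threshold, "SD", "NSD"),
                        levels = c("SD", "NSD"))
    surv <- switch(outcomeModel,
      rdc = simulateSurvival(rdc = ibm$rdc, baseHazard = baseHazard,
                             betaLucent = betaLucent,
                             censoringRate = censoringRate),
      group = simulateSurvival(group = trueGroup, baseHazard = baseHazard,
                               logHR = logHR,
                               censoringRate = censoringRate),
      none = simulateSurvival(n = n, baseHazard = baseHazard,
                              censoringRate = censoringRate))
    clin <- simulateClinical(n)
    out <- cbind(ibm, clin[, setdiff(names(clin), "subject_id")], surv,
                 true_fraction = f, true_group = trueGroup)
    attr(out, "volumes") <- volumes
    out
  })
}
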