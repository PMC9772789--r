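#' Cohort simulation settings
#'
#' Bundles everything needed to draw a participant-level feature cohort with
#' a proportional-hazards mortality process: feature moments and
#' inter-feature correlation (Gaussian copula with normal marginals, so
#' correlation and marginals are set independently), per-SD log-hazard
#' coefficients defining the ground-truth active set, an age/sex-like
#' covariate block with its own coefficients, a baseline hazard and the
#' censoring mechanism.
#'
#' Defaults emulate an older-adult wrist-accelerometer cohort: 21 features
#' with means/SDs on the published scale (mean acceleration 31.8 (9.7) mg,
#' intensity gradient -2.08 (0.22), ...), strong inter-feature correlation
#' (single-factor structure, pairwise |r| about 0.42) except for activity
#' timing (near zero), and roughly 10% deaths over an 8-year administrative
#' horizon.
#'
#' @param n Number of participants.
#' @param featureNames Feature columns (default the canonical 21).
#' @param means,sds Marginal moments per feature.
#' @param correlation Correlation matrix (symmetric PSD, unit diagonal).
#'   Default: single-factor structure with loadings `corLoadings`.
#' @param corLoadings Factor loadings used to build the default correlation.
#' @param beta Named per-SD log-hazard coefficients; non-zero entries define
#'   the ground-truth active set.
#' @param covariates Function `(n) -> data.frame` drawing the covariate
#'   block; default draws `age` (years) and `sex` (1 = female).
#' @param covariateBeta Named log-hazard coefficients of the covariate block
#'   (on the covariate's own scale; `age` is centred before use).
#' @param baseline List: `dist` "exponential" or "weibull", `rate` (>0) and,
#'   for Weibull, `shape` (>0).
#' @param horizonYears Administrative censoring horizon (years).
#' @param censorRate Rate of an additional exponential random-censoring
#'   process (0 = administrative censoring only).
#' @param seed Integer seed; all cohort randomness flows from it.
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(n = 2000,
                       featureNames = featureNames21(),
                       means = NULL, sds = NULL,
                       correlation = NULL, corLoadings = NULL,
                       beta = NULL,
                       covariates = NULL, covariateBeta = NULL,
                       baseline = list(dist = "exponential", rate = 0.0073),
                       horizonYears = 8, censorRate = 0,
                       seed = 1L) {
  p <- length(featureNames)
  if (identical(featureNames, featureNames21())) {
    defMeans <- c(31.8, 717.9, 210.3, 56.1, 11.5, 2.4, 2.3,
                  147.1, 185.7, 385.0, 184.0, 26.4, 43.4, 12.7,
                  71.8, 86.0, 23.2, 4.5, 12.4, -2.08, 10.2)
    defSds <- c(9.7, 100.1, 69.1, 38.5, 5.9, 0.4, 0.9,
                41.0, 45.3, 143.0, 54.1, 21.3, 27.6, 17.2,
                16.0, 21.6, 13.6, 2.5, 0.7, 0.22, 1.6)
    # sign of each feature's correlation with the "less active" direction
    defSign <- c(-1, 1, -1, -1, 1, -1, -1,
                 -1, -1, 1, -1, -1, -1, -1,
                 -1, -1, -1, -1, 1, -1, 0)
    if (is.null(means)) means <- setNames(defMeans, featureNames)
    if (is.null(sds)) sds <- setNames(defSds, featureNames)
    if (is.null(corLoadings)) corLoadings <- setNames(0.65 * defSign, featureNames)
    if (is.null(beta)) {
      beta <- setNames(rep(0, p), featureNames)
      beta[c("mean_acceleration", "dur_SB", "sb_ge30",
             "mvpa_lt10", "intensity_gradient")] <-
        0.26 * c(-1, 1, 1, -1, -1)
    }
  } else {
    if (is.null(means)) means <- setNames(rep(0, p), featureNames)
    if (is.null(sds)) sds <- setNames(rep(1, p), featureNames)
    if (is.null(beta)) beta <- setNames(rep(0, p), featureNames)
  }
  if (is.null(correlation)) {
    if (is.null(corLoadings)) corLoadings <- setNames(rep(0, p), featureNames)
    correlation <- tcrossprod(corLoadings)
    diag(correlation) <- 1
    dimnames(correlation) <- list(featureNames, featureNames)
  }
  if (is.null(covariates)) {
    covariates <- function(n) data.frame(
      age = rnorm(n, 69.4, 5.5),
      sex = rbinom(n, 1, 0.26))
    if (is.null(covariateBeta))
      covariateBeta <- c(age = 0.09, sex = -0.35)
  }
  if (is.null(covariateBeta)) covariateBeta <- numeric()
  spec <- list(n = as.integer(n), featureNames = featureNames, p = p,
               means = means, sds = sds, correlation = correlation,
               beta = beta, covariates = covariates,
               covariateBeta = covariateBeta, baseline = baseline,
               horizonYears = horizonYears, censorRate = censorRate,
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  .validateCohortSpec(spec)
  spec
}

.validateCohortSpec <- function(spec) {
  R <- spec$correlation
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "correlation matrix is not positive semi-definite (smallest eigenvalue %.3g)",
      min(ev)))
  if (spec$horizonYears <= 0)
    stop("censoring horizon must be > 0")
  if (any(spec$sds < 0)) stop("feature SDs must be non-negative")
  invisible(TRUE)
}

## ---- epoch-level simulation -------------------------------------------

.stationaryBoutDist <- function(P) {
  if (nrow(P) == 1L) return(setNames(1, rownames(P)))
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  setNames(v / sum(v), rownames(P))
}

.drawBoutEpochs <- function(profile, state) {
  m <- profile@boutMeanMin[state]
  if (profile@boutDist == "geometric") {
    1L + rgeom(1L, prob = 1 / m)
  } else {
    sdl <- profile@boutSdlog[state]
    max(1L, as.integer(round(rlnorm(1L, meanlog = log(m) - sdl^2 / 2,
                                    sdlog = sdl))))
  }
}

.drawEmissions <- function(profile, state, nEpochs) {
  sup <- .stateSupports(profile@sbThreshold, profile@mvpaThreshold,
                        profile@maxMg)[[state]]
  em <- profile@emission[[state]]
  sup[1] + (sup[2] - sup[1]) * rbeta(nEpochs, em$shape1, em$shape2)
}

#' Simulate epoch-level acceleration series
#'
#' Draws, for each participant and day, an alternating-state semi-Markov
#' sequence of activity bouts that fills the waking period exactly; each
#' 60-s epoch carries one intensity draw (mg) from its state's emission
#' distribution. Because emission supports respect the SB/LIPA/MVPA
#' thresholds, the generating state of every epoch is recoverable by
#' thresholding.
#'
#' @param profile An [ActivityProfile-class].
#' @param nParticipants Number of participants.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param keepState Keep the generating state as an extra `state` column
#'   (not part of the epoch CSV dialect; useful for validating that
#'   thresholding recovers the generating states).
#' @return A data.frame in the epoch dialect: `participant_id`, `day_index`,
#'   `epoch_index` (minutes since midnight, 0-based), `timestamp_iso8601`,
#'   `enmo_mg`, `waking`.
#' @examples
#' prof <- activityProfile(days = 2L, wakingMinutes = 480)
#' ep <- simulateEpochSeries(prof, nParticipants = 2, seed = 7)
#' head(ep)
#' @export
simulateEpochSeries <- function(profile, nParticipants, seed = 1L,
                                keepState = FALSE) {
  stopifnot(is(profile, "ActivityProfile"))
  validObject(profile)
  if (profile@wakingMinutes < 1)
    stop("waking period shorter than one 60-s epoch")
  set.seed(as.integer(seed))
  nEp <- as.integer(profile@wakingMinutes)
  states <- profile@states
  P <- profile@transition
  pi0 <- .stationaryBoutDist(P)
  timeWeight <- pi0 * profile@boutMeanMin[states]
  timeWeight <- timeWeight / sum(timeWeight)
  startMin <- as.integer(round(profile@wakingStartHour * 60))
  out <- vector("list", nParticipants * profile@days)
  idx <- 0L
  for (i in seq_len(nParticipants)) {
    pid <- sprintf("P%04d", i)
    for (d in seq_len(profile@days)) {
      lab <- character(nEp)
      mg <- numeric(nEp)
      filled <- 0L
      state <- if (length(states) == 1L) states else
        sample(states, 1L, prob = timeWeight)
      while (filled < nEp) {
        len <- min(.drawBoutEpochs(profile, state), nEp - filled)
        lab[(filled + 1L):(filled + len)] <- state
        mg[(filled + 1L):(filled + len)] <- .drawEmissions(profile, state, len)
        filled <- filled + len
        if (length(states) > 1L)
          state <- sample(states, 1L, prob = P[state, ])
      }
      epoch <- startMin + seq_len(nEp) - 1L
      idx <- idx + 1L
      df <- data.frame(
        participant_id = pid, day_index = d, epoch_index = epoch,
        timestamp_iso8601 = sprintf("2013-01-%02dT%02d:%02d:00",
                                    d, epoch %/% 60L, epoch %% 60L),
        enmo_mg = mg, waking = 1L,
        stringsAsFactors = FALSE)
      if (keepState) df$state <- lab
      out[[idx]] <- df
    }
  }
  do.call(rbind, out)
}

## ---- feature-level simulation -----------------------------------------

#' Simulate a participant-level feature cohort with known ground truth
#'
#' Draws an n x p feature table from a Gaussian copula with the requested
#' correlation matrix and normal marginals (given means/SDs), plus the
#' covariate block, and records the ground truth: active feature set,
#' per-SD log-hazard coefficients and the latent linear predictor
#' (computed on standardised features, so coefficients read per SD).
#'
#' @param spec A [cohortSpec()] object.
#' @return An [ActivityCohort-class] with `metadata()$groundTruth`.
#' @export
simulateFeatureCohort <- function(spec) {
  .validateCohortSpec(spec)
  set.seed(spec$seed)
  n <- spec$n; p <- spec$p
  R <- spec$correlation
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) # PSD-safe root
  Z <- matrix(rnorm(n * p), n, p) %*% t(L)
  X <- sweep(sweep(Z, 2, spec$sds, "*"), 2, spec$means, "+")
  colnames(X) <- spec$featureNames
  cov <- spec$covariates(n)
  lp <- as.numeric(Z %*% spec$beta) # Z is the standardised scale
  for (nm in names(spec$covariateBeta)) {
    x <- cov[[nm]]
    lp <- lp + spec$covariateBeta[[nm]] * (x - mean(x))
  }
  gt <- list(activeSet = spec$featureNames[spec$beta != 0],
             beta = spec$beta,
             covariateBeta = spec$covariateBeta,
             linearPredictor = lp,
             eventFraction = NA_real_)
  activityCohort(X, colData = cov, groundTruth = gt)
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times follow hazard `baseline x exp(linear predictor)`; the
#' observed time is the minimum of the event time, an optional exponential
#' random-censoring time and the administrative horizon.
#'
#' @param linearPredictor Numeric vector of log-relative hazards.
#' @param spec A [cohortSpec()] (its `baseline`, `horizonYears`,
#'   `censorRate` fields are used).
#' @param seed Integer seed (default: the spec's seed plus one, so feature
#'   and outcome draws do not share a stream).
#' @return data.frame with `time_years` and `event`.
#' @export
simulateSurvival <- function(linearPredictor, spec, seed = spec$seed + 1L) {
  b <- spec$baseline
  if (is.null(b$rate) || b$rate <= 0)
    stop("baseline hazard rate must be positive")
  if (identical(b$dist, "weibull") && (is.null(b$shape) || b$shape <= 0))
    stop("Weibull baseline shape must be positive")
  set.seed(as.integer(seed))
  n <- length(linearPredictor)
  u <- rexp(n) / (b$rate * exp(linearPredictor)) # cumulative-hazard inversion
  tEvent <- if (identical(b$dist, "weibull")) u^(1 / b$shape) else u
  cTime <- rep(spec$horizonYears, n)
  if (spec$censorRate > 0)
    cTime <- pmin(cTime, rexp(n, rate = spec$censorRate))
  data.frame(time_years = pmin(tEvent, cTime),
             event = as.integer(tEvent <= cTime))
}

#' Attach simulated survival outcomes to a cohort
#'
#' Convenience wrapper: draws outcomes from the cohort's stored latent
#' linear predictor and records the realised event fraction in the ground
#' truth.
#'
#' @param cohort An [ActivityCohort-class] carrying ground truth.
#' @param spec The [cohortSpec()] that generated it.
#' @param seed Passed to [simulateSurvival()].
#' @return The cohort with `time_years`/`event` columns in `colData`.
#' @export
addSimulatedSurvival <- function(cohort, spec, seed = spec$seed + 1L) {
  gt <- groundTruth(cohort)
  if (is.null(gt)) stop("cohort carries no ground truth")
  surv <- simulateSurvival(gt$linearPredictor, spec, seed = seed)
  SummarizedExperiment::colData(cohort)$time_years <- surv$time_years
  SummarizedExperiment::colData(cohort)$event <- surv$event
  gt$eventFraction <- mean(surv$event)
  S4Vectors::metadata(cohort)$groundTruth <- gt
  validObject(cohort)
  cohort
}
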