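#' Fit a Cox proportional-hazards model on named design columns
#'
#' Thin wrapper around the partial-likelihood machinery of the survival
#' package (Newton-Raphson with Efron or Breslow tie handling) returning a
#' `CoxFit` list: coefficients with standard errors, partial log-likelihood,
#' `AIC = -2 loglik + 2 p`, and the per-participant linear predictor. An
#' empty design fits the null model (linear predictor 0).
#'
#' @param records data.frame with `time_years`, `event` and the design
#'   columns.
#' @param design Character vector of design column names (possibly empty).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List of class `CoxFit`.
#' @export
fitCoxModel <- function(records, design = character(), ties = "efron") {
  stopifnot(all(c("time_years", "event") %in% names(records)))
  if (sum(records$event) < 1) stop("at least one event is required")
  if (length(design) == 0) {
    ll <- survival::coxph(survival::Surv(time_years, event) ~ 1,
                          data = records)$loglik[1]
    fit <- list(coef = numeric(0), se = numeric(0), loglik = ll,
                aic = -2 * ll, lp = rep(0, nrow(records)),
                ties = ties, design = design, records = records,
                coxph = NULL)
    class(fit) <- "CoxFit"
    return(fit)
  }
  X <- as.matrix(records[, design, drop = FALSE])
  # a constant covariate leaves the partial likelihood flat: coefficient 0,
  # loglik unchanged, but the parameter still counts towards the AIC
  isConst <- apply(X, 2, function(v) diff(range(v)) == 0)
  active <- design[!isConst]
  if (length(active) == 0L) {
    fit <- fitCoxModel(records, character(), ties)
    fit$coef <- setNames(rep(0, length(design)), design)
    fit$se <- setNames(rep(NA_real_, length(design)), design)
    fit$aic <- fit$aic + 2 * length(design)
    fit$design <- design
    return(fit)
  }
  if (qr(X[, !isConst, drop = FALSE])$rank < length(active))
    stop("design matrix is rank deficient")
  design0 <- design
  design <- active
  f <- stats::reformulate(sprintf("`%s`", design),
                          response = "survival::Surv(time_years, event)")
  cox <- survival::coxph(f, data = records, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  if (any(is.na(coef(cox))))
    stop("Cox fit produced undefined coefficients (collinear design)")
  if (any(abs(coef(cox)) > 15))
    stop("separation detected: coefficient diverging")
  if (cox$iter >= 50)
    stop(sprintf("Cox fit did not converge in 50 iterations (score norm %.3g)",
                 max(abs(colSums(residuals(cox, type = "score"))))))
  ll <- cox$loglik[2]
  cf <- setNames(rep(0, length(design0)), design0)
  se <- setNames(rep(NA_real_, length(design0)), design0)
  cf[design] <- coef(cox)
  se[design] <- sqrt(diag(cox$var))
  fit <- list(coef = cf, se = se,
              loglik = ll, aic = -2 * ll + 2 * length(design0),
              lp = unname(cox$linear.predictors),
              ties = ties, design = design0, records = records,
              coxph = cox)
  class(fit) <- "CoxFit"
  fit
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("CoxFit (%s ties): %d covariate(s), loglik %.2f, AIC %.1f\n",
              x$ties, length(x$coef), x$loglik, x$aic))
  if (length(x$coef)) {
    hr <- exp(x$coef)
    for (nm in names(x$coef))
      cat(sprintf("  %-22s HR %.3f (%.3f, %.3f)\n", nm, hr[nm],
                  exp(x$coef[nm] - 1.96 * x$se[nm]),
                  exp(x$coef[nm] + 1.96 * x$se[nm])))
  }
  invisible(x)
}

#' Hazard ratio per standard deviation with 95% CI
#'
#' Reads `exp(beta)` and its Wald interval off a `CoxFit` for a feature
#' that entered the design standardised to SD 1 (so the HR is per one SD
#' increment); refuses unstandardised inputs.
#'
#' @param fit A `CoxFit`.
#' @param feature Design column name.
#' @return Named numeric: `hr`, `lower`, `upper`.
#' @export
hazardRatioPerSD <- function(fit, feature) {
  stopifnot(feature %in% names(fit$coef))
  s <- sd(fit$records[[feature]])
  if (abs(s - 1) > 1e-6)
    stop(sprintf("feature '%s' is not standardised to SD 1 (SD = %.4f)",
                 feature, s))
  b <- fit$coef[[feature]]; se <- fit$se[[feature]]
  c(hr = exp(b), lower = exp(b - 1.96 * se), upper = exp(b + 1.96 * se))
}

#' Harrell's concordance index for survival data
#'
#' Over pairs `(i, j)` comparable when `t_i < t_j` and participant `i` had
#' the event, the pair is concordant when the earlier-event participant has
#' the higher predicted risk; tied predictors score half.
#'
#' @param lp Linear predictor (higher = higher predicted risk).
#' @param time,event Survival outcome.
#' @return Concordance in `[0, 1]`.
#' @export
harrellC <- function(lp, time, event) {
  stopifnot(all(is.finite(lp)))
  r <- .harrellC_cpp(as.numeric(lp), as.numeric(time), as.integer(event))
  if (r[2] == 0) stop("no comparable pairs")
  r[1] / r[2]
}

#' Royston's explained-variation measure R2_D
#'
#' The linear predictor is replaced by standard-normal order-statistic
#' (rankit) scores divided by `kappa = sqrt(8/pi)`; the Cox coefficient of
#' that regressor is the prognostic-separation statistic `D`, and
#' `R2_D = (D^2/kappa^2) / (pi^2/6 + D^2/kappa^2)`.
#'
#' @param lp Linear predictor.
#' @param time,event Survival outcome.
#' @return R2_D in `[0, 1)`; 0 with a warning for a constant predictor.
#' @export
roystonR2D <- function(lp, time, event) {
  if (length(unique(lp)) < 2L) {
    warning("constant predictor: R2_D = 0")
    return(0)
  }
  kappa <- sqrt(8 / pi)
  n <- length(lp)
  rk <- rank(lp, ties.method = "average")
  z <- qnorm((rk - 3 / 8) / (n + 1 / 4)) / kappa
  df <- data.frame(time_years = time, event = event, z = z)
  D <- coef(survival::coxph(survival::Surv(time_years, event) ~ z, data = df))[[1]]
  (D^2 / kappa^2) / (pi^2 / 6 + D^2 / kappa^2)
}

#' Youden-optimal classification cutoff, sensitivity and specificity
#'
#' Labels a participant positive when the event was observed during
#' follow-up (censoring time is ignored, a documented simplification), then
#' scans every midpoint between sorted unique risk scores and returns the
#' cutoff maximising sensitivity + specificity - 1, the earliest cutoff on
#' ties.
#'
#' @param score Risk score (higher = predicted positive).
#' @param event 0/1 outcome labels, both classes present.
#' @return Named numeric: `cutoff`, `sensitivity`, `specificity` (the last
#'   two in percent).
#' @export
youdenCutoff <- function(score, event) {
  if (length(unique(event)) < 2L)
    stop("both outcome classes are required")
  u <- sort(unique(score))
  if (length(u) < 2L) stop("constant score: no cutoff exists")
  cuts <- (head(u, -1L) + u[-1L]) / 2
  pos <- score[event == 1]; neg <- score[event == 0]
  sens <- vapply(cuts, function(cc) mean(pos >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(neg < cc), numeric(1))
  j <- sens + spec - 1
  k <- which(j >= max(j) - 1e-12)[1] # earliest cutoff on ties
  c(cutoff = cuts[k], sensitivity = 100 * sens[k], specificity = 100 * spec[k])
}

#' Predictive-performance panel for a fitted Cox model
#'
#' @param fit A `CoxFit`.
#' @return List of class `PerformancePanel`: `r2d`, `aic`, `c` (Harrell),
#'   `cutoff`, `sensitivity`, `specificity` (percent).
#' @export
performancePanel <- function(fit) {
  rec <- fit$records
  yj <- if (length(unique(fit$lp)) < 2L)
    c(cutoff = NA_real_, sensitivity = NA_real_, specificity = NA_real_)
  else {
    risk <- 1 - exp(-exp(fit$lp - mean(fit$lp))) # monotone in lp
    youdenCutoff(risk, rec$event)
  }
  out <- list(r2d = roystonR2D(fit$lp, rec$time_years, rec$event),
              aic = fit$aic,
              c = harrellC(fit$lp, rec$time_years, rec$event),
              cutoff = unname(yj["cutoff"]),
              sensitivity = unname(yj["sensitivity"]),
              specificity = unname(yj["specificity"]))
  class(out) <- "PerformancePanel"
  out
}

#' @export
print.PerformancePanel <- function(x, ...) {
  cat(sprintf("R2_D %.3f | AIC %.1f | C %.3f | Youden cutoff %.3f (sens %.1f%%, spec %.1f%%)\n",
              x$r2d, x$aic, x$c, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Bootstrap comparison of nested Cox models
#'
#' Point differences in AIC and Harrell C (augmented minus reference) come
#' from the full-sample fits; percentile confidence intervals from `B`
#' participant-level resamples refitting both models. A difference is
#' flagged significant when its interval excludes zero. Replicates whose
#' fit fails are redrawn (more than 10% failures aborts).
#'
#' @param records data.frame with outcome and design columns.
#' @param designRef,designAug Column sets, reference nested in augmented.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @param ties Tie handling for the Cox fits.
#' @return List of class `ComparisonResult`.
#' @export
compareNestedModels <- function(records, designRef, designAug,
                                B = 1000L, seed = 1L, ties = "efron") {
  if (!all(designRef %in% designAug))
    stop("reference design must be nested in the augmented design")
  fitBoth <- function(dat) {
    fr <- fitCoxModel(dat, designRef, ties)
    fa <- fitCoxModel(dat, designAug, ties)
    c(dAIC = fa$aic - fr$aic,
      dC = harrellC(fa$lp, dat$time_years, dat$event) -
           harrellC(fr$lp, dat$time_years, dat$event))
  }
  point <- fitBoth(records)
  set.seed(as.integer(seed))
  n <- nrow(records)
  reps <- matrix(NA_real_, B, 2)
  fails <- 0L
  b <- 1L
  while (b <= B) {
    dat <- records[sample.int(n, n, replace = TRUE), , drop = FALSE]
    r <- tryCatch(suppressWarnings(fitBoth(dat)), error = function(e) NULL)
    if (is.null(r)) {
      fails <- fails + 1L
      if (fails > max(10L, B %/% 10L))
        stop(sprintf("more than 10%% of bootstrap replicates failed (%d)", fails))
      next
    }
    reps[b, ] <- r
    b <- b + 1L
  }
  ciAIC <- unname(quantile(reps[, 1], c(0.025, 0.975)))
  ciC <- unname(quantile(reps[, 2], c(0.025, 0.975)))
  out <- list(deltaAIC = unname(point["dAIC"]), deltaC = unname(point["dC"]),
              ciAIC = ciAIC, ciC = ciC, B = B,
              significantAIC = ciAIC[1] > 0 || ciAIC[2] < 0,
              significantC = ciC[1] > 0 || ciC[2] < 0,
              redrawn = fails)
  class(out) <- "ComparisonResult"
  out
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("dAIC %.1f (%.1f, %.1f)%s | dC %.4f (%.4f, %.4f)%s | B = %d\n",
              x$deltaAIC, x$ciAIC[1], x$ciAIC[2],
              if (x$significantAIC) "*" else "",
              x$deltaC, x$ciC[1], x$ciC[2],
              if (x$significantC) "*" else "", x$B))
  invisible(x)
}

# restricted-cubic-spline nonlinear basis columns (truncated power form,
# Harrell parameterisation); k knots give k-2 columns
.rcsBasis <- function(x, knots) {
  k <- length(knots)
  if (anyDuplicated(knots))
    stop("duplicate spline knots: score variance too low")
  scl <- (knots[k] - knots[1])^2
  pp <- function(u) pmax(u, 0)^3
  vapply(seq_len(k - 2L), function(j) {
    (pp(x - knots[j]) -
       pp(x - knots[k - 1L]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1L]) +
       pp(x - knots[k]) * (knots[k - 1L] - knots[j]) / (knots[k] - knots[k - 1L])) / scl
  }, numeric(length(x)))
}

#' Likelihood-ratio test for nonlinearity of a score's mortality association
#'
#' Adds the nonlinear restricted-cubic-spline component of the score
#' (3 knots at the 10th/50th/90th percentiles, one added basis column) to
#' the model with a linear score term, and compares by a likelihood-ratio
#' test against chi-square with df = number of added columns.
#'
#' @param records data.frame with outcome, `score` column and covariates.
#' @param score Name of the score column.
#' @param covariates Further design columns of the linear model.
#' @return List: `statistic`, `df`, `p.value`, `knots`.
#' @export
splineNonlinearityTest <- function(records, score, covariates = character()) {
  x <- records[[score]]
  knots <- unname(quantile(x, c(0.1, 0.5, 0.9)))
  basis <- .rcsBasis(x, knots)
  rec <- records
  nlNames <- sprintf("%s_rcs%d", score, seq_len(ncol(basis)))
  rec[nlNames] <- basis
  fitLin <- fitCoxModel(rec, c(covariates, score))
  fitSpl <- fitCoxModel(rec, c(covariates, score, nlNames))
  stat <- max(0, 2 * (fitSpl$loglik - fitLin$loglik))
  df <- ncol(basis)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), knots = knots)
}

#' Subgroup analysis of a composite score's added predictive value
#'
#' Reruns the reference-vs-augmented machinery (covariates only versus
#' covariates plus score) inside each stratum: per-SD hazard ratio of the
#' score with 95% CI and the bootstrap delta-C panel. Strata without
#' events are skipped with a warning.
#'
#' @param records data.frame with outcome, score, covariates and a grouping
#'   column.
#' @param score Score column name (standardised to SD 1 within stratum
#'   before fitting).
#' @param grouping Grouping column name.
#' @param covariates Covariate design columns.
#' @param B Bootstrap replicates per stratum.
#' @param seed Integer seed.
#' @return data.frame, one row per analysed stratum.
#' @export
subgroupAnalysis <- function(records, score, grouping,
                             covariates = character(), B = 200L, seed = 1L) {
  out <- list()
  for (g in unique(records[[grouping]])) {
    sub <- records[records[[grouping]] == g, , drop = FALSE]
    if (sum(sub$event) < 1) {
      warning(sprintf("stratum '%s' has no events: skipped", g))
      next
    }
    sub[[score]] <- as.numeric(scale(sub[[score]]))
    fit2 <- fitCoxModel(sub, c(covariates, score))
    hr <- hazardRatioPerSD(fit2, score)
    cmp <- compareNestedModels(sub, covariates, c(covariates, score),
                               B = B, seed = seed)
    out[[length(out) + 1L]] <- data.frame(
      group = as.character(g), n = nrow(sub), events = sum(sub$event),
      hr = hr[["hr"]], hr_lower = hr[["lower"]], hr_upper = hr[["upper"]],
      delta_c = cmp$deltaC, delta_c_lower = cmp$ciC[1],
      delta_c_upper = cmp$ciC[2], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' External validation of a composite-score model in a new cohort
#'
#' Scores the external cohort with [applyScore()] (local standardisation by
#' default, appropriate when device placement or wear protocol differs from
#' the derivation cohort), then fits the covariates-only reference model
#' and the score-augmented model on the external cohort only and returns
#' both performance panels, the per-SD hazard ratio of composite score 1
#' and the bootstrap comparison.
#'
#' @param model A [SplsCoxModel-class].
#' @param features External participants x features matrix.
#' @param records External data.frame with outcome and covariates.
#' @param covariates Covariate design columns.
#' @param standardization Passed to [applyScore()].
#' @param B,seed Bootstrap settings.
#' @return List: `hr`, `panelRef`, `panelAug`, `comparison`, `records`.
#' @export
externalValidation <- function(model, features, records,
                               covariates = character(),
                               standardization = "local",
                               B = 1000L, seed = 1L) {
  sc <- applyScore(model, features, standardization)
  rec <- records
  rec$score1 <- as.numeric(scale(sc[, 1]))
  fitRef <- fitCoxModel(rec, covariates)
  fitAug <- fitCoxModel(rec, c(covariates, "score1"))
  list(hr = hazardRatioPerSD(fitAug, "score1"),
       panelRef = performancePanel(fitRef),
       panelAug = performancePanel(fitAug),
       comparison = compareNestedModels(rec, covariates,
                                        c(covariates, "score1"),
                                        B = B, seed = seed),
       records = rec)
}
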