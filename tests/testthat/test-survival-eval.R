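test_that("Cox coefficient matches a profile-likelihood oracle", {
  rec <- data.frame(time_years = c(1, 2, 3, 4, 5, 6, 7, 8) + 0.1,
                    event = c(1, 0, 1, 1, 0, 1, 1, 0),
                    x = c(1, 1, 0, 1, 0, 0, 1, 0))
  fit <- fitCoxModel(rec, "x")
  ora <- oracleCoxCoef(rec$time_years, rec$event, rec$x)
  expect_equal(unname(fit$coef["x"]), ora, tolerance = 1e-6)
  expect_equal(fit$aic, -2 * fit$loglik + 2, tolerance = 1e-9)
})

test_that("a constant covariate contributes nothing but its AIC penalty", {
  rec <- simTwoGroup(200, log(2), seed = 7)
  rec$zero <- 0
  f0 <- fitCoxModel(rec, character())
  fz <- fitCoxModel(rec, "zero")
  expect_equal(unname(fz$coef["zero"]), 0)
  expect_equal(fz$loglik, f0$loglik)
  expect_equal(fz$aic, f0$aic + 2)
})

test_that("two-group exponential data recover the true hazard ratio", {
  rec <- simTwoGroup(20000, log(2), seed = 9)
  fit <- fitCoxModel(rec, "g")
  expect_gt(exp(fit$coef[["g"]]), 1.9)
  expect_lt(exp(fit$coef[["g"]]), 2.1)
})

test_that("degenerate designs are rejected", {
  rec <- simTwoGroup(100, log(2), seed = 11)
  rec$g2 <- rec$g
  expect_error(fitCoxModel(rec, c("g", "g2")), "rank deficient")
  rec0 <- rec; rec0$event <- 0
  expect_error(fitCoxModel(rec0, "g"), "event")
})

test_that("per-SD hazard ratios use the Wald formula and demand SD 1", {
  rec <- simTwoGroup(2000, log(1.5), seed = 13)
  rec$z <- as.numeric(scale(rec$g + rnorm(2000, 0, 0.3)))
  fit <- fitCoxModel(rec, c("z", "g"))
  hr <- hazardRatioPerSD(fit, "z")
  b <- fit$coef[["z"]]; se <- fit$se[["z"]]
  expect_equal(unname(hr), unname(exp(c(b, b - 1.96 * se, b + 1.96 * se))))
  expect_error(hazardRatioPerSD(fit, "g"), "not standardised")
})

test_that("concordance matches trivial cases and the pair-count oracle", {
  expect_equal(harrellC(c(3, 2, 1), c(1, 2, 3), c(1, 1, 0)), 1)
  expect_equal(harrellC(c(1, 2, 3), c(1, 2, 3), c(1, 1, 0)), 0)
  set.seed(17)
  lp <- sample(rnorm(50), 200, replace = TRUE) # some predictor ties
  time <- round(runif(200, 0, 10), 2)          # and some time ties
  event <- rbinom(200, 1, 0.5)
  expect_equal(harrellC(lp, time, event), oracleC(lp, time, event))
  # reversal symmetry without predictor ties
  lp2 <- rnorm(200)
  expect_equal(harrellC(-lp2, time, event), 1 - harrellC(lp2, time, event))
  expect_error(harrellC(1, 5, 0), "comparable")
})

test_that("Royston R2_D behaves at the null, formula zero, and monotonically", {
  set.seed(19)
  rec <- simTwoGroup(2000, 0, seed = 19)
  expect_lt(roystonR2D(rnorm(2000), rec$time_years, rec$event), 0.02)
  expect_warning(r0 <- roystonR2D(rep(1, 100), rec$time_years[1:100],
                                  rec$event[1:100]), "constant")
  expect_equal(r0, 0)
  r2 <- vapply(c(0, 0.2, 0.4, 0.8), function(b) {
    set.seed(100 + round(100 * b))
    x <- rnorm(5000)
    t <- rexp(5000, rate = 0.1 * exp(b * x))
    roystonR2D(x, pmin(t, 15), as.integer(t <= 15))
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 >= 0 & r2 < 1))
})

test_that("Youden cutoff equals an exhaustive scan and handles separation", {
  sep <- youdenCutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(sep["sensitivity"]), 100)
  expect_equal(unname(sep["specificity"]), 100)
  hand <- list(score = c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2),
               event = c(0, 1, 0, 1, 1, 0))
  got <- youdenCutoff(hand$score, hand$event)
  ora <- oracleYouden(hand$score, hand$event)
  expect_equal(unname(got["cutoff"]), ora$cutoff)
  expect_equal(unname(got["sensitivity"]), ora$sens)
  expect_equal(unname(got["specificity"]), ora$spec)
  set.seed(23)
  for (i in 1:25) {
    sc <- round(runif(40), 2)
    ev <- rbinom(40, 1, 0.4)
    if (length(unique(ev)) < 2) next
    g <- youdenCutoff(sc, ev)
    o <- oracleYouden(sc, ev)
    expect_equal(unname(g["cutoff"]), o$cutoff)
  }
  expect_error(youdenCutoff(1:5, rep(1, 5)), "both outcome classes")
  # independent of outcome: Youden index stays small
  set.seed(29)
  scN <- rnorm(2000); evN <- rbinom(2000, 1, 0.3)
  yN <- youdenCutoff(scN, evN)
  expect_lt(yN[["sensitivity"]] / 100 + yN[["specificity"]] / 100 - 1, 0.08)
})

test_that("performance panel is internally consistent", {
  rec <- simTwoGroup(500, log(2), seed = 31)
  fit <- fitCoxModel(rec, "g")
  pan <- performancePanel(fit)
  expect_equal(pan$aic, fit$aic)
  expect_equal(pan$c, harrellC(fit$lp, rec$time_years, rec$event))
  expect_true(pan$c >= 0 && pan$c <= 1)
  expect_true(pan$r2d >= 0 && pan$r2d < 1)
  expect_true(pan$sensitivity >= 0 && pan$sensitivity <= 100)
  expect_true(pan$specificity >= 0 && pan$specificity <= 100)
})

test_that("nested-model comparison: exact point deltas, determinism, nesting", {
  rec <- simTwoGroup(300, log(2), seed = 37)
  rec$noise <- rnorm(300)
  cmp <- compareNestedModels(rec, "g", c("g", "noise"), B = 1, seed = 3)
  fR <- fitCoxModel(rec, "g"); fA <- fitCoxModel(rec, c("g", "noise"))
  expect_equal(cmp$deltaAIC, fA$aic - fR$aic)
  expect_equal(cmp$deltaC,
               harrellC(fA$lp, rec$time_years, rec$event) -
                 harrellC(fR$lp, rec$time_years, rec$event))
  cmp2 <- compareNestedModels(rec, "g", c("g", "noise"), B = 1, seed = 3)
  expect_identical(cmp, cmp2)
  expect_error(compareNestedModels(rec, "noise", "g"), "nested")
  expect_true(all(diff(cmp$ciC) >= 0) && all(diff(cmp$ciAIC) >= 0))
})

test_that("augmented log-likelihood never decreases", {
  rec <- simTwoGroup(400, log(1.5), seed = 41)
  rec$noise <- rnorm(400)
  fR <- fitCoxModel(rec, "g")
  fA <- fitCoxModel(rec, c("g", "noise"))
  expect_gte(fA$loglik, fR$loglik - 1e-9)
})

test_that("spline nonlinearity test detects curvature and respects its df", {
  set.seed(43)
  n <- 2000
  x <- rnorm(n)
  t <- rexp(n, rate = 0.08 * exp(0.5 * x^2))
  rec <- data.frame(time_years = pmin(t, 15), event = as.integer(t <= 15),
                    score = x)
  res <- splineNonlinearityTest(rec, "score")
  expect_lt(res$p.value, 0.01)
  expect_equal(res$df, 1)
  expect_gte(res$statistic, 0)
  lowVar <- rec; lowVar$score <- rep(c(0, 0, 0, 1), n / 4)
  expect_error(splineNonlinearityTest(lowVar, "score"), "knots")
})

test_that("subgroup analysis reduces to the unstratified result and flags empties", {
  rec <- simTwoGroup(400, log(2), seed = 47)
  rec$score <- as.numeric(scale(rec$g + rnorm(400, 0, 0.5)))
  rec$all <- "everyone"
  sg <- subgroupAnalysis(rec, "score", "all", covariates = "g",
                         B = 25, seed = 5)
  fit <- fitCoxModel(rec, c("g", "score"))
  hr <- hazardRatioPerSD(fit, "score")
  expect_equal(sg$hr, unname(hr["hr"]))
  cmp <- compareNestedModels(rec, "g", c("g", "score"), B = 25, seed = 5)
  expect_equal(sg$delta_c, cmp$deltaC)
  rec$grp <- ifelse(seq_len(400) <= 20, "tiny", "rest")
  rec$event[rec$grp == "tiny"] <- 0
  expect_warning(sg2 <- subgroupAnalysis(rec, "score", "grp",
                                         covariates = "g", B = 25, seed = 5),
                 "no events")
  expect_equal(sg2$group, "rest")
})

test_that("external validation on the derivation cohort reproduces the internal panel", {
  spec <- cohortSpec(n = 500, seed = 53,
                     baseline = list(dist = "exponential", rate = 0.05))
  co <- addSimulatedSurvival(simulateFeatureCohort(spec), spec)
  pd <- participantData(co)
  X <- featureMatrix(co)
  m <- fitSplsCox(X, pd$time_years, pd$event, K = 1, eta = 0.4)
  ev <- externalValidation(m, X, pd, covariates = c("age", "sex"),
                           standardization = "derivation", B = 10, seed = 7)
  # identity transport: same records, same score, same panel
  rec <- pd
  rec$score1 <- as.numeric(scale(applyScore(m, X, "derivation")[, 1]))
  fit2 <- fitCoxModel(rec, c("age", "sex", "score1"))
  expect_equal(unclass(ev$panelAug), unclass(performancePanel(fit2)))
  expect_equal(unname(ev$hr), unname(hazardRatioPerSD(fit2, "score1")))
})

test_that("a score unrelated to the external outcome shows no association", {
  covers <- 0L
  for (i in 1:40) {
    set.seed(6000 + i)
    n <- 400
    x <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    t <- rexp(n, 0.05)
    rec <- data.frame(time_years = pmin(t, 10),
                      event = as.integer(t <= 10))
    rec$score1 <- as.numeric(scale(x[, 1]))
    fit <- fitCoxModel(rec, "score1")
    hr <- hazardRatioPerSD(fit, "score1")
    if (hr["lower"] <= 1 && hr["upper"] >= 1) covers <- covers + 1L
  }
  expect_gte(covers, 33) # ~95% nominal coverage
})
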