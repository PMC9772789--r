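test_that("epoch classification uses the 40/100 mg boundary semantics", {
  expect_identical(classifyEpochs(c(0, 39.99, 40, 99.9, 100, 400)),
                   c("SB", "SB", "LIPA", "LIPA", "MVPA", "MVPA"))
  expect_identical(unique(classifyEpochs(rep(0, 100))), "SB")
  expect_error(classifyEpochs(1:3, 40, 40), "thresholds")
  expect_error(classifyEpochs(c(5, -1, 7)), "epoch 2")
})

test_that("bout detection equals a run-length-encoding oracle", {
  lab <- c(rep("SB", 10), rep("LIPA", 5), rep("SB", 3))
  b <- detectBouts(lab)
  expect_equal(b$length_min, c(10, 5, 3))
  expect_equal(b$state, c("SB", "LIPA", "SB"))

  b1 <- detectBouts(c("SB", "LIPA", "SB"))
  expect_equal(b1$length_min, c(1, 1, 1))

  set.seed(7)
  for (i in 1:50) {
    lab <- sample(c("SB", "LIPA", "MVPA"), 1000, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
    day <- sort(sample(1:3, 1000, replace = TRUE))
    got <- detectBouts(lab, day)
    ora <- oracleRLE(lab, day)
    expect_equal(got$state, ora$state)
    expect_equal(got$length_min, ora$length_min)
    expect_equal(got$start, ora$start)
  }
})

test_that("a day boundary always terminates a bout", {
  b <- detectBouts(rep("SB", 20), rep(1:2, each = 10))
  expect_equal(nrow(b), 2)
  expect_equal(b$length_min, c(10, 10))
})

test_that("the worked 960-min trace yields the hand-computed features", {
  fv <- extractFeatures(makeTrace960())
  expect_equal(unname(fv["mean_acceleration"]),
               (600 * 20 + 300 * 60 + 60 * 150) / 960)
  expect_equal(unname(fv["mean_acceleration"]), 40.625)
  expect_equal(unname(fv[c("dur_SB", "dur_LIPA", "dur_MVPA")]),
               c(600, 300, 60))
  expect_equal(unname(fv[c("n_bouts_SB", "n_bouts_LIPA", "n_bouts_MVPA")]),
               c(1, 1, 1))
  expect_equal(unname(fv["mean_bout_SB"]), 600)
  expect_equal(unname(fv[c("sb_lt10", "sb_10_30", "sb_ge30")]),
               c(0, 0, 600))
  expect_equal(unname(fv[c("mvpa_lt10", "mvpa_ge10")]), c(0, 60))
  expect_equal(unname(fv[c("lipa_lt10", "lipa_ge10")]), c(0, 300))
  expect_equal(unname(fv["days_mvpa30"]), 1)
  # most active 5-h window starts at the 661st waking epoch (07:00 + 11 h)
  expect_equal(unname(fv["timing_pa"]), 7 + 11)
})

test_that("sedentary bout categories split at 10 and 30 minutes", {
  mk <- function(sbLen) {
    mg <- c(rep(60, 400), rep(20, sbLen), rep(60, 560 - sbLen))
    data.frame(participant_id = "p", day_index = 1L,
               epoch_index = seq_along(mg) - 1L,
               timestamp_iso8601 = "x", enmo_mg = mg, waking = 1L)
  }
  fv29 <- extractFeatures(mk(29))
  expect_equal(unname(fv29["sb_10_30"]), 29)
  expect_equal(unname(fv29["sb_ge30"]), 0)
  fv30 <- extractFeatures(mk(30))
  expect_equal(unname(fv30["sb_10_30"]), 0)
  expect_equal(unname(fv30["sb_ge30"]), 30)
})

test_that("feature-vector identities hold on random traces", {
  for (i in 1:100) {
    ep <- randomEpochDF(nDays = sample(1:3, 1), seed = 1000 + i)
    fv <- extractFeatures(ep)
    waking <- nrow(ep) / length(unique(ep$day_index))
    expect_equal(unname(fv["dur_SB"] + fv["dur_LIPA"] + fv["dur_MVPA"]),
                 waking)
    expect_equal(unname(fv["sb_lt10"] + fv["sb_10_30"] + fv["sb_ge30"]),
                 unname(fv["dur_SB"]))
    expect_equal(unname(fv["lipa_lt10"] + fv["lipa_ge10"]),
                 unname(fv["dur_LIPA"]))
    expect_equal(unname(fv["mvpa_lt10"] + fv["mvpa_ge10"]),
                 unname(fv["dur_MVPA"]))
    for (s in c("SB", "LIPA", "MVPA"))
      expect_equal(unname(fv[paste0("mean_bout_", s)] *
                            fv[paste0("n_bouts_", s)]),
                   unname(fv[paste0("dur_", s)]))
    expect_true(all(fv[setdiff(featureNames21(),
                               c("intensity_gradient",
                                 "intensity_intercept"))] >= 0))
    # cross-check durations against an independent per-day tabulation
    lab <- classifyEpochs(ep$enmo_mg)
    tot <- Reduce(`+`, lapply(split(lab, ep$day_index),
                              function(l) oracleDayTotals(l)$dur))
    expect_equal(unname(fv[c("dur_SB", "dur_LIPA", "dur_MVPA")]),
                 unname(tot) / length(unique(ep$day_index)))
  }
})

test_that("features are invariant to day concatenation order", {
  d1 <- randomEpochDF(1, seed = 5)
  d2 <- randomEpochDF(1, seed = 6)
  d2$day_index <- 2L
  fv12 <- extractFeatures(rbind(d1, d2))
  fv21 <- extractFeatures(rbind(d2, d1))
  expect_equal(fv12, fv21)
})

test_that("intensity gradient recovers a constructed power law", {
  # bin minutes proportional to midpoint^-2 across bins 12.5-487.5 mg
  mids <- (seq_len(20) - 0.5) * 25
  minutes <- round(2e5 / mids^2)
  keep <- minutes > 0
  mg <- rep(mids[keep], minutes[keep])
  got <- intensityDistribution(mg, nDays = 1)
  ora <- lm(log(minutes[keep]) ~ log(mids[keep]))
  expect_equal(unname(got["intensity_gradient"]),
               unname(coef(ora)[2]), tolerance = 1e-10)
  expect_equal(unname(got["intensity_intercept"]),
               unname(coef(ora)[1]), tolerance = 1e-10)
  expect_lt(abs(got["intensity_gradient"] + 2), 0.05)
})

test_that("two occupied bins give the two-point slope and one bin errors", {
  mg <- c(rep(10, 120), rep(60, 30))
  got <- intensityDistribution(mg, nDays = 1)
  expect_equal(unname(got["intensity_gradient"]),
               (log(30) - log(120)) / (log(62.5) - log(12.5)))
  expect_error(intensityDistribution(rep(10, 50)), "2 non-empty")
})

test_that("plausible simulated profiles give a negative gradient", {
  prof <- activityProfile(days = 2L)
  ep <- simulateEpochSeries(prof, 3, seed = 17)
  for (p in unique(ep$participant_id)) {
    fv <- extractFeatures(ep[ep$participant_id == p, ])
    expect_lt(fv[["intensity_gradient"]], -1)
    expect_gt(fv[["intensity_gradient"]], -3.5)
  }
})

test_that("M5 timing matches exhaustive window search and tie rules", {
  # constant day: earliest window wins, start = waking start (07:00)
  flat <- makeTrace960()
  flat$enmo_mg <- 25
  expect_equal(timingM5(flat), 7)
  # single 5-h high block starting at epoch 101
  blk <- makeTrace960()
  blk$enmo_mg <- c(rep(10, 100), rep(200, 300), rep(10, 560))
  expect_equal(timingM5(blk), 7 + 100 / 60)
  for (i in 1:100) {
    ep <- randomEpochDF(1, minutes = 400L, seed = 2000 + i)
    got <- timingM5(ep)
    ora <- oracleM5(ep$enmo_mg)
    expect_equal(got, (420 + ora - 1) / 60)
  }
  short <- makeTrace960()[1:200, ]
  expect_error(timingM5(short), "5 h")
})

test_that("waking-period standardisation rescales durations and counts", {
  fv <- extractFeatures(makeTrace960())
  expect_equal(standardizeByWaking(fv, 960, reference = 960), fv)
  half <- standardizeByWaking(fv, 1920, reference = 960)
  expect_equal(unname(half["dur_SB"]), unname(fv["dur_SB"]) / 2)
  expect_equal(unname(half["n_bouts_SB"]), unname(fv["n_bouts_SB"]) / 2)
  expect_equal(unname(half["mean_acceleration"]),
               unname(fv["mean_acceleration"]))
  expect_equal(unname(half["timing_pa"]), unname(fv["timing_pa"]))
  expect_equal(unname(half["dur_SB"] + half["dur_LIPA"] + half["dur_MVPA"]),
               960 / 2)
  expect_error(standardizeByWaking(fv, 0), "positive")
  # identities survive rescaling on random vectors
  for (i in 1:20) {
    ep <- randomEpochDF(1, seed = 3000 + i)
    f0 <- extractFeatures(ep)
    f1 <- standardizeByWaking(f0, 960, reference = 840)
    expect_equal(unname(f1["sb_lt10"] + f1["sb_10_30"] + f1["sb_ge30"]),
                 unname(f1["dur_SB"]))
    expect_equal(unname(f1["dur_SB"] + f1["dur_LIPA"] + f1["dur_MVPA"]), 840)
  }
})

test_that("extraction requires waking epochs", {
  ep <- makeTrace960()
  ep$waking <- 0L
  expect_error(extractFeatures(ep), "zero retained days")
})
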