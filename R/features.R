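#' Classify 60-s epochs into SB / LIPA / MVPA
#'
#' Intensity classification of waking epochs: below `sbThreshold` mg is
#' sedentary behaviour, from `sbThreshold` up to (excluding)
#' `mvpaThreshold` is light-intensity activity, and at or above
#' `mvpaThreshold` is moderate-to-vigorous activity.
#'
#' @param enmo Numeric vector of epoch-average accelerations (mg, >= 0).
#' @param sbThreshold,mvpaThreshold Thresholds in mg,
#'   `0 < sbThreshold < mvpaThreshold`.
#' @return Character vector of labels `"SB"`, `"LIPA"`, `"MVPA"`.
#' @examples
#' classifyEpochs(c(0, 39.99, 40, 99.9, 100, 250))
#' @export
classifyEpochs <- function(enmo, sbThreshold = 40, mvpaThreshold = 100) {
  if (sbThreshold <= 0 || sbThreshold >= mvpaThreshold)
    stop("thresholds must satisfy 0 < sbThreshold < mvpaThreshold")
  bad <- which(enmo < 0)
  if (length(bad))
    stop(sprintf("negative acceleration at epoch %d (%.3f mg)",
                 bad[1], enmo[bad[1]]))
  ifelse(enmo < sbThreshold, "SB",
         ifelse(enmo < mvpaThreshold, "LIPA", "MVPA"))
}

#' Detect activity bouts (maximal uninterrupted same-state runs)
#'
#' A bout is a maximal run of consecutive waking epochs carrying the same
#' state; a day boundary always terminates a bout. No interruption
#' tolerance is applied.
#'
#' @param labels Character vector of epoch states (from [classifyEpochs()]).
#' @param dayIndex Optional integer vector of the same length; runs never
#'   cross a change in `dayIndex`.
#' @return data.frame with `day`, `state`, `start` (1-based epoch position
#'   within the day's waking sequence) and `length_min`.
#' @export
detectBouts <- function(labels, dayIndex = NULL) {
  if (is.null(dayIndex)) dayIndex <- rep(1L, length(labels))
  out <- lapply(split(seq_along(labels), dayIndex), function(ii) {
    r <- rle(labels[ii])
    ends <- cumsum(r$lengths)
    data.frame(day = dayIndex[ii[1]], state = r$values,
               start = c(1L, head(ends, -1L) + 1L),
               length_min = r$lengths, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intensity distribution: log-log intercept and gradient
#'
#' Waking epochs are binned by acceleration into fixed-width intensity bins
#' starting at 0 mg; ordinary least squares of `ln(minutes per day in bin)`
#' on `ln(bin midpoint)` over the non-empty bins yields the intercept and
#' the (negative) gradient describing how accumulated time drops off with
#' intensity.
#'
#' @param enmo Waking-epoch accelerations (mg), pooled over days.
#' @param nDays Number of recorded days (bin minutes are per-day averages).
#' @param binWidth Bin width in mg (default 25).
#' @return Named numeric: `intensity_intercept`, `intensity_gradient`.
#' @export
intensityDistribution <- function(enmo, nDays = 1L, binWidth = 25) {
  stopifnot(binWidth > 0, nDays >= 1)
  bin <- floor(enmo / binWidth)
  tab <- table(bin)
  if (length(tab) < 2L)
    stop("need at least 2 non-empty intensity bins to fit a gradient")
  mid <- (as.numeric(names(tab)) + 0.5) * binWidth
  minutes <- as.numeric(tab) / nDays
  fit <- lm(log(minutes) ~ log(mid))
  c(intensity_intercept = unname(coef(fit)[1]),
    intensity_gradient = unname(coef(fit)[2]))
}

# start position (1-based, within the day's waking sequence) of the
# maximal-sum 300-epoch window; earliest window wins ties
.m5Start <- function(enmo, windowEpochs = 300L) {
  n <- length(enmo)
  cs <- c(0, cumsum(enmo))
  sums <- cs[(windowEpochs + 1L):(n + 1L)] - cs[1:(n - windowEpochs + 1L)]
  which.max(sums) # which.max returns the first maximum
}

#' Timing of physical activity: start of the most active 5 consecutive hours
#'
#' For each retained day, finds the 300-consecutive-epoch waking window with
#' the maximal summed acceleration (earliest window on ties) and reports its
#' start in clock hours; the per-day starts are averaged.
#'
#' @param epochs Single-participant epoch data.frame (epoch dialect); only
#'   `waking == 1` rows are used.
#' @return Mean start time in clock hours.
#' @export
timingM5 <- function(epochs) {
  w <- epochs[epochs$waking == 1, , drop = FALSE]
  starts <- vapply(split(w, w$day_index), function(day) {
    if (nrow(day) < 300L) return(NA_real_)
    day <- day[order(day$epoch_index), , drop = FALSE]
    day$epoch_index[.m5Start(day$enmo_mg)] / 60
  }, numeric(1))
  starts <- starts[!is.na(starts)]
  if (!length(starts))
    stop("waking period is shorter than 5 h on every day")
  mean(starts)
}

#' Extract the 21 movement-behaviour features for one participant
#'
#' Per-day quantities (state durations, bout-category times, bout counts)
#' are computed day by day and averaged with equal weight over retained
#' days; mean bout durations are ratios of sums (total state time over
#' total bout count) so that `mean_bout x n_bouts = duration` holds exactly
#' at the participant level; `days_mvpa30` is the count of days with at
#' least 30 min of MVPA; the intensity intercept/gradient and M5 timing are
#' delegated to [intensityDistribution()] and [timingM5()].
#'
#' @param epochs Single-participant epoch data.frame (epoch dialect).
#' @param sbThreshold,mvpaThreshold Classification thresholds (mg).
#' @param binWidth Intensity-bin width (mg).
#' @return Named numeric vector of the 21 features ([featureNames21()]).
#' @export
extractFeatures <- function(epochs, sbThreshold = 40, mvpaThreshold = 100,
                            binWidth = 25) {
  w <- epochs[epochs$waking == 1, , drop = FALSE]
  if (nrow(w) == 0L) stop("no waking epochs: zero retained days")
  w <- w[order(w$day_index, w$epoch_index), , drop = FALSE]
  lab <- classifyEpochs(w$enmo_mg, sbThreshold, mvpaThreshold)
  bouts <- detectBouts(lab, w$day_index)
  days <- unique(w$day_index)
  nDays <- length(days)

  dur <- numeric(3); names(dur) <- ACTIVITY_STATES
  nB <- dur
  for (s in ACTIVITY_STATES) {
    bs <- bouts[bouts$state == s, , drop = FALSE]
    dur[s] <- sum(bs$length_min) / nDays
    nB[s] <- nrow(bs) / nDays
  }
  meanBout <- ifelse(nB > 0, dur / nB, 0)

  catTime <- function(state, lo, hi) {
    bs <- bouts[bouts$state == state &
                  bouts$length_min >= lo & bouts$length_min < hi, ,
                drop = FALSE]
    sum(bs$length_min) / nDays
  }
  mvpaByDay <- vapply(split(lab, w$day_index),
                      function(x) sum(x == "MVPA"), numeric(1))

  c(mean_acceleration = mean(w$enmo_mg),
    dur_SB = unname(dur["SB"]), dur_LIPA = unname(dur["LIPA"]),
    dur_MVPA = unname(dur["MVPA"]),
    mean_bout_SB = unname(meanBout["SB"]),
    mean_bout_LIPA = unname(meanBout["LIPA"]),
    mean_bout_MVPA = unname(meanBout["MVPA"]),
    sb_lt10 = catTime("SB", 0, 10),
    sb_10_30 = catTime("SB", 10, 30),
    sb_ge30 = catTime("SB", 30, Inf),
    lipa_lt10 = catTime("LIPA", 0, 10),
    lipa_ge10 = catTime("LIPA", 10, Inf),
    mvpa_lt10 = catTime("MVPA", 0, 10),
    mvpa_ge10 = catTime("MVPA", 10, Inf),
    n_bouts_SB = unname(nB["SB"]), n_bouts_LIPA = unname(nB["LIPA"]),
    n_bouts_MVPA = unname(nB["MVPA"]),
    days_mvpa30 = sum(mvpaByDay >= 30),
    intensityDistribution(w$enmo_mg, nDays = nDays, binWidth = binWidth),
    timing_pa = timingM5(epochs))
}

#' Extract features for every participant in an epoch table
#'
#' @param epochs Multi-participant epoch data.frame (epoch dialect).
#' @inheritParams extractFeatures
#' @return Numeric matrix, participants x 21, rownames = participant ids.
#' @export
extractCohortFeatures <- function(epochs, sbThreshold = 40,
                                  mvpaThreshold = 100, binWidth = 25) {
  byP <- split(epochs, epochs$participant_id)
  X <- t(vapply(byP, extractFeatures, numeric(21),
                sbThreshold = sbThreshold, mvpaThreshold = mvpaThreshold,
                binWidth = binWidth))
  colnames(X) <- featureNames21()
  X
}

#' Rescale duration and frequency features to a reference waking period
#'
#' Duration-type features (state totals and bout-category times, min/day)
#' and bout counts are multiplied by `reference / wakingMinutes`; mean bout
#' durations, `days_mvpa30`, intensity and timing features are left
#' unchanged. The tiling and category-additivity identities of the feature
#' vector are preserved, now relative to the reference period.
#'
#' @param fv Named feature vector ([featureNames21()]) or a participants x
#'   21 matrix.
#' @param wakingMinutes Actual waking duration (min/day), > 0.
#' @param reference Reference waking duration (min/day).
#' @return Rescaled feature vector or matrix.
#' @export
standardizeByWaking <- function(fv, wakingMinutes, reference = 960) {
  if (any(wakingMinutes <= 0)) stop("waking duration must be positive")
  scaled <- c("dur_SB", "dur_LIPA", "dur_MVPA",
              "sb_lt10", "sb_10_30", "sb_ge30",
              "lipa_lt10", "lipa_ge10", "mvpa_lt10", "mvpa_ge10",
              "n_bouts_SB", "n_bouts_LIPA", "n_bouts_MVPA")
  f <- reference / wakingMinutes
  if (is.matrix(fv)) fv[, scaled] <- fv[, scaled] * f
  else fv[scaled] <- fv[scaled] * f
  fv
}
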