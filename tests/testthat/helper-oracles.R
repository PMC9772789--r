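# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths.

# run-length encoding by explicit loop
oracleRLE <- function(labels, dayIndex = rep(1L, length(labels))) {
  out <- list()
  start <- 1L
  for (i in seq_along(labels)[-1]) {
    if (labels[i] != labels[i - 1L] || dayIndex[i] != dayIndex[i - 1L]) {
      out[[length(out) + 1L]] <- data.frame(
        day = dayIndex[start], state = labels[start], start = start,
        length_min = i - start, stringsAsFactors = FALSE)
      start <- i
    }
  }
  out[[length(out) + 1L]] <- data.frame(
    day = dayIndex[start], state = labels[start], start = start,
    length_min = length(labels) - start + 1L, stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  # re-express start positions within each day
  for (d in unique(res$day)) {
    ii <- res$day == d
    off <- min(which(dayIndex == d)) - 1L
    res$start[ii] <- res$start[ii] - off
  }
  res
}

# O(n^2) concordance pair count
oracleC <- function(lp, time, event) {
  conc <- 0; comp <- 0
  n <- length(lp)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      comp <- comp + 1
      if (lp[i] > lp[j]) conc <- conc + 1
      else if (lp[i] == lp[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# exhaustive search for the maximal-sum 300-epoch window (earliest on ties)
oracleM5 <- function(enmo, window = 300L) {
  n <- length(enmo)
  sums <- vapply(seq_len(n - window + 1L),
                 function(s) sum(enmo[s:(s + window - 1L)]), numeric(1))
  which(sums == max(sums))[1]
}

# exhaustive Youden scan over all midpoints
oracleYouden <- function(score, event) {
  u <- sort(unique(score))
  cuts <- (head(u, -1) + u[-1]) / 2
  best <- NULL
  for (cc in cuts) {
    sens <- mean(score[event == 1] >= cc)
    spec <- mean(score[event == 0] < cc)
    if (is.null(best) || sens + spec - 1 > best$j + 1e-12)
      best <- list(cutoff = cc, j = sens + spec - 1,
                   sens = 100 * sens, spec = 100 * spec)
  }
  best
}

# profile partial log-likelihood for a single covariate, no ties
oraclePartialLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    atRisk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[atRisk])))
  }
  ll
}

oracleCoxCoef <- function(time, event, x) {
  stats::optimize(oraclePartialLoglik, c(-10, 10), maximum = TRUE,
                  time = time, event = event, x = x,
                  tol = 1e-10)$maximum
}

# Nelson-Aalen + closed-form residual oracle
oracleDevianceResiduals <- function(time, event) {
  n <- length(time)
  Lambda <- numeric(n)
  for (i in seq_len(n)) {
    ut <- sort(unique(time[event == 1 & time <= time[i]]))
    Lambda[i] <- sum(vapply(ut, function(t)
      sum(time == t & event == 1) / sum(time >= t), numeric(1)))
  }
  m <- event - Lambda
  d <- sign(m) * sqrt(-2 * (m + ifelse(event == 1, log(event - m), 0)))
  list(martingale = m, deviance = d)
}

# survival data under a two-group exponential proportional-hazards model
simTwoGroup <- function(n, logHR, baseRate = 0.1, horizon = 20, seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = baseRate * exp(logHR * g))
  data.frame(time_years = pmin(t, horizon),
             event = as.integer(t <= horizon), g = g)
}

# the worked 960-min single-day trace: 600 epochs at 20 mg, 300 at 60 mg,
# 60 at 150 mg, waking start at 07:00
makeTrace960 <- function() {
  mg <- c(rep(20, 600), rep(60, 300), rep(150, 60))
  ep <- 420L + seq_along(mg) - 1L
  data.frame(participant_id = "P0001", day_index = 1L, epoch_index = ep,
             timestamp_iso8601 = sprintf("2013-01-01T%02d:%02d:00",
                                         ep %/% 60L, ep %% 60L),
             enmo_mg = mg, waking = 1L, stringsAsFactors = FALSE)
}

# random epoch day(s) with integer-ish intensity structure
randomEpochDF <- function(nDays = 1L, minutes = 960L, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(nDays), function(d) {
    mg <- sample(c(runif(minutes, 0, 39.9), runif(minutes, 40, 250)),
                 minutes)
    ep <- 420L + seq_len(minutes) - 1L
    data.frame(participant_id = "P0001", day_index = d, epoch_index = ep,
               timestamp_iso8601 = sprintf("2013-01-%02dT%02d:%02d:00", d,
                                           ep %/% 60L, ep %% 60L),
               enmo_mg = mg, waking = 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# per-day independent feature tabulation used by the invariant sweep
oracleDayTotals <- function(labels) {
  r <- rle(labels)
  list(dur = vapply(c("SB", "LIPA", "MVPA"), function(s)
         sum(r$lengths[r$values == s]), numeric(1)),
       nBouts = vapply(c("SB", "LIPA", "MVPA"), function(s)
         sum(r$values == s), numeric(1)))
}
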