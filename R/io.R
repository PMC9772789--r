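#' Read / write the epoch CSV dialect
#'
#' One row per 60-s epoch with columns `participant_id`, `day_index`,
#' `epoch_index`, `timestamp_iso8601`, `enmo_mg`, `waking` (0/1).
#'
#' @param path CSV file.
#' @return data.frame in the epoch dialect.
#' @export
readEpochCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day_index", "epoch_index",
            "timestamp_iso8601", "enmo_mg", "waking")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("epoch CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (!all(df$waking %in% c(0L, 1L)))
    stop("waking must be 0/1")
  df
}

#' @rdname readEpochCSV
#' @param epochs Epoch data.frame.
#' @export
writeEpochCSV <- function(epochs, path) {
  write.csv(epochs, path, row.names = FALSE)
  invisible(path)
}

#' Read / write the participant-level cohort CSV
#'
#' One row per participant: `participant_id`, the 21 canonical feature
#' columns, any covariate columns, `time_years`, `event`.
#'
#' @param path CSV file.
#' @return An [ActivityCohort-class].
#' @export
readCohortCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  fn <- featureNames21()
  miss <- setdiff(fn, names(df))
  if (length(miss))
    stop(sprintf("cohort CSV is missing feature column(s): %s",
                 paste(miss, collapse = ", ")))
  X <- as.matrix(df[, fn, drop = FALSE])
  if ("participant_id" %in% names(df)) rownames(X) <- df$participant_id
  cd <- df[, setdiff(names(df), c(fn, "participant_id")), drop = FALSE]
  activityCohort(X, colData = if (ncol(cd)) cd else NULL)
}

#' @rdname readCohortCSV
#' @param cohort An [ActivityCohort-class].
#' @export
writeCohortCSV <- function(cohort, path) {
  df <- data.frame(participant_id = colnames(cohort),
                   featureMatrix(cohort),
                   participantData(cohort),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
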