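#' @import methods
#' @importFrom stats coef quantile rnorm runif rexp rbinom rgeom rlnorm rbeta
#'   sd setNames qnorm pnorm pchisq ks.test cor lm predict residuals var
#'   complete.cases
#' @importFrom utils head read.csv write.csv packageVersion modifyList
#' @importFrom Rcpp sourceCpp
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @useDynLib actisurv, .registration = TRUE
NULL

ACTIVITY_STATES <- c("SB", "LIPA", "MVPA")

#' Canonical names of the 21 movement-behaviour features
#'
#' The feature set spans six dimensions of daily movement behaviour:
#' overall activity level (`mean_acceleration`, mg), total duration per state
#' (`dur_SB`, `dur_LIPA`, `dur_MVPA`, min/day), bout duration
#' (`mean_bout_*` in min; sedentary time split into bouts of `[0,10)`,
#' `[10,30)` and `[30,Inf)` min as `sb_lt10`, `sb_10_30`, `sb_ge30`;
#' LIPA/MVPA split at 10 min), frequency (`n_bouts_*` per day and
#' `days_mvpa30`, the count of days with at least 30 min of MVPA),
#' intensity distribution (`intensity_intercept`, `intensity_gradient` from
#' the log-log fit of accumulated time on intensity) and timing
#' (`timing_pa`, clock-hour start of the most active 5 consecutive hours).
#'
#' @return Character vector of length 21.
#' @export
featureNames21 <- function() {
  c("mean_acceleration",
    "dur_SB", "dur_LIPA", "dur_MVPA",
    "mean_bout_SB", "mean_bout_LIPA", "mean_bout_MVPA",
    "sb_lt10", "sb_10_30", "sb_ge30",
    "lipa_lt10", "lipa_ge10", "mvpa_lt10", "mvpa_ge10",
    "n_bouts_SB", "n_bouts_LIPA", "n_bouts_MVPA",
    "days_mvpa30",
    "intensity_intercept", "intensity_gradient",
    "timing_pa")
}

#' ActivityProfile: generative model of a day of waking movement behaviour
#'
#' A semi-Markov bout process over the states SB (sedentary, <40 mg),
#' LIPA (light, 40-99 mg) and MVPA (moderate-to-vigorous, >=100 mg).
#' States alternate according to a transition matrix with zero diagonal;
#' each bout has a positive duration in whole 60-s epochs; each epoch draws
#' one intensity value (mg) from its state's emission distribution, whose
#' support respects the classification thresholds so that the generating
#' state of every epoch can be recovered exactly by thresholding.
#'
#' @slot states Character vector, subset of c("SB","LIPA","MVPA").
#' @slot transition Square transition matrix over `states`, zero diagonal,
#'   rows summing to 1 (ignored for single-state profiles).
#' @slot boutMeanMin Named numeric, mean bout duration per state (minutes).
#' @slot boutDist Either "geometric" (memoryless on epochs) or "lognormal".
#' @slot boutSdlog Named numeric, log-scale SD per state (lognormal only).
#' @slot emission List per state: `list(shape1, shape2)` of a Beta law
#'   rescaled onto the state's intensity support; MVPA uses
#'   `[100, maxMg]`.
#' @slot wakingMinutes Waking-period duration (min/day), multiple of 1 min.
#' @slot wakingStartHour Clock hour at which the waking period begins.
#' @slot days Number of recorded days per participant (integer >= 1).
#' @slot maxMg Upper bound of the MVPA emission support (mg).
#' @slot sbThreshold,mvpaThreshold Classification thresholds (mg).
#' @export
setClass("ActivityProfile",
  representation(
    states = "character",
    transition = "matrix",
    boutMeanMin = "numeric",
    boutDist = "character",
    boutSdlog = "numeric",
    emission = "list",
    wakingMinutes = "numeric",
    wakingStartHour = "numeric",
    days = "integer",
    maxMg = "numeric",
    sbThreshold = "numeric",
    mvpaThreshold = "numeric"
  )
)

setValidity("ActivityProfile", function(object) {
  msg <- character()
  st <- object@states
  if (length(st) < 1L || !all(st %in% ACTIVITY_STATES))
    msg <- c(msg, "states must be a non-empty subset of SB/LIPA/MVPA")
  if (object@sbThreshold <= 0 || object@sbThreshold >= object@mvpaThreshold)
    msg <- c(msg, "thresholds must satisfy 0 < sbThreshold < mvpaThreshold")
  if (object@wakingMinutes < 1)
    msg <- c(msg, "waking period must contain at least one 60-s epoch")
  if (object@days < 1L)
    msg <- c(msg, "days must be >= 1")
  if (!all(st %in% names(object@boutMeanMin)) ||
      any(!is.finite(object@boutMeanMin[st])) ||
      any(object@boutMeanMin[st] <= 0))
    msg <- c(msg, "bout-duration means must be positive and finite for every state")
  if (!object@boutDist %in% c("geometric", "lognormal"))
    msg <- c(msg, "boutDist must be 'geometric' or 'lognormal'")
  if (length(st) > 1L) {
    tm <- object@transition
    if (is.null(dimnames(tm)) || !identical(rownames(tm), st) ||
        !identical(colnames(tm), st))
      msg <- c(msg, "transition matrix must be named by states")
    else {
      if (any(diag(tm) != 0))
        msg <- c(msg, "self-transitions are not allowed (diagonal must be zero)")
      if (any(abs(rowSums(tm) - 1) > 1e-8) || any(tm < 0))
        msg <- c(msg, "transition rows must be non-negative and sum to 1")
    }
  }
  # emission supports must respect thresholds so states are threshold-recoverable
  sup <- .stateSupports(object@sbThreshold, object@mvpaThreshold, object@maxMg)
  for (s in st) {
    em <- object@emission[[s]]
    if (is.null(em) || any(!is.finite(c(em$shape1, em$shape2))) ||
        em$shape1 <= 0 || em$shape2 <= 0)
      msg <- c(msg, sprintf("emission for state %s must have positive Beta shapes", s))
  }
  if (object@maxMg <= object@mvpaThreshold)
    msg <- c(msg, "maxMg must exceed the MVPA threshold")
  if (length(msg)) msg else TRUE
})

.stateSupports <- function(sb, mvpa, maxMg) {
  list(SB = c(0, sb), LIPA = c(sb, mvpa), MVPA = c(mvpa, maxMg))
}

#' Construct an ActivityProfile
#'
#' Defaults describe an older-adult cohort: roughly three quarters of a
#' 960-min waking day sedentary, short light-activity bouts, a small MVPA
#' fraction, and a cohort mean acceleration close to 32 mg.
#'
#' @param states States permitted in the process.
#' @param transition Transition matrix (zero diagonal). Ignored when a single
#'   state is permitted.
#' @param boutMeanMin Named mean bout durations in minutes.
#' @param boutDist "geometric" or "lognormal" bout-length law (on epochs).
#' @param boutSdlog Log-scale SDs, used when `boutDist = "lognormal"`.
#' @param emission Per-state Beta shape parameters rescaled to the state's
#'   intensity support.
#' @param wakingMinutes Waking duration per day in minutes.
#' @param wakingStartHour Clock hour of waking onset.
#' @param days Recorded days per participant.
#' @param maxMg Upper intensity bound (mg).
#' @param sbThreshold,mvpaThreshold Intensity thresholds in mg.
#' @return A validated [ActivityProfile-class] object.
#' @examples
#' p <- activityProfile()
#' p
#' @export
activityProfile <- function(states = c("SB", "LIPA", "MVPA"),
                            transition = NULL,
                            boutMeanMin = c(SB = 10.5, LIPA = 2.4, MVPA = 2.3),
                            boutDist = "geometric",
                            boutSdlog = c(SB = 0.9, LIPA = 0.5, MVPA = 0.5),
                            emission = list(
                              SB = list(shape1 = 2, shape2 = 3),
                              LIPA = list(shape1 = 2, shape2 = 3.5),
                              MVPA = list(shape1 = 1, shape2 = 4)),
                            wakingMinutes = 960,
                            wakingStartHour = 7,
                            days = 9L,
                            maxMg = 450,
                            sbThreshold = 40,
                            mvpaThreshold = 100) {
  if (is.null(transition)) {
    transition <- matrix(0, 3, 3,
                         dimnames = list(ACTIVITY_STATES, ACTIVITY_STATES))
    transition["SB", ] <- c(0, 0.90, 0.10)
    transition["LIPA", ] <- c(0.83, 0, 0.17)
    transition["MVPA", ] <- c(0.25, 0.75, 0)
    transition <- transition[states, states, drop = FALSE]
    if (length(states) > 1L)
      transition <- sweep(transition, 1, rowSums(transition), "/")
  }
  new("ActivityProfile",
      states = states, transition = as.matrix(transition),
      boutMeanMin = boutMeanMin, boutDist = boutDist, boutSdlog = boutSdlog,
      emission = emission, wakingMinutes = wakingMinutes,
      wakingStartHour = wakingStartHour, days = as.integer(days),
      maxMg = maxMg, sbThreshold = sbThreshold, mvpaThreshold = mvpaThreshold)
}

setMethod("show", "ActivityProfile", function(object) {
  cat("ActivityProfile:", paste(object@states, collapse = "/"),
      sprintf("| waking %g min/day x %d day(s), start %02.0f:00\n",
              object@wakingMinutes, object@days, object@wakingStartHour))
  cat("  bout means (min):",
      paste(sprintf("%s=%.1f", object@states,
                    object@boutMeanMin[object@states]), collapse = ", "),
      sprintf("[%s]\n", object@boutDist))
  cat(sprintf("  thresholds: SB <%g mg, MVPA >=%g mg, max %g mg\n",
              object@sbThreshold, object@mvpaThreshold, object@maxMg))
})

#' ActivityCohort: participant-level features, covariates and survival
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass holding
#' the movement-behaviour feature matrix as the `"features"` assay (features
#' in rows, participants in columns). Survival outcome (`time_years`,
#' `event`), covariates and subgroup labels live in `colData`; simulation
#' ground truth (active set, true coefficients, latent linear predictor) in
#' `metadata()$groundTruth`.
#'
#' @export
setClass("ActivityCohort", contains = "SummarizedExperiment")

setValidity("ActivityCohort", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- SummarizedExperiment::colData(object)
  if ("time_years" %in% colnames(cd)) {
    tt <- cd$time_years
    if (any(!is.finite(tt)) || any(tt < 0))
      msg <- c(msg, "time_years must be finite and non-negative")
    if (!"event" %in% colnames(cd) || !all(cd$event %in% c(0, 1)))
      msg <- c(msg, "event must accompany time_years and be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ActivityCohort
#'
#' @param features Numeric matrix, participants x features (transposed
#'   internally to the assay orientation) with feature column names.
#' @param colData Data frame of per-participant outcome/covariate columns.
#' @param groundTruth Optional list stored in `metadata()$groundTruth`.
#' @return An [ActivityCohort-class].
#' @export
activityCohort <- function(features, colData = NULL, groundTruth = NULL) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("P%04d", seq_len(nrow(features)))
  assay <- t(features)
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(assay))
  else
    colData <- S4Vectors::DataFrame(colData, row.names = colnames(assay))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), colData = colData)
  if (!is.null(groundTruth))
    S4Vectors::metadata(se)$groundTruth <- groundTruth
  new("ActivityCohort", se)
}

#' @describeIn ActivityCohort-class participant x feature matrix.
#' @param x,object An `ActivityCohort`.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @describeIn ActivityCohort-class survival/covariate data.frame
#'   (one row per participant).
#' @export
participantData <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn ActivityCohort-class simulation ground truth (or NULL).
#' @export
groundTruth <- function(x) S4Vectors::metadata(x)$groundTruth

setMethod("show", "ActivityCohort", function(object) {
  cat("ActivityCohort:", ncol(object), "participants,",
      nrow(object), "features\n")
  cd <- SummarizedExperiment::colData(object)
  if ("event" %in% colnames(cd))
    cat(sprintf("  survival: %d events / %d participants (%.1f%%)\n",
                sum(cd$event), ncol(object),
                100 * mean(cd$event)))
  extra <- setdiff(colnames(cd), c("time_years", "event"))
  if (length(extra))
    cat("  covariates:", paste(head(extra, 8), collapse = ", "),
        if (length(extra) > 8) "..." else "", "\n")
  if (!is.null(groundTruth(object)))
    cat("  ground truth: active set of",
        length(groundTruth(object)$activeSet), "features\n")
})

#' SplsCoxModel: sparse PLS composite-score model for censored outcomes
#'
#' Holds everything needed to reproduce and transfer the composite scores:
#' feature standardisation constants, per-component sparse weight vectors
#' (unit Euclidean norm), X-loadings, the rotation used for score transfer,
#' in-sample scores, score standardisation constants, the sparsity fraction
#' `eta`, the number of components `K`, selected feature sets, and the
#' cross-validation trace.
#'
#' @slot featureNames Feature columns the model was derived on.
#' @slot center,scale Standardisation constants of the derivation cohort.
#' @slot weights p x K matrix of sparse weight vectors (unit norm).
#' @slot loadings p x K matrix of X-loadings.
#' @slot rotation p x K rotation `W (P'W)^-1` mapping standardised features
#'   directly to scores.
#' @slot scores n x K in-sample component scores (unstandardised).
#' @slot scoreCenter,scoreScale Derivation-cohort mean/SD of each score.
#' @slot eta Sparsity fraction in `[0,1)`.
#' @slot K Number of components.
#' @slot support List of selected feature names per component.
#' @slot tuning Cross-validation trace (grid and criterion values), possibly
#'   empty when `eta`/`K` were fixed by the caller.
#' @export
setClass("SplsCoxModel",
  representation(
    featureNames = "character",
    center = "numeric",
    scale = "numeric",
    weights = "matrix",
    loadings = "matrix",
    rotation = "matrix",
    scores = "matrix",
    scoreCenter = "numeric",
    scoreScale = "numeric",
    eta = "numeric",
    K = "integer",
    support = "list",
    tuning = "list"
  )
)

setValidity("SplsCoxModel", function(object) {
  msg <- character()
  p <- length(object@featureNames)
  K <- object@K
  if (!all(dim(object@weights) == c(p, K)))
    msg <- c(msg, "weights must be p x K")
  nrm <- sqrt(colSums(object@weights^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "each weight vector must have unit Euclidean norm")
  for (k in seq_len(K)) {
    sup <- object@featureNames[object@weights[, k] != 0]
    if (!setequal(sup, object@support[[k]]))
      msg <- c(msg, sprintf("support of component %d must equal the weight support", k))
  }
  if (object@eta < 0 || object@eta >= 1)
    msg <- c(msg, "eta must lie in [0,1)")
  if (any(object@scoreScale <= 0))
    msg <- c(msg, "score SDs must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SplsCoxModel", function(object) {
  cat(sprintf("SplsCoxModel: K = %d component(s), eta = %.2f, p = %d features\n",
              object@K, object@eta, length(object@featureNames)))
  for (k in seq_len(object@K)) {
    sup <- object@support[[k]]
    cat(sprintf("  score %d: %d feature(s) selected: %s\n", k, length(sup),
                paste(head(sup, 6), collapse = ", ")))
  }
  if (length(object@tuning))
    cat(sprintf("  tuned by %d-fold CV over %d grid cells (criterion: Harrell C)\n",
                object@tuning$folds, nrow(object@tuning$trace)))
})

#' @describeIn SplsCoxModel-class selected feature names per component.
#' @param object A `SplsCoxModel`.
#' @export
selectedFeatures <- function(object) object@support

#' @describeIn SplsCoxModel-class p x K sparse weight matrix.
#' @export
scoreWeights <- function(object) object@weights

#' @describeIn SplsCoxModel-class p x K X-loading matrix.
#' @export
scoreLoadings <- function(object) object@loadings
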