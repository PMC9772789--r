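#' Martingale and deviance residuals of the covariate-free survival model
#'
#' Computes the Nelson-Aalen estimate of the cumulative hazard of the
#' null model, the martingale residual `m_i = delta_i - Lambda0(t_i)` and
#' its symmetrised deviance transform
#' `d_i = sign(m_i) sqrt(-2 [m_i + delta_i log(delta_i - m_i)])`
#' (with the `delta_i log(.)` term taken as 0 for censored participants).
#' The deviance residuals serve as the working response for the sparse
#' PLS derivation of composite scores under censoring.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicators (0/1), at least one event.
#' @return List with `martingale` and `deviance` numeric vectors.
#' @export
nullDevianceResiduals <- function(time, event) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  if (sum(event) == 0) stop("no events: null cumulative hazard is undefined")
  ut <- sort(unique(time[event == 1]))
  st <- sort(time)
  n <- length(time)
  # sum(time >= t) and sum(time == t & event == 1) via sorted lookups
  nRisk <- n - findInterval(ut, st, left.open = TRUE)
  dEv <- as.numeric(table(factor(time[event == 1], levels = ut)))
  cumHaz <- c(0, cumsum(dEv / nRisk))
  Lambda <- cumHaz[findInterval(time, ut) + 1L]
  m <- event - Lambda
  inner <- m + ifelse(event == 1, log(pmax(event - m, .Machine$double.xmin)), 0)
  d <- sign(m) * sqrt(pmax(-2 * inner, 0))
  list(martingale = m, deviance = d)
}

#' Soft-thresholding operator
#'
#' Componentwise `sign(v) max(0, |v| - lambda)` with
#' `lambda = eta * max|v|`; `eta = 0` returns `v` unchanged. This is the
#' selection step of the sparse PLS weight update.
#'
#' @param v Non-zero numeric vector.
#' @param eta Sparsity fraction in `[0, 1)`.
#' @return Thresholded vector (may be all zero for flat `|v|` and large
#'   `eta`; callers treat that as an empty-selection condition).
#' @export
softThreshold <- function(v, eta) {
  stopifnot(eta >= 0, eta < 1)
  if (all(v == 0)) stop("v must be non-zero")
  lambda <- eta * max(abs(v))
  sign(v) * pmax(0, abs(v) - lambda)
}

.emptySelectionError <- function(k, eta) {
  stop(errorCondition(
    sprintf("empty selection at component %d (eta = %.3f): all weights thresholded to zero",
            k, eta),
    class = c("emptySelectionError", "error", "condition"),
    k = k, eta = eta))
}

#' Fit sparse PLS components against deviance residuals
#'
#' Core derivation: for `k = 1..K` the weight vector is the
#' soft-thresholded covariance `X' d` (unit-normalised), the component
#' score is `t_k = X w_k`, and both `X` and the residual are deflated by
#' regression on `t_k`, making in-sample scores mutually orthogonal.
#' Component 1 is "composite score 1", component 2 "composite score 2".
#'
#' @param X Column-standardised feature matrix (mean 0, SD 1).
#' @param d Deviance residuals ([nullDevianceResiduals()]).
#' @param K Number of components (>= 1).
#' @param eta Sparsity fraction in `[0, 1)`.
#' @param center,scale Standardisation constants to record in the model
#'   (defaults say "X arrived standardised").
#' @return A [SplsCoxModel-class].
#' @export
fitSplsComponents <- function(X, d, K = 2L, eta = 0,
                              center = NULL, scale = NULL) {
  X <- as.matrix(X)
  p <- ncol(X); K <- as.integer(K)
  stopifnot(K >= 1, nrow(X) == length(d))
  fn <- colnames(X)
  if (is.null(fn)) fn <- sprintf("x%02d", seq_len(p))
  if (is.null(center)) center <- setNames(rep(0, p), fn)
  if (is.null(scale)) scale <- setNames(rep(1, p), fn)
  X0 <- X
  Xk <- X; dk <- d
  W <- P <- matrix(0, p, K, dimnames = list(fn, NULL))
  Tm <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    cvec <- drop(crossprod(Xk, dk))
    # a numerically exhausted deflated X yields no usable direction
    if (max(abs(cvec)) < sqrt(.Machine$double.eps) * nrow(X))
      .emptySelectionError(k, eta)
    w <- softThreshold(cvec, eta)
    if (all(w == 0)) .emptySelectionError(k, eta)
    w <- w / sqrt(sum(w^2))
    tk <- drop(Xk %*% w)
    tt <- sum(tk^2)
    pk <- drop(crossprod(Xk, tk)) / tt
    Xk <- Xk - tcrossprod(tk, pk)
    dk <- dk - tk * sum(tk * dk) / tt
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tk
  }
  rotation <- W %*% solve(crossprod(P, W))
  dimnames(rotation) <- list(fn, NULL)
  new("SplsCoxModel",
      featureNames = fn,
      center = setNames(as.numeric(center), fn),
      scale = setNames(as.numeric(scale), fn),
      weights = W, loadings = P, rotation = rotation, scores = Tm,
      scoreCenter = colMeans(Tm),
      scoreScale = apply(Tm, 2, sd),
      eta = eta, K = K,
      support = lapply(seq_len(K), function(k) fn[W[, k] != 0]),
      tuning = list())
}

.standardizeColumns <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, sd)
  if (any(scale <= 0 | !is.finite(scale))) {
    bad <- colnames(X)[which(scale <= 0 | !is.finite(scale))[1]]
    stop(sprintf("zero-variance feature column: %s", bad))
  }
  list(X = sweep(sweep(X, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

#' Derive composite scores from a feature table and a censored outcome
#'
#' Convenience front end: standardises the features, computes the null-model
#' deviance residuals and fits [fitSplsComponents()].
#'
#' @param features Participants x features numeric matrix.
#' @param time,event Survival outcome.
#' @inheritParams fitSplsComponents
#' @return A [SplsCoxModel-class] carrying the standardisation constants.
#' @export
fitSplsCox <- function(features, time, event, K = 2L, eta = 0) {
  std <- .standardizeColumns(as.matrix(features))
  d <- nullDevianceResiduals(time, event)$deviance
  fitSplsComponents(std$X, d, K = K, eta = eta,
                    center = std$center, scale = std$scale)
}

.stratifiedFolds <- function(event, folds, seed) {
  if (sum(event == 1) < folds || sum(event == 0) < folds)
    stop("cannot stratify folds: fewer participants than folds in an outcome class")
  set.seed(as.integer(seed))
  f <- integer(length(event))
  for (cls in c(0, 1)) {
    idx <- which(event == cls)
    f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  f
}

#' Tune the sparse PLS by event-stratified cross-validation
#'
#' For each `(K, eta)` grid cell the model is fitted on the training folds,
#' validation-fold scores are obtained by the model rotation, a Cox model of
#' the training scores provides the validation-fold linear predictor, and
#' the criterion is the average validation-fold Harrell C. The maximising
#' cell is refitted on the full sample; ties favour the sparser (larger
#' `eta`) then smaller-`K` cell. Cells where some component selects no
#' feature are skipped (NA in the trace).
#'
#' @param features Participants x features matrix.
#' @param time,event Survival outcome.
#' @param KGrid,etaGrid Candidate values.
#' @param folds Number of CV folds (>= 2), event-stratified.
#' @param seed Integer seed governing fold assignment.
#' @return A [SplsCoxModel-class] fitted at the chosen cell, with the full
#'   trace in `@tuning`.
#' @export
tuneSplsCox <- function(features, time, event,
                        KGrid = 1:2, etaGrid = seq(0, 0.9, by = 0.1),
                        folds = 5L, seed = 1L) {
  stopifnot(folds >= 2, length(KGrid) >= 1, length(etaGrid) >= 1)
  X <- as.matrix(features)
  fold <- .stratifiedFolds(event, folds, seed)
  trace <- expand.grid(eta = etaGrid, K = KGrid)
  trace$cvC <- NA_real_
  cellC <- matrix(NA_real_, nrow(trace), folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    # standardisation and null-model residuals are shared by all grid cells
    std <- .standardizeColumns(X[tr, , drop = FALSE])
    d <- nullDevianceResiduals(time[tr], event[tr])$deviance
    for (i in seq_len(nrow(trace))) {
      fit <- tryCatch(
        fitSplsComponents(std$X, d, K = trace$K[i], eta = trace$eta[i],
                          center = std$center, scale = std$scale),
        emptySelectionError = function(e) NULL)
      if (is.null(fit)) next
      sTr <- applyScore(fit, X[tr, , drop = FALSE], "derivation")
      sVal <- applyScore(fit, X[!tr, , drop = FALSE], "derivation")
      cox <- survival::coxph(survival::Surv(time[tr], event[tr]) ~ sTr)
      lpVal <- drop(sVal %*% coef(cox))
      cellC[i, f] <- harrellC(lpVal, time[!tr], event[!tr])
    }
  }
  trace$cvC <- rowMeans(cellC) # NA if any fold had an empty selection
  if (all(is.na(trace$cvC)))
    stop("cross-validation failed in every grid cell")
  best <- which(trace$cvC >= max(trace$cvC, na.rm = TRUE) - 1e-12)
  best <- best[order(-trace$eta[best], trace$K[best])][1]
  model <- fitSplsCox(X, time, event, K = trace$K[best], eta = trace$eta[best])
  model@tuning <- list(trace = trace, folds = folds, seed = as.integer(seed),
                       chosen = list(K = trace$K[best], eta = trace$eta[best]))
  model
}

#' Apply a composite-score model to a feature table
#'
#' Features are standardised either with the derivation cohort's constants
#' (`"derivation"`) or with the target table's own means/SDs (`"local"`,
#' the default choice for transfer across devices or wear protocols), then
#' rotated into component scores and standardised by the stored
#' (derivation) or locally recomputed constants; under `"local"` mode each
#' returned score has mean 0 and SD 1.
#'
#' @param model A [SplsCoxModel-class].
#' @param newFeatures Feature table containing the model's feature columns.
#' @param standardization `"derivation"` or `"local"`.
#' @return n x K matrix of standardised composite scores.
#' @export
applyScore <- function(model, newFeatures,
                       standardization = c("derivation", "local")) {
  standardization <- match.arg(standardization)
  newFeatures <- as.matrix(newFeatures)
  miss <- setdiff(model@featureNames, colnames(newFeatures))
  if (length(miss))
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  X <- newFeatures[, model@featureNames, drop = FALSE]
  if (standardization == "derivation")
    Xs <- .standardizeColumns(X, model@center, model@scale)$X
  else
    Xs <- .standardizeColumns(X)$X
  Tm <- Xs %*% model@rotation
  if (standardization == "derivation")
    sweep(sweep(Tm, 2, model@scoreCenter, "-"), 2, model@scoreScale, "/")
  else
    sweep(sweep(Tm, 2, colMeans(Tm), "-"), 2, apply(Tm, 2, sd), "/")
}

#' Serialise a composite-score model to JSON
#'
#' @param model A [SplsCoxModel-class].
#' @param path Output file.
#' @export
writeSplsModel <- function(model, path) {
  obj <- list(featureNames = model@featureNames,
              center = model@center, scale = model@scale,
              weights = model@weights, loadings = model@loadings,
              rotation = model@rotation,
              scoreCenter = model@scoreCenter, scoreScale = model@scoreScale,
              eta = model@eta, K = model@K, support = model@support,
              tuning = if (length(model@tuning))
                list(trace = model@tuning$trace, folds = model@tuning$folds,
                     seed = model@tuning$seed, chosen = model@tuning$chosen)
              else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a serialised composite-score model
#'
#' The in-sample score matrix is not serialised; round-tripped models score
#' new data identically but carry an empty `@scores` slot.
#'
#' @param path JSON file written by [writeSplsModel()].
#' @return A [SplsCoxModel-class].
#' @export
readSplsModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(o$featureNames); K <- as.integer(o$K)
  mat <- function(m) matrix(as.numeric(as.matrix(m)), p, K,
                            dimnames = list(o$featureNames, NULL))
  sup <- if (is.list(o$support)) lapply(o$support, as.character)
         else list(as.character(o$support))
  new("SplsCoxModel",
      featureNames = o$featureNames,
      center = setNames(as.numeric(o$center), o$featureNames),
      scale = setNames(as.numeric(o$scale), o$featureNames),
      weights = mat(o$weights), loadings = mat(o$loadings),
      rotation = mat(o$rotation),
      scores = matrix(numeric(0), 0, K),
      scoreCenter = as.numeric(o$scoreCenter),
      scoreScale = as.numeric(o$scoreScale),
      eta = o$eta, K = K, support = sup,
      tuning = if (!is.null(o$tuning)) o$tuning else list())
}
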