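#' Default pipeline configuration
#'
#' Returns the demo configuration: a 500-participant cohort recorded over
#' 3 days, 5-fold cross-validated score derivation, 200-replicate
#' bootstrap model comparison and a 300-participant external cohort.
#' Any subset of fields can be overridden via `...` (nested lists are
#' merged) or by an equivalent YAML file passed to [runPipeline()].
#'
#' @param ... Named overrides, e.g. `simulate = list(n = 1000)`.
#' @return Nested list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 20130101L,
    outDir = tempfile("actisurv_run_"),
    stages = list(simulate = TRUE, extract = TRUE, deriveScore = TRUE,
                  evaluate = TRUE, validate = TRUE),
    paths = list(epochs = NULL, cohort = NULL, model = NULL),
    simulate = list(n = 500L, days = 3L, wakingMinutes = 960,
                    horizonYears = 8, censorRate = 0,
                    baselineRate = 0.0073, nExternal = 300L),
    features = list(sbThreshold = 40, mvpaThreshold = 100, binWidth = 25,
                    standardizeWaking = FALSE, referenceWaking = 960),
    spls = list(KGrid = 1:2, etaGrid = seq(0, 0.9, by = 0.1), folds = 5L),
    evaluate = list(B = 200L, ageCut = 74),
    validate = list(B = 200L, standardization = "local"))
  ov <- list(...)
  for (nm in names(ov))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  class(cfg) <- "PipelineConfig"
  cfg
}

.validatePipelineConfig <- function(cfg) {
  st <- cfg$stages
  if (isTRUE(st$extract) && !isTRUE(st$simulate) && is.null(cfg$paths$epochs))
    stop("extract stage enabled but no simulate stage and no epoch file configured")
  if (isTRUE(st$deriveScore) && !isTRUE(st$extract) && is.null(cfg$paths$cohort))
    stop("derive-score stage enabled but no extract stage and no cohort file configured")
  if ((isTRUE(st$evaluate) || isTRUE(st$validate)) &&
      !isTRUE(st$deriveScore) && is.null(cfg$paths$model))
    stop("evaluation enabled but no score stage and no score file configured")
  invisible(TRUE)
}

.readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

.stageLog <- function(stage, t0) {
  message(sprintf("[actisurv] %-12s %6.1f s", stage,
                  as.numeric(Sys.time()) - t0))
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "outDir")],
                              auto_unbox = TRUE, force = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

# simulate one cohort through the epoch route: epochs -> features ->
# survival on the standardised extracted features
.simulateEpochCohort <- function(cfg, n, seed) {
  sim <- cfg$simulate
  prof <- activityProfile(days = as.integer(sim$days),
                          wakingMinutes = sim$wakingMinutes)
  epochs <- simulateEpochSeries(prof, n, seed = seed)
  fx <- cfg$features
  X <- extractCohortFeatures(epochs, fx$sbThreshold, fx$mvpaThreshold,
                             fx$binWidth)
  if (isTRUE(fx$standardizeWaking))
    X <- standardizeByWaking(X, sim$wakingMinutes, fx$referenceWaking)
  spec <- cohortSpec(n = n,
                     baseline = list(dist = "exponential",
                                     rate = sim$baselineRate),
                     horizonYears = sim$horizonYears,
                     censorRate = sim$censorRate, seed = seed)
  set.seed(seed + 1L)
  cov <- spec$covariates(n)
  Z <- scale(X)
  lp <- drop(Z %*% spec$beta)
  for (nm in names(spec$covariateBeta))
    lp <- lp + spec$covariateBeta[[nm]] * (cov[[nm]] - mean(cov[[nm]]))
  surv <- simulateSurvival(lp, spec, seed = seed + 2L)
  gt <- list(activeSet = spec$featureNames[spec$beta != 0], beta = spec$beta,
             covariateBeta = spec$covariateBeta, linearPredictor = lp,
             eventFraction = mean(surv$event))
  cohort <- activityCohort(X, colData = cbind(cov, surv), groundTruth = gt)
  list(epochs = epochs, cohort = cohort, spec = spec)
}

#' Run the simulate / extract / derive-score / evaluate / validate pipeline
#'
#' Executes the enabled stages in order from a single configuration: epoch
#' simulation, 21-feature extraction, sparse-PLS composite-score derivation
#' with cross-validated tuning, nested Cox-model evaluation (hazard ratios
#' per SD, performance panels for Models 1-3, bootstrap comparisons, spline
#' nonlinearity tests, age/sex subgroup panels) and external validation in
#' an independently simulated cohort. All intermediate artifacts are
#' written to `outDir` (epoch and cohort CSVs, model JSON, report JSON and
#' Markdown); every number in the report is regenerable from the
#' configuration and seed.
#'
#' @param config A [pipelineConfig()] list or the path of a YAML file of
#'   overrides.
#' @return The report, invisibly also written to
#'   `<outDir>/report.json` and `<outDir>/report.md`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- .readPipelineConfig(config)
  .validatePipelineConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  report <- list(package = "actisurv",
                 version = as.character(packageVersion("actisurv")),
                 seed = seed, configHash = .configHash(config),
                 parameters = config[c("simulate", "features", "spls",
                                       "evaluate", "validate")])
  covarNames <- c("age", "sex")
  cohort <- NULL; model <- NULL

  if (isTRUE(config$stages$simulate) || isTRUE(config$stages$extract)) {
    t0 <- as.numeric(Sys.time())
    sim <- .simulateEpochCohort(config, config$simulate$n, seed)
    writeEpochCSV(sim$epochs, file.path(config$outDir, "epochs.csv"))
    writeCohortCSV(sim$cohort, file.path(config$outDir, "cohort.csv"))
    jsonlite::write_json(groundTruth(sim$cohort)[c("activeSet", "beta",
                                                   "covariateBeta",
                                                   "eventFraction")],
                         file.path(config$outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    cohort <- sim$cohort
    X <- featureMatrix(cohort)
    report$cohortSummary <- data.frame(
      feature = colnames(X),
      mean = unname(colMeans(X)), sd = unname(apply(X, 2, sd)))
    report$eventFraction <- groundTruth(cohort)$eventFraction
    .stageLog("simulate", t0)
  } else if (!is.null(config$paths$cohort)) {
    cohort <- readCohortCSV(config$paths$cohort)
  }

  if (isTRUE(config$stages$deriveScore)) {
    t0 <- as.numeric(Sys.time())
    X <- featureMatrix(cohort)
    pd <- participantData(cohort)
    model <- tuneSplsCox(X, pd$time_years, pd$event,
                         KGrid = config$spls$KGrid,
                         etaGrid = config$spls$etaGrid,
                         folds = config$spls$folds, seed = seed + 3L)
    writeSplsModel(model, file.path(config$outDir, "model.json"))
    report$spls <- list(K = model@K, eta = model@eta,
                        support = model@support,
                        weights = apply(model@weights, 2, setNames,
                                        model@featureNames, simplify = FALSE),
                        loadings = apply(model@loadings, 2, setNames,
                                         model@featureNames, simplify = FALSE),
                        cvTrace = model@tuning$trace)
    .stageLog("derive-score", t0)
  } else if (!is.null(config$paths$model)) {
    model <- readSplsModel(config$paths$model)
  }

  if (isTRUE(config$stages$evaluate)) {
    t0 <- as.numeric(Sys.time())
    X <- featureMatrix(cohort)
    pd <- participantData(cohort)
    sc <- applyScore(model, X, "derivation")
    rec <- pd
    rec$score1 <- as.numeric(scale(sc[, 1]))
    if (model@K >= 2) rec$score2 <- as.numeric(scale(sc[, 2]))
    designs <- list(model1 = covarNames,
                    model2 = c(covarNames, "score1"))
    if (model@K >= 2)
      designs$model3 <- c(covarNames, "score1", "score2")
    fits <- lapply(designs, function(d) fitCoxModel(rec, d))
    report$models <- lapply(names(designs), function(nm) {
      f <- fits[[nm]]
      pan <- performancePanel(f)
      hrs <- lapply(intersect(c("score1", "score2"), f$design),
                    function(s) as.list(hazardRatioPerSD(f, s)))
      names(hrs) <- intersect(c("score1", "score2"), f$design)
      list(model = nm, design = f$design, hr = hrs,
           panel = unclass(pan))
    })
    names(report$models) <- names(designs)
    B <- config$evaluate$B
    report$comparisons <- list(
      model2_vs_model1 = unclass(
        compareNestedModels(rec, designs$model1, designs$model2,
                            B = B, seed = seed + 4L)))
    if (model@K >= 2)
      report$comparisons$model3_vs_model2 <- unclass(
        compareNestedModels(rec, designs$model2, designs$model3,
                            B = B, seed = seed + 4L))
    report$nonlinearity <- lapply(
      intersect(c("score1", "score2"), names(rec)),
      function(s) splineNonlinearityTest(rec, s, covarNames)[
        c("statistic", "df", "p.value")])
    names(report$nonlinearity) <- intersect(c("score1", "score2"), names(rec))
    rec$age_band <- ifelse(rec$age < config$evaluate$ageCut,
                           sprintf("age<%g", config$evaluate$ageCut),
                           sprintf("age>=%g", config$evaluate$ageCut))
    rec$sex_band <- ifelse(rec$sex == 1, "women", "men")
    report$subgroups <- rbind(
      subgroupAnalysis(rec, "score1", "age_band", covarNames,
                       B = B, seed = seed + 4L),
      subgroupAnalysis(rec, "score1", "sex_band", covarNames,
                       B = B, seed = seed + 4L))
    .stageLog("evaluate", t0)
  }

  if (isTRUE(config$stages$validate)) {
    t0 <- as.numeric(Sys.time())
    ext <- .simulateEpochCohort(config, config$simulate$nExternal,
                                seed + 5L)
    writeCohortCSV(ext$cohort, file.path(config$outDir,
                                         "external_cohort.csv"))
    pdE <- participantData(ext$cohort)
    ev <- externalValidation(model, featureMatrix(ext$cohort), pdE,
                             covariates = covarNames,
                             standardization = config$validate$standardization,
                             B = config$validate$B, seed = seed + 6L)
    report$external <- list(n = nrow(pdE), events = sum(pdE$event),
                            hr = as.list(ev$hr),
                            panelRef = unclass(ev$panelRef),
                            panelAug = unclass(ev$panelAug),
                            comparison = unclass(ev$comparison))
    .stageLog("validate", t0)
  }

  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  writeLines(.reportMarkdown(report), file.path(config$outDir, "report.md"))
  invisible(report)
}

.fmtPanel <- function(p)
  sprintf("R2_D %.3f | AIC %.1f | C %.3f | sens %.1f%% | spec %.1f%%",
          p$r2d, p$aic, p$c, p$sensitivity, p$specificity)

.reportMarkdown <- function(report) {
  out <- c(sprintf("# actisurv run report (v%s, seed %d)", report$version,
                   report$seed),
           sprintf("config hash: %s", report$configHash), "")
  if (!is.null(report$cohortSummary)) {
    cs <- report$cohortSummary
    out <- c(out, "## Cohort feature summary", "",
             "| feature | mean | SD |", "|---|---|---|",
             sprintf("| %s | %.2f | %.2f |", cs$feature, cs$mean, cs$sd),
             "", sprintf("Event fraction: %.3f", report$eventFraction), "")
  }
  if (!is.null(report$spls)) {
    out <- c(out, "## Composite scores", "",
             sprintf("Chosen K = %d, eta = %.2f", report$spls$K,
                     report$spls$eta),
             vapply(seq_along(report$spls$support), function(k)
               sprintf("- score %d support: %s", k,
                       paste(report$spls$support[[k]], collapse = ", ")),
               character(1)), "")
  }
  if (!is.null(report$models)) {
    out <- c(out, "## Internal validation", "")
    for (m in report$models) {
      out <- c(out, sprintf("- %s: %s", m$model, .fmtPanel(m$panel)))
      for (s in names(m$hr))
        out <- c(out, sprintf("    - %s HR per SD %.3f (%.3f, %.3f)", s,
                              m$hr[[s]]$hr, m$hr[[s]]$lower, m$hr[[s]]$upper))
    }
    out <- c(out, "")
    for (nm in names(report$comparisons)) {
      cmp <- report$comparisons[[nm]]
      out <- c(out, sprintf(
        "- %s: dAIC %.1f (%.1f, %.1f); dC %.4f (%.4f, %.4f); B = %d", nm,
        cmp$deltaAIC, cmp$ciAIC[1], cmp$ciAIC[2],
        cmp$deltaC, cmp$ciC[1], cmp$ciC[2], cmp$B))
    }
    out <- c(out, "")
    for (nm in names(report$nonlinearity))
      out <- c(out, sprintf("- nonlinearity LRT %s: p = %.3f", nm,
                            report$nonlinearity[[nm]]$p.value))
    out <- c(out, "")
  }
  if (!is.null(report$subgroups)) {
    sg <- report$subgroups
    out <- c(out, "## Subgroups", "",
             "| group | n | events | HR (95% CI) | dC (95% CI) |",
             "|---|---|---|---|---|",
             sprintf("| %s | %d | %d | %.3f (%.3f, %.3f) | %.4f (%.4f, %.4f) |",
                     sg$group, sg$n, sg$events, sg$hr, sg$hr_lower,
                     sg$hr_upper, sg$delta_c, sg$delta_c_lower,
                     sg$delta_c_upper), "")
  }
  if (!is.null(report$external)) {
    ex <- report$external
    out <- c(out, "## External validation", "",
             sprintf("n = %d, events = %d", ex$n, ex$events),
             sprintf("- score 1 HR per SD: %.3f (%.3f, %.3f)",
                     ex$hr$hr, ex$hr$lower, ex$hr$upper),
             sprintf("- reference: %s", .fmtPanel(ex$panelRef)),
             sprintf("- augmented: %s", .fmtPanel(ex$panelAug)),
             sprintf("- dAIC %.1f (%.1f, %.1f); dC %.4f (%.4f, %.4f)",
                     ex$comparison$deltaAIC, ex$comparison$ciAIC[1],
                     ex$comparison$ciAIC[2], ex$comparison$deltaC,
                     ex$comparison$ciC[1], ex$comparison$ciC[2]), "")
  }
  out
}
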