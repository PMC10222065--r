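## Single entry point wiring the full chain: simulate (or load) -> extract
## features -> collinearity diagnostics + lasso selection -> baselines ->
## MCMA -> comparison (and optionally the ablation grid), with YAML
## configuration and reproducibility stamping.

defaultRunConfig <- function() {
  list(
    seed = 1L,
    outDir = NULL,
    manifest = NULL,
    gen = list(nSubjects = 38L, recordsPerCondition = 1L, subjectSd = 3,
               noiseSd = 1, nonlinear = FALSE),
    selection = list(nFolds = 10L, rule = "lambda.1se"),
    baseline = list(REML = TRUE, logScore = FALSE,
                    svr = list(C = 1, epsilon = 0.1)),
    mcma = list(T = 8L, dModel = 256L, nHeads = 8L, convFilters = c(8L, 16L),
                headHidden = 64L, fusion = "flatten", lr = 1e-3,
                batchSize = 32L, epochs = 60L, patience = 10L,
                weightDecay = 1e-4, lrDecayFactor = 0.3, lrDecayEvery = 40L,
                attnScale = "sqrt", mhaResidual = TRUE),
    evaluation = list(fractions = c(0.6, 0.2, 0.2), grouping = "subject",
                      ablation = FALSE, ablationSeeds = c(1L, 2L, 3L))
  )
}

mergeConfig <- function(defaults, user, path = character()) {
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      tactileError(sprintf("unknown config key: %s", here), "configError")
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) {
        tactileError(sprintf("config key %s must be a mapping", here), "configError")
      }
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      mode_ok <- is.null(defaults[[nm]]) || is.null(user[[nm]]) ||
        (is.numeric(defaults[[nm]]) && is.numeric(user[[nm]])) ||
        (is.character(defaults[[nm]]) && is.character(user[[nm]])) ||
        (is.logical(defaults[[nm]]) && is.logical(user[[nm]]))
      if (!mode_ok) {
        tactileError(sprintf("config key %s has wrong type", here), "configError")
      }
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills defaults and rejects unknown keys (with the
#' offending key path in the error). An empty file yields the all-defaults
#' configuration.
#'
#' @param path YAML file, or `NULL` for defaults.
#' @return A validated `RunConfig` list.
#' @export
loadConfig <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- mergeConfig(defaultRunConfig(), user)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Generates a synthetic dataset (or loads one from `config$manifest`),
#' extracts features, runs the collinearity diagnostics and lasso
#' selection, splits at subject level, fits the mixed-effects and SVR
#' baselines and trains the MCMA network on identical splits, and returns
#' the comparison report (plus the ablation table when
#' `config$evaluation$ablation` is set). When `config$outDir` is given,
#' writes `features.csv`, `selection.json`, `report.json` and the effective
#' configuration. Idempotent given the seed.
#'
#' @param config a `RunConfig` from [loadConfig()].
#' @param verbose print progress.
#' @return A list of class `PipelineResult`.
#' @export
runPipeline <- function(config = loadConfig(), verbose = FALSE) {
  seed <- as.integer(config$seed)
  records <- if (!is.null(config$manifest)) {
    loadDataset(config$manifest)
  } else {
    gp <- do.call(genParams, c(config$gen, list(seed = seed)))
    generateDataset(gp)$records
  }

  splits <- splitDataset(records, fractions = config$evaluation$fractions,
                         grouping = config$evaluation$grouping, seed = seed + 2L)

  ft <- featureTable(records)
  X <- as.matrix(ft[FEATURE_NAMES])
  diag <- farrarGlauber(X)
  lasso <- lassoSelect(X, ft$bart_score, nFolds = config$selection$nFolds,
                       seed = seed + 1L, rule = config$selection$rule)
  selected <- lasso$selected
  if (length(selected) < 2L) selected <- setdiff(FEATURE_NAMES, "mHR")

  mcfg <- do.call(mcmaConfig, c(config$mcma, list(seed = seed + 3L)))
  cmp <- compareModels(splits, mcfg, featureNames = selected,
                       svrArgs = config$baseline$svr, REML = config$baseline$REML)

  abl <- NULL
  if (isTRUE(config$evaluation$ablation)) {
    abl <- runAblation(splits, mcfg, seeds = config$evaluation$ablationSeeds,
                       verbose = verbose)
  }

  result <- structure(list(
    comparison = cmp, ablation = abl, collinearity = diag, lasso = lasso,
    selectedFeatures = selected, features = ft,
    config = config, seed = seed), class = "PipelineResult")

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ft, file.path(config$outDir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(vif = as.list(diag$vif), fgDeterminant = diag$fgDeterminant,
           fgChi2 = diag$fgChi2, fgDf = diag$fgDf,
           lambdaMin = lasso$lambdaMin, lambda1se = lasso$lambda1se,
           selected = selected),
      file.path(config$outDir, "selection.json"), auto_unbox = TRUE, digits = NA)
    cfgOut <- unclass(config)
    cfgOut$outDir <- NULL      # report content must not depend on where it lives
    rep <- list(seed = seed, config = cfgOut,
                comparison = cmp$table, splitInfo = cmp$splitInfo)
    if (!is.null(abl)) rep$ablation <- abl$table
    jsonlite::write_json(rep, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @exportS3Method base::print
print.PipelineResult <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %d records, selected features: %s\n",
              x$seed, nrow(x$features), paste(x$selectedFeatures, collapse = ", ")))
  print(x$comparison$table, digits = 4)
  if (!is.null(x$ablation)) print(x$ablation$table, digits = 4)
  invisible(x)
}
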