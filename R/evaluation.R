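## Metrics, leakage-safe splitting, model comparison and the ablation
## harness.

#' Regression metrics: MAE, RMSE, R-squared
#'
#' `mae = mean |e|`, `rmse = sqrt(mean e^2)`, `r2 = 1 - SSE/SST` with SST
#' about the mean of `yTrue`. A constant `yTrue` (SST = 0) is reported with
#' `r2 = NA` and `degenerate = TRUE` rather than an error.
#'
#' @param yTrue,yPred equal-length numeric vectors.
#' @return A list of class `Metrics`: `mae`, `rmse`, `r2`, `degenerate`.
#' @export
computeMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) == 0L) {
    tactileError("yTrue and yPred must have equal non-zero length", "invalidInput")
  }
  e <- yPred - yTrue
  sst <- sum((yTrue - mean(yTrue))^2)
  degenerate <- sst == 0
  structure(list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
                 r2 = if (degenerate) NA_real_ else 1 - sum(e^2) / sst,
                 degenerate = degenerate),
            class = "Metrics")
}

#' @exportS3Method base::print
print.Metrics <- function(x, ...) {
  cat(sprintf("MAE %.3f | RMSE %.3f | R2 %s\n", x$mae, x$rmse,
              if (x$degenerate) "degenerate (constant truth)" else sprintf("%.3f", x$r2)))
  invisible(x)
}

#' Leakage-safe train/validation/test split
#'
#' Partitions records into three disjoint sets covering the input. Under
#' `grouping = "subject"` (default) all records of a subject land in the
#' same split, honouring the within-subject design; `"record"` splits rows
#' independently. Validation and test sizes are floors of their fractions;
#' the remainder goes to training. Deterministic under `seed`.
#'
#' @param records list of [PhysioRecord-class] objects.
#' @param fractions numeric triple summing to 1 (train, val, test).
#' @param grouping `"subject"` or `"record"`.
#' @param seed integer.
#' @return A list with elements `train`, `val`, `test` (record lists).
#' @export
splitDataset <- function(records, fractions = c(0.6, 0.2, 0.2),
                         grouping = c("subject", "record"), seed = 1) {
  grouping <- match.arg(grouping)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L) {
    tactileError("fractions must be three numbers summing to 1", "invalidInput")
  }
  if (grouping == "subject") {
    subjects <- unique(vapply(records, subjectId, character(1)))
    n <- length(subjects)
    nVal <- floor(fractions[2] * n)
    nTest <- floor(fractions[3] * n)
    nTrain <- n - nVal - nTest
    if (nTrain < 1L || nVal < 1L || nTest < 1L) {
      tactileError("too few subjects for three non-empty splits",
                   "insufficientGroups")
    }
    perm <- withLocalSeed(seed, sample(subjects))
    assign <- rep(c("train", "val", "test"), c(nTrain, nVal, nTest))
    names(assign) <- perm
    grp <- assign[vapply(records, subjectId, character(1))]
  } else {
    n <- length(records)
    nVal <- floor(fractions[2] * n)
    nTest <- floor(fractions[3] * n)
    nTrain <- n - nVal - nTest
    if (nTrain < 1L || nVal < 1L || nTest < 1L) {
      tactileError("too few records for three non-empty splits",
                   "insufficientGroups")
    }
    perm <- withLocalSeed(seed, sample.int(n))
    grp <- character(n)
    grp[perm] <- rep(c("train", "val", "test"), c(nTrain, nVal, nTest))
  }
  list(train = records[grp == "train"],
       val = records[grp == "val"],
       test = records[grp == "test"])
}

#' The default seven-variant ablation grid
#'
#' One variant per disabled input branch (EDA, BVP, IBI, TEMP, condition),
#' one with attention fusion replaced by concatenation, and the full model.
#'
#' @return Named list of ablation specs (`branches`, `mhaEnabled`).
#' @export
defaultAblationGrid <- function() {
  specs <- lapply(ALL_BRANCHES, function(br) {
    list(branches = setdiff(ALL_BRANCHES, br), mhaEnabled = TRUE)
  })
  names(specs) <- paste0("no_", c("eda", "bvp", "ibi", "temp", "condition"))
  specs$no_mha <- list(branches = ALL_BRANCHES, mhaEnabled = FALSE)
  specs$full <- list(branches = ALL_BRANCHES, mhaEnabled = TRUE)
  specs
}

applyAblation <- function(baseConfig, spec, seed) {
  cfg <- baseConfig
  cfg$branches <- spec$branches
  cfg$mhaEnabled <- isTRUE(spec$mhaEnabled)
  cfg$seed <- as.integer(seed)
  validateMcmaConfig(cfg)
  cfg
}

#' Run the ablation study
#'
#' Trains one MCMA model per (variant, seed), disabling an input branch by
#' removing its token from the fusion, or replacing multihead attention by
#' plain concatenation of the embeddings. Per-seed test metrics are
#' retained; the aggregate is their mean.
#'
#' @param splits a [splitDataset()] result.
#' @param baseConfig the full-model `McmaConfig`.
#' @param variants named list of ablation specs (default the seven-variant
#'   grid of [defaultAblationGrid()]).
#' @param seeds integer vector of training seeds.
#' @param verbose print progress.
#' @return A list of class `EvalReport`: `table` (one aggregated row per
#'   variant), `perSeed` (all runs), `splitInfo`.
#' @export
runAblation <- function(splits, baseConfig, variants = defaultAblationGrid(),
                        seeds = c(1, 2, 3), verbose = FALSE) {
  for (v in variants) {
    if (length(v$branches) == 0L) {
      tactileError("ablation variant disables every branch", "invalidAblation")
    }
  }
  yTest <- vapply(splits$test, bartScore, numeric(1))
  rows <- list()
  for (vn in names(variants)) {
    for (s in seeds) {
      cfg <- applyAblation(baseConfig, variants[[vn]], s)
      tr <- trainMcma(cfg, splits$train, splits$val)
      m <- computeMetrics(yTest, predict(tr$model, splits$test))
      if (verbose) message(sprintf("%-12s seed %d: MAE %.3f", vn, s, m$mae))
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, seed = s, mae = m$mae, rmse = m$rmse, r2 = m$r2,
        stringsAsFactors = FALSE)
    }
  }
  perSeed <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(perSeed, perSeed$variant), function(d) {
    data.frame(variant = d$variant[1L], mae = mean(d$mae), rmse = mean(d$rmse),
               r2 = mean(d$r2), stringsAsFactors = FALSE)
  }))
  agg <- agg[match(names(variants), agg$variant), ]
  rownames(agg) <- NULL
  structure(list(table = agg, perSeed = perSeed,
                 splitInfo = splitSizes(splits, seeds)),
            class = "EvalReport")
}

splitSizes <- function(splits, seeds = NULL) {
  list(nTrain = length(splits$train), nVal = length(splits$val),
       nTest = length(splits$test), seeds = seeds)
}

#' Compare the mixed-effects, SVR and MCMA models on identical splits
#'
#' Fits the random-intercept mixed model and the RBF SVR on the extracted
#' features (the SVR additionally receives condition dummies; the mixed
#' model codes condition as a fixed effect) and trains the MCMA network on
#' the raw signals, all on the same subject-level splits, then evaluates
#' all three on the test set.
#'
#' @param splits a [splitDataset()] result.
#' @param mcmaCfg an `McmaConfig`.
#' @param featureNames feature columns for the feature-based models
#'   (default: the 11 features minus `mHR`, the variable eliminated by the
#'   collinearity analysis).
#' @param svrArgs list of [fitSvr()] hyperparameters.
#' @param REML logical for the mixed model.
#' @return A list of class `EvalReport`: `table` (3 rows x MAE/RMSE/R2),
#'   `predictions`, `fits`, `splitInfo`.
#' @export
compareModels <- function(splits, mcmaCfg,
                          featureNames = setdiff(FEATURE_NAMES, "mHR"),
                          svrArgs = list(), REML = TRUE) {
  ftTrain <- featureTable(splits$train)
  ftVal <- featureTable(splits$val)
  ftTest <- featureTable(splits$test)
  ftFit <- rbind(ftTrain, ftVal)   # feature models have no early stopping;
                                   # they see train+val, MCMA sees the same
                                   # records as train vs val
  yTest <- ftTest$bart_score

  mixedFit <- fitMixed(ftFit[featureNames], ftFit$condition, ftFit$subject_id,
                       ftFit$bart_score, REML = REML)
  mixedPred <- predictMixed(mixedFit, ftTest[featureNames], ftTest$condition,
                            ftTest$subject_id)

  svrX <- cbind(as.matrix(ftFit[featureNames]), conditionDummies(ftFit$condition))
  svrFit <- do.call(fitSvr, c(list(features = svrX, y = ftFit$bart_score), svrArgs))
  svrPred <- predict(svrFit, cbind(as.matrix(ftTest[featureNames]),
                                   conditionDummies(ftTest$condition)))

  mcmaTr <- trainMcma(mcmaCfg, splits$train, splits$val)
  mcmaPred <- predict(mcmaTr$model, splits$test)

  mk <- function(pred) computeMetrics(yTest, pred)
  ms <- list(mixed = mk(mixedPred), svr = mk(svrPred), mcma = mk(mcmaPred))
  tab <- data.frame(model = names(ms),
                    mae = vapply(ms, `[[`, numeric(1), "mae"),
                    rmse = vapply(ms, `[[`, numeric(1), "rmse"),
                    r2 = vapply(ms, `[[`, numeric(1), "r2"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 predictions = list(yTest = yTest, mixed = mixedPred,
                                    svr = svrPred, mcma = mcmaPred),
                 fits = list(mixed = mixedFit, svr = svrFit, mcma = mcmaTr$model,
                             mcmaHistory = mcmaTr$history),
                 splitInfo = splitSizes(splits)),
            class = "EvalReport")
}

#' @exportS3Method base::print
print.EvalReport <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}
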