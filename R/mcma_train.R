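## Mini-batch Adam training of the MCMA model with early stopping on
## validation MAE. Gradients come from the hand-written backward passes in
## mcma_layers.R / mcma_model.R.

## paths to trainable numeric leaves (batch-norm running statistics and the
## input/response scalers are state, not parameters)
collectParamPaths <- function(x, prefix = character()) {
  out <- list()
  for (nm in names(x)) {
    if (nm %in% c("running", "scaler", "yScaler")) next
    el <- x[[nm]]
    if (is.list(el)) {
      out <- c(out, collectParamPaths(el, c(prefix, nm)))
    } else if (is.numeric(el)) {
      out[[length(out) + 1L]] <- c(prefix, nm)
    }
  }
  out
}

getByPath <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

setByPath <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
  } else {
    x[[path[1L]]] <- setByPath(x[[path[1L]]], path[-1L], value)
  }
  x
}

flattenParams <- function(params) {
  paths <- collectParamPaths(params)
  lapply(paths, function(p) getByPath(params, p))
}

## one forward+backward pass on a prepared batch; y is in scaled space
mcmaBatchGrad <- function(params, config, inputs, y, train = TRUE) {
  fw <- mcmaForwardCore(params, config, inputs, train = train)
  err <- fw$pred - y
  loss <- mean(err^2)
  dPred <- 2 * err / length(y)
  grads <- mcmaBackwardCore(fw$params, config, fw$cache, dPred)
  list(loss = loss, grads = grads, params = fw$params, pred = fw$pred)
}

subsetInputs <- function(inputs, idx) {
  out <- list()
  for (nm in names(inputs)) {
    out[[nm]] <- if (nm == "condition") {
      inputs[[nm]][idx, , drop = FALSE]
    } else {
      inputs[[nm]][idx, , , , drop = FALSE]
    }
  }
  out
}

adamInit <- function(params, paths) {
  zeros <- lapply(paths, function(p) {
    v <- getByPath(params, p)
    v * 0
  })
  list(m = zeros, v = zeros, t = 0L)
}

## Adam with decoupled weight decay on weight matrices (leaf names
## containing "W"); biases and batch-norm parameters are not decayed.
adamStep <- function(params, grads, state, paths, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(paths)) {
    g <- getByPath(grads, paths[[k]])
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    w <- getByPath(params, paths[[k]])
    upd <- lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    if (weightDecay > 0 && grepl("W", utils::tail(paths[[k]], 1L))) {
      upd <- upd + lr * weightDecay * w
    }
    params <- setByPath(params, paths[[k]], w - upd)
  }
  list(params = params, state = state)
}

#' Train an MCMA model
#'
#' Minimises squared error by mini-batch Adam on the training records, with
#' early stopping on validation MAE (configured patience). Per-branch input
#' scalers and the response scaler are fixed from the training set. Fully
#' deterministic under `config$seed`.
#'
#' @param config an `McmaConfig` from [mcmaConfig()].
#' @param trainRecords,valRecords disjoint lists of
#'   [PhysioRecord-class] objects.
#' @param verbose print per-epoch progress.
#' @return A list: `model` (the [McmaModel-class] at the best validation
#'   epoch) and `history` (data.frame epoch / trainLoss / valMae).
#' @export
trainMcma <- function(config, trainRecords, valRecords, verbose = FALSE) {
  model <- mcmaInit(config)
  params <- model@params
  inputs <- mcmaInputs(trainRecords, config)
  valInputs <- mcmaInputs(valRecords, config)
  y <- vapply(trainRecords, bartScore, numeric(1))
  valY <- vapply(valRecords, bartScore, numeric(1))

  for (br in intersect(SIGNAL_BRANCHES, config$branches)) {
    params$scaler$center[[br]] <- mean(inputs[[br]])
    params$scaler$scale[[br]] <- max(stats::sd(inputs[[br]]), 1e-8)
  }
  params$yScaler <- list(center = mean(y), scale = max(stats::sd(y), 1e-8))
  yS <- (y - params$yScaler$center) / params$yScaler$scale

  paths <- collectParamPaths(params)
  adam <- adamInit(params, paths)
  n <- length(trainRecords)
  bestMae <- Inf
  bestParams <- params
  bestEpoch <- 0L
  history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                        valMae = numeric(0))
  wd <- if (is.null(config$weightDecay)) 0 else config$weightDecay
  for (epoch in seq_len(config$epochs)) {
    lrEpoch <- config$lr
    if (!is.null(config$lrDecayFactor) && config$lrDecayFactor < 1) {
      lrEpoch <- config$lr * config$lrDecayFactor^((epoch - 1L) %/% config$lrDecayEvery)
    }
    idx <- withLocalSeed(config$seed + 7L * epoch, sample.int(n))
    lossSum <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config$batchSize)) {
      bidx <- idx[start:min(start + config$batchSize - 1L, n)]
      bg <- mcmaBatchGrad(params, config, subsetInputs(inputs, bidx),
                          yS[bidx], train = TRUE)
      params <- bg$params
      st <- adamStep(params, bg$grads, adam, paths, lrEpoch, wd)
      params <- st$params
      adam <- st$state
      lossSum <- lossSum + bg$loss
      nb <- nb + 1L
    }
    valPred <- mcmaForwardCore(params, config, valInputs, train = FALSE)$pred *
      params$yScaler$scale + params$yScaler$center
    valMae <- mean(abs(valPred - valY))
    history <- rbind(history, data.frame(epoch = epoch, trainLoss = lossSum / nb,
                                         valMae = valMae))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val MAE %.3f", epoch,
                      lossSum / nb, valMae))
    }
    if (valMae < bestMae - 1e-9) {
      bestMae <- valMae
      bestParams <- params
      bestEpoch <- epoch
    } else if (epoch - bestEpoch >= config$patience) {
      break
    }
  }
  model@params <- bestParams
  list(model = model, history = history)
}
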