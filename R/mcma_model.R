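## The multi-input convolutional multihead-attention (MCMA) model: one
## convolutional branch per raw channel (EDA, BVP, IBI, TEMP), a one-hot
## condition branch, embedding of every branch to a common width, multihead
## self-attention over the stacked branch tokens, and a small regression
## head that predicts the BART score.

SIGNAL_BRANCHES <- c("EDA", "BVP", "IBI", "TEMP")
ALL_BRANCHES <- c(SIGNAL_BRANCHES, "condition")

#' MCMA architecture and training configuration
#'
#' Defaults follow the stated architecture: inputs of modal lengths 72
#' (EDA, 4 Hz), 1200 (BVP, 64 Hz), 16 (IBI intervals) and 72 (TEMP, 4 Hz),
#' sliced into `T = 8` time steps; per-branch convolutional blocks with
#' batch normalisation and an intermediate (2 x 2) max pooling — (2 x 1) for
#' the IBI branch whose per-step width is only 2 — followed by the sum of
#' global average and global max pooling; 256-unit embeddings; multihead
#' self-attention over the 5 stacked tokens with `h = 8` heads and
#' `d_k = d_v = 256/8 = 32`; and a linear regression head on the flattened
#' fused tokens. Attention scaling defaults to `1/sqrt(d_k)`; `"dk"`
#' selects the linear-scaling variant. Conv filter counts default to (8, 16)
#' to keep single-CPU training fast; all are overridable.
#'
#' @param T number of time steps each input is sliced into.
#' @param inputLengths named integer vector over EDA/BVP/IBI/TEMP; each must
#'   be divisible by `T`.
#' @param dModel embedding width (tokens are `dModel`-vectors).
#' @param nHeads number of attention heads; must divide `dModel`.
#' @param convFilters integer pair: filters of the two conv layers.
#' @param kernel odd kernel size of the square conv filters.
#' @param branches character subset of
#'   `c("EDA","BVP","IBI","TEMP","condition")`: the enabled input branches
#'   (ablation switches).
#' @param mhaEnabled logical; `FALSE` replaces attention fusion by plain
#'   concatenation of the embeddings (ablation switch).
#' @param mhaResidual logical; add the token matrix to the attention output
#'   (the standard Transformer residual connection, default `TRUE`). Without
#'   it the near-uniform attention of an untrained model averages the five
#'   tokens together and token identity is lost to the regression head.
#' @param attnScale `"sqrt"` or `"dk"`.
#' @param headHidden width of the hidden layer in the regression head.
#' @param fusion `"flatten"` (concatenate the fused tokens, default) or
#'   `"mean"` (average them) before the regression head; averaging gives a
#'   five-fold smaller head, which can generalise better on small samples.
#' @param lr,batchSize,epochs,patience Adam learning rate, mini-batch size,
#'   epoch cap and early-stopping patience (on validation MAE).
#' @param weightDecay decoupled weight decay applied to weight matrices
#'   (not biases or batch-norm parameters).
#' @param lrDecayFactor,lrDecayEvery step learning-rate schedule:
#'   multiply the rate by `lrDecayFactor` every `lrDecayEvery` epochs
#'   (factor 1 disables).
#' @param seed integer seed for initialisation and batch shuffling.
#' @return A validated list of class `McmaConfig`.
#' @export
mcmaConfig <- function(T = 8,
                       inputLengths = c(EDA = 72, BVP = 1200, IBI = 16, TEMP = 72),
                       dModel = 256, nHeads = 8,
                       convFilters = c(8, 16), kernel = 3,
                       branches = ALL_BRANCHES,
                       mhaEnabled = TRUE,
                       mhaResidual = TRUE,
                       attnScale = c("sqrt", "dk"),
                       headHidden = 64,
                       fusion = c("flatten", "mean"),
                       lr = 1e-3, batchSize = 32, epochs = 60, patience = 10,
                       weightDecay = 1e-4, lrDecayFactor = 0.3,
                       lrDecayEvery = 40, seed = 0) {
  fusion <- match.arg(fusion)
  attnScale <- match.arg(attnScale)
  cfg <- list(T = as.integer(T), inputLengths = inputLengths,
              dModel = as.integer(dModel), nHeads = as.integer(nHeads),
              dK = as.integer(dModel / nHeads), dV = as.integer(dModel / nHeads),
              convFilters = as.integer(convFilters), kernel = as.integer(kernel),
              branches = branches, mhaEnabled = isTRUE(mhaEnabled),
              mhaResidual = isTRUE(mhaResidual),
              attnScale = attnScale, headHidden = as.integer(headHidden),
              fusion = fusion,
              lr = lr, batchSize = as.integer(batchSize),
              epochs = as.integer(epochs), patience = as.integer(patience),
              weightDecay = weightDecay, lrDecayFactor = lrDecayFactor,
              lrDecayEvery = as.integer(lrDecayEvery),
              seed = as.integer(seed))
  class(cfg) <- "McmaConfig"
  validateMcmaConfig(cfg)
  cfg
}

validateMcmaConfig <- function(cfg) {
  if (!all(SIGNAL_BRANCHES %in% names(cfg$inputLengths))) {
    tactileError("inputLengths must name EDA, BVP, IBI, TEMP", "invalidConfig")
  }
  if (any(cfg$inputLengths %% cfg$T != 0)) {
    tactileError("every input length must be divisible by T", "invalidConfig")
  }
  if (cfg$dModel %% cfg$nHeads != 0) {
    tactileError("dModel must be divisible by nHeads", "invalidConfig")
  }
  if (!all(cfg$branches %in% ALL_BRANCHES) || length(cfg$branches) == 0) {
    tactileError("branches must be a non-empty subset of the five input branches",
                 "invalidAblation")
  }
  if (cfg$kernel %% 2 != 1) tactileError("kernel must be odd", "invalidConfig")
  invisible(cfg)
}

## per-branch step width and intermediate pooling size; the IBI branch pools
## (2 x 1) because its step width (2) would not survive a width-2 pool twice
branchGeometry <- function(cfg, branch) {
  Fw <- as.integer(cfg$inputLengths[[branch]] / cfg$T)
  pool <- if (Fw < 4) c(2L, 1L) else c(2L, 2L)
  list(Fw = Fw, pool = pool)
}

#' Canonicalise a sequence to a fixed length
#'
#' Longer inputs keep their most recent `targetLength` samples (the tail);
#' shorter inputs are pre-padded with copies of their first sample.
#'
#' @param x numeric vector, non-empty.
#' @param targetLength the fixed model input length.
#' @return Numeric vector of length `targetLength`.
#' @export
canonicalizeLength <- function(x, targetLength) {
  n <- length(x)
  if (n == 0L) tactileError("cannot canonicalise an empty series", "insufficientData")
  if (n >= targetLength) {
    x[(n - targetLength + 1L):n]
  } else {
    c(rep(x[1L], targetLength - n), x)
  }
}

#' Slice a fixed-length sequence into T time steps
#'
#' Row `t` of the result holds samples `[(t-1) * L/T + 1, t * L/T]`;
#' flattening the rows in order restores the input.
#'
#' @param x numeric vector whose length is divisible by `T`.
#' @param T number of time steps (rows).
#' @return A `T x (length(x)/T)` matrix.
#' @export
sliceToTimesteps <- function(x, T) {
  L <- length(x)
  if (L %% T != 0) {
    tactileError("length must be divisible by T after canonicalisation",
                 "shapeError")
  }
  matrix(x, nrow = T, ncol = L / T, byrow = TRUE)
}

#' One-hot encode an interaction condition
#'
#' Fixed ordering (LI, HI, NT, NR).
#'
#' @param cond a condition label.
#' @return Numeric 4-vector summing to 1.
#' @export
encodeCondition <- function(cond) {
  if (!cond %in% CONDITIONS) {
    tactileError(sprintf("unknown condition: %s", cond), "invalidCondition")
  }
  as.numeric(CONDITIONS == cond)
}

#' McmaModel: parameters plus configuration
#'
#' @slot params list of all learnable parameters (per-branch conv blocks,
#'   embeddings, attention projections, regression head), batch-norm running
#'   statistics, and the input/response scalers fixed at training time.
#' @slot config the `McmaConfig` list.
#' @export
setClass("McmaModel", representation(params = "list", config = "list"))

setMethod("show", "McmaModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "McmaModel: branches [%s], T = %d, d_model = %d, heads = %d, MHA %s\n",
    paste(cfg$branches, collapse = ", "), cfg$T, cfg$dModel, cfg$nHeads,
    if (cfg$mhaEnabled) "on" else "off (concatenation fusion)"))
  cat(sprintf("  %d parameters\n",
              sum(vapply(flattenParams(object@params), length, integer(1)))))
  invisible(object)
})

heInit <- function(nr, nc, fanIn) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fanIn)), nr, nc)
glorotInit <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)

#' Initialise an MCMA model
#'
#' Weights are drawn reproducibly from `config$seed` (He initialisation for
#' the ReLU conv/dense layers, Glorot for the attention projections).
#'
#' @param config an `McmaConfig`.
#' @return An [McmaModel-class] with untrained weights.
#' @export
mcmaInit <- function(config) {
  validateMcmaConfig(config)
  k <- config$kernel
  C1 <- config$convFilters[1]; C2 <- config$convFilters[2]
  params <- withLocalSeed(config$seed, {
    p <- list(branches = list())
    for (br in intersect(SIGNAL_BRANCHES, config$branches)) {
      p$branches[[br]] <- list(
        convW1 = heInit(k * k * 1L, C1, k * k),
        bn1 = list(gamma = rep(1, C1), beta = numeric(C1),
                   running = list(mean = numeric(C1), var = rep(1, C1))),
        convW2 = heInit(k * k * C1, C2, k * k * C1),
        bn2 = list(gamma = rep(1, C2), beta = numeric(C2),
                   running = list(mean = numeric(C2), var = rep(1, C2))),
        embW = heInit(C2, config$dModel, C2),
        embB = numeric(config$dModel))
    }
    if ("condition" %in% config$branches) {
      p$condition <- list(embW = heInit(4L, config$dModel, 4L),
                          embB = numeric(config$dModel))
    }
    if (config$mhaEnabled) {
      d <- config$dModel
      p$mha <- list(
        Wq = glorotInit(d, config$nHeads * config$dK), bq = numeric(config$nHeads * config$dK),
        Wk = glorotInit(d, config$nHeads * config$dK), bk = numeric(config$nHeads * config$dK),
        Wv = glorotInit(d, config$nHeads * config$dV), bv = numeric(config$nHeads * config$dV),
        ## zero-init output projection: with the residual connection the
        ## fusion starts as the identity and attention is learned smoothly
        Wo = matrix(0, config$nHeads * config$dV, d), bo = numeric(d))
    }
    nTok <- length(config$branches)
    headIn <- if (identical(config$fusion, "mean")) config$dModel else nTok * config$dModel
    p$head <- list(
      W1 = heInit(headIn, config$headHidden, headIn),
      b1 = numeric(config$headHidden),
      W2 = heInit(config$headHidden, 1L, config$headHidden),
      b2 = numeric(1L))
    ## input/response scalers: identity until train() fixes them
    p$scaler <- list(center = stats::setNames(rep(0, 4), SIGNAL_BRANCHES),
                     scale = stats::setNames(rep(1, 4), SIGNAL_BRANCHES))
    p$yScaler <- list(center = 0, scale = 1)
    p
  })
  new("McmaModel", params = params, config = unclass(config))
}

## records -> list of input arrays: per signal branch (B, T, F, 1) and the
## one-hot condition matrix (B, 4)
mcmaInputs <- function(records, config) {
  B <- length(records)
  out <- list()
  for (br in intersect(SIGNAL_BRANCHES, config$branches)) {
    L <- config$inputLengths[[br]]
    geom <- branchGeometry(config, br)
    arr <- array(0, c(B, config$T, geom$Fw, 1L))
    for (i in seq_len(B)) {
      r <- records[[i]]
      x <- switch(br,
                  EDA = signalValues(eda(r)),
                  BVP = signalValues(bvp(r)),
                  TEMP = signalValues(temp(r)),
                  IBI = durations(ibi(r)))
      arr[i, , , 1L] <- sliceToTimesteps(canonicalizeLength(x, L), config$T)
    }
    out[[br]] <- arr
  }
  if ("condition" %in% config$branches) {
    out$condition <- t(vapply(records, function(r) encodeCondition(condition(r)),
                              numeric(4)))
  }
  out
}

#' Convolutional block of one branch
#'
#' conv (same padding) -> batch norm -> ReLU -> max pool -> conv -> batch
#' norm -> ReLU -> global average pooling + global max pooling (summed).
#' Exposed for inspection/testing on a single `T x F` slice matrix; `train`
#' selects batch vs running statistics in the batch-norm layers.
#'
#' @param x a `T x F` matrix (one sliced input).
#' @param branchParams one entry of `model@params$branches`.
#' @param pool integer pair, the intermediate pooling size.
#' @param kernel conv kernel size.
#' @param train logical.
#' @return Representation vector of length `convFilters[2]`.
#' @export
convBlock <- function(x, branchParams, pool = c(2L, 2L), kernel = 3L, train = FALSE) {
  arr <- array(0, c(1L, nrow(x), ncol(x), 1L))
  arr[1L, , , 1L] <- x
  fw <- branchForward(arr, branchParams, pool, kernel, train)
  as.numeric(fw$emb$out)
}

branchForward <- function(x, bp, pool, k, train) {
  c1 <- conv2dForward(x, bp$convW1, k)
  n1 <- bnForward(c1$out, bp$bn1$gamma, bp$bn1$beta, bp$bn1$running, train)
  r1 <- reluForward(n1$out)
  p1 <- maxPoolForward(r1$out, pool[1], pool[2])
  c2 <- conv2dForward(p1$out, bp$convW2, k)
  n2 <- bnForward(c2$out, bp$bn2$gamma, bp$bn2$beta, bp$bn2$running, train)
  r2 <- reluForward(n2$out)
  g <- gapGmpForward(r2$out)
  emb <- denseForward(g$out, bp$embW, bp$embB)
  list(c1 = c1, n1 = n1, r1 = r1, p1 = p1, c2 = c2, n2 = n2, r2 = r2,
       g = g, emb = emb, running1 = n1$running, running2 = n2$running)
}

branchBackward <- function(dEmb, bp, cache, k) {
  de <- denseBackward(dEmb, bp$embW, cache$emb$cache)
  dg <- gapGmpBackward(de$dx, cache$g$cache)
  dr2 <- reluBackward(dg, cache$r2$cache)
  dn2 <- bnBackward(dr2, bp$bn2$gamma, cache$n2$cache)
  dc2 <- conv2dBackward(dn2$dx, bp$convW2, cache$c2$cache)
  dp1 <- maxPoolBackward(dc2$dx, cache$p1$cache)
  dr1 <- reluBackward(dp1, cache$r1$cache)
  dn1 <- bnBackward(dr1, bp$bn1$gamma, cache$n1$cache)
  ## the input gradient of the first conv layer is never used
  dc1 <- conv2dBackward(dn1$dx, bp$convW1, cache$c1$cache, needDx = FALSE)
  list(grads = list(convW1 = dc1$dW,
                    bn1 = list(gamma = dn1$dgamma, beta = dn1$dbeta),
                    convW2 = dc2$dW,
                    bn2 = list(gamma = dn2$dgamma, beta = dn2$dbeta),
                    embW = de$dW, embB = de$db))
}

## Full forward pass on prepared inputs. Returns scaled-space predictions
## plus every cache needed for the backward pass; updates running BN stats
## in `params` when train = TRUE (caller keeps the returned params).
mcmaForwardCore <- function(params, config, inputs, train) {
  B <- if ("condition" %in% config$branches) nrow(inputs$condition) else dim(inputs[[1]])[1]
  k <- config$kernel
  nTok <- length(config$branches)
  tok <- array(0, c(B, nTok, config$dModel))
  caches <- list()
  ti <- 0L
  for (br in config$branches) {
    ti <- ti + 1L
    if (br == "condition") {
      emb <- denseForward(inputs$condition, params$condition$embW, params$condition$embB)
      tok[, ti, ] <- emb$out
      caches[[br]] <- emb
    } else {
      geom <- branchGeometry(config, br)
      xin <- (inputs[[br]] - params$scaler$center[[br]]) / params$scaler$scale[[br]]
      fw <- branchForward(xin, params$branches[[br]], geom$pool, k, train)
      if (train) {
        params$branches[[br]]$bn1$running <- fw$running1
        params$branches[[br]]$bn2$running <- fw$running2
      }
      tok[, ti, ] <- fw$emb$out
      caches[[br]] <- fw
    }
  }
  if (config$mhaEnabled) {
    alpha <- if (config$attnScale == "sqrt") 1 / sqrt(config$dK) else 1 / config$dK
    mh <- mhaForward(tok, params$mha, config$nHeads, config$dK, config$dV, alpha)
    fused <- if (isTRUE(config$mhaResidual)) tok + mh$out else mh$out
    caches$mha <- mh
  } else {
    fused <- tok
  }
  if (identical(config$fusion, "mean")) {
    flat <- matrix(0, B, config$dModel)
    for (ti in seq_len(nTok)) flat <- flat + matrix(fused[, ti, ], B, config$dModel)
    flat <- flat / nTok
  } else {
    flat <- fused
    dim(flat) <- c(B, nTok * config$dModel)
  }
  h1 <- denseForward(flat, params$head$W1, params$head$b1)
  a1 <- reluForward(h1$out)
  h2 <- denseForward(a1$out, params$head$W2, params$head$b2)
  pred <- as.numeric(h2$out)
  if (any(!is.finite(pred))) {
    tactileError("non-finite activations: training diverged", "trainingDiverged")
  }
  list(pred = pred, params = params,
       cache = list(tok = tok, caches = caches, h1 = h1, a1 = a1, h2 = h2,
                    B = B, nTok = nTok))
}

## Backward pass: dPred is dLoss/dPred (length B, scaled space).
mcmaBackwardCore <- function(params, config, cache, dPred) {
  B <- cache$B; nTok <- cache$nTok
  grads <- list()
  d2 <- denseBackward(matrix(dPred, B, 1L), params$head$W2, cache$h2$cache)
  da1 <- reluBackward(d2$dx, cache$a1$cache)
  d1 <- denseBackward(da1, params$head$W1, cache$h1$cache)
  grads$head <- list(W1 = d1$dW, b1 = d1$db, W2 = d2$dW, b2 = d2$db)
  if (identical(config$fusion, "mean")) {
    dFlat <- array(0, c(B, nTok, config$dModel))
    for (ti in seq_len(nTok)) dFlat[, ti, ] <- d1$dx / nTok
  } else {
    dFlat <- d1$dx
    dim(dFlat) <- c(B, nTok, config$dModel)
  }
  if (config$mhaEnabled) {
    mb <- mhaBackward(dFlat, params$mha, cache$caches$mha$cache,
                      config$nHeads, config$dK, config$dV)
    grads$mha <- mb$grads
    dTok <- if (isTRUE(config$mhaResidual)) dFlat + mb$dx else mb$dx
  } else {
    dTok <- dFlat
  }
  ti <- 0L
  for (br in config$branches) {
    ti <- ti + 1L
    dEmb <- matrix(dTok[, ti, ], B, config$dModel)
    if (br == "condition") {
      de <- denseBackward(dEmb, params$condition$embW, cache$caches[[br]]$cache)
      grads$condition <- list(embW = de$dW, embB = de$db)
    } else {
      bb <- branchBackward(dEmb, params$branches[[br]], cache$caches[[br]],
                           config$kernel)
      grads$branches[[br]] <- bb$grads
    }
  }
  grads
}

#' Predict BART scores with an MCMA model
#'
#' Runs the network in evaluation mode (batch-norm running statistics) on a
#' list of records and maps predictions back to the score scale.
#'
#' @param object an [McmaModel-class].
#' @param records list of [PhysioRecord-class] objects.
#' @param ... unused.
#' @return Numeric vector of predicted BART scores.
#' @export
setMethod("predict", "McmaModel", function(object, records, ...) {
  inputs <- mcmaInputs(records, object@config)
  fw <- mcmaForwardCore(object@params, object@config, inputs, train = FALSE)
  fw$pred * object@params$yScaler$scale + object@params$yScaler$center
})
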