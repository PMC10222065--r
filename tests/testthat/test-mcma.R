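test_that("slicing the modal input lengths gives the stated step widths", {
  m <- sliceToTimesteps(seq_len(72), 8)
  expect_equal(dim(m), c(8, 9))
  expect_equal(dim(sliceToTimesteps(seq_len(1200), 8)), c(8, 150))
  expect_equal(dim(sliceToTimesteps(seq_len(16), 8)), c(8, 2))
  ## row t holds the t-th contiguous block; flattening restores the input
  expect_equal(m[1, ], 1:9)
  expect_equal(as.vector(t(m)), seq_len(72))
  col <- sliceToTimesteps(seq_len(8), 8)
  expect_equal(dim(col), c(8, 1))
  expect_equal(as.vector(t(col)), 1:8)
  expect_error(sliceToTimesteps(seq_len(10), 8), class = "shapeError")
})

test_that("length canonicalisation keeps the tail and pre-pads with the edge", {
  x <- seq_len(72)
  expect_identical(canonicalizeLength(x, 72), x)
  expect_identical(canonicalizeLength(seq_len(80), 72), 9:80)
  short <- canonicalizeLength(seq_len(60), 72)
  expect_length(short, 72)
  expect_identical(short[1:13], c(rep(1L, 12), 1L))
  expect_identical(short[13:72], 1:60)
  expect_error(canonicalizeLength(numeric(0), 10), class = "insufficientData")
})

test_that("condition one-hot coding uses the fixed LI/HI/NT/NR order", {
  expect_equal(encodeCondition("HI"), c(0, 1, 0, 0))
  for (cc in CONDITIONS) expect_equal(sum(encodeCondition(cc)), 1)
  expect_error(encodeCondition("ZZ"), class = "invalidCondition")
})

test_that("scaled dot-product attention satisfies its structural identities", {
  set.seed(61)
  ## identical query rows give identical output rows
  Q <- matrix(rep(rnorm(4), each = 3), 3)
  K <- matrix(rnorm(5 * 4), 5)
  V <- matrix(rnorm(5 * 2), 5)
  out <- scaledDotProductAttention(Q, K, V)
  expect_equal(out[1, ], out[2, ])
  expect_equal(out[1, ], out[3, ])

  ## saturation: a query aligned with an orthogonal key picks that value row
  Ko <- diag(4)
  Vo <- matrix(rnorm(4 * 3), 4)
  qs <- matrix(100 * Ko[2, ], 1)
  expect_equal(as.numeric(scaledDotProductAttention(qs, Ko, Vo)), Vo[2, ],
               tolerance = 1e-10)

  ## uniform attention averages the value rows
  u <- scaledDotProductAttention(matrix(0, 2, 4), Ko, diag(4))
  expect_equal(unname(u), matrix(0.25, 2, 4))

  expect_error(scaledDotProductAttention(matrix(0, 2, 3), Ko, Vo),
               class = "shapeError")
})

test_that("softmax rows sum to one and outputs stay in the value hull", {
  set.seed(62)
  for (i in 1:20) {
    S <- matrix(rnorm(5 * 5, 0, 3), 5)
    P <- softmaxRows(S)
    expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
    V <- matrix(rnorm(5 * 4), 5)
    out <- P %*% V
    for (j in 1:4) {
      expect_true(all(out[, j] <= max(V[, j]) + 1e-10))
      expect_true(all(out[, j] >= min(V[, j]) - 1e-10))
    }
  }
})

test_that("multihead attention reduces to single-head attention and matches the loop oracle", {
  set.seed(63)
  d <- 6
  ## h = 1 with identity projections equals plain attention
  idParams <- list(Wq = diag(d), bq = numeric(d), Wk = diag(d), bk = numeric(d),
                   Wv = diag(d), bv = numeric(d), Wo = diag(d), bo = numeric(d))
  X <- matrix(rnorm(5 * d), 5)
  expect_equal(multiHeadAttention(X, idParams, 1, d, d),
               scaledDotProductAttention(X, X, X), tolerance = 1e-12)

  ## naive triple-loop oracle on random 5 x 256 inputs, 8 heads
  for (i in 1:5) {
    X2 <- matrix(rnorm(5 * 256), 5)
    pars <- randomMhaParams(256, 8, 32, 32)
    got <- multiHeadAttention(X2, pars, 8, 32, 32)
    want <- oracleMha(X2, pars, 8, 32, 32, 1 / sqrt(32))
    expect_equal(got, want, tolerance = 1e-6)
  }

  ## self-attention without positions is permutation-equivariant
  X3 <- matrix(rnorm(5 * 256), 5)
  pars <- randomMhaParams(256, 8, 32, 32)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(multiHeadAttention(X3[perm, ], pars, 8, 32, 32),
               multiHeadAttention(X3, pars, 8, 32, 32)[perm, ],
               tolerance = 1e-10)

  ## the printed linear-scaling variant is selectable and differs
  gotDk <- multiHeadAttention(X3, pars, 8, 32, 32, scale = "dk")
  wantDk <- oracleMha(X3, pars, 8, 32, 32, 1 / 32)
  expect_equal(gotDk, wantDk, tolerance = 1e-6)
})

test_that("the convolutional block matches hand-computed cases", {
  ## 1x1 conv with known weights on a 2x2 input is elementwise scaling
  x <- array(0, c(1, 2, 2, 1))
  x[1, , , 1] <- matrix(c(1, 2, 3, 4), 2)
  cf <- tactileRisk:::conv2dForward(x, matrix(2.5, 1, 1), 1L)
  expect_equal(cf$out[1, , , 1], matrix(c(1, 2, 3, 4), 2) * 2.5)

  ## constant map through an identity conv block: GAP + GMP = 2c per channel
  C1 <- 2; C2 <- 3; k <- 3
  W1 <- matrix(0, k * k, C1); W1[5, ] <- 1          # centre tap only
  W2 <- matrix(0, k * k * C1, C2)
  for (j in seq_len(C2)) W2[4 * C1 + 1, j] <- 1     # centre tap, channel 1
  bp <- list(convW1 = W1,
             bn1 = list(gamma = rep(1, C1), beta = rep(0, C1),
                        running = list(mean = rep(0, C1), var = rep(1, C1))),
             convW2 = W2,
             bn2 = list(gamma = rep(1, C2), beta = rep(0, C2),
                        running = list(mean = rep(0, C2), var = rep(1, C2))),
             embW = diag(C2), embB = numeric(C2))
  cval <- 1.7
  rep2c <- convBlock(matrix(cval, 4, 4), bp, pool = c(2L, 2L), kernel = 3L,
                     train = FALSE)
  expect_equal(rep2c, rep(2 * cval, C2), tolerance = 1e-4)

  ## GMP >= GAP elementwise for any map
  set.seed(64)
  xr <- array(rnorm(2 * 4 * 6 * 3), c(2, 4, 6, 3))
  g <- tactileRisk:::gapGmpForward(xr)$out
  for (b in 1:2) for (cc in 1:3) {
    expect_gte(g[b, cc], 2 * mean(xr[b, , , cc]))   # gap+gmp >= 2*gap
  }
})

test_that("analytic gradients match central differences on a tiny model", {
  set.seed(65)
  ds <- generateDataset(genParams(nSubjects = 3, seed = 66))
  cfg <- tinyMcmaConfig(seed = 42)
  m <- mcmaInit(cfg)
  inputs <- tactileRisk:::mcmaInputs(ds$records[1:5], cfg)
  y <- rnorm(5)
  p <- m@params
  bg <- tactileRisk:::mcmaBatchGrad(p, cfg, inputs, y, train = TRUE)
  paths <- tactileRisk:::collectParamPaths(p)
  for (pp in paths) {
    w <- tactileRisk:::getByPath(p, pp)
    g <- tactileRisk:::getByPath(bg$grads, pp)
    for (kk in sample(seq_along(w), min(2, length(w)))) {
      eps <- 1e-5
      wp <- w; wp[kk] <- w[kk] + eps
      wm <- w; wm[kk] <- w[kk] - eps
      lp <- tactileRisk:::mcmaBatchGrad(tactileRisk:::setByPath(p, pp, wp),
                                        cfg, inputs, y, TRUE)$loss
      lm_ <- tactileRisk:::mcmaBatchGrad(tactileRisk:::setByPath(p, pp, wm),
                                         cfg, inputs, y, TRUE)$loss
      num <- (lp - lm_) / (2 * eps)
      expect_equal(g[kk], num, tolerance = 1e-3)
    }
  }
})

test_that("the forward pass is deterministic and stacks five 256-wide tokens", {
  ds <- generateDataset(genParams(nSubjects = 3, seed = 67))
  cfg <- mcmaConfig(seed = 7)
  m <- mcmaInit(cfg)
  recs <- ds$records[1:4]
  p1 <- predict(m, recs)
  p2 <- predict(m, recs)
  expect_identical(p1, p2)
  expect_length(p1, 4)
  expect_true(all(is.finite(p1)))

  inputs <- tactileRisk:::mcmaInputs(recs, cfg)
  fw <- tactileRisk:::mcmaForwardCore(m@params, m@config, inputs, train = FALSE)
  expect_equal(dim(fw$cache$tok), c(4, 5, 256))

  ## zeroing the regression head forces the prediction to its bias
  m2 <- m
  m2@params$head$W1[] <- 0
  m2@params$head$W2[] <- 0
  m2@params$head$b2[] <- 0.42
  expect_equal(unname(tactileRisk:::mcmaForwardCore(m2@params, m2@config, inputs,
                                                    train = FALSE)$pred),
               rep(0.42, 4))
})

test_that("training is seeded, early-stops, and learns a planted linear signal", {
  ds <- generateDataset(genParams(nSubjects = 24, seed = 68))
  sp <- splitDataset(ds$records, seed = 1)
  cfg <- mcmaConfig(convFilters = c(4, 8), epochs = 4, patience = 2,
                    batchSize = 16, seed = 5)
  t1 <- trainMcma(cfg, sp$train, sp$val)
  t2 <- trainMcma(cfg, sp$train, sp$val)
  expect_identical(t1$model@params, t2$model@params)
  expect_identical(t1$history, t2$history)

  ## early stopping: when training halts before the epoch cap, the last
  ## epoch is exactly `patience` epochs past the best validation epoch
  cfgStall <- mcmaConfig(convFilters = c(2, 2), epochs = 50, patience = 3,
                         lr = 0, batchSize = 16, seed = 5)
  ts <- trainMcma(cfgStall, sp$train, sp$val)
  expect_lt(nrow(ts$history), 50)
  expect_equal(nrow(ts$history), which.min(ts$history$valMae) + 3)
})

test_that("a planted linear dataset is learnable end to end", {
  ## subject intercept sd 1 so the irreducible between-subject variance does
  ## not cap the attainable validation R2 below the learnability threshold
  ds <- generateDataset(genParams(nSubjects = 60, subjectSd = 1, seed = 0))
  sp <- splitDataset(ds$records, seed = 0)
  cfg <- mcmaConfig(batchSize = 32, lr = 2e-3, epochs = 60, patience = 60,
                    lrDecayEvery = 30, lrDecayFactor = 0.3,
                    fusion = "mean", weightDecay = 1e-3, seed = 0)
  tr <- trainMcma(cfg, sp$train, sp$val)
  valY <- vapply(sp$val, bartScore, numeric(1))
  m <- computeMetrics(valY, predict(tr$model, sp$val))
  expect_gt(m$r2, 0.8)
})
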