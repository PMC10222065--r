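## Independent brute-force oracles used across the suite. These deliberately
## use naive loops and first-principles formulas, never the package's own
## code paths.

## --- feature oracles ---------------------------------------------------

oracleIbi <- function(d) {
  m <- 0
  for (x in d) m <- m + x
  m <- m / length(d)
  ss <- 0
  for (x in d) ss <- ss + (x - m)^2
  sdn <- sqrt(ss / length(d))
  rs <- 0
  for (i in seq_len(length(d) - 1)) rs <- rs + (d[i + 1] - d[i])^2
  c(mHR = 60 / m, mRRi = m, IBISDNN = sdn, IBIRMSSD = sqrt(rs / (length(d) - 1)))
}

## all-pairs sliding-window oracle for the SCR event count: enumerate every
## (start, end) pair spanning strictly less than windowS seconds whose net
## gain exceeds thresh; repeatedly take the earliest-ending window starting
## after the previous episode's peak, extending each counted episode to the
## local maximum of its rise (one monotone rise counts once).
oracleScrCount <- function(v, rate, thresh = 0.05, windowS = 5) {
  n <- length(v)
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if ((j - i) / rate >= windowS) next
      if (v[j] - v[i] > thresh) {
        starts <- c(starts, i); ends <- c(ends, j)
      }
    }
  }
  if (!length(starts)) return(0L)
  ord <- order(ends, starts)
  count <- 0L
  pos <- 1L
  for (k in ord) {
    if (starts[k] >= pos) {
      count <- count + 1L
      e <- ends[k]
      while (e < n && v[e + 1L] > v[e]) e <- e + 1L
      pos <- e + 1L
    }
  }
  count
}

oracleEda <- function(v, rate) {
  s <- 0
  for (i in seq_len(length(v) - 1)) s <- s + abs(v[i + 1] - v[i])
  c(mAmp = sum(v) / length(v), Slope = s / (length(v) - 1),
    event = oracleScrCount(v, rate))
}

oracleBvp <- function(v) {
  c(mBVP = sum(abs(v)) / length(v), miBVP = min(v), maBVP = max(v))
}

oracleTcr <- function(v, rate) {
  s <- 0
  for (i in seq_len(length(v) - 1)) s <- s + (v[i + 1] - v[i])
  (s / (length(v) - 1)) * rate
}

## --- attention oracles -------------------------------------------------

oracleSoftmaxRow <- function(x) {
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}

oracleAttention <- function(Q, K, V, alpha) {
  n <- nrow(Q); dv <- ncol(V)
  out <- matrix(0, n, dv)
  for (i in seq_len(n)) {
    scores <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) scores[j] <- sum(Q[i, ] * K[j, ]) * alpha
    p <- oracleSoftmaxRow(scores)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + p[j] * V[j, ]
  }
  out
}

## naive multihead self-attention: per-head projections, attention, concat,
## output projection, all as explicit loops over heads
oracleMha <- function(X, params, nHeads, dK, dV, alpha) {
  n <- nrow(X)
  H <- matrix(0, n, nHeads * dV)
  for (i in seq_len(nHeads)) {
    ck <- ((i - 1) * dK + 1):(i * dK)
    cv <- ((i - 1) * dV + 1):(i * dV)
    Q <- sweep(X %*% params$Wq[, ck, drop = FALSE], 2, params$bq[ck], "+")
    K <- sweep(X %*% params$Wk[, ck, drop = FALSE], 2, params$bk[ck], "+")
    V <- sweep(X %*% params$Wv[, cv, drop = FALSE], 2, params$bv[cv], "+")
    H[, cv] <- oracleAttention(Q, K, V, alpha)
  }
  sweep(H %*% params$Wo, 2, params$bo, "+")
}

randomMhaParams <- function(d, nHeads, dK, dV) {
  list(Wq = matrix(rnorm(d * nHeads * dK, 0, 0.2), d),
       bq = rnorm(nHeads * dK, 0, 0.1),
       Wk = matrix(rnorm(d * nHeads * dK, 0, 0.2), d),
       bk = rnorm(nHeads * dK, 0, 0.1),
       Wv = matrix(rnorm(d * nHeads * dV, 0, 0.2), d),
       bv = rnorm(nHeads * dV, 0, 0.1),
       Wo = matrix(rnorm(nHeads * dV * d, 0, 0.2), nHeads * dV),
       bo = rnorm(d, 0, 0.1))
}

## --- small fixtures ----------------------------------------------------

## a tiny but valid PhysioRecord built directly (not via the generator)
makeRecord <- function(subject = "S01", cond = "NR", bart = 20,
                       edaVals = rep(1, 72), bvpVals = sin(seq_len(1200) / 8),
                       tempVals = rep(33, 72),
                       ibiDur = rep(0.9, 18)) {
  PhysioRecord(
    subjectId = subject, condition = cond,
    eda = SignalSeries(edaVals, 4, "EDA"),
    bvp = SignalSeries(bvpVals, 64, "BVP"),
    temp = SignalSeries(tempVals, 4, "TEMP"),
    ibi = IbiSeries(cumsum(ibiDur), ibiDur),
    bartScore = bart
  )
}

## tiny MCMA configuration for fast structural/gradient tests
tinyMcmaConfig <- function(...) {
  mcmaConfig(T = 4, inputLengths = c(EDA = 8, BVP = 16, IBI = 8, TEMP = 8),
             dModel = 8, nHeads = 2, convFilters = c(2, 3), headHidden = 5,
             batchSize = 4, epochs = 2, patience = 2, ...)
}
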