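## Neural-network primitives for the multi-input convolutional
## multihead-attention model: 2-D convolution (im2col, BLAS-backed), batch
## normalisation, ReLU, non-overlapping max pooling, global average+max
## pooling, dense layers, and scaled dot-product / multihead attention.
## Every layer has an explicit forward (returning a cache) and backward
## (returning input and parameter gradients); no autodiff framework is used.
##
## Tensor convention: signal maps are arrays (B, H, W, C), column-major, so
## dim<-c(B*H*W, C) is a consistent flattening with row index encoding
## (b, h, w).

## column-wise scale/shift (compiled); a has length ncol(x)
mulCols <- function(x, a) cpp_mul_cols(x, a)
addCols <- function(x, a) cpp_add_cols(x, a)

rowMaxs <- function(x) {
  m <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, j])
  m
}

zeroPad <- function(x, ph, pw) {
  d <- dim(x)
  if (ph == 0 && pw == 0) return(x)
  out <- array(0, c(d[1], d[2] + 2 * ph, d[3] + 2 * pw, d[4]))
  out[, ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- x
  out
}

## im2col for a k x k kernel with 'same' zero padding, stride 1:
## returns (B*H*W, k*k*Cin); column block o = (dw-1)*k + dh holds the input
## shifted by (dh, dw). Compiled inner loop.
im2col <- function(x, k) {
  d <- dim(x)
  cpp_im2col(x, d[1], d[2], d[3], d[4], k)
}

## W is stored as a matrix (k*k*Cin, Cout) with rows ordered to match
## im2col. No bias: every conv here is followed by batch normalisation,
## which absorbs it.
conv2dForward <- function(x, W, k) {
  d <- dim(x)
  xc <- im2col(x, k)
  y <- xc %*% W
  dim(y) <- c(d[1], d[2], d[3], ncol(W))
  list(out = y, cache = list(xc = xc, dimX = d, k = k))
}

conv2dBackward <- function(dy, W, cache, needDx = TRUE) {
  d <- cache$dimX
  B <- d[1]; H <- d[2]; W_ <- d[3]; Cin <- d[4]
  k <- cache$k
  Cout <- ncol(W)
  dym <- dy
  dim(dym) <- c(B * H * W_, Cout)
  dW <- crossprod(cache$xc, dym)
  if (!needDx) return(list(dx = NULL, dW = dW))
  dxc <- tcrossprod(dym, W)          # (B*H*W, k*k*Cin)
  dx <- cpp_col2im(dxc, B, H, W_, Cin, k)
  list(dx = dx, dW = dW)
}

## Batch normalisation over (B, H, W) per channel. In training mode batch
## statistics are used and running statistics updated (momentum 0.9); in
## eval mode the running statistics are used and the transform is affine.
bnForward <- function(x, gamma, beta, running, train, eps = 1e-5, momentum = 0.9) {
  d <- dim(x)
  C <- d[4]
  xm <- x
  dim(xm) <- c(prod(d[1:3]), C)
  if (train) {
    mu <- colMeans(xm)
    xc <- addCols(xm, -mu)
    v <- colMeans(xc^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- addCols(xm, -mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- mulCols(xc, istd)
  y <- addCols(mulCols(xhat, gamma), beta)
  dim(y) <- d
  list(out = y, running = running,
       cache = list(xhat = xhat, istd = istd, dimX = d, train = train))
}

bnBackward <- function(dy, gamma, cache) {
  d <- cache$dimX
  m <- prod(d[1:3])
  dym <- dy
  dim(dym) <- c(m, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$train) {
    dxhat <- mulCols(dym, gamma)
    t1 <- addCols(dxhat, -colMeans(dxhat))
    t2 <- mulCols(cache$xhat, colMeans(dxhat * cache$xhat))
    dx <- mulCols(t1 - t2, cache$istd)
  } else {
    dx <- mulCols(mulCols(dym, gamma), cache$istd)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
reluBackward <- function(dy, cache) dy * cache

## Non-overlapping (ph x pw) max pooling; trailing rows/columns that do not
## fill a window are dropped (floor semantics). Ties route to the first
## window position. The forward pass records the flat index of every
## window maximum so the backward pass is a single scatter (windows are
## disjoint, so indices never collide).
maxPoolForward <- function(x, ph, pw) {
  d <- dim(x)
  r <- cpp_maxpool_fwd(x, d[1], d[2], d[3], d[4], ph, pw)
  list(out = r$out, cache = list(flat = r$flat, dimX = d))
}

maxPoolBackward <- function(dy, cache) {
  d <- cache$dimX
  cpp_maxpool_bwd(dy, cache$flat, d[1], d[2], d[3], d[4])
}

## Global average pooling + global max pooling over (H, W), summed: the
## branch representation is one value per channel. Works on the (B, HW*C)
## flattening, channel block by channel block, to avoid array transposes.
gapGmpForward <- function(x) {
  d <- dim(x)
  r <- cpp_gapgmp_fwd(x, d[1], d[2] * d[3], d[4])
  list(out = r$out, cache = list(arg = r$arg, dimX = d, HW = d[2] * d[3]))
}

gapGmpBackward <- function(dy, cache) {
  d <- cache$dimX
  dx <- cpp_gapgmp_bwd(dy, cache$arg, d[1], cache$HW, d[4])
  dim(dx) <- d
  dx
}

denseForward <- function(x, W, b) {
  list(out = addCols(x %*% W, b), cache = x)
}

denseBackward <- function(dy, W, cache) {
  list(dx = tcrossprod(dy, W), dW = crossprod(cache, dy), db = colSums(dy))
}

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix.
#'
#' @param x numeric matrix.
#' @return Matrix of the same shape; each row sums to 1.
#' @export
softmaxRows <- function(x) {
  e <- exp(x - rowMaxs(x))
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' * scale) V` with row-wise softmax.
#' The default scale is `1/sqrt(d_k)` (the standard Transformer scaling);
#' `scale = "dk"` divides by `d_k` instead (the linear-scaling variant).
#' Each output row is a convex combination of the rows of `V`.
#'
#' @param Q query matrix (n x d_k).
#' @param K key matrix (m x d_k).
#' @param V value matrix (m x d_v).
#' @param scale `"sqrt"` (default) or `"dk"`.
#' @return An (n x d_v) matrix.
#' @export
scaledDotProductAttention <- function(Q, K, V, scale = c("sqrt", "dk")) {
  scale <- match.arg(scale)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    tactileError("attention dimension mismatch: need ncol(Q) == ncol(K) and nrow(K) == nrow(V)",
                 "shapeError")
  }
  a <- if (scale == "sqrt") 1 / sqrt(ncol(K)) else 1 / ncol(K)
  softmaxRows(tcrossprod(Q, K) * a) %*% V
}

## attention with cache for backprop (single head, single example)
sdpaForward <- function(Q, K, V, alpha) {
  P <- softmaxRows(tcrossprod(Q, K) * alpha)
  list(out = P %*% V, cache = list(P = P, Q = Q, K = K, V = V, alpha = alpha))
}

sdpaBackward <- function(dO, cache) {
  P <- cache$P
  dV <- crossprod(P, dO)
  dP <- tcrossprod(dO, cache$V)
  dS <- P * (dP - rowSums(dP * P))
  dQ <- (dS %*% cache$K) * cache$alpha
  dK <- crossprod(dS, cache$Q) * cache$alpha
  list(dQ = dQ, dK = dK, dV = dV)
}

## Multihead self-attention over a batch of token matrices.
## x: (B, n, d); params: Wq/Wk/Wv (d, h*dk|h*dv), bq/bk/bv, Wo (h*dv, d), bo.
mhaForward <- function(x, params, nHeads, dK, dV, alpha) {
  d <- dim(x)
  B <- d[1]; n <- d[2]; dm <- d[3]
  xm <- x
  dim(xm) <- c(B * n, dm)
  Qm <- addCols(xm %*% params$Wq, params$bq)
  Km <- addCols(xm %*% params$Wk, params$bk)
  Vm <- addCols(xm %*% params$Wv, params$bv)
  Hm <- matrix(0, B * n, nHeads * dV)
  caches <- vector("list", B * nHeads)
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(n) - 1L)
    for (i in seq_len(nHeads)) {
      ck <- ((i - 1L) * dK + 1L):(i * dK)
      cv <- ((i - 1L) * dV + 1L):(i * dV)
      att <- sdpaForward(Qm[rows, ck, drop = FALSE], Km[rows, ck, drop = FALSE],
                         Vm[rows, cv, drop = FALSE], alpha)
      Hm[rows, cv] <- att$out
      caches[[(b - 1L) * nHeads + i]] <- att$cache
    }
  }
  Om <- addCols(Hm %*% params$Wo, params$bo)
  out <- Om
  dim(out) <- c(B, n, dm)
  list(out = out,
       cache = list(xm = xm, Qm = Qm, Km = Km, Vm = Vm, Hm = Hm,
                    caches = caches, B = B, n = n, dm = dm))
}

mhaBackward <- function(dOut, params, cache, nHeads, dK, dV) {
  B <- cache$B; n <- cache$n; dm <- cache$dm
  dOm <- dOut
  dim(dOm) <- c(B * n, dm)
  dWo <- crossprod(cache$Hm, dOm)
  dbo <- colSums(dOm)
  dHm <- tcrossprod(dOm, params$Wo)
  dQm <- matrix(0, B * n, ncol(params$Wq))
  dKm <- matrix(0, B * n, ncol(params$Wk))
  dVm <- matrix(0, B * n, ncol(params$Wv))
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(n) - 1L)
    for (i in seq_len(nHeads)) {
      ck <- ((i - 1L) * dK + 1L):(i * dK)
      cv <- ((i - 1L) * dV + 1L):(i * dV)
      g <- sdpaBackward(dHm[rows, cv, drop = FALSE],
                        cache$caches[[(b - 1L) * nHeads + i]])
      dQm[rows, ck] <- g$dQ
      dKm[rows, ck] <- g$dK
      dVm[rows, cv] <- g$dV
    }
  }
  dxm <- tcrossprod(dQm, params$Wq) + tcrossprod(dKm, params$Wk) +
    tcrossprod(dVm, params$Wv)
  dx <- dxm
  dim(dx) <- c(B, n, dm)
  list(dx = dx,
       grads = list(Wq = crossprod(cache$xm, dQm), bq = colSums(dQm),
                    Wk = crossprod(cache$xm, dKm), bk = colSums(dKm),
                    Wv = crossprod(cache$xm, dVm), bv = colSums(dVm),
                    Wo = dWo, bo = dbo))
}

#' Multihead self-attention on a single token matrix
#'
#' Applies `MHA(X, X, X) = Concat(head_1, ..., head_h) W_O` with learned
#' per-head projections, on one (n x d_model) token matrix. This is the
#' fusion operation of the network; the training loop uses the batched
#' internal equivalent.
#'
#' @param X token matrix (n x d_model).
#' @param params list with `Wq`, `Wk`, `Wv` ((d_model x h*d_k/h*d_v)
#'   matrices), `bq`, `bk`, `bv`, `Wo` ((h*d_v x d_model)), `bo`.
#' @param nHeads number of heads `h`.
#' @param dK,dV per-head key/value width; `d_q = d_k`.
#' @param scale `"sqrt"` (default, 1/sqrt(d_k)) or `"dk"`.
#' @return An (n x d_model) matrix.
#' @export
multiHeadAttention <- function(X, params, nHeads, dK, dV, scale = c("sqrt", "dk")) {
  scale <- match.arg(scale)
  alpha <- if (scale == "sqrt") 1 / sqrt(dK) else 1 / dK
  x <- array(0, c(1L, nrow(X), ncol(X)))
  x[1L, , ] <- X
  out <- mhaForward(x, params, nHeads, dK, dV, alpha)$out
  matrix(out[1L, , ], nrow(X), ncol(X))
}
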