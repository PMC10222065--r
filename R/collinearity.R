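## Multicollinearity diagnostics and lasso feature selection.

perFeatureR2 <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(1)
    r2 <- 1 - sum(fit$residuals^2) / tss
    min(max(r2, 0), 1)
  }, numeric(1))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of determination
#' from regressing feature `j` on all the others. Exact collinearity is
#' reported as an `Inf` sentinel together with a flag, not an error.
#'
#' @param X numeric matrix or data.frame of predictors (rows > columns, no
#'   constant column).
#' @return Named numeric vector of VIFs with attribute `"infinite"` (logical
#'   vector flagging exactly collinear columns).
#' @export
computeVif <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) {
    tactileError("computeVif needs more rows than columns", "insufficientData")
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) tactileError("constant column in X", "insufficientData")
  r2 <- perFeatureR2(X)
  tol <- 1e-12
  vif <- ifelse(1 - r2 < tol, Inf, 1 / (1 - r2))
  names(vif) <- colnames(X)
  attr(vif, "infinite") <- !is.finite(vif)
  vif
}

#' Farrar-Glauber multicollinearity diagnostics
#'
#' Overall test: the determinant of the predictor correlation matrix (1 for
#' orthogonal predictors, 0 under exact collinearity) and the chi-square
#' statistic `-(n - 1 - (2p + 5)/6) * log(det)` on `p(p-1)/2` degrees of
#' freedom. Individual diagnosis: per-feature F statistics
#' `F_j = (R2_j / (p - 1)) / ((1 - R2_j) / (n - p))` from the same auxiliary
#' regressions as [computeVif()].
#'
#' @param X numeric matrix or data.frame of predictors.
#' @return A list of class `CollinearityReport`: `vif`, `fgDeterminant`,
#'   `fgChi2`, `fgDf`, `perFeatureF`.
#' @export
farrarGlauber <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  vif <- computeVif(X)
  R <- stats::cor(X)
  dt <- det(R)
  dt <- min(max(dt, 0), 1)
  chi2 <- if (dt <= 0) Inf else -(n - 1 - (2 * p + 5) / 6) * log(dt)
  r2 <- 1 - 1 / ifelse(is.finite(vif), vif, Inf)
  fj <- (r2 / (p - 1)) / ((1 - r2) / (n - p))
  names(fj) <- colnames(X)
  structure(list(vif = vif, fgDeterminant = dt, fgChi2 = max(chi2, 0),
                 fgDf = p * (p - 1) / 2, perFeatureF = fj),
            class = "CollinearityReport")
}

#' @exportS3Method base::print
print.CollinearityReport <- function(x, ...) {
  cat(sprintf("Farrar-Glauber: det(R) = %.4g, chi2 = %.2f on %d df\n",
              x$fgDeterminant, x$fgChi2, x$fgDf))
  cat("VIF:\n")
  print(round(x$vif, 3))
  invisible(x)
}

#' Lasso-path feature selection with cross-validated penalty
#'
#' Fits the lasso path over a decreasing log-spaced penalty grid with
#' K-fold cross-validation (via coordinate descent in \pkg{glmnet}),
#' standardising the predictors internally, and selects the support at the
#' one-standard-error penalty (the sparser conventional choice; the
#' cross-validation-minimising penalty is also reported).
#'
#' @param X numeric predictor matrix.
#' @param y numeric response.
#' @param nFolds number of cross-validation folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param rule `"lambda.1se"` (default) or `"lambda.min"`: which penalty
#'   defines the selected support.
#' @return A list of class `LassoPath`: `lambdas` (decreasing grid),
#'   `coefficients` (lambda x feature matrix, original scale, no intercept),
#'   `lambdaMin`, `lambda1se`, `selected` (character vector of features with
#'   nonzero coefficients at the chosen penalty), and the underlying
#'   `cv.glmnet` fit as `cvFit`.
#' @export
lassoSelect <- function(X, y, nFolds = 10, seed = 1, rule = c("lambda.1se", "lambda.min")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (nFolds < 2 || nrow(X) < nFolds) {
    tactileError("need at least 2 folds and rows >= folds", "invalidFolds")
  }
  foldid <- withLocalSeed(seed, sample(rep_len(seq_len(nFolds), nrow(X))))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid, standardize = TRUE)
  beta <- t(as.matrix(cv$glmnet.fit$beta))   # lambda x feature
  lam <- cv$lambda
  chosen <- if (rule == "lambda.1se") cv$lambda.1se else cv$lambda.min
  coefAt <- as.matrix(stats::coef(cv, s = chosen))[-1L, 1L]
  structure(list(lambdas = lam, coefficients = beta,
                 lambdaMin = cv$lambda.min, lambda1se = cv$lambda.1se,
                 selected = names(coefAt)[coefAt != 0],
                 rule = rule, cvFit = cv),
            class = "LassoPath")
}

#' @exportS3Method base::print
print.LassoPath <- function(x, ...) {
  cat(sprintf("Lasso path: %d lambdas; lambda.min = %.4g, lambda.1se = %.4g\n",
              length(x$lambdas), x$lambdaMin, x$lambda1se))
  cat(sprintf("Selected at %s: %s\n", x$rule,
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"))
  invisible(x)
}
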