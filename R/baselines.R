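## Reference predictors: the random-intercept mixed-effects model and the
## RBF-kernel support vector regression.

#' MixedModelFit: a fitted random-intercept mixed-effects model
#'
#' Wraps a restricted-maximum-likelihood (or maximum-likelihood) fit of
#' `bart_score ~ features + condition + (1 | subject)`, with the condition
#' treatment-coded against the no-robot (NR) control.
#'
#' @slot beta named numeric fixed-effect coefficients (intercept, feature
#'   block coefficients, condition contrasts).
#' @slot u named numeric per-subject random-intercept estimates (BLUPs).
#' @slot sigmaU random-intercept standard deviation.
#' @slot sigmaE residual standard deviation.
#' @slot featureNames character, the feature columns used.
#' @slot logScore logical, whether the response was log(1 + score).
#' @slot model the underlying `lmerMod` object.
#'
#' @export
setClass("MixedModelFit",
  representation(beta = "numeric", u = "numeric", sigmaU = "numeric",
                 sigmaE = "numeric", featureNames = "character",
                 logScore = "logical", model = "ANY"))

setValidity("MixedModelFit", function(object) {
  msgs <- character(0)
  if (object@sigmaU < 0) msgs <- c(msgs, "sigmaU must be >= 0")
  if (object@sigmaE <= 0) msgs <- c(msgs, "sigmaE must be > 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MixedModelFit", function(object) {
  cat(sprintf("MixedModelFit: %d fixed effects, %d subjects; sigma_u = %.3f, sigma_e = %.3f\n",
              length(object@beta), length(object@u), object@sigmaU, object@sigmaE))
  print(round(object@beta, 4))
  invisible(object)
})

mixedFrame <- function(features, conditions, subjectIds, y = NULL) {
  df <- as.data.frame(features)
  df$condition <- conditionFactor(conditions)
  df$subject <- factor(as.character(subjectIds))
  if (!is.null(y)) df$.y <- y
  df
}

#' Fit the random-intercept mixed-effects model
#'
#' Fits `y ~ feature block + condition + (1 | subject)` by REML (default) or
#' ML. One coefficient is estimated per feature column; the condition enters
#' as treatment-coded contrasts with the no-robot control (NR) as reference.
#'
#' @param features data.frame or matrix of feature columns (the selection
#'   output).
#' @param conditions character/factor of condition labels.
#' @param subjectIds character/factor of subject identifiers.
#' @param y numeric response (BART scores).
#' @param REML logical, restricted maximum likelihood (default `TRUE`).
#' @param logScore logical; model `log(1 + y)` instead of `y`.
#' @return A [MixedModelFit-class].
#' @export
fitMixed <- function(features, conditions, subjectIds, y, REML = TRUE,
                     logScore = FALSE) {
  subjectIds <- as.character(subjectIds)
  tab <- table(subjectIds)
  if (length(tab) < 2L) {
    tactileError("need at least 2 subjects", "degenerateGrouping")
  }
  if (max(tab) < 2L) {
    tactileError("need repeated measures: some subject with >= 2 records",
                 "degenerateGrouping")
  }
  yy <- if (logScore) log1p(y) else y
  df <- mixedFrame(features, conditions, subjectIds, yy)
  featNames <- colnames(as.data.frame(features))
  form <- stats::as.formula(paste(
    ".y ~", paste(c(featNames, "condition"), collapse = " + "), "+ (1 | subject)"))
  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = REML,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) {
      if (grepl("rank deficient|singular|dropped", conditionMessage(e), ignore.case = TRUE)) {
        tactileError(paste("singular design:", conditionMessage(e)), "singularDesign")
      }
      stop(e)
    })
  fe <- lme4::fixef(fit)
  if (anyNA(fe)) tactileError("singular design: NA fixed effects", "singularDesign")
  re <- lme4::ranef(fit)$subject
  u <- stats::setNames(re[, 1L], rownames(re))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigmaU <- vc$sdcor[vc$grp == "subject"]
  sigmaE <- stats::sigma(fit)
  new("MixedModelFit", beta = fe, u = u, sigmaU = sigmaU,
      sigmaE = max(sigmaE, .Machine$double.eps), featureNames = featNames,
      logScore = logScore, model = fit)
}

#' Predict BART scores from a mixed-effects fit
#'
#' Subjects seen in training receive their estimated random intercept;
#' unseen subjects are predicted from the fixed effects alone (u = 0).
#'
#' @param fit a [MixedModelFit-class].
#' @param features feature columns matching the fit.
#' @param conditions condition labels.
#' @param subjectIds subject identifiers.
#' @return Numeric predictions on the original score scale.
#' @export
predictMixed <- function(fit, features, conditions, subjectIds) {
  df <- mixedFrame(features, conditions, subjectIds)
  pred <- stats::predict(fit@model, newdata = df, allow.new.levels = TRUE)
  if (fit@logScore) expm1(pred) else unname(pred)
}

#' Numeric residual diagnostics for a mixed-effects fit
#'
#' The numeric content of the four classical regression diagnostic panels:
#' residuals vs fitted, normal quantile-quantile straightness, the
#' scale-location trend, and leverage/influence.
#'
#' @param fit a [MixedModelFit-class].
#' @return A list: `fitted`, `residuals`, `stdResiduals`, `qq` (data.frame
#'   of theoretical and sample quantiles) with `qqCorrelation`,
#'   `scaleLocationSlope` (trend of sqrt(|std resid|) on fitted),
#'   `leverage`, `influence` (Cook's-distance-style measure), and
#'   `degenerate` (TRUE when the residuals are numerically all zero).
#' @export
residualDiagnostics <- function(fit) {
  res <- stats::residuals(fit@model)
  fitted <- stats::fitted(fit@model)
  degenerate <- stats::sd(res) < 1e-10 * max(1, stats::sd(fitted))
  X <- lme4::getME(fit@model, "X")
  H <- X %*% solve(crossprod(X), t(X))
  lev <- pmin(diag(H), 1 - 1e-12)
  p <- ncol(X)
  if (degenerate) {
    return(list(fitted = fitted, residuals = res, stdResiduals = res * 0,
                qq = NULL, qqCorrelation = NA_real_,
                scaleLocationSlope = NA_real_, leverage = lev,
                influence = rep(0, length(res)), degenerate = TRUE))
  }
  std <- res / (fit@sigmaE * sqrt(1 - lev))
  ord <- order(std)
  theo <- stats::qnorm(stats::ppoints(length(std)))
  qq <- data.frame(theoretical = theo, sample = std[ord])
  qqCor <- stats::cor(qq$theoretical, qq$sample)
  sl <- stats::coef(stats::lm(sqrt(abs(std)) ~ fitted))[2L]
  infl <- std^2 * lev / ((1 - lev) * p)
  list(fitted = fitted, residuals = res, stdResiduals = std, qq = qq,
       qqCorrelation = qqCor, scaleLocationSlope = unname(sl),
       leverage = lev, influence = infl, degenerate = FALSE)
}

#' Fit an RBF-kernel support vector regression
#'
#' Epsilon-SVR with a radial basis function kernel (libsvm via \pkg{e1071});
#' features are z-scored internally. Hyperparameter defaults: `C = 1`,
#' `gamma = 1/p` on the scaled features (equivalently 1/(p var)), tube
#' `epsilon = 0.1`.
#'
#' @param features data.frame or matrix of predictors (condition dummies may
#'   be included by the caller).
#' @param y numeric response.
#' @param C regularisation constant.
#' @param gamma RBF bandwidth; default `1/ncol(features)` on scaled inputs.
#' @param epsilon insensitivity tube width.
#' @return A list of class `SvrFit` holding the `svm` object.
#' @export
fitSvr <- function(features, y, C = 1, gamma = NULL, epsilon = 0.1) {
  X <- as.matrix(features)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    tactileError("non-finite inputs to fitSvr", "invalidInput")
  }
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  if (stats::sd(y) < 1e-12) {
    ## degenerate response: the epsilon-tube solution is the constant
    return(structure(list(svm = NULL, constant = y[1L], C = C, gamma = gamma,
                          epsilon = epsilon), class = "SvrFit"))
  }
  fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                    cost = C, gamma = gamma, epsilon = epsilon, scale = TRUE)
  structure(list(svm = fit, constant = NULL, C = C, gamma = gamma,
                 epsilon = epsilon), class = "SvrFit")
}

#' Predict from an SVR fit
#'
#' @param object an `SvrFit` from [fitSvr()].
#' @param newdata predictor matrix with the training columns.
#' @param ... unused.
#' @return Numeric predictions.
#' @exportS3Method stats::predict
predict.SvrFit <- function(object, newdata, ...) {
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(as.matrix(newdata))))
  }
  unname(stats::predict(object$svm, as.matrix(newdata)))
}

#' @exportS3Method base::print
print.SvrFit <- function(x, ...) {
  if (is.null(x$svm)) {
    cat(sprintf("SvrFit: degenerate constant predictor (%g)\n", x$constant))
    return(invisible(x))
  }
  cat(sprintf("SvrFit: RBF epsilon-SVR, C = %g, gamma = %g, epsilon = %g, %d support vectors\n",
              x$C, x$gamma, x$epsilon, x$svm$tot.nSV))
  invisible(x)
}

#' One-hot condition dummies for feature-based models
#'
#' @param conditions character vector of condition labels.
#' @return Matrix with columns `cond_LI`, `cond_HI`, `cond_NT`, `cond_NR`
#'   (fixed ordering).
#' @export
conditionDummies <- function(conditions) {
  f <- conditionFactor(conditions)
  out <- sapply(CONDITIONS, function(cc) as.numeric(as.character(f) == cc))
  colnames(out) <- paste0("cond_", CONDITIONS)
  out
}
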