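makeLinearData <- function(nSubjects = 20, subjectSd = 3, noiseSd = 1, seed = 44) {
  ds <- generateDataset(genParams(nSubjects = nSubjects, subjectSd = subjectSd,
                                  noiseSd = noiseSd, seed = seed))
  list(ds = ds, ft = featureTable(ds$records),
       beta = ds$params$beta, gp = ds$params)
}

test_that("the mixed model identifies planted coefficients exactly at zero noise", {
  d <- makeLinearData(nSubjects = 14, subjectSd = 0, noiseSd = 0, seed = 45)
  fit <- suppressMessages(suppressWarnings(
    fitMixed(d$ft[names(d$beta)], d$ft$condition, d$ft$subject_id,
             d$ft$bart_score)))
  est <- fit@beta[names(d$beta)]
  expect_equal(unname(est), unname(d$beta), tolerance = 1e-3)
  expect_equal(unname(fit@beta["(Intercept)"]), d$gp$intercept, tolerance = 1e-3)
  ## condition contrasts against the no-robot reference
  expect_equal(unname(fit@beta["conditionHI"]),
               d$gp$conditionScoreEffects[["HI"]], tolerance = 1e-3)
})

test_that("the mixed-model fit is invariant to record order", {
  d <- makeLinearData(seed = 46)
  f1 <- fitMixed(d$ft[names(d$beta)], d$ft$condition, d$ft$subject_id,
                 d$ft$bart_score)
  perm <- sample(nrow(d$ft))
  f2 <- fitMixed(d$ft[perm, names(d$beta)], d$ft$condition[perm],
                 d$ft$subject_id[perm], d$ft$bart_score[perm])
  expect_equal(f1@beta, f2@beta, tolerance = 1e-8)
  expect_equal(f1@sigmaU, f2@sigmaU, tolerance = 1e-8)
})

test_that("grouping degeneracies raise classed errors", {
  d <- makeLinearData(seed = 47)
  one <- d$ft[d$ft$subject_id == d$ft$subject_id[1], ]
  expect_error(fitMixed(one[names(d$beta)], one$condition, one$subject_id,
                        one$bart_score), class = "degenerateGrouping")
  expect_error(fitMixed(d$ft[names(d$beta)], d$ft$condition,
                        seq_len(nrow(d$ft)), d$ft$bart_score),
               class = "degenerateGrouping")
})

test_that("mixed-model predictions follow the random-intercept arithmetic", {
  d <- makeLinearData(seed = 48)
  fit <- fitMixed(d$ft[names(d$beta)], d$ft$condition, d$ft$subject_id,
                  d$ft$bart_score)
  ## training rows reproduce fitted values
  pr <- predictMixed(fit, d$ft[names(d$beta)], d$ft$condition, d$ft$subject_id)
  expect_equal(pr, unname(fitted(fit@model)), tolerance = 1e-10)

  ## all-zero features, unseen subject, reference condition -> intercept only
  zero <- as.data.frame(as.list(setNames(rep(0, length(d$beta)), names(d$beta))))
  p0 <- predictMixed(fit, zero, "NR", "GHOST")
  expect_equal(p0, unname(fit@beta["(Intercept)"]), tolerance = 1e-10)

  ## a seen subject differs from an unseen one by exactly its intercept
  sid <- names(fit@u)[1]
  ps <- predictMixed(fit, zero, "NR", sid)
  expect_equal(ps - p0, unname(fit@u[sid]), tolerance = 1e-10)

  expect_error(predictMixed(fit, zero, "??", "GHOST"), class = "invalidCondition")
})

test_that("with no subject variance the fixed effects equal OLS", {
  d <- makeLinearData(nSubjects = 25, subjectSd = 0, noiseSd = 2, seed = 49)
  fit <- suppressMessages(fitMixed(d$ft[names(d$beta)], d$ft$condition,
                                   d$ft$subject_id, d$ft$bart_score, REML = FALSE))
  cond <- factor(d$ft$condition, levels = c("NR", "LI", "HI", "NT"))
  ols <- lm(d$ft$bart_score ~ as.matrix(d$ft[names(d$beta)]) + cond)
  expect_lt(fit@sigmaU, 1e-6)   # boundary estimate: no subject variance
  expect_equal(unname(fit@beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("residual diagnostics quantify the classical panels", {
  ## Gaussian residuals: the Q-Q straightness statistic approaches 1
  set.seed(50)
  n <- 500
  subj <- rep(sprintf("S%02d", 1:50), each = 10)
  x <- rnorm(n)
  y <- 2 * x + rep(rnorm(50, 0, 2), each = 10) + rnorm(n)
  fit <- fitMixed(data.frame(x = x), sample(CONDITIONS, n, TRUE), subj, y)
  dg <- residualDiagnostics(fit)
  expect_false(dg$degenerate)
  expect_gt(dg$qqCorrelation, 0.99)
  expect_lt(abs(dg$scaleLocationSlope), 0.5)
  expect_equal(length(dg$leverage), n)

  ## a gross outlier has the largest influence measure
  y2 <- y; y2[123] <- y2[123] + 40
  fit2 <- fitMixed(data.frame(x = x), sample(CONDITIONS, n, TRUE), subj, y2)
  dg2 <- residualDiagnostics(fit2)
  expect_equal(unname(which.max(dg2$influence)), 123)

  ## perfectly linear noiseless data -> degenerate flag
  d <- makeLinearData(nSubjects = 10, subjectSd = 0, noiseSd = 0, seed = 51)
  fit3 <- suppressMessages(fitMixed(d$ft[names(d$beta)], d$ft$condition,
                                    d$ft$subject_id, d$ft$bart_score))
  dg3 <- residualDiagnostics(fit3)
  expect_true(dg3$degenerate)
})

test_that("the SVR behaves like an epsilon-tube RBF regressor", {
  set.seed(52)
  X <- matrix(rnorm(60 * 3), 60)

  ## constant response -> constant prediction within the tube
  f1 <- fitSvr(X, rep(5, 60))
  expect_equal(predict(f1, X), rep(5, 60), tolerance = 0.1)

  ## exact linear function, generous capacity -> training MAE below 0.1
  y <- as.numeric(X %*% c(1, -2, 0.5))
  f2 <- fitSvr(X, y, C = 100, gamma = 0.05, epsilon = 0.01)
  expect_lt(mean(abs(predict(f2, X) - y)), 0.1)

  ## duplicated training rows leave predictions unchanged
  f3 <- fitSvr(rbind(X, X), c(y, y), C = 10)
  f4 <- fitSvr(X, y, C = 10)
  ## same function class and data support; compare on fresh points
  Xn <- matrix(rnorm(20 * 3), 20)
  expect_equal(predict(f3, Xn), predict(f4, Xn), tolerance = 0.15)

  expect_error(fitSvr(cbind(X, NA), y), class = "invalidInput")
})

test_that("SVR predictions are invariant to affine input rescaling", {
  set.seed(53)
  X <- matrix(rnorm(80 * 4), 80)
  y <- as.numeric(sin(X[, 1]) + X[, 2]^2 + rnorm(80, 0, 0.1))
  Xs <- sweep(sweep(X, 2, c(10, 0.1, 5, 2), "*"), 2, c(1, -3, 0, 7), "+")
  f1 <- fitSvr(X, y)
  f2 <- fitSvr(Xs, y)
  Xn <- matrix(rnorm(20 * 4), 20)
  Xns <- sweep(sweep(Xn, 2, c(10, 0.1, 5, 2), "*"), 2, c(1, -3, 0, 7), "+")
  expect_equal(predict(f1, Xn), predict(f2, Xns), tolerance = 1e-6)
})
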