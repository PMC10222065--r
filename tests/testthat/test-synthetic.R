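test_that("the generator is fully deterministic under its seed", {
  gp <- genParams(nSubjects = 4, seed = 17)
  a <- generateDataset(gp)
  b <- generateDataset(gp)
  expect_identical(a$truth, b$truth)
  edaOf <- function(r) signalValues(eda(r))
  expect_identical(lapply(a$records, edaOf), lapply(b$records, edaOf))
  expect_identical(vapply(a$records, bartScore, numeric(1)),
                   vapply(b$records, bartScore, numeric(1)))
})

test_that("latent arousal follows the planted condition/subject structure", {
  ## all effects zeroed -> arousal identically 0
  gp0 <- genParams(nSubjects = 3, conditionEffects = c(LI = 0, HI = 0, NT = 0, NR = 0),
                   arousalSubjectSd = 0, arousalJitterSd = 0, seed = 2)
  for (cond in CONDITIONS) expect_equal(simulateArousal(gp0, 2, cond), 0)

  ## determinism: the same call twice gives the same value
  gp <- genParams(nSubjects = 5, seed = 3)
  expect_identical(simulateArousal(gp, 4, "HI"), simulateArousal(gp, 4, "HI"))
  expect_error(simulateArousal(gp, 1, "XX"), class = "invalidCondition")

  ## Monte-Carlo mean over many subjects matches the condition effect
  gpm <- genParams(nSubjects = 400,
                   conditionEffects = c(HI = 1, LI = 0.5, NT = 0, NR = 0),
                   arousalSubjectSd = 0, seed = 11)
  hi <- vapply(seq_len(400), function(i) simulateArousal(gpm, i, "HI"), numeric(1))
  expect_equal(mean(hi), 1, tolerance = 0.05)
})

test_that("interbeat simulation carries arousal in the designed directions", {
  set.seed(1)
  ## zero variability and trend -> constant RR -> zero SDNN/RMSSD downstream
  ibi0 <- simulateIbi(0, 30, rrSd = 0, trend = 0)$series
  f0 <- ibiFeatures(ibi0)
  expect_equal(unname(f0["IBISDNN"]), 0)
  expect_equal(unname(f0["IBIRMSSD"]), 0)

  ## E[mHR] increases with arousal (Monte-Carlo, 200 draws per level)
  mhr <- function(a) mean(vapply(seq_len(200), function(i) {
    ibiFeatures(simulateIbi(a, 60)$series)[["mHR"]]
  }, numeric(1)))
  rmssd <- function(a) mean(vapply(seq_len(200), function(i) {
    ibiFeatures(simulateIbi(a, 60)$series)[["IBIRMSSD"]]
  }, numeric(1)))
  expect_lt(mhr(0), mhr(1.5))
  expect_gt(rmssd(0), rmssd(1.5))

  ## beat count ~ duration / mean interval
  n <- length(durations(simulateIbi(0, 60, rrSd = 0, trend = 0)$series))
  expect_equal(n, 60, tolerance = 2)
})

test_that("EDA simulation plants countable SCR events", {
  set.seed(4)
  ## no events, no noise -> downstream count 0
  e0 <- simulateEda(0, 18, nEvents = 0, tonicSd = 0, noiseSd = 0)
  expect_equal(unname(edaFeatures(e0$series)["event"]), 0)

  ## three planted 0.2-uS bumps in a 72-sample window, no noise -> count 3
  e3 <- simulateEda(0, 18, nEvents = 3, onsets = c(2, 8, 14), amp = 0.2,
                    tonicSd = 0, tonicDrift = 0, noiseSd = 0)
  got <- unname(edaFeatures(e3$series)["event"])
  ## verify against the all-pairs brute-force oracle as well
  expect_equal(got, oracleScrCount(signalValues(e3$series), 4))
  expect_equal(got, 3)

  ## doubling arousal raises the expected event count
  cnt <- function(a) mean(vapply(seq_len(200), function(i) {
    edaFeatures(simulateEda(a, 18)$series)[["event"]]
  }, numeric(1)))
  expect_lt(cnt(0.5), cnt(2))
})

test_that("BVP simulation matches the closed-form sinusoid mean", {
  set.seed(5)
  z <- simulateBvp(0, 18.75, ampScale = 0, noiseSd = 0)
  expect_equal(unname(bvpFeatures(z)["mBVP"]), 0)

  ## mean |A sin| = 2A/pi within 2% at 64 Hz
  s <- simulateBvp(0, 18.75, ampScale = 1.3, harmonic = 0, noiseSd = 0)
  expect_equal(unname(bvpFeatures(s)["mBVP"]), 2 * 1.3 / pi, tolerance = 0.02)
  expect_lt(min(signalValues(s)), 0)
  expect_gt(max(signalValues(s)), 0)

  set.seed(9); s1 <- simulateBvp(1, 10)
  set.seed(9); s2 <- simulateBvp(1, 10)
  expect_identical(signalValues(s1), signalValues(s2))
})

test_that("temperature simulation plants an exact linear drift", {
  set.seed(6)
  const <- simulateTemp(1, 100, kSlope = 0, driftSd = 0, noiseSd = 0)
  expect_equal(tempFeature(const$series), 0, tolerance = 1e-12)

  planted <- simulateTemp(1, 100, kSlope = 0.01, driftSd = 0, noiseSd = 0)
  expect_equal(tempFeature(planted$series), 0.01, tolerance = 1e-9)

  hot <- simulateTemp(50, 1000, kSlope = 0.05, noiseSd = 0)
  expect_true(all(signalValues(hot$series) >= 20 & signalValues(hot$series) <= 45))
})

test_that("generated datasets have the study's design structure", {
  ds <- generateDataset(genParams(nSubjects = 10, seed = 21))
  expect_length(ds$records, 40)
  tab <- table(vapply(ds$records, subjectId, character(1)))
  expect_true(all(tab == 4))
  percond <- table(vapply(ds$records, condition, character(1)))
  expect_true(all(percond == 10))
  expect_error(generateDataset(genParams(nSubjects = 0)), class = "invalidGenParams")
})

test_that("noiseless linear scores are exactly identified from features", {
  gp <- genParams(nSubjects = 12, subjectSd = 0, noiseSd = 0, seed = 8)
  ds <- generateDataset(gp)
  ft <- featureTable(ds$records)
  X <- as.matrix(ft[names(gp$beta)])
  cond <- factor(ft$condition, levels = c("NR", "LI", "HI", "NT"))
  fit <- lm(ft$bart_score ~ X + cond)
  est <- coef(fit)[paste0("X", names(gp$beta))]
  expect_equal(unname(est), unname(gp$beta), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["(Intercept)"]), gp$intercept, tolerance = 1e-6)
})

test_that("between-subject score spread grows with the planted subject sd", {
  grid <- c(0.5, 1.5, 3, 6, 10)
  spread <- vapply(grid, function(s) {
    ds <- generateDataset(genParams(nSubjects = 50, subjectSd = s, seed = 33))
    ft <- featureTable(ds$records)
    res <- resid(lm(bart_score ~ condition, data = ft))
    var(tapply(res, ft$subject_id, mean))
  }, numeric(1))
  expect_gt(cor(rank(grid), rank(spread)), 0.9)
})
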