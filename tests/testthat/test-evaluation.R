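test_that("metrics follow their definitions", {
  m <- computeMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$mae, m$rmse, m$r2), c(0, 0, 1))

  m2 <- computeMetrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(c(m2$mae, m2$rmse, m2$r2), c(1, 1, -0.5))

  set.seed(71)
  y <- rnorm(50); p <- y + rnorm(50)
  perm <- sample(50)
  a <- computeMetrics(y, p)
  b <- computeMetrics(y[perm], p[perm])
  expect_equal(a[c("mae", "rmse", "r2")], b[c("mae", "rmse", "r2")])

  d <- computeMetrics(rep(2, 5), rnorm(5))
  expect_true(d$degenerate)
  expect_true(is.na(d$r2))

  expect_error(computeMetrics(1:3, 1:4), class = "invalidInput")
})

test_that("mae never exceeds rmse", {
  set.seed(72)
  for (i in 1:50) {
    y <- rnorm(sample(5:40, 1))
    p <- y + rnorm(length(y), 0, runif(1, 0.1, 3))
    m <- computeMetrics(y, p)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
  ## equality iff all absolute errors are equal
  m <- computeMetrics(c(0, 0, 0), c(1, -1, 1))
  expect_equal(m$mae, m$rmse)
})

test_that("subject-level splits are exact, disjoint and leakage-free", {
  ds <- generateDataset(genParams(nSubjects = 10, seed = 73))
  sp <- splitDataset(ds$records, fractions = c(0.6, 0.2, 0.2),
                     grouping = "subject", seed = 3)
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 24L, val = 8L, test = 8L))
  subj <- lapply(sp, function(g) unique(vapply(g, subjectId, character(1))))
  expect_length(subj$train, 6); expect_length(subj$val, 2); expect_length(subj$test, 2)
  expect_length(intersect(subj$train, subj$val), 0)
  expect_length(intersect(subj$train, subj$test), 0)
  expect_length(intersect(subj$val, subj$test), 0)
  ## union covers the input
  expect_equal(sum(vapply(sp, length, integer(1))), 40L)

  sp2 <- splitDataset(ds$records, fractions = c(0.6, 0.2, 0.2),
                      grouping = "subject", seed = 3)
  expect_identical(lapply(sp$train, subjectId), lapply(sp2$train, subjectId))

  expect_error(splitDataset(ds$records[1:8], grouping = "subject", seed = 1),
               class = "insufficientGroups")
  expect_error(splitDataset(ds$records, fractions = c(0.5, 0.2, 0.2)),
               class = "invalidInput")
})

test_that("record-level splitting is available behind the explicit flag", {
  ds <- generateDataset(genParams(nSubjects = 5, seed = 74))
  sp <- splitDataset(ds$records, grouping = "record", seed = 2)
  expect_equal(sum(vapply(sp, length, integer(1))), 20L)
  expect_equal(length(sp$val), 4L)
  expect_equal(length(sp$test), 4L)
})

test_that("the ablation grid has the published structure", {
  grid <- defaultAblationGrid()
  expect_length(grid, 7)
  expect_equal(names(grid)[7], "full")
  expect_false(grid$no_mha$mhaEnabled)
  expect_equal(sort(setdiff(grid$full$branches, grid$no_temp$branches)), "TEMP")

  expect_error(
    runAblation(list(), mcmaConfig(),
                variants = list(bad = list(branches = character(0))), seeds = 1),
    class = "invalidAblation")
})

test_that("ablation reports aggregate per-seed runs consistently", {
  ds <- generateDataset(genParams(nSubjects = 10, seed = 75))
  sp <- splitDataset(ds$records, seed = 4)
  cfg <- tinyMcmaConfig(seed = 1)
  variants <- list(no_temp = list(branches = setdiff(c("EDA", "BVP", "IBI", "TEMP",
                                                       "condition"), "TEMP"),
                                  mhaEnabled = TRUE),
                   full = list(branches = c("EDA", "BVP", "IBI", "TEMP",
                                            "condition"), mhaEnabled = TRUE))
  rep <- runAblation(sp, cfg, variants = variants, seeds = c(1, 2))
  expect_equal(nrow(rep$table), 2)
  expect_equal(nrow(rep$perSeed), 4)
  expect_equal(rep$table$mae[rep$table$variant == "full"],
               mean(rep$perSeed$mae[rep$perSeed$variant == "full"]))

  ## the full-model variant equals a direct train of the unablated config
  cfgFull <- cfg; cfgFull$seed <- 1L
  direct <- trainMcma(cfgFull, sp$train, sp$val)
  yTest <- vapply(sp$test, bartScore, numeric(1))
  mDirect <- computeMetrics(yTest, predict(direct$model, sp$test))
  expect_equal(rep$perSeed$mae[rep$perSeed$variant == "full" &
                               rep$perSeed$seed == 1], mDirect$mae)
})

test_that("the model comparison report is internally consistent", {
  ds <- generateDataset(genParams(nSubjects = 12, seed = 76))
  sp <- splitDataset(ds$records, seed = 5)
  rep <- compareModels(sp, tinyMcmaConfig(seed = 2))
  expect_equal(nrow(rep$table), 3)
  expect_setequal(rep$table$model, c("mixed", "svr", "mcma"))
  for (mod in rep$table$model) {
    m <- computeMetrics(rep$predictions$yTest, rep$predictions[[mod]])
    expect_equal(rep$table$mae[rep$table$model == mod], m$mae)
    expect_equal(rep$table$rmse[rep$table$model == mod], m$rmse)
  }
})
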