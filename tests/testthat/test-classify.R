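blobData <- function(n = 60, sep = 6, seed = 1) {
  set.seed(seed)
  data.frame(
    x1 = c(rnorm(n), rnorm(n, sep)),
    x2 = c(rnorm(n), rnorm(n, sep)),
    label = factor(rep(c("super_critical", "sub_critical"), each = n),
      levels = c("super_critical", "critical", "sub_critical")
    )
  )
}

test_that("regime labels split the g axis at the critical ratio", {
  lab <- regimeLabel(c(1.2, 1.49, 1.5, 1.51, 1.8))
  expect_equal(
    as.character(lab),
    c("super_critical", "super_critical", "critical", "sub_critical",
      "sub_critical")
  )
  # grid arithmetic of the full protocol: 61 g values, 300/200/300 samples
  cfg <- fullScaleConfig()
  expect_equal(nSimulations(cfg), 800)
  gs <- c(rep(gGrid(cfg), each = cfg$repsPerG),
          rep(cfg$gCritical, cfg$extraCritical))
  expect_equal(as.vector(table(regimeLabel(gs))), c(300L, 200L, 300L))
  expect_equal(nSimulations(reducedConfig()), 405)
})

test_that("separable classes are classified perfectly", {
  d <- blobData()
  res <- trainEval(d, task = 1, c("x1", "x2"), repeats = 5, seed = 3)
  expect_equal(meanAccuracy(res), 1)
  expect_equal(res@nRepeats, 5L)
  expect_length(res@accuracies, 5)
})

test_that("shuffled labels score at chance", {
  d <- blobData(n = 100)
  set.seed(9)
  d$label <- sample(d$label)
  res <- trainEval(d, task = 1, c("x1", "x2"), repeats = 20, seed = 4)
  expect_lt(abs(meanAccuracy(res) - 0.5), 0.05)
})

test_that("repeated evaluation with one seed reproduces every split", {
  d <- blobData(n = 30, sep = 2)
  r1 <- trainEval(d, task = 1, c("x1", "x2"), repeats = 6, seed = 11)
  r2 <- trainEval(d, task = 1, c("x1", "x2"), repeats = 6, seed = 11)
  expect_identical(r1@accuracies, r2@accuracies)
  r3 <- trainEval(d, task = 1, c("x1", "x2"), repeats = 6, seed = 12)
  expect_false(identical(r1@accuracies, r3@accuracies))
})

test_that("degenerate tasks are rejected", {
  d <- blobData()
  d$label[] <- "sub_critical"
  expect_error(trainEval(d, 1, c("x1", "x2")), "single class")
  expect_error(trainEval(blobData(), 5, "x1"), "task")
})

test_that("task filtering drops or merges the critical class", {
  d <- blobData(n = 20)
  d$label[1:10] <- "critical"
  td1 <- spikeTopo:::.taskData(d, 1)
  expect_equal(length(td1$keep), 30)
  expect_equal(nlevels(td1$y), 2)
  td3 <- spikeTopo:::.taskData(d, 3)
  expect_equal(length(td3$keep), 40)
  expect_equal(levels(td3$y), c("critical", "non_critical"))
  expect_equal(sum(td3$y == "critical"), 10)
})

test_that("a tiny end-to-end dataset build is deterministic and labeled", {
  cfg <- spikeTopoConfig(
    N = 60, gMin = 1.2, gMax = 1.8, gStep = 0.3, repsPerG = 2,
    extraCritical = 2, tTotal = 3000, tTransient = 500,
    vertexCap = 20, measures = "pearson", masterSeed = 5
  )
  ds <- buildDataset(cfg)
  expect_equal(nrow(ds), nSimulations(cfg))
  expect_equal(sum(ds$label == "critical"), 4)  # 2 grid reps + 2 extra
  expect_true(all(c(
    "meanActivity", "varActivity", "pearson.f1", "pearson.f4"
  ) %in% names(ds)))
  expect_true(all(is.finite(as.matrix(ds[, -(1:3)]))))
  ds2 <- buildDataset(cfg)
  expect_identical(ds, ds2)
})

test_that("trend report aggregates replicate means and sds", {
  samples <- data.frame(
    g = rep(c(1.2, 1.5), each = 3),
    label = regimeLabel(rep(c(1.2, 1.5), each = 3)),
    simIndex = 1:6,
    meanActivity = c(1, 2, 3, 4, 5, 6),
    pearson.f1 = rep(0.5, 6)
  )
  tr <- featureTrendReport(samples)
  expect_equal(nrow(tr), 2 * 2)  # 2 g values x 2 feature columns
  f1 <- tr[tr$feature == "pearson.f1", ]
  expect_equal(f1$sd, c(0, 0))  # constant feature: zero spread
  ma <- tr[tr$feature == "meanActivity", ]
  expect_equal(ma$mean, c(2, 5))
})
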