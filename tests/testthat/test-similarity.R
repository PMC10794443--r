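trainSet <- function(trains, t0 = 0, t1 = 1000) {
  names(trains) <- as.character(seq_along(trains))
  new("SpikeTrainSet", trains = trains, tStart = t0, tEnd = t1)
}

test_that("spike binning uses half-open bins and drops the partial tail", {
  ts <- trainSet(list(c(0, 3, 4, 9), numeric(0)), 0, 12)
  counts <- binSpikeCounts(ts, 4)
  expect_equal(unname(counts[1, ]), c(2, 1, 1))
  expect_equal(unname(counts[2, ]), c(0, 0, 0))
  # partial last bin dropped: window [0, 14) with bin 4 keeps 3 bins
  ts2 <- trainSet(list(c(0, 3, 4, 9, 13)), 0, 14)
  expect_equal(ncol(binSpikeCounts(ts2, 4)), 3)
  expect_equal(sum(binSpikeCounts(ts2, 4)), 4)
  # 1-ms bins on integer spike times reproduce the raster
  r <- simulateNetwork(NetworkParams(N = 30, g = 1.5, seed = 2), 2000, 500)
  counts <- binSpikeCounts(spikeTrains(r), 1)
  A <- activityTrace(r)
  expect_equal(unname(colSums(counts)), A)
  expect_error(binSpikeCounts(trainSet(list(1), 0, 2), 4), "window")
})

test_that("Pearson dissimilarity is 1 - r clipped to the unit range", {
  counts <- rbind(a = c(1, 0, 2, 5), b = c(1, 0, 2, 5))
  D <- pearsonDissimilarity(counts)
  expect_equal(as.matrix(D)[1, 2], 0)
  # perfectly anti-correlated rows clip at 1
  counts <- rbind(a = c(1, 0, 1, 0), b = c(0, 1, 0, 1))
  expect_equal(as.matrix(pearsonDissimilarity(counts))[1, 2], 1)
  # independent rows hover near 1 - r with |r| small
  set.seed(8)
  counts <- rbind(rbinom(1e4, 1, 0.2), rbinom(1e4, 1, 0.2))
  d <- as.matrix(pearsonDissimilarity(counts))[1, 2]
  expect_lt(abs(d - 1), 0.05)
  expect_error(
    pearsonDissimilarity(rbind(c(1, 1, 1), c(1, 2, 3))),
    "zero-variance"
  )
})

test_that("SPIKE-synchronization matches its definition", {
  a <- sort(runif(40, 0, 1000))
  expect_equal(spikeSyncValue(a, a), 1)
  # all spikes farther apart than any coincidence window
  expect_equal(spikeSyncValue(c(100, 200, 300), c(150, 250, 350)), 0)
  # cross-validated against the naive double-loop oracle
  for (k in 1:20) {
    set.seed(100 + k)
    a <- sort(runif(rpois(1, 30) + 1, 0, 1000))
    b <- sort(runif(rpois(1, 30) + 1, 0, 1000))
    expect_equal(spikeSyncValue(a, b), syncOracle(a, b), tolerance = 1e-12)
  }
})

test_that("SPIKE-distance matches dense sampling of its profile", {
  a <- sort(runif(40, 0, 1000))
  expect_equal(spikeDistanceValue(a, a, 0, 1000), 0)
  for (k in 1:20) {
    set.seed(200 + k)
    a <- sort(runif(rpois(1, 25) + 1, 0, 500))
    b <- sort(runif(rpois(1, 25) + 1, 0, 500))
    exact <- spikeDistanceValue(a, b, 0, 500)
    expect_equal(exact, spikeDistOracle(a, b, 0, 500), tolerance = 2e-3)
    # symmetry
    expect_equal(exact, spikeDistanceValue(b, a, 0, 500), tolerance = 1e-12)
    expect_gte(exact, 0)
    expect_lte(exact, 1)
  }
})

test_that("all three matrices are symmetric, zero-diagonal and in [0,1]", {
  r <- simulateNetwork(NetworkParams(N = 40, g = 1.4, seed = 6), 4000, 1000)
  for (m in c("pearson", "spike_sync", "spike_distance")) {
    D <- dissimilarity(r, m, binMs = 4)
    M <- as.matrix(D)
    expect_true(isSymmetric(M))
    expect_true(all(diag(M) == 0))
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(measureName(D), m)
  }
})

test_that("vertex selection removes sparse trains and caps deterministically", {
  trains <- trainSet(list(
    c(10, 20, 30), c(15, 26, 37), numeric(0), 500,
    c(100, 200, 300), c(110, 210, 310)
  ))
  D <- dissimilarity(trains, "spike_distance")
  expect_equal(vertexIds(D), c(1L, 2L, 5L, 6L))  # <2 spikes dropped
  D1 <- dissimilarity(trains, "spike_distance", vertexCap = 3, seed = 5)
  D2 <- dissimilarity(trains, "spike_distance", vertexCap = 3, seed = 5)
  expect_identical(vertexIds(D1), vertexIds(D2))
  expect_equal(length(vertexIds(D1)), 3)
  expect_true(all(vertexIds(D1) %in% c(1L, 2L, 5L, 6L)))
})

test_that("the three measures rank pairs differently on structured spikes", {
  # P1: a train and its copy shifted by 3 ms. The shift is inside every
  # adaptive coincidence window (rate 25/s), so SPIKE-synchronization
  # calls the pair nearly identical, while 4-ms binned counts decorrelate.
  set.seed(31)
  mother <- sort(runif(250, 0, 10000))
  mother <- mother[c(TRUE, diff(mother) > 8)]  # enforce ISI > shift
  p1 <- trainSet(list(mother, mother + 3), 0, 10010)
  # P2: two independent Poisson thinnings of a common slow on/off rate
  # envelope: correlated counts without spike-time coincidences.
  set.seed(32)
  env <- function() {
    x <- sort(runif(2500, 0, 10000))
    x[(x %% 200) < 100]  # keep spikes in the "on" half-cycles
  }
  p2 <- trainSet(list(env(), env()), 0, 10010)
  pearson <- function(ts) {
    as.matrix(pearsonDissimilarity(binSpikeCounts(ts, 4)))[1, 2]
  }
  sync <- function(ts) 1 - spikeSyncValue(ts@trains[[1]], ts@trains[[2]])
  # Pearson ranks P2 as more similar than P1; SPIKE-sync says the opposite
  expect_lt(pearson(p2), pearson(p1))
  expect_lt(sync(p1), sync(p2))
})

test_that("jittered synchrony keeps SPIKE measures low and Pearson high", {
  ts <- makeSynchronousTrains(6, baseRate = 25, jitterMs = 2, seed = 44)
  Dsync <- dissimilarity(ts, "spike_sync")
  Dpear <- dissimilarity(ts, "pearson", binMs = 4)
  mOff <- function(D) mean(as.matrix(D)[upper.tri(as.matrix(D))])
  expect_lt(mOff(Dsync), mOff(Dpear))
})

test_that("dissimilarity files round-trip", {
  r <- simulateNetwork(NetworkParams(N = 20, g = 1.5, seed = 12), 3000, 500)
  D <- dissimilarity(r, "pearson", binMs = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDissimilarity(D, path)
  D2 <- readDissimilarity(path)
  expect_equal(as.matrix(D2), as.matrix(D), tolerance = 1e-15)
  expect_identical(vertexIds(D2), vertexIds(D))
  expect_identical(measureName(D2), "pearson")
  expect_identical(D2@binMs, 4)
})
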