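triangleMatrix <- function(d12, d13, d23) {
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- d12
  M[1, 3] <- M[3, 1] <- d13
  M[2, 3] <- M[3, 2] <- d23
  M
}

test_that("dimension-0 deaths are the spanning-tree edge weights", {
  d <- vrH0(triangleMatrix(0.2, 0.5, 0.9))
  b <- persistenceBars(d, 0)
  expect_equal(b$birth, c(0, 0, 0))
  expect_equal(sort(b$death), c(0.2, 0.5, Inf))
  # coincident points: n - 1 zero-length deaths
  d <- vrH0(matrix(0, 4, 4))
  b <- persistenceBars(d, 0)
  expect_equal(b$death, c(0, 0, 0, Inf))
  # single point: only the essential component
  d <- vrPersistence(matrix(0, 1, 1))
  expect_equal(persistenceBars(d, 0)$death, Inf)
  expect_error(vrPersistence(matrix(numeric(0), 0, 0)), "empty")
})

test_that("a triangle carries no 1-cycle but a 4-ring does", {
  expect_equal(nrow(persistenceBars(
    vrH1(triangleMatrix(0.3, 0.4, 0.5)), 1
  )), 0)
  b <- persistenceBars(vrH1(makeCycleMatrix(4, 0.3, 0.8)), 1)
  expect_equal(b$birth, 0.3)
  expect_equal(b$death, 0.8)
})

test_that("diagrams equal the exhaustive reduction on random matrices", {
  for (s in 1:10) {
    n <- 3 + (s %% 6)
    M <- randomDissimMatrix(n, seed = s, quantize = (s %% 3 == 0))
    imp <- canonicalBars(vrPersistence(M)@bars)
    ora <- canonicalBars(bruteForcePersistence(M))
    expect_equal(imp, ora, tolerance = 0)
  }
  # truncated filtration leaves essential 1-cycles
  M <- as.matrix(makeCycleMatrix(5, 0.2, 0.9))
  imp <- canonicalBars(vrPersistence(M, epsMax = 0.5)@bars)
  ora <- canonicalBars(bruteForcePersistence(M, epsMax = 0.5))
  expect_equal(imp, ora, tolerance = 0)
  expect_true(any(imp$dim == 1 & is.infinite(imp$death)))
})

test_that("the circle fixture has one prominent 1-cycle", {
  D <- makeCircleMatrix(20, 0.05, seed = 3)
  b <- persistenceBars(vrPersistence(D), 1)
  expect_equal(sum(b$death - b$birth > 0.3), 1)
  f <- topoFeatures(vrPersistence(D))
  expect_gte(f@f3, 1)
})

test_that("Betti curves count live bars with the half-open convention", {
  diag <- vrPersistence(triangleMatrix(0.2, 0.5, 0.9))
  bc <- bettiCurve(diag, 0, c(0.1, 0.3, 0.7))
  expect_equal(bc@beta, c(3L, 2L, 1L))
  # at a death value the component is already gone
  expect_equal(bettiCurve(diag, 0, c(0.2, 0.5))@beta, c(2L, 1L))
  empty <- new("PersistenceDiagram", bars = data.frame(
    dim = numeric(0), birth = numeric(0), death = numeric(0)
  ))
  expect_equal(bettiCurve(empty, 1, c(0.1, 0.9))@beta, c(0L, 0L))
  # beta0 is non-increasing and pinned to n and 1 at the extremes
  for (s in 1:50) {
    n <- 3 + (s %% 6)
    M <- randomDissimMatrix(n, seed = 1000 + s)
    bc <- bettiCurve(vrPersistence(M), 0, seq(0, 1, length.out = 201))
    expect_true(all(diff(bc@beta) <= 0))
    off <- M[upper.tri(M)]
    expect_equal(bc@beta[bc@grid < min(off)][1], n)
    expect_equal(bc@beta[201], 1L)  # connected at eps >= max weight
  }
})

test_that("features follow the bar-sum formulas", {
  # two clusters of three: known step curve
  f <- topoFeatures(vrPersistence(makeClusterMatrix(c(3, 3), 0.1, 0.9)))
  expect_equal(f@f1, 0.1)
  expect_equal(f@f2, 2.3)
  expect_equal(f@f3, 0)
  expect_equal(f@f4, 0)
  # 4-ring: one loop of lifetime 0.5
  f <- topoFeatures(vrPersistence(makeCycleMatrix(4, 0.3, 0.8)))
  expect_equal(f@f3, 1)
  expect_equal(f@f4, 0.5)
  # 6-ring fixture
  f <- topoFeatures(vrPersistence(makeCycleMatrix(6, 0.2, 0.9)))
  expect_equal(f@f3, 1)
  expect_equal(f@f4, 0.7)
  # single vertex: no edge ever appears
  f <- topoFeatures(vrPersistence(matrix(0, 1, 1)))
  expect_equal(as.numeric(f), c(f1 = 1, f2 = 1, f3 = 0, f4 = 0))
  # coincident pair: turning point at 0
  expect_equal(topoFeatures(vrPersistence(matrix(0, 2, 2)))@f1, 0)
})

test_that("bar-sum areas agree with dense step integration", {
  nGrid <- 1e5
  delta <- 1 / nGrid
  grid <- seq(0, 1 - delta, by = delta)  # left-Riemann cells
  cases <- list(
    makeClusterMatrix(c(3, 3), 0.1, 0.9),
    makeCycleMatrix(6, 0.2, 0.9),
    makeCircleMatrix(15, 0.05, seed = 2),
    randomDissimMatrix(8, seed = 77)
  )
  for (M in cases) {
    diag <- vrPersistence(M)
    f <- topoFeatures(diag)
    area0 <- sum(bettiCurve(diag, 0, grid)@beta) * delta
    area1 <- sum(bettiCurve(diag, 1, grid)@beta) * delta
    expect_lt(abs(f@f2 - area0), 1e-3)
    expect_lt(abs(f@f4 - area1), 1e-3)
  }
})

test_that("invalid matrices are rejected", {
  M <- triangleMatrix(0.2, 0.5, 0.9)
  M[1, 2] <- 0.3  # asymmetric
  expect_error(vrPersistence(M), "symmetric")
  expect_error(vrPersistence(triangleMatrix(0.2, 0.5, 1.5)), "symmetric|\\[0, 1\\]")
})

test_that("diagram files round-trip including essential bars", {
  diag <- vrPersistence(makeCircleMatrix(12, 0.05, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  writeDiagram(diag, path)
  d2 <- readDiagram(path)
  expect_equal(canonicalBars(d2@bars), canonicalBars(diag@bars))
})
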