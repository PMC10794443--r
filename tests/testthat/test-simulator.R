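test_that("firing probability is the piecewise-linear sigmoid", {
  par <- NetworkParams(theta = 1, Gamma = 0.2)
  expect_equal(phiGain(1, par), 0)        # at threshold
  expect_equal(phiGain(6, par), 1)        # at saturation theta + 1/Gamma
  expect_equal(phiGain(3.5, par), 0.5)    # linear in between
  expect_equal(phiGain(-5, par), 0)
  expect_equal(phiGain(100, par), 1)
  v <- seq(-2, 10, by = 0.01)
  p <- phiGain(v, par)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
  expect_equal(saturationPotential(par), 6)
})

test_that("critical point follows the mean-field formula", {
  expect_equal(unname(criticalPoint(NetworkParams())["g_c"]), 1.5,
    tolerance = 1e-12
  )
  expect_identical(unname(criticalPoint(NetworkParams())["Wbar_c"]), 5)
  # leaky variant, evaluated directly from the closed form
  expect_equal(
    unname(criticalPoint(NetworkParams(mu = 0.5))["g_c"]), 2.75
  )
  # p = q with a steep gain: correction term vanishes, g_c -> p/q = 1
  gC <- unname(criticalPoint(
    NetworkParams(p = 0.5, Gamma = 1e8)
  )["g_c"])
  expect_equal(gC, 1, tolerance = 1e-6)
  expect_error(criticalPoint(NetworkParams(p = 1)), "q = 0")
})

test_that("network parameter validity is enforced", {
  expect_error(NetworkParams(mu = 1), "mu")
  expect_error(NetworkParams(Gamma = 0), "Gamma")
  expect_error(NetworkParams(g = -1), "g")
  expect_equal(nExcitatory(NetworkParams(N = 1000, p = 0.8)), 800L)
})

test_that("one network step matches the membrane update rule", {
  par <- NetworkParams(N = 1000, mu = 0, Iext = 0)
  # silent network with no input stays silent (absorbing state)
  set.seed(1)
  st <- stepNetwork(rep(0, 1000), rep(0L, 1000), par)
  expect_true(all(st$V == 0))
  expect_true(all(st$X == 0L))
  # one excitatory spike injects J/N into every quiescent neuron
  X <- rep(0L, 1000)
  X[1] <- 1L
  set.seed(1)
  st <- stepNetwork(rep(0, 1000), X, par)
  expect_equal(st$V[2], 10 / 1000)
  expect_equal(st$V[1], 0)  # fired neuron resets
})

test_that("Monte-Carlo population rates match one mean-field iteration", {
  par <- NetworkParams(N = 10000)
  NE <- nExcitatory(par)
  set.seed(42)
  X <- as.integer(runif(par@N) < 0.1)
  cntE <- sum(X[1:NE])
  cntI <- sum(X[(NE + 1):par@N])
  u <- par@Iext + (par@J * cntE - par@g * par@J * cntI) / par@N
  st <- stepNetwork(rep(0, par@N), X, par)
  pFire <- phiGain(u, par)
  for (pop in list(
    list(idx = 1:NE, cnt = cntE),
    list(idx = (NE + 1):par@N, cnt = cntI)
  )) {
    nQuiescent <- length(pop$idx) - pop$cnt
    expected <- nQuiescent * pFire
    se <- sqrt(nQuiescent * pFire * (1 - pFire))
    expect_lt(abs(sum(st$X[pop$idx]) - expected), 3 * se)
  }
})

test_that("mean-field map has the directed-percolation phase portrait", {
  # sub-critical: activity decays to the absorbing state
  trSub <- meanFieldTrajectory(NetworkParams(g = 1.8), 0.1, 1000)
  expect_lt(trSub$rhoE[1001], 1e-6)
  # super-critical: a stable active phase, rho* = 1 - 1/(Gamma * Wbar)
  trSup <- meanFieldTrajectory(NetworkParams(g = 1.2), 0.1, 1000)
  expect_gt(trSup$rhoE[1001], 1e-3)
  expect_equal(trSup$rhoE[1001], 1 - 5 / 5.6, tolerance = 1e-9)
  # rho = 0 is absorbing
  tr0 <- meanFieldTrajectory(NetworkParams(g = 1.2), 0, 100)
  expect_true(all(tr0$rhoE == 0))
})

test_that("simulated rasters are deterministic and drive keeps activity on", {
  par <- NetworkParams(N = 100, g = 1.6, seed = 9)
  r1 <- simulateNetwork(par, 5000, 1000)
  r2 <- simulateNetwork(par, 5000, 1000)
  expect_identical(spikeEvents(r1), spikeEvents(r2))
  expect_identical(driveTimes(r1), driveTimes(r2))
  r3 <- simulateNetwork(par, 5000, 1000, streamIndex = 1)
  expect_false(identical(spikeEvents(r1), spikeEvents(r3)))
  # every recorded step has at least one spike
  expect_true(all(activityTrace(r1) >= 1))
  expect_true(all(activityTrace(r1)[driveTimes(r1) + 1] >= 1))
  # a single recorded step still carries the forced spike
  r4 <- simulateNetwork(par, 1001, 1000)
  expect_equal(nSteps(r4), 1L)
  expect_gte(length(spikeEvents(r4)$time), 1L)
})

test_that("mean activity decreases across the critical point", {
  gs <- c(1.2, 1.5, 1.8)
  act <- sapply(1:3, function(seed) {
    sapply(gs, function(g) {
      meanActivity(simulateNetwork(
        NetworkParams(N = 200, g = g, seed = seed), 20000, 2000
      ))
    })
  })
  m <- rowMeans(act)
  s <- apply(act, 1, sd)
  expect_gt(m[1] - m[2], max(s))  # super > critical, beyond seed noise
  expect_gt(m[2] - m[3], max(s))  # critical > sub
})

test_that("raster files round-trip exactly", {
  par <- NetworkParams(N = 50, g = 1.37, seed = 4)
  r <- simulateNetwork(par, 3000, 500)
  path <- withr::local_tempfile(fileext = ".txt")
  writeSpikeRaster(r, path)
  r2 <- readSpikeRaster(path)
  expect_identical(spikeEvents(r2), spikeEvents(r))
  expect_identical(driveTimes(r2), driveTimes(r))
  expect_identical(r2@params@g, par@g)
  expect_identical(nSteps(r2), nSteps(r))
})
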