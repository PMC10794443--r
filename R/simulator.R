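#' Construct network parameters
#'
#' Defaults are the standard simulation parameters of the model: `N = 1000`
#' neurons of which 80% are excitatory, `J = 10`, `Gamma = 0.2`, `mu = 0`,
#' `theta = 1` and `Iext = theta` (zero external field, the regime in which
#' the mean-field critical point of [criticalPoint()] applies; a silent
#' network then stays silent because `phiGain(theta) = 0`, and activity is
#' maintained by the offline drive of [simulateNetwork()]). With these
#' values the critical inhibition ratio is `g = 1.5`.
#'
#' @param N total number of neurons.
#' @param p excitatory fraction; `round(p * N)` neurons are excitatory.
#' @param J mean excitatory synaptic weight.
#' @param g inhibition ratio; the inhibitory weight is `W = g * J`.
#' @param Gamma firing gain (1/potential).
#' @param mu leakage in `[0, 1)`.
#' @param theta firing threshold.
#' @param Iext tonic external current; defaults to `theta` (zero field).
#' @param seed master RNG seed used by [simulateNetwork()].
#'
#' @return A [NetworkParams-class] object.
#' @examples
#' par <- NetworkParams(g = 1.5)
#' criticalPoint(par)
#' @export
NetworkParams <- function(N = 1000, p = 0.8, J = 10, g = 1.5, Gamma = 0.2,
                          mu = 0, theta = 1, Iext = theta, seed = 1L) {
  new("NetworkParams",
    N = as.integer(N), p = as.numeric(p), J = as.numeric(J),
    g = as.numeric(g), Gamma = as.numeric(Gamma), mu = as.numeric(mu),
    theta = as.numeric(theta), Iext = as.numeric(Iext),
    seed = as.integer(seed)
  )
}

#' Number of excitatory neurons
#' @param params a [NetworkParams-class] object.
#' @return Integer count; the inhibitory count is `nNeurons(params) - nExcitatory(params)`.
#' @export
nExcitatory <- function(params) as.integer(round(params@p * params@N))

#' Saturation potential of the firing nonlinearity
#' @param params a [NetworkParams-class] object.
#' @return `theta + 1/Gamma`, the potential at which the firing probability
#'   reaches 1.
#' @export
saturationPotential <- function(params) params@theta + 1 / params@Gamma

#' @describeIn NetworkParams-class total neuron count.
#' @param x object.
#' @export
setMethod("nNeurons", "NetworkParams", function(x) x@N)

setMethod("show", "NetworkParams", function(object) {
  cp <- criticalPoint(object)
  cat(sprintf(
    "NetworkParams: N=%d (E=%d/I=%d)  J=%g  g=%g  Gamma=%g  mu=%g\n",
    object@N, nExcitatory(object), object@N - nExcitatory(object),
    object@J, object@g, object@Gamma, object@mu
  ))
  cat(sprintf(
    "  theta=%g  Iext=%g  V_S=%g  seed=%d  critical g_c=%g\n",
    object@theta, object@Iext, saturationPotential(object), object@seed,
    cp[["g_c"]]
  ))
})

#' Piecewise-linear firing probability
#'
#' The probability that a neuron with membrane potential `V` fires in the
#' next step: 0 below the threshold `theta`, `(V - theta) * Gamma` between
#' threshold and the saturation potential `theta + 1/Gamma`, and 1 above.
#'
#' @param V membrane potential(s); vectorized.
#' @param params a [NetworkParams-class] object.
#' @return Firing probabilities in `[0, 1]`.
#' @examples
#' par <- NetworkParams()
#' phiGain(c(0, 1, 3.5, 6, 10), par)
#' @export
phiGain <- function(V, params) {
  pmin(pmax((V - params@theta) * params@Gamma, 0), 1)
}

#' Mean-field critical point of the network
#'
#' For the fully connected network the population-averaged dynamics have a
#' directed-percolation phase transition in the net coupling
#' \eqn{\bar W = pJ - qW}. The transition sits at
#' \eqn{\bar W_c = (1-\mu)/\Gamma}, equivalently at the inhibition ratio
#' \eqn{g_c = p/q - (1-\mu)/(q \Gamma J)}. With the default parameters
#' (`p = 0.8`, `q = 0.2`, `Gamma = 0.2`, `J = 10`, `mu = 0`) this gives
#' `g_c = 1.5`: the network is super-critical (self-sustained activity) for
#' `g < 1.5` and sub-critical for `g > 1.5`.
#'
#' @param params a [NetworkParams-class] object with `q > 0`, `Gamma > 0`,
#'   `J > 0`.
#' @return Named numeric vector with elements `Wbar_c` and `g_c`.
#' @examples
#' criticalPoint(NetworkParams())
#' @export
criticalPoint <- function(params) {
  q <- 1 - params@p
  if (q <= 0) stop("critical point undefined for q = 0")
  if (params@J == 0) stop("critical point undefined for J = 0")
  WbarC <- (1 - params@mu) / params@Gamma
  gC <- params@p / q - (1 - params@mu) / (q * params@Gamma * params@J)
  c(Wbar_c = WbarC, g_c = gC)
}

#' One synchronous update of the network state
#'
#' Applies the membrane-potential update
#' \deqn{V_i[t+1] = (\mu V_i[t] + I_{ext} + pJ\rho_E[t] - qW\rho_I[t])(1 - X_i[t])}
#' (the homogeneous all-to-all couplings make the recurrent input identical
#' for every neuron, so the update costs O(N)) and then draws each spike
#' indicator independently as Bernoulli with probability
#' `phiGain(V[t+1])`. Draws use R's global RNG, so the update is
#' reproducible under [set.seed()]. [simulateNetwork()] runs the same
#' dynamics in compiled code with a private RNG stream.
#'
#' @param V numeric vector of membrane potentials, length `N`.
#' @param X integer/logical vector of current spike indicators, length `N`.
#' @param params a [NetworkParams-class] object.
#' @return List with the updated `V` and `X`.
#' @export
stepNetwork <- function(V, X, params) {
  N <- params@N
  stopifnot(length(V) == N, length(X) == N)
  X <- as.integer(X != 0)
  NE <- nExcitatory(params)
  W <- params@g * params@J
  rec <- params@Iext +
    (params@J * sum(X[seq_len(NE)]) - W * sum(X[seq.int(NE + 1, length.out = N - NE)])) / N
  Vnew <- (params@mu * V + rec) * (1 - X)
  pFire <- phiGain(Vnew, params)
  Xnew <- as.integer(stats::runif(N) < pFire)
  list(V = Vnew, X = Xnew)
}

#' Simulate the network and return a spike raster
#'
#' Iterates the stochastic dynamics for `tTotal` steps of 1 ms, discards the
#' first `tTransient` steps and returns the remaining spikes re-indexed to
#' start at time 0. The initial condition activates each neuron
#' independently with probability `initProb` at `V = 0`. Whenever the
#' Bernoulli draws of a step leave the whole network silent, one uniformly
#' chosen neuron is forced to spike at that same step (the offline drive),
#' so every recorded step has activity of at least one spike; the forced
#' times are recorded and delimit neuronal avalanches.
#'
#' All randomness comes from a private counter-based stream derived from
#' `(params@seed, streamIndex)`, so a raster is a pure function of the
#' parameters and the stream index, independent of R's RNG state.
#'
#' @param params a [NetworkParams-class] object.
#' @param tTotal total number of simulated steps (ms).
#' @param tTransient initial steps to discard (`0 <= tTransient < tTotal`).
#' @param streamIndex index of the RNG stream, for replicate simulations
#'   sharing one master seed.
#' @param initProb initial activation probability per neuron.
#' @return A [SpikeRaster-class] object.
#' @examples
#' par <- NetworkParams(N = 100, g = 1.5, seed = 7)
#' r <- simulateNetwork(par, tTotal = 2000, tTransient = 500)
#' meanActivity(r)
#' @export
simulateNetwork <- function(params, tTotal = 1e6, tTransient = 1e4,
                            streamIndex = 0L, initProb = 0.1) {
  if (tTotal <= 0) stop("tTotal must be positive")
  if (tTransient < 0 || tTransient >= tTotal) {
    stop("need 0 <= tTransient < tTotal")
  }
  NE <- nExcitatory(params)
  res <- .simulate_network_cpp(
    params@N, NE, params@J, params@g * params@J, params@mu, params@theta,
    params@Gamma, params@Iext, as.integer(tTotal), as.integer(tTransient),
    initProb, as.numeric(params@seed), as.numeric(streamIndex)
  )
  new("SpikeRaster",
    N = params@N, T = as.integer(tTotal - tTransient),
    neuron = res$neuron, time = res$time, driveTimes = res$driveTimes,
    params = params
  )
}

#' Deterministic mean-field trajectory of the population dynamics
#'
#' Iterates the population-averaged map of the network. Writing
#' \eqn{\rho_{E/I}} for the firing fractions and \eqn{V_{E/I}} for the mean
#' potentials, the common recurrent field is
#' \eqn{u[t] = \mu V[t] + I_{ext} + pJ\rho_E[t] - qW\rho_I[t]} and
#' \deqn{\rho[t+1] = (1 - \rho[t])\,\Phi(u[t]), \qquad
#'       V[t+1] = u[t]\,(1 - \rho[t]),}
#' per population: the fraction \eqn{\rho} of neurons that have just fired
#' sit at the reset potential and cannot fire again, while the remaining
#' fraction fires with probability \eqn{\Phi} of the field. Linearizing at
#' zero field (`Iext = theta`) around \eqn{\rho = 0} gives the branching
#' ratio \eqn{\Gamma \bar W/(1-\mu)}, which crosses 1 exactly at the
#' critical point of [criticalPoint()].
#'
#' @param params a [NetworkParams-class] object.
#' @param rho0 initial firing fraction in `[0, 1]` for both populations.
#' @param steps number of iterations.
#' @return A data.frame with columns `t`, `VE`, `VI`, `rhoE`, `rhoI`.
#' @examples
#' tr <- meanFieldTrajectory(NetworkParams(g = 1.2), rho0 = 0.1, steps = 500)
#' tail(tr, 1)  # super-critical: settles at a positive rate
#' @export
meanFieldTrajectory <- function(params, rho0 = 0.1, steps = 1000) {
  stopifnot(rho0 >= 0, rho0 <= 1)
  p <- params@p
  q <- 1 - p
  W <- params@g * params@J
  VE <- VI <- numeric(steps + 1)
  rhoE <- rhoI <- numeric(steps + 1)
  rhoE[1] <- rhoI[1] <- rho0
  for (t in seq_len(steps)) {
    uE <- params@mu * VE[t] + params@Iext + p * params@J * rhoE[t] - q * W * rhoI[t]
    uI <- params@mu * VI[t] + params@Iext + p * params@J * rhoE[t] - q * W * rhoI[t]
    rhoE[t + 1] <- (1 - rhoE[t]) * phiGain(uE, params)
    rhoI[t + 1] <- (1 - rhoI[t]) * phiGain(uI, params)
    VE[t + 1] <- uE * (1 - rhoE[t])
    VI[t + 1] <- uI * (1 - rhoI[t])
  }
  data.frame(t = 0:steps, VE = VE, VI = VI, rhoE = rhoE, rhoI = rhoI)
}

## ---- SpikeRaster accessors ----

#' @describeIn SpikeRaster-class neuron count.
#' @param x a `SpikeRaster`.
#' @export
setMethod("nNeurons", "SpikeRaster", function(x) x@N)

#' @describeIn SpikeRaster-class number of recorded steps.
#' @export
setMethod("nSteps", "SpikeRaster", function(x) x@T)

#' @describeIn SpikeRaster-class spike events as a data.frame with columns
#'   `neuron`, `time`.
#' @export
setMethod("spikeEvents", "SpikeRaster", function(x) {
  data.frame(neuron = x@neuron, time = x@time)
})

#' @describeIn SpikeRaster-class times at which the offline drive forced a
#'   spike.
#' @export
setMethod("driveTimes", "SpikeRaster", function(x) x@driveTimes)

#' @describeIn SpikeRaster-class spike count per recorded step
#'   (length-`T` integer vector).
#' @export
setMethod("activityTrace", "SpikeRaster", function(x) {
  as.integer(tabulate(x@time + 1L, nbins = x@T))
})

#' @describeIn SpikeRaster-class mean activity per neuron per step,
#'   `sum(A) / (N * T)`.
#' @export
setMethod("meanActivity", "SpikeRaster", function(x) {
  length(x@time) / (as.numeric(x@N) * as.numeric(x@T))
})

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf(
    "SpikeRaster: %d neurons x %d ms, %d spikes (%d drive events)\n",
    object@N, object@T, length(object@time), length(object@driveTimes)
  ))
  cat(sprintf(
    "  g=%g  mean activity=%.4g spikes/neuron/ms\n",
    object@params@g, meanActivity(object)
  ))
})

## ---- raster file round trip ----

#' Write a spike raster as a plain-text event list
#'
#' One `neuron<TAB>time` line per spike; `#`-prefixed header lines carry the
#' raster dimensions, drive times and the producing parameters as
#' `key=value` pairs. [readSpikeRaster()] round-trips the file exactly.
#'
#' @param raster a [SpikeRaster-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpikeRaster <- function(raster, path) {
  p <- raster@params
  hdr <- c(
    sprintf("# N=%d T=%d", raster@N, raster@T),
    sprintf(
      "# p=%.17g J=%.17g g=%.17g Gamma=%.17g mu=%.17g theta=%.17g Iext=%.17g seed=%d",
      p@p, p@J, p@g, p@Gamma, p@mu, p@theta, p@Iext, p@seed
    ),
    paste0("# driveTimes=", paste(raster@driveTimes, collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (length(raster@neuron)) {
    writeLines(paste(raster@neuron, raster@time, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a spike raster written by [writeSpikeRaster()]
#'
#' @param path file path.
#' @return A [SpikeRaster-class].
#' @export
readSpikeRaster <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  kv <- list()
  for (h in hdr) {
    for (tok in strsplit(sub("^#\\s*", "", h), "\\s+")[[1]]) {
      parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2) kv[[parts[1]]] <- parts[2]
    }
  }
  num <- function(k) as.numeric(kv[[k]])
  params <- NetworkParams(
    N = num("N"), p = num("p"), J = num("J"), g = num("g"),
    Gamma = num("Gamma"), mu = num("mu"), theta = num("theta"),
    Iext = num("Iext"), seed = num("seed")
  )
  drv <- kv[["driveTimes"]]
  drv <- if (is.null(drv) || !nzchar(drv)) integer(0) else {
    as.integer(strsplit(drv, ",", fixed = TRUE)[[1]])
  }
  if (length(body)) {
    sp <- strsplit(body, "\t", fixed = TRUE)
    neuron <- as.integer(vapply(sp, `[[`, "", 1L))
    time <- as.integer(vapply(sp, `[[`, "", 2L))
  } else {
    neuron <- time <- integer(0)
  }
  new("SpikeRaster",
    N = as.integer(num("N")), T = as.integer(num("T")),
    neuron = neuron, time = time, driveTimes = drv, params = params
  )
}
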