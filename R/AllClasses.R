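#' @import methods
NULL

#' Parameters of the stochastic E/I integrate-and-fire network
#'
#' Container for the parameters of a fully connected excitatory/inhibitory
#' network of stochastic leaky integrate-and-fire neurons. Each neuron
#' carries a membrane potential \eqn{V} (dimensionless potential units) that
#' integrates recurrent input with leakage \eqn{\mu} and fires with the
#' piecewise-linear probability \eqn{\Phi(V)} (see [phiGain()]); firing
#' resets the potential to zero. Excitatory synapses have homogeneous weight
#' \eqn{J}, inhibitory ones \eqn{W = gJ}, so the inhibition ratio \eqn{g}
#' is the single control parameter of the dynamics.
#'
#' @slot N total number of neurons; the first `round(p * N)` are excitatory.
#' @slot p excitatory fraction (the inhibitory fraction is `q = 1 - p`).
#' @slot J mean excitatory synaptic weight.
#' @slot g inhibition ratio `W/J` (inhibitory weight `W = g * J`).
#' @slot Gamma firing gain of the probabilistic threshold unit (1/potential).
#' @slot mu leakage parameter in `[0, 1)`.
#' @slot theta firing threshold.
#' @slot Iext tonic external current. The default `Iext = theta` places the
#'   network at zero external field, where the mean-field critical point of
#'   [criticalPoint()] governs the dynamics.
#' @slot seed master RNG seed for simulations run from these parameters.
#'
#' @seealso [NetworkParams()], [criticalPoint()], [simulateNetwork()]
#' @name NetworkParams-class
#' @rdname NetworkParams-class
#' @exportClass NetworkParams
setClass("NetworkParams",
  representation(
    N = "integer", p = "numeric", J = "numeric", g = "numeric",
    Gamma = "numeric", mu = "numeric", theta = "numeric",
    Iext = "numeric", seed = "integer"
  )
)

setValidity("NetworkParams", function(object) {
  msg <- character(0)
  scalars <- c("p", "J", "g", "Gamma", "mu", "theta", "Iext")
  for (s in scalars) {
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s))) {
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    }
  }
  if (length(msg)) return(msg)
  if (object@N < 1L) msg <- c(msg, "N must be >= 1")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (object@g < 0) msg <- c(msg, "g must be >= 0")
  if (object@Gamma <= 0) msg <- c(msg, "Gamma must be > 0")
  if (object@mu < 0 || object@mu >= 1) msg <- c(msg, "mu must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' A spike raster produced by the network simulator
#'
#' Spike events of `N` neurons over `T` recorded 1-ms time steps
#' (post-transient, times re-indexed to start at 0). Neuron ids are 1-based.
#' `driveTimes` records the steps at which the offline drive forced a spike
#' because the network had fallen silent; these delimit neuronal avalanches
#' (see [extractAvalanches()]).
#'
#' @slot N neuron count.
#' @slot T number of recorded steps (ms).
#' @slot neuron integer vector of spike neuron ids in `[1, N]`.
#' @slot time integer vector of spike times in `[0, T)`, parallel to `neuron`.
#' @slot driveTimes integer vector of forced-spike times.
#' @slot params the [NetworkParams-class] that produced the raster.
#'
#' @seealso [simulateNetwork()], [spikeTrains()], [activityTrace()]
#' @name SpikeRaster-class
#' @rdname SpikeRaster-class
#' @exportClass SpikeRaster
setClass("SpikeRaster",
  representation(
    N = "integer", T = "integer", neuron = "integer", time = "integer",
    driveTimes = "integer", params = "NetworkParams"
  )
)

setValidity("SpikeRaster", function(object) {
  msg <- character(0)
  if (length(object@neuron) != length(object@time)) {
    msg <- c(msg, "'neuron' and 'time' must have equal length")
  }
  if (length(object@neuron) &&
      (min(object@neuron) < 1L || max(object@neuron) > object@N)) {
    msg <- c(msg, "neuron ids must lie in [1, N]")
  }
  if (length(object@time) &&
      (min(object@time) < 0L || max(object@time) >= object@T)) {
    msg <- c(msg, "spike times must lie in [0, T)")
  }
  if (length(msg)) msg else TRUE
})

#' A set of spike trains on a common observation window
#'
#' Per-neuron sorted spike-time vectors (ms) on the half-open window
#' `[tStart, tEnd]`. This is the input format of the spike-train
#' dissimilarity measures.
#'
#' @slot trains named list of sorted numeric spike-time vectors.
#' @slot tStart,tEnd observation window (ms).
#'
#' @seealso [spikeTrains()], [dissimilarity()]
#' @name SpikeTrainSet-class
#' @rdname SpikeTrainSet-class
#' @exportClass SpikeTrainSet
setClass("SpikeTrainSet",
  representation(trains = "list", tStart = "numeric", tEnd = "numeric")
)

setValidity("SpikeTrainSet", function(object) {
  msg <- character(0)
  if (object@tEnd <= object@tStart) msg <- c(msg, "tEnd must exceed tStart")
  ok <- vapply(object@trains, function(x) {
    is.numeric(x) && !is.unsorted(x) &&
      (!length(x) || (x[1] >= object@tStart && x[length(x)] <= object@tEnd))
  }, logical(1))
  if (!all(ok)) {
    msg <- c(msg, "trains must be sorted numeric vectors within the window")
  }
  if (length(msg)) msg else TRUE
})

#' A pairwise spike-train dissimilarity matrix
#'
#' Symmetric matrix of pairwise dissimilarities in `[0, 1]` with zero
#' diagonal, tagged by the measure that produced it. These matrices are the
#' edge-weight input of the Vietoris-Rips filtration.
#'
#' @slot M symmetric numeric matrix, entries in `[0, 1]`, zero diagonal.
#' @slot measure one of `"pearson"`, `"spike_sync"`, `"spike_distance"`.
#' @slot binMs bin width in ms (Pearson only; `NA` for the binless measures).
#' @slot vertexIds neuron ids retained as vertices (after removing neurons
#'   with too few spikes, and optional subsampling).
#'
#' @seealso [dissimilarity()], [vrPersistence()]
#' @name DissimilarityMatrix-class
#' @rdname DissimilarityMatrix-class
#' @exportClass DissimilarityMatrix
setClass("DissimilarityMatrix",
  representation(
    M = "matrix", measure = "character", binMs = "numeric",
    vertexIds = "integer"
  )
)

setValidity("DissimilarityMatrix", function(object) {
  M <- object@M
  msg <- character(0)
  if (nrow(M) != ncol(M)) msg <- c(msg, "M must be square")
  if (!all(is.finite(M))) msg <- c(msg, "M must be finite")
  else {
    if (max(abs(M - t(M))) > 1e-12) msg <- c(msg, "M must be symmetric")
    if (any(diag(M) != 0)) msg <- c(msg, "diagonal must be zero")
    if (min(M) < 0 || max(M) > 1) msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (!object@measure %in% c("pearson", "spike_sync", "spike_distance")) {
    msg <- c(msg, "unknown measure")
  }
  if (length(object@vertexIds) && length(object@vertexIds) != nrow(M)) {
    msg <- c(msg, "vertexIds must match matrix dimension")
  }
  if (length(msg)) msg else TRUE
})

#' A persistence diagram (dimensions 0 and 1)
#'
#' Birth-death bars of the Vietoris-Rips filtration. Dimension-0 bars are
#' born at 0 and die at the minimum-spanning-tree edge weights; exactly one
#' is essential (death `Inf`) when the complex is connected at the end of
#' the filtration. Dimension-1 bars record 1-cycles.
#'
#' @slot bars data.frame with columns `dim` (0 or 1), `birth`, `death`
#'   (`Inf` for essential classes).
#'
#' @seealso [vrPersistence()], [bettiCurve()], [topoFeatures()]
#' @name PersistenceDiagram-class
#' @rdname PersistenceDiagram-class
#' @exportClass PersistenceDiagram
setClass("PersistenceDiagram", representation(bars = "data.frame"))

setValidity("PersistenceDiagram", function(object) {
  b <- object@bars
  msg <- character(0)
  if (!all(c("dim", "birth", "death") %in% names(b))) {
    msg <- c(msg, "bars needs columns dim, birth, death")
  } else {
    if (!all(b$dim %in% c(0, 1))) msg <- c(msg, "dim must be 0 or 1")
    if (any(b$death < b$birth)) msg <- c(msg, "death must be >= birth")
  }
  if (length(msg)) msg else TRUE
})

#' A Betti curve
#'
#' The Betti number \eqn{\beta_k(\epsilon)} of the filtration as a step
#' function of the threshold, evaluated on a grid with the half-open
#' convention `birth <= eps < death`.
#'
#' @slot grid increasing filtration thresholds in `[0, 1]`.
#' @slot beta Betti numbers on the grid.
#' @slot dim homology dimension (0 or 1).
#'
#' @seealso [bettiCurve()]
#' @name BettiCurve-class
#' @rdname BettiCurve-class
#' @exportClass BettiCurve
setClass("BettiCurve",
  representation(grid = "numeric", beta = "integer", dim = "integer")
)

setValidity("BettiCurve", function(object) {
  msg <- character(0)
  if (length(object@grid) != length(object@beta)) {
    msg <- c(msg, "grid and beta must have equal length")
  }
  if (is.unsorted(object@grid, strictly = TRUE)) {
    msg <- c(msg, "grid must be strictly increasing")
  }
  if (any(object@beta < 0L)) msg <- c(msg, "beta must be non-negative")
  if (length(msg)) msg else TRUE
})

#' The four scalar Betti-curve features
#'
#' Scalar summaries of the dimension-0 and dimension-1 Betti curves used as
#' classifier inputs: `f1` the turning point of the Betti-0 curve (the
#' filtration value at which it starts to decrease, i.e. the smallest
#' pairwise dissimilarity), `f2` the area under the Betti-0 curve, `f3` the
#' global maximum of the Betti-1 curve and `f4` the area under the Betti-1
#' curve. Areas are exact bar-length sums over `[0, epsMax]`; essential bars
#' are capped at `epsMax`.
#'
#' @slot f1,f2,f3,f4 the four features.
#' @slot epsMax filtration truncation value used for the areas.
#' @slot measure dissimilarity measure the filtration was built from
#'   (may be `NA` for synthetic matrices).
#'
#' @seealso [topoFeatures()]
#' @name TopoFeatures-class
#' @rdname TopoFeatures-class
#' @exportClass TopoFeatures
setClass("TopoFeatures",
  representation(
    f1 = "numeric", f2 = "numeric", f3 = "numeric", f4 = "numeric",
    epsMax = "numeric", measure = "character"
  )
)

#' Result of one SVM classification experiment
#'
#' Mean and per-split test accuracies of the RBF-kernel SVM on one of the
#' three regime-discrimination tasks.
#'
#' @slot task 1 (super- vs sub-critical), 2 (all three regimes) or
#'   3 (critical vs non-critical).
#' @slot featureSet names of the feature columns used.
#' @slot accuracies per-split test accuracies.
#' @slot nRepeats number of repeated stratified 80/20 splits.
#'
#' @seealso [trainEval()]
#' @name ClassificationResult-class
#' @rdname ClassificationResult-class
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  representation(
    task = "integer", featureSet = "character", accuracies = "numeric",
    nRepeats = "integer"
  )
)

setValidity("ClassificationResult", function(object) {
  if (length(object@accuracies) != object@nRepeats) {
    return("one accuracy per repeat required")
  }
  if (any(object@accuracies < 0 | object@accuracies > 1)) {
    return("accuracies must lie in [0, 1]")
  }
  TRUE
})
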