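#' Experiment configuration
#'
#' A flat list of every knob of the simulation-to-classification pipeline:
#' network parameters, the grid of inhibition ratios, replicate counts,
#' run lengths, dissimilarity settings and classifier settings. All
#' randomness of a run derives from `masterSeed`: simulation `i` of the
#' dataset uses RNG stream `(masterSeed, i)` and auxiliary draws (vertex
#' subsampling, split shuffling) use seeds derived from `masterSeed` and
#' the simulation/repeat index.
#'
#' @param N,p,J,Gamma,mu,theta,Iext network parameters, see
#'   [NetworkParams()].
#' @param gMin,gMax,gStep inhibition-ratio grid.
#' @param gCritical the critical ratio used for labels and extra
#'   replicates.
#' @param repsPerG replicate simulations per grid value.
#' @param extraCritical additional replicates at `gCritical`.
#' @param tTotal,tTransient run length and discarded transient (steps).
#' @param binMs Pearson bin width (ms).
#' @param vertexCap maximum vertices per dissimilarity matrix
#'   (`Inf` = none).
#' @param minSpikes minimum spikes for a neuron to be a vertex.
#' @param epsMax filtration truncation.
#' @param measures dissimilarity measures to compute (may be empty to skip
#'   the topological features, e.g. for the activity-baseline analysis).
#' @param repeats repeated train/test splits per classification.
#' @param masterSeed master RNG seed.
#' @return A list with class `"spikeTopoConfig"`.
#' @seealso [reducedConfig()], [fullScaleConfig()], [buildDataset()]
#' @export
spikeTopoConfig <- function(N = 1000, p = 0.8, J = 10, Gamma = 0.2, mu = 0,
                            theta = 1, Iext = theta,
                            gMin = 1.2, gMax = 1.8, gStep = 0.01,
                            gCritical = 1.5, repsPerG = 10,
                            extraCritical = 190,
                            tTotal = 1e6, tTransient = 1e4,
                            binMs = 4, vertexCap = Inf, minSpikes = 2,
                            epsMax = 1,
                            measures = c("pearson", "spike_sync",
                                         "spike_distance"),
                            repeats = 20, masterSeed = 1L) {
  cfg <- list(
    N = as.integer(N), p = p, J = J, Gamma = Gamma, mu = mu, theta = theta,
    Iext = Iext, gMin = gMin, gMax = gMax, gStep = gStep,
    gCritical = gCritical, repsPerG = as.integer(repsPerG),
    extraCritical = as.integer(extraCritical),
    tTotal = as.integer(tTotal), tTransient = as.integer(tTransient),
    binMs = binMs, vertexCap = vertexCap, minSpikes = as.integer(minSpikes),
    epsMax = epsMax, measures = measures, repeats = as.integer(repeats),
    masterSeed = as.integer(masterSeed)
  )
  class(cfg) <- "spikeTopoConfig"
  cfg
}

#' Desk-scale default configuration
#'
#' A reduced-scale version of the full study: `N = 200` neurons, 60,000
#' steps with a 5,000-step transient, 5 replicates per grid value plus
#' 100 extra critical replicates (405 simulations), vertex cap 100. With
#' `measures = character(0)` (activity baselines only) the whole run
#' takes a few minutes on one CPU; with the three dissimilarity measures
#' and their Betti features expect on the order of an hour or two.
#'
#' @param ... overrides passed to [spikeTopoConfig()].
#' @return A `spikeTopoConfig`.
#' @export
reducedConfig <- function(...) {
  spikeTopoConfig(
    N = 200, repsPerG = 5, extraCritical = 100, tTotal = 60000,
    tTransient = 5000, vertexCap = 100, ...
  )
}

#' Full-scale study configuration
#'
#' The protocol of the original study: `N = 1000`, one million steps with
#' a 10,000-step transient, `g` from 1.20 to 1.80 in steps of 0.01 with 10
#' replicates each plus 190 extra critical replicates (800 simulations).
#' Expect a long run.
#'
#' @param ... overrides passed to [spikeTopoConfig()].
#' @return A `spikeTopoConfig`.
#' @export
fullScaleConfig <- function(...) spikeTopoConfig(...)

#' The inhibition-ratio grid of a configuration
#' @param config a `spikeTopoConfig`.
#' @return Numeric vector of `g` values (rounded to the grid resolution).
#' @export
gGrid <- function(config) {
  round(seq(config$gMin, config$gMax, by = config$gStep), 10)
}

#' Number of simulations a configuration prescribes
#' @param config a `spikeTopoConfig`.
#' @return `length(gGrid) * repsPerG + extraCritical`.
#' @export
nSimulations <- function(config) {
  length(gGrid(config)) * config$repsPerG + config$extraCritical
}

#' @export
print.spikeTopoConfig <- function(x, ...) {
  cat(sprintf(
    "spikeTopoConfig: N=%d, g in [%g, %g] step %g, %d sims (%d critical extra)\n",
    x$N, x$gMin, x$gMax, x$gStep, nSimulations(x), x$extraCritical
  ))
  cat(sprintf(
    "  T=%d (transient %d), bin=%g ms, vertexCap=%s, measures=%s, seed=%d\n",
    x$tTotal, x$tTransient, x$binMs,
    ifelse(is.finite(x$vertexCap), x$vertexCap, "none"),
    if (length(x$measures)) paste(x$measures, collapse = ",") else "none",
    x$masterSeed
  ))
  invisible(x)
}

#' Write a configuration as flat `key=value` text
#' @param config a `spikeTopoConfig`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) paste(v, collapse = ",") else {
      x <- as.numeric(v)
      paste(ifelse(is.finite(x), sprintf("%.17g", x), "Inf"),
        collapse = ","
      )
    }
  }
  writeLines(
    vapply(names(config), function(k) {
      sprintf("%s=%s", k, fmt(config[[k]]))
    }, ""),
    path
  )
  invisible(path)
}

#' Read a configuration written by [writeConfig()]
#' @param path file path.
#' @return A `spikeTopoConfig`.
#' @export
readConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) x[2]),
    vapply(kv, `[[`, "", 1L)
  )
  args <- lapply(names(vals), function(k) {
    raw <- vals[[k]]
    if (is.na(raw)) raw <- ""
    v <- strsplit(raw, ",", fixed = TRUE)[[1]]
    if (k == "measures") v else as.numeric(v)
  })
  names(args) <- names(vals)
  if (!is.null(args$measures) && identical(args$measures, "")) {
    args$measures <- character(0)
  }
  do.call(spikeTopoConfig, args)
}
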