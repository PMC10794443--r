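## Pairwise spike-train dissimilarities used as Vietoris-Rips edge weights.
##
## Three measures: Pearson correlation of binned spike counts (converted to
## a dissimilarity by x -> 1 - x and clipped to [0, 1]), SPIKE-
## synchronization (fraction of coincident spikes under the adaptive
## coincidence window, converted by 1 - x) and the time-averaged
## SPIKE-distance (already a dissimilarity in [0, 1]).

#' Convert a raster to a spike-train set
#'
#' @param x a [SpikeRaster-class].
#' @param ... unused.
#' @return A [SpikeTrainSet-class] with one train per neuron (possibly
#'   empty), times in ms on the window `[0, T]`.
#' @export
setMethod("spikeTrains", "SpikeRaster", function(x, ...) {
  trains <- split(as.numeric(x@time), factor(x@neuron, levels = seq_len(x@N)))
  names(trains) <- as.character(seq_len(x@N))
  new("SpikeTrainSet", trains = trains, tStart = 0, tEnd = as.numeric(x@T))
})

#' @describeIn SpikeTrainSet-class number of trains.
#' @param x a `SpikeTrainSet`.
#' @export
setMethod("nNeurons", "SpikeTrainSet", function(x) length(x@trains))

setMethod("show", "SpikeTrainSet", function(object) {
  ns <- lengths(object@trains)
  cat(sprintf(
    "SpikeTrainSet: %d trains on [%g, %g] ms, %d spikes (median %g/train)\n",
    length(ns), object@tStart, object@tEnd, sum(ns), stats::median(ns)
  ))
})

#' Spike counts per neuron and time bin
#'
#' Counts spikes in half-open bins `[k * binMs, (k+1) * binMs)` measured
#' from the start of the observation window; a trailing partial bin is
#' dropped.
#'
#' @param trains a [SpikeTrainSet-class].
#' @param binMs bin width in ms (>= 1).
#' @return Integer matrix, neurons x bins.
#' @examples
#' ts <- new("SpikeTrainSet", trains = list(a = c(0, 3, 4, 9)),
#'           tStart = 0, tEnd = 12)
#' binSpikeCounts(ts, 4)
#' @export
binSpikeCounts <- function(trains, binMs = 4) {
  stopifnot(binMs >= 1)
  nBins <- floor((trains@tEnd - trains@tStart) / binMs)
  if (nBins < 1) stop("observation window shorter than one bin")
  counts <- t(vapply(trains@trains, function(x) {
    b <- floor((x - trains@tStart) / binMs) + 1
    tabulate(b[b <= nBins], nbins = nBins)
  }, integer(nBins)))
  dimnames(counts) <- list(names(trains@trains), NULL)
  counts
}

.asDissimilarity <- function(M, measure, binMs = NA_real_,
                             vertexIds = integer(0)) {
  M <- (M + t(M)) / 2  # enforce exact symmetry against rounding
  dimnames(M) <- NULL
  diag(M) <- 0
  M <- pmin(pmax(M, 0), 1)
  new("DissimilarityMatrix",
    M = M, measure = measure, binMs = as.numeric(binMs),
    vertexIds = as.integer(vertexIds)
  )
}

#' Pearson-correlation dissimilarity of binned spike counts
#'
#' Pairwise Pearson correlation `r` of the binned counts, converted to a
#' dissimilarity by `1 - r` and clipped to `[0, 1]` (anticorrelated pairs
#' map to 1) so that all filtration weights share the unit range.
#' Zero-variance rows are a contract violation: neurons with fewer than two
#' spikes must be removed upstream (see [dissimilarity()]).
#'
#' @param counts neurons x bins count matrix from [binSpikeCounts()]
#'   (>= 2 bins).
#' @param binMs bin width recorded in the result.
#' @param vertexIds neuron ids recorded in the result.
#' @return A [DissimilarityMatrix-class] with `measure = "pearson"`.
#' @export
pearsonDissimilarity <- function(counts, binMs = NA_real_,
                                 vertexIds = integer(0)) {
  if (ncol(counts) < 2) stop("need at least two bins")
  v <- apply(counts, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance count rows must be filtered out before correlation")
  }
  r <- stats::cor(t(counts))
  .asDissimilarity(1 - r, "pearson", binMs = binMs, vertexIds = vertexIds)
}

## nearest-distance from each x to the spike set y (both sorted)
.nearestDist <- function(x, y) {
  k <- findInterval(x, y)
  lo <- ifelse(k >= 1, y[pmax(k, 1)], -Inf)
  hi <- ifelse(k < length(y), y[pmin(k + 1, length(y))], Inf)
  pmin(x - lo, hi - x)
}

## SPIKE-synchronization coincidence indicators for spikes of `a` against
## `b`: spike i of `a` is coincident if its nearest spike in `b` lies
## strictly within half the minimum of the surrounding inter-spike
## intervals of both spikes (missing boundary ISIs are ignored).
.syncCoincidences <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  isiPrevA <- c(NA, diff(a))
  isiNextA <- c(diff(a), NA)
  k <- findInterval(a, b)
  dLo <- ifelse(k >= 1, a - b[pmax(k, 1)], Inf)
  dHi <- ifelse(k < nb, b[pmin(k + 1, nb)] - a, Inf)
  j <- ifelse(dLo <= dHi, pmax(k, 1), pmin(k + 1, nb))
  d <- pmin(dLo, dHi)
  isiPrevB <- c(NA, diff(b))[j]
  isiNextB <- c(diff(b), NA)[pmin(j, nb)]
  isiNextB[j >= nb] <- NA
  tau <- 0.5 * suppressWarnings(pmin(isiPrevA, isiNextA, isiPrevB, isiNextB,
    na.rm = TRUE
  ))
  tau[!is.finite(tau)] <- Inf  # two singleton trains: any distance counts
  d < tau
}

#' SPIKE-synchronization value of a pair of spike trains
#'
#' Fraction of spikes (pooled over both trains) that have a coincident
#' partner in the other train, where a pair of spikes is coincident if
#' their distance is strictly less than half the minimum of the
#' inter-spike intervals surrounding either spike (the adaptive,
#' parameter-free coincidence window). 1 means every spike is matched,
#' 0 means none is.
#'
#' @param a,b sorted spike-time vectors with at least one spike each.
#' @return The synchronization value in `[0, 1]`.
#' @export
spikeSyncValue <- function(a, b) {
  if (!length(a) || !length(b)) stop("trains must contain spikes")
  (sum(.syncCoincidences(a, b)) + sum(.syncCoincidences(b, a))) /
    (length(a) + length(b))
}

#' Time-averaged SPIKE-distance of a pair of spike trains
#'
#' The parameter-free dissimilarity profile of Kreuz et al.: at each time
#' the profile weighs, for each train, the distances from its preceding and
#' following spikes to the nearest spikes of the other train, normalized by
#' the local inter-spike intervals; the pair profile is averaged over the
#' observation window. Auxiliary spikes at the window edges bound the edge
#' intervals. The profile is piecewise linear between spikes, so the time
#' average is computed exactly segment by segment. 0 means identical
#' trains.
#'
#' @param a,b sorted spike-time vectors with at least one spike each.
#' @param tStart,tEnd observation window containing all spikes.
#' @return The distance value in `[0, 1]`.
#' @export
spikeDistanceValue <- function(a, b, tStart, tEnd) {
  if (!length(a) || !length(b)) stop("trains must contain spikes")
  aa <- unique(c(tStart, a, tEnd))
  bb <- unique(c(tStart, b, tEnd))
  m <- sort(unique(c(aa, bb)))  # profile breakpoints
  nSeg <- length(m) - 1L
  left <- m[-length(m)]
  right <- m[-1L]

  segsOne <- function(tt, other) {
    # index of the spike of tt preceding (<=) each segment start
    k <- findInterval(left, tt)
    tP <- tt[k]
    tF <- tt[k + 1L]
    list(
      tP = tP, tF = tF,
      dP = .nearestDist(tP, other), dF = .nearestDist(tF, other),
      isi = tF - tP
    )
  }
  sa <- segsOne(aa, bb)
  sb <- segsOne(bb, aa)

  Sat <- function(s, t) (s$dP * (s$tF - t) + s$dF * (t - s$tP)) / s$isi
  profile <- function(t) {
    (Sat(sa, t) * sb$isi + Sat(sb, t) * sa$isi) /
      (2 * ((sa$isi + sb$isi) / 2)^2)
  }
  sLeft <- profile(left)
  sRight <- profile(right)
  sum((sLeft + sRight) / 2 * (right - left)) / (tEnd - tStart)
}

.pairMatrix <- function(trains, fun) {
  n <- length(trains@trains)
  M <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        M[i, j] <- M[j, i] <- fun(trains@trains[[i]], trains@trains[[j]])
      }
    }
  }
  M
}

#' SPIKE-synchronization dissimilarity matrix
#'
#' Pairwise `1 - S` where `S` is the [spikeSyncValue()] of the two trains.
#' Every retained train must contain at least one spike.
#'
#' @param trains a [SpikeTrainSet-class].
#' @param vertexIds neuron ids recorded in the result.
#' @return A [DissimilarityMatrix-class] with `measure = "spike_sync"`.
#' @export
spikeSyncDissimilarity <- function(trains, vertexIds = integer(0)) {
  M <- .pairMatrix(trains, function(a, b) 1 - spikeSyncValue(a, b))
  .asDissimilarity(M, "spike_sync", vertexIds = vertexIds)
}

#' SPIKE-distance dissimilarity matrix
#'
#' Pairwise time-averaged [spikeDistanceValue()]; used directly as the
#' dissimilarity (larger distance = more dissimilar, no conversion).
#'
#' @param trains a [SpikeTrainSet-class].
#' @param vertexIds neuron ids recorded in the result.
#' @return A [DissimilarityMatrix-class] with `measure = "spike_distance"`.
#' @export
spikeDistanceMatrix <- function(trains, vertexIds = integer(0)) {
  M <- .pairMatrix(trains, function(a, b) {
    spikeDistanceValue(a, b, trains@tStart, trains@tEnd)
  })
  .asDissimilarity(M, "spike_distance", vertexIds = vertexIds)
}

## run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  expr
}

#' Pairwise dissimilarity matrix of a raster or spike-train set
#'
#' High-level entry point: selects the vertex set (neurons with at least
#' `minSpikes` spikes in the window; the Pearson correlation is undefined
#' for silent neurons and the SPIKE measures require spikes), optionally
#' subsamples it to at most `vertexCap` vertices (uniformly, seeded), and
#' computes the requested measure.
#'
#' @param x a [SpikeRaster-class] or [SpikeTrainSet-class].
#' @param measure `"pearson"`, `"spike_sync"` or `"spike_distance"`.
#' @param binMs bin width in ms for the Pearson measure.
#' @param minSpikes minimum spike count for a neuron to be retained.
#' @param vertexCap maximum number of vertices (`Inf` = no cap).
#' @param seed seed for the subsampling draw (required if the cap binds).
#' @return A [DissimilarityMatrix-class]; `vertexIds(x)` records the
#'   retained neurons.
#' @examples
#' r <- simulateNetwork(NetworkParams(N = 50, g = 1.4, seed = 3),
#'   tTotal = 3000, tTransient = 500
#' )
#' D <- dissimilarity(r, "pearson", binMs = 4)
#' dim(as.matrix(D))
#' @export
dissimilarity <- function(x,
                          measure = c("pearson", "spike_sync",
                                      "spike_distance"),
                          binMs = 4, minSpikes = 2, vertexCap = Inf,
                          seed = NULL) {
  measure <- match.arg(measure)
  trains <- if (is(x, "SpikeRaster")) spikeTrains(x) else x
  stopifnot(is(trains, "SpikeTrainSet"))
  keep <- which(lengths(trains@trains) >= minSpikes)
  if (length(keep) < 2) stop("fewer than two active neurons in the window")
  if (is.finite(vertexCap) && length(keep) > vertexCap) {
    keep <- sort(.withSeed(seed, sample(keep, vertexCap)))
  }
  sub <- new("SpikeTrainSet",
    trains = trains@trains[keep], tStart = trains@tStart,
    tEnd = trains@tEnd
  )
  switch(measure,
    pearson = pearsonDissimilarity(binSpikeCounts(sub, binMs),
      binMs = binMs, vertexIds = keep
    ),
    spike_sync = spikeSyncDissimilarity(sub, vertexIds = keep),
    spike_distance = spikeDistanceMatrix(sub, vertexIds = keep)
  )
}

## ---- DissimilarityMatrix accessors & IO ----

#' @describeIn DissimilarityMatrix-class the raw symmetric matrix.
#' @param x a `DissimilarityMatrix`.
#' @param ... unused.
#' @export
setMethod("as.matrix", "DissimilarityMatrix", function(x, ...) x@M)

#' @describeIn DissimilarityMatrix-class the measure tag.
#' @export
setMethod("measureName", "DissimilarityMatrix", function(x) x@measure)

#' @describeIn DissimilarityMatrix-class retained neuron ids.
#' @export
setMethod("vertexIds", "DissimilarityMatrix", function(x) x@vertexIds)

#' @describeIn DissimilarityMatrix-class number of vertices.
#' @export
setMethod("nNeurons", "DissimilarityMatrix", function(x) nrow(x@M))

setMethod("show", "DissimilarityMatrix", function(object) {
  off <- object@M[upper.tri(object@M)]
  cat(sprintf(
    "DissimilarityMatrix (%s): %d vertices, weights in [%.3f, %.3f]\n",
    object@measure, nrow(object@M),
    if (length(off)) min(off) else 0, if (length(off)) max(off) else 0
  ))
})

#' Write a dissimilarity matrix as CSV
#'
#' First row and column carry the vertex ids; a `#` comment line records
#' the measure and bin width.
#'
#' @param D a [DissimilarityMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDissimilarity <- function(D, path) {
  ids <- if (length(D@vertexIds)) D@vertexIds else seq_len(nrow(D@M))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# measure=%s binMs=%g", D@measure, D@binMs), con)
  writeLines(paste(c("id", ids), collapse = ","), con)
  for (i in seq_len(nrow(D@M))) {
    writeLines(paste(c(ids[i], sprintf("%.17g", D@M[i, ])), collapse = ","),
      con
    )
  }
  invisible(path)
}

#' Read a dissimilarity matrix written by [writeDissimilarity()]
#' @param path file path.
#' @return A [DissimilarityMatrix-class].
#' @export
readDissimilarity <- function(path) {
  lines <- readLines(path)
  meta <- sub("^#\\s*", "", lines[1])
  kv <- strsplit(strsplit(meta, "\\s+")[[1]], "=", fixed = TRUE)
  meta <- stats::setNames(
    vapply(kv, `[[`, "", 2L),
    vapply(kv, `[[`, "", 1L)
  )
  tab <- utils::read.csv(text = lines[-1], check.names = FALSE)
  ids <- as.integer(tab$id)
  M <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(M) <- NULL
  binMs <- meta[["binMs"]]
  binMs <- if (binMs == "NA") NA_real_ else as.numeric(binMs)
  .asDissimilarity(M, meta[["measure"]], binMs = binMs, vertexIds = ids)
}
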