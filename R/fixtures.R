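## Synthetic inputs with analytically known structure, used as oracle
## inputs for the dissimilarity and persistence stages and to exercise the
## full pipeline without external data.

#' Independent homogeneous Poisson spike trains
#'
#' @param n number of trains (>= 1).
#' @param rate firing rate in spikes/s.
#' @param duration observation window length in ms.
#' @param seed RNG seed (draws are local; the global RNG state is
#'   restored).
#' @return A [SpikeTrainSet-class] on `[0, duration]`.
#' @examples
#' ts <- makePoissonTrains(3, rate = 20, duration = 1000, seed = 1)
#' lengths(ts@trains)
#' @export
makePoissonTrains <- function(n, rate, duration, seed = 1L) {
  if (n < 1) stop("need n >= 1")
  if (rate <= 0 || duration <= 0) stop("rate and duration must be positive")
  trains <- .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      k <- stats::rpois(1, rate * duration / 1000)
      sort(stats::runif(k, 0, duration))
    })
  })
  names(trains) <- as.character(seq_len(n))
  new("SpikeTrainSet", trains = trains, tStart = 0, tEnd = duration)
}

#' Jittered copies of a common mother train
#'
#' One mother Poisson train; each of the `n` children copies its spikes
#' with independent Gaussian jitter (truncated to the window). With zero
#' jitter all children are identical, so all pairwise dissimilarities
#' vanish; with jitter of a few ms the children stay nearly synchronous
#' for the adaptive-window SPIKE measures while their binned counts
#' decorrelate, which is what makes the three measures genuinely disagree.
#'
#' @param n number of child trains.
#' @param baseRate mother rate in spikes/s.
#' @param jitterMs Gaussian jitter SD in ms (>= 0).
#' @param duration window length in ms.
#' @param seed RNG seed.
#' @return A [SpikeTrainSet-class].
#' @export
makeSynchronousTrains <- function(n, baseRate, jitterMs, duration = 10000,
                                  seed = 1L) {
  if (jitterMs < 0) stop("jitterMs must be >= 0")
  .withSeed(seed, {
    k <- stats::rpois(1, baseRate * duration / 1000)
    mother <- sort(stats::runif(k, 0, duration))
    trains <- lapply(seq_len(n), function(i) {
      x <- mother + if (jitterMs > 0) stats::rnorm(k, 0, jitterMs) else 0
      sort(pmin(pmax(x, 0), duration))
    })
    names(trains) <- as.character(seq_len(n))
    new("SpikeTrainSet", trains = trains, tStart = 0, tEnd = duration)
  })
}

#' Ring dissimilarity matrix with one known 1-cycle
#'
#' `n` points on a ring: adjacent pairs at distance `rWithin`, all other
#' pairs at `rAcross`. For `n >= 4` the Vietoris-Rips filtration has
#' exactly one dimension-1 bar, born at `rWithin` (the ring closes) and
#' dying at `rAcross` (the chords fill it in); for `n = 3` the triangle is
#' filled the moment it appears, so there is no bar.
#'
#' @param n number of points (>= 3).
#' @param rWithin adjacent distance, `0 <= rWithin < rAcross <= 1`.
#' @param rAcross non-adjacent distance.
#' @return A [DissimilarityMatrix-class].
#' @export
makeCycleMatrix <- function(n, rWithin = 0.3, rAcross = 0.8) {
  if (n < 3) stop("need n >= 3")
  if (!(rWithin >= 0 && rWithin < rAcross && rAcross <= 1)) {
    stop("need 0 <= rWithin < rAcross <= 1")
  }
  M <- matrix(rAcross, n, n)
  idx <- seq_len(n)
  nxt <- c(idx[-1], 1L)
  M[cbind(idx, nxt)] <- rWithin
  M[cbind(nxt, idx)] <- rWithin
  diag(M) <- 0
  .asDissimilarity(M, "pearson", vertexIds = idx)
}

#' Block "cluster" dissimilarity matrix with no 1-cycles
#'
#' Points in blocks: distance `dWithin` inside a block, `dBetween` across
#' blocks. The Betti-0 curve drops from `sum(sizes)` to `length(sizes)` at
#' `dWithin` and to 1 at `dBetween`; dimension 1 is empty (every cycle is
#' filled as soon as it appears).
#'
#' @param sizes block sizes (non-empty, each >= 1).
#' @param dWithin within-block distance, `0 <= dWithin < dBetween <= 1`.
#' @param dBetween between-block distance.
#' @return A [DissimilarityMatrix-class].
#' @export
makeClusterMatrix <- function(sizes, dWithin = 0.1, dBetween = 0.9) {
  if (!length(sizes) || any(sizes < 1)) stop("need non-empty block sizes")
  if (!(dWithin >= 0 && dWithin < dBetween && dBetween <= 1)) {
    stop("need 0 <= dWithin < dBetween <= 1")
  }
  block <- rep(seq_along(sizes), sizes)
  n <- length(block)
  M <- matrix(dBetween, n, n)
  same <- outer(block, block, `==`)
  M[same] <- dWithin
  diag(M) <- 0
  .asDissimilarity(M, "pearson", vertexIds = seq_len(n))
}

#' Points on a noisy circle, as a normalized distance matrix
#'
#' `n` angles equally spaced with Gaussian jitter; pairwise chord distances
#' normalized by the diameter so weights lie in `[0, 1]`. The filtration
#' carries one prominent 1-cycle.
#'
#' @param n number of points.
#' @param jitterSd angular jitter SD in radians.
#' @param seed RNG seed.
#' @return A [DissimilarityMatrix-class].
#' @export
makeCircleMatrix <- function(n = 20, jitterSd = 0.05, seed = 1L) {
  ang <- .withSeed(seed, {
    sort((seq_len(n) - 1) * 2 * pi / n + stats::rnorm(n, 0, jitterSd))
  })
  x <- cos(ang)
  y <- sin(ang)
  M <- sqrt(outer(x, x, `-`)^2 + outer(y, y, `-`)^2) / 2
  .asDissimilarity(M, "pearson", vertexIds = seq_len(n))
}
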