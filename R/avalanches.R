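#' Extract neuronal avalanches from a raster
#'
#' The offline drive of [simulateNetwork()] forces a spike the moment the
#' network falls silent, so silent gaps have zero length and each forced
#' spike starts a new avalanche. An avalanche is the maximal interval
#' between consecutive avalanche starts (recording onset or a drive time);
#' its duration is the interval length in ms and its size the total number
#' of spikes inside it. The trailing interval, cut off by the end of the
#' recording, is discarded.
#'
#' @param raster a [SpikeRaster-class].
#' @return A data.frame with one row per avalanche and columns `start`,
#'   `duration`, `size`. Empty rasters, or rasters whose single avalanche
#'   is cut off, give zero rows.
#' @examples
#' r <- simulateNetwork(NetworkParams(N = 100, g = 1.8, seed = 2),
#'   tTotal = 5000, tTransient = 1000
#' )
#' av <- extractAvalanches(r)
#' summary(av$size)
#' @export
extractAvalanches <- function(raster) {
  empty <- data.frame(start = integer(0), duration = integer(0),
                      size = integer(0))
  if (length(raster@time) == 0L) return(empty)
  starts <- sort(unique(c(0L, raster@driveTimes)))
  if (length(starts) < 2L) return(empty)
  A <- activityTrace(raster)
  cumA <- c(0, cumsum(A))
  s <- starts[-length(starts)]
  e <- starts[-1L]
  data.frame(
    start = s,
    duration = e - s,
    size = as.integer(cumA[e + 1L] - cumA[s + 1L])
  )
}

#' Empirical complementary cumulative distribution function
#'
#' Survival probabilities `P(X >= x)` at each distinct observed value, the
#' standard way of displaying heavy-tailed avalanche size and duration
#' distributions.
#'
#' @param samples non-empty numeric vector (e.g. avalanche sizes).
#' @return A data.frame with columns `value` (sorted distinct values) and
#'   `survival` (non-increasing, starting at 1).
#' @examples
#' avalancheCCDF(c(1, 1, 2, 4))
#' @export
avalancheCCDF <- function(samples) {
  if (length(samples) == 0L) stop("need at least one sample")
  v <- sort(unique(samples))
  n <- length(samples)
  nBelow <- findInterval(v, sort(samples), left.open = TRUE)
  data.frame(value = v, survival = (n - nBelow) / n)
}
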