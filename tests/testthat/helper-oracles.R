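# Independent oracles used to validate the pipeline. None of these call
# the implementation under test: persistence is recomputed by exhaustive
# enumeration and full boundary-matrix reduction, SPIKE-synchronization by
# a naive double loop, and the SPIKE-distance by dense time sampling of
# the definition.

# random symmetric dissimilarity matrix with zero diagonal
randomDissimMatrix <- function(n, seed, quantize = FALSE) {
  set.seed(seed)
  M <- matrix(0, n, n)
  w <- runif(n * (n - 1) / 2)
  if (quantize) w <- round(w, 1)  # exercises filtration ties
  M[upper.tri(M)] <- w
  M + t(M)
}

# Exhaustive persistence of the Vietoris-Rips filtration up to dim-2
# simplices: enumerate every vertex/edge/triangle with filtration value
# <= epsMax, sort by (value, dim), reduce the full boundary matrix over
# GF(2). Returns all bars of dims 0 and 1 including zero-length ones.
bruteForcePersistence <- function(M, epsMax = 1) {
  n <- nrow(M)
  verts <- lapply(seq_len(n), function(i) list(v = i, filt = 0, dim = 0L))
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && M[i, j] <= epsMax) {
        edges[[length(edges) + 1]] <- list(
          v = c(i, j), filt = M[i, j], dim = 1L
        )
      }
    }
  }
  tris <- list()
  if (n >= 3) {
    cmb <- utils::combn(n, 3)
    for (k in seq_len(ncol(cmb))) {
      v <- cmb[, k]
      w <- max(M[v[1], v[2]], M[v[1], v[3]], M[v[2], v[3]])
      if (w <= epsMax) {
        tris[[length(tris) + 1]] <- list(v = v, filt = w, dim = 2L)
      }
    }
  }
  simp <- c(verts, edges, tris)
  filt <- vapply(simp, `[[`, 0, "filt")
  dims <- vapply(simp, `[[`, 0L, "dim")
  ord <- order(filt, dims)
  simp <- simp[ord]
  filt <- filt[ord]
  dims <- dims[ord]
  key <- vapply(simp, function(s) paste(sort(s$v), collapse = "-"), "")
  pos <- stats::setNames(seq_along(simp), key)

  m <- length(simp)
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$dim == 0L) {
      cols[[j]] <- integer(0)
    } else {
      faces <- utils::combn(sort(s$v), s$dim)
      cols[[j]] <- sort(
        vapply(seq_len(ncol(faces)), function(k) {
          pos[[paste(faces[, k], collapse = "-")]]
        }, 0L),
        decreasing = TRUE
      )
    }
  }

  lowOwner <- integer(m)  # 0 = free
  pairedAsBirth <- logical(m)
  bars <- list()
  for (j in seq_len(m)) {
    col <- cols[[j]]
    while (length(col) && lowOwner[col[1]] != 0L) {
      other <- cols[[lowOwner[col[1]]]]
      both <- c(col, other)
      col <- sort(both[!(both %in% both[duplicated(both)])],
        decreasing = TRUE
      )
    }
    cols[[j]] <- col
    if (length(col)) {
      low <- col[1]
      lowOwner[low] <- j
      pairedAsBirth[low] <- TRUE
      bars[[length(bars) + 1]] <- list(
        dim = dims[low], birth = filt[low], death = filt[j]
      )
    }
  }
  # positive simplices never paired: essential classes
  for (j in seq_len(m)) {
    if (length(cols[[j]]) == 0L && !pairedAsBirth[j] && dims[j] <= 1L) {
      bars[[length(bars) + 1]] <- list(
        dim = dims[j], birth = filt[j], death = Inf
      )
    }
  }
  out <- do.call(rbind, lapply(bars, as.data.frame))
  out[order(out$dim, out$birth, out$death), , drop = FALSE]
}

# canonical multiset form of a diagram for exact comparison; dim-1 bars of
# zero persistence carry no topology and are dropped on both sides
canonicalBars <- function(bars) {
  keep <- bars$dim == 0 | bars$death > bars$birth
  b <- bars[keep, c("dim", "birth", "death"), drop = FALSE]
  b <- b[order(b$dim, b$birth, b$death), , drop = FALSE]
  rownames(b) <- NULL
  b
}

# naive SPIKE-synchronization: double loop over spikes
syncOracle <- function(a, b) {
  count <- function(x, y) {
    cx <- 0
    for (i in seq_along(x)) {
      d <- abs(x[i] - y)
      j <- which.min(d)
      isis <- c(
        if (i > 1) x[i] - x[i - 1],
        if (i < length(x)) x[i + 1] - x[i],
        if (j > 1) y[j] - y[j - 1],
        if (j < length(y)) y[j + 1] - y[j]
      )
      tau <- if (length(isis)) min(isis) / 2 else Inf
      if (d[j] < tau) cx <- cx + 1
    }
    cx
  }
  (count(a, b) + count(b, a)) / (length(a) + length(b))
}

# dense midpoint sampling of the SPIKE-distance profile
spikeDistOracle <- function(a, b, t0, t1, dt = 0.02) {
  aa <- unique(c(t0, a, t1))
  bb <- unique(c(t0, b, t1))
  ts <- seq(t0, t1, by = dt)
  ts <- ts[-length(ts)] + dt / 2
  one <- function(tt, other, t) {
    k <- findInterval(t, tt)
    tP <- tt[k]
    tF <- tt[k + 1]
    nd <- function(x) vapply(x, function(z) min(abs(z - other)), 0)
    list(S = (nd(tP) * (tF - t) + nd(tF) * (t - tP)) / (tF - tP),
         isi = tF - tP)
  }
  sa <- one(aa, bb, ts)
  sb <- one(bb, aa, ts)
  S <- (sa$S * sb$isi + sb$S * sa$isi) / (2 * ((sa$isi + sb$isi) / 2)^2)
  mean(S)
}

# raster assembled by hand from an activity profile (for avalanche tests):
# A[t] spikes at step t, spread over distinct neurons
rasterFromActivity <- function(A, driveTimes, N = max(A) + 1L) {
  time <- rep(seq_along(A) - 1L, A)
  neuron <- unlist(lapply(A, seq_len))
  new("SpikeRaster",
    N = as.integer(N), T = length(A), neuron = as.integer(neuron),
    time = as.integer(time), driveTimes = as.integer(driveTimes),
    params = NetworkParams(N = N)
  )
}
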