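#' Vietoris-Rips persistent homology of a dissimilarity matrix
#'
#' Builds the Vietoris-Rips filtration of the weighted graph whose edge
#' weights are the pairwise dissimilarities (a simplex enters at its
#' largest pairwise weight; simplices up to dimension 2), truncated at
#' `epsMax`, and computes the persistence pairs in dimensions 0 and 1.
#' Dimension-0 deaths are the minimum-spanning-tree edge weights (elder
#' rule); dimension-1 pairs come from boundary-matrix reduction over GF(2).
#' Classes still alive at `epsMax` get death `Inf` and are capped at
#' `epsMax` in downstream feature areas. Zero-persistence dimension-1
#' pairs (a cycle filled in the instant it appears, e.g. any triangle) are
#' omitted; dimension-0 bars of length zero (coincident points) are kept.
#'
#' @param D a [DissimilarityMatrix-class], or a plain symmetric matrix with
#'   zero diagonal and entries in `[0, 1]`.
#' @param epsMax filtration truncation value (default 1, the maximum
#'   possible weight).
#' @return A [PersistenceDiagram-class] holding both dimensions.
#' @examples
#' D <- makeCycleMatrix(4, 0.3, 0.8)
#' persistenceBars(vrPersistence(D), dim = 1)  # one loop: (0.3, 0.8)
#' @export
vrPersistence <- function(D, epsMax = 1) {
  M <- if (is(D, "DissimilarityMatrix")) D@M else {
    if (!is.matrix(D) || !nrow(D)) stop("empty dissimilarity matrix")
    if (nrow(D) != ncol(D) || !all(is.finite(D)) ||
        max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0) ||
        min(D) < 0 || max(D) > 1) {
      stop("D must be a finite symmetric matrix, zero diagonal, in [0, 1]")
    }
    D
  }
  n <- nrow(M)
  if (n == 0L) stop("empty dissimilarity matrix")
  res <- .vr_persistence_cpp(M, epsMax)
  n0 <- length(res$h0Death)
  n1 <- length(res$h1Birth)
  bars <- data.frame(
    dim = c(rep(0, n0 + res$h0Inf), rep(1, n1)),
    birth = c(rep(0, n0 + res$h0Inf), res$h1Birth),
    death = c(res$h0Death, rep(Inf, res$h0Inf), res$h1Death)
  )
  new("PersistenceDiagram", bars = bars)
}

#' Dimension-0 part of the Vietoris-Rips diagram
#' @inheritParams vrPersistence
#' @return A [PersistenceDiagram-class] with the dimension-0 bars only.
#' @export
vrH0 <- function(D, epsMax = 1) {
  d <- vrPersistence(D, epsMax)
  new("PersistenceDiagram", bars = d@bars[d@bars$dim == 0, , drop = FALSE])
}

#' Dimension-1 part of the Vietoris-Rips diagram
#' @inheritParams vrPersistence
#' @return A [PersistenceDiagram-class] with the dimension-1 bars only.
#' @export
vrH1 <- function(D, epsMax = 1) {
  d <- vrPersistence(D, epsMax)
  new("PersistenceDiagram", bars = d@bars[d@bars$dim == 1, , drop = FALSE])
}

#' @describeIn PersistenceDiagram-class bars of one dimension as a
#'   data.frame (`birth`, `death`), rows sorted by birth then death.
#' @param x a `PersistenceDiagram`.
#' @param dim homology dimension, 0 or 1.
#' @export
setMethod("persistenceBars", "PersistenceDiagram", function(x, dim) {
  b <- x@bars[x@bars$dim == dim, c("birth", "death"), drop = FALSE]
  b <- b[order(b$birth, b$death), , drop = FALSE]
  rownames(b) <- NULL
  b
})

setMethod("show", "PersistenceDiagram", function(object) {
  for (d in 0:1) {
    b <- object@bars[object@bars$dim == d, ]
    cat(sprintf(
      "H%d: %d bars (%d essential)\n", d, nrow(b), sum(is.infinite(b$death))
    ))
  }
})

#' Betti curve of a persistence diagram
#'
#' Evaluates \eqn{\beta_k(\epsilon) = \#\{bars : birth \le \epsilon <
#' death\}} (half-open convention) on a grid of thresholds.
#'
#' @param diag a [PersistenceDiagram-class].
#' @param dim homology dimension, 0 or 1.
#' @param grid strictly increasing thresholds in `[0, 1]`.
#' @return A [BettiCurve-class].
#' @examples
#' D <- makeClusterMatrix(c(3, 3), 0.1, 0.9)
#' bc <- bettiCurve(vrPersistence(D), 0, c(0.05, 0.5, 0.95))
#' bc@beta  # 6 components, then 2 clusters, then 1
#' @export
bettiCurve <- function(diag, dim, grid = seq(0, 1, length.out = 101)) {
  b <- diag@bars[diag@bars$dim == dim, , drop = FALSE]
  birth <- sort(b$birth)
  death <- sort(b$death[is.finite(b$death)])
  beta <- findInterval(grid, birth) - findInterval(grid, death)
  new("BettiCurve",
    grid = as.numeric(grid), beta = as.integer(beta), dim = as.integer(dim)
  )
}

#' The four Betti-curve features of a filtration
#'
#' Computed exactly from the persistence diagram (no sampling grid):
#' \describe{
#'   \item{f1}{turning point of the Betti-0 curve: the smallest finite
#'     dimension-0 death, i.e. the smallest pairwise dissimilarity
#'     (`epsMax` for a single vertex, which never connects).}
#'   \item{f2}{area under the Betti-0 curve on `[0, epsMax]`: the sum of
#'     dimension-0 bar lengths with deaths capped at `epsMax`; the
#'     essential component contributes `epsMax`.}
#'   \item{f3}{global maximum of the Betti-1 curve, obtained by sweeping
#'     the bar endpoints.}
#'   \item{f4}{area under the Betti-1 curve: capped dimension-1 bar-length
#'     sum.}
#' }
#'
#' @param diag a [PersistenceDiagram-class] holding dimensions 0 and 1 (as
#'   returned by [vrPersistence()]).
#' @param epsMax filtration truncation value used for capping.
#' @param measure optional measure tag carried into the result.
#' @return A [TopoFeatures-class].
#' @examples
#' topoFeatures(vrPersistence(makeClusterMatrix(c(3, 3), 0.1, 0.9)))
#' @export
topoFeatures <- function(diag, epsMax = 1, measure = NA_character_) {
  b0 <- diag@bars[diag@bars$dim == 0, , drop = FALSE]
  b1 <- diag@bars[diag@bars$dim == 1, , drop = FALSE]
  finite0 <- b0$death[is.finite(b0$death)]
  f1 <- if (length(finite0)) min(finite0) else epsMax
  f2 <- sum(pmin(b0$death, epsMax) - b0$birth)
  if (nrow(b1)) {
    # beta1 attains its maximum at a birth value
    f3 <- max(vapply(b1$birth, function(e) {
      sum(b1$birth <= e & b1$death > e)
    }, numeric(1)))
    f4 <- sum(pmin(b1$death, epsMax) - pmin(b1$birth, epsMax))
  } else {
    f3 <- 0
    f4 <- 0
  }
  new("TopoFeatures",
    f1 = f1, f2 = f2, f3 = f3, f4 = f4, epsMax = epsMax,
    measure = as.character(measure)
  )
}

#' @describeIn TopoFeatures-class the features as a named numeric vector
#'   `c(f1, f2, f3, f4)`.
#' @param x a `TopoFeatures` object.
#' @param ... unused.
#' @export
setMethod("as.numeric", "TopoFeatures", function(x, ...) {
  c(f1 = x@f1, f2 = x@f2, f3 = x@f3, f4 = x@f4)
})

setMethod("show", "TopoFeatures", function(object) {
  cat(sprintf(
    "TopoFeatures (%s): f1=%.4g f2=%.4g f3=%g f4=%.4g (epsMax=%g)\n",
    object@measure, object@f1, object@f2, object@f3, object@f4,
    object@epsMax
  ))
})

#' Write a persistence diagram as CSV
#'
#' Columns `dim,birth,death`; essential classes have death `inf`.
#'
#' @param diag a [PersistenceDiagram-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDiagram <- function(diag, path) {
  b <- diag@bars
  death <- ifelse(is.infinite(b$death), "inf", sprintf("%.17g", b$death))
  writeLines(
    c("dim,birth,death",
      sprintf("%d,%.17g,%s", as.integer(b$dim), b$birth, death)),
    path
  )
  invisible(path)
}

#' Read a persistence diagram written by [writeDiagram()]
#' @param path file path.
#' @return A [PersistenceDiagram-class].
#' @export
readDiagram <- function(path) {
  tab <- utils::read.csv(path, colClasses = c("integer", "numeric",
                                              "character"))
  death <- ifelse(tab$death == "inf", Inf, as.numeric(tab$death))
  new("PersistenceDiagram",
    bars = data.frame(dim = tab$dim, birth = tab$birth, death = death)
  )
}
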