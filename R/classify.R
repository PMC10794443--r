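#' Regime label for an inhibition ratio
#'
#' The network is super-critical (self-sustained activity) below the
#' critical ratio, sub-critical above it.
#'
#' @param g inhibition ratio(s).
#' @param gCritical the critical ratio (default 1.5, the value for the
#'   default parameters).
#' @return Factor with levels `super_critical`, `critical`, `sub_critical`.
#' @export
regimeLabel <- function(g, gCritical = 1.5) {
  lab <- ifelse(abs(g - gCritical) < 1e-9, "critical",
    ifelse(g < gCritical, "super_critical", "sub_critical")
  )
  factor(lab, levels = c("super_critical", "critical", "sub_critical"))
}

.simFeatures <- function(params, config, streamIndex) {
  raster <- simulateNetwork(params,
    tTotal = config$tTotal, tTransient = config$tTransient,
    streamIndex = streamIndex
  )
  A <- activityTrace(raster) / params@N
  out <- list(meanActivity = mean(A), varActivity = stats::var(A))
  for (m in config$measures) {
    D <- dissimilarity(raster, m,
      binMs = config$binMs, minSpikes = config$minSpikes,
      vertexCap = config$vertexCap,
      seed = config$masterSeed + 7919L * streamIndex
    )
    f <- topoFeatures(vrPersistence(D, config$epsMax),
      epsMax = config$epsMax, measure = m
    )
    out[paste(m, c("f1", "f2", "f3", "f4"), sep = ".")] <- as.numeric(f)
  }
  out
}

#' Build the labeled regime dataset
#'
#' Runs one simulation per replicate of every grid value of the inhibition
#' ratio (plus the extra critical replicates), and computes for each run
#' the baseline activity features (mean network activity per neuron per
#' step and the variance over time of the per-step activity fraction) and,
#' for every configured dissimilarity measure, the four Betti-curve
#' features. Simulation `i` uses RNG stream `(masterSeed, i)`, so the
#' returned table is a pure function of the configuration.
#'
#' @param config a [spikeTopoConfig()].
#' @param verbose print one progress line per simulation.
#' @return A data.frame with one row per simulation: `g`, `label`,
#'   `simIndex`, `meanActivity`, `varActivity` and, per measure,
#'   `<measure>.f1` .. `<measure>.f4`.
#' @export
buildDataset <- function(config, verbose = FALSE) {
  gs <- c(
    rep(gGrid(config), each = config$repsPerG),
    rep(config$gCritical, config$extraCritical)
  )
  rows <- vector("list", length(gs))
  for (i in seq_along(gs)) {
    params <- NetworkParams(
      N = config$N, p = config$p, J = config$J, g = gs[i],
      Gamma = config$Gamma, mu = config$mu, theta = config$theta,
      Iext = config$Iext, seed = config$masterSeed
    )
    feats <- tryCatch(
      .simFeatures(params, config, streamIndex = i),
      error = function(e) {
        stop(sprintf(
          "simulation %d (g=%.3f, stream %d) failed: %s",
          i, gs[i], i, conditionMessage(e)
        ), call. = FALSE)
      }
    )
    rows[[i]] <- c(list(g = gs[i], simIndex = i), feats)
    if (verbose) {
      message(sprintf("sim %d/%d g=%.2f done", i, length(gs), gs[i]))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out$label <- regimeLabel(out$g, config$gCritical)
  out[, c(
    "g", "label", "simIndex",
    setdiff(names(out), c("g", "label", "simIndex"))
  )]
}

## task -> (filtered rows, response factor)
.taskData <- function(samples, task) {
  lab <- samples$label
  if (task == 1) {
    keep <- lab != "critical"
    y <- droplevels(lab[keep])
  } else if (task == 2) {
    keep <- rep(TRUE, length(lab))
    y <- lab
  } else if (task == 3) {
    keep <- rep(TRUE, length(lab))
    y <- factor(ifelse(lab == "critical", "critical", "non_critical"),
      levels = c("critical", "non_critical")
    )
  } else {
    stop("task must be 1, 2 or 3")
  }
  if (nlevels(droplevels(y)) < 2) stop("task is degenerate: single class")
  list(keep = which(keep), y = y)
}

.stratifiedSplit <- function(y, frac = 0.8) {
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    nTr <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    train <- c(train, idx[seq_len(nTr)])
  }
  sort(train)
}

.stratifiedFolds <- function(y, k = 10) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

## median-heuristic RBF kernel width on the standardized training matrix
.medianGamma <- function(X) {
  d2 <- stats::dist(X)^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) 1 / ncol(X) else 1 / (2 * med)
}

#' Train and evaluate the RBF-kernel SVM on a regime task
#'
#' For each of `repeats` repetitions: draw a stratified 80/20
#' train/test split, standardize the features with training-set statistics
#' only, select the regularization constant `C` from
#' `10^(-2), ..., 10^3` by stratified 10-fold cross-validation on the
#' training portion (RBF kernel width fixed by the median heuristic on the
#' training set), refit on the full training portion and record the test
#' accuracy. The SVM is the standard L2-regularized (soft-margin) RBF
#' machine of [e1071::svm()].
#'
#' @param samples dataset from [buildDataset()] (or any data.frame with a
#'   `label` factor column and numeric feature columns).
#' @param task 1 = super- vs sub-critical (critical rows dropped), 2 = all
#'   three regimes, 3 = critical vs non-critical.
#' @param featureSet character vector of feature column names.
#' @param repeats number of repeated splits.
#' @param seed seed for the split draws (results are reproducible).
#' @return A [ClassificationResult-class].
#' @examples
#' \donttest{
#' cfg <- spikeTopoConfig(
#'   N = 100, gStep = 0.1, repsPerG = 3, extraCritical = 4,
#'   tTotal = 5000, tTransient = 1000, measures = character(0)
#' )
#' ds <- buildDataset(cfg)
#' meanAccuracy(trainEval(ds, 1, "meanActivity", repeats = 5))
#' }
#' @export
trainEval <- function(samples, task, featureSet, repeats = 20, seed = 1L) {
  td <- .taskData(samples, task)
  X <- as.matrix(samples[td$keep, featureSet, drop = FALSE])
  storage.mode(X) <- "double"
  y <- td$y
  if (any(!is.finite(X))) stop("non-finite feature values")
  cGrid <- 10^seq(-2, 3)
  acc <- .withSeed(seed, {
    vapply(seq_len(repeats), function(r) {
      tr <- .stratifiedSplit(y)
      te <- setdiff(seq_along(y), tr)
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      Xs <- scale(X, center = mu, scale = sg)
      gamma <- .medianGamma(Xs[tr, , drop = FALSE])
      fold <- .stratifiedFolds(y[tr])
      cvAcc <- vapply(cGrid, function(C) {
        hits <- vapply(sort(unique(fold)), function(f) {
          inTr <- tr[fold != f]
          inTe <- tr[fold == f]
          fit <- e1071::svm(Xs[inTr, , drop = FALSE],
            droplevels(y[inTr]),
            kernel = "radial", gamma = gamma, cost = C, scale = FALSE
          )
          sum(as.character(predict(fit, Xs[inTe, , drop = FALSE])) ==
                as.character(y[inTe]))
        }, numeric(1))
        sum(hits) / length(tr)
      }, numeric(1))
      C <- cGrid[which.max(cvAcc)]
      fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
        kernel = "radial", gamma = gamma, cost = C, scale = FALSE
      )
      mean(as.character(predict(fit, Xs[te, , drop = FALSE])) ==
             as.character(y[te]))
    }, numeric(1))
  })
  new("ClassificationResult",
    task = as.integer(task), featureSet = featureSet, accuracies = acc,
    nRepeats = as.integer(repeats)
  )
}

#' @describeIn ClassificationResult-class mean test accuracy over the
#'   repeated splits.
#' @param x a `ClassificationResult`.
#' @export
setMethod("meanAccuracy", "ClassificationResult", function(x) {
  mean(x@accuracies)
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf(
    "ClassificationResult task %d [%s]: mean accuracy %.2f%% over %d splits (sd %.2f%%)\n",
    object@task, paste(object@featureSet, collapse = ", "),
    100 * meanAccuracy(object), object@nRepeats,
    100 * stats::sd(object@accuracies)
  ))
})

#' Replicate mean and SD of every feature along the inhibition-ratio grid
#'
#' @param samples dataset from [buildDataset()].
#' @return A long data.frame with columns `g`, `feature` (column name),
#'   `mean`, `sd`, suitable for feature-versus-g trend plots.
#' @export
featureTrendReport <- function(samples) {
  featCols <- grep("\\.f[1-4]$|^meanActivity$|^varActivity$",
    names(samples),
    value = TRUE
  )
  out <- do.call(rbind, lapply(featCols, function(fc) {
    m <- tapply(samples[[fc]], samples$g, mean)
    s <- tapply(samples[[fc]], samples$g, stats::sd)
    data.frame(
      g = as.numeric(names(m)), feature = fc, mean = as.numeric(m),
      sd = as.numeric(s)
    )
  }))
  rownames(out) <- NULL
  out
}
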