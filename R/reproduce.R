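#' Run the full reduced-scale analysis and write a report
#'
#' Drives the whole pipeline from one configuration: builds the labeled
#' dataset, writes the feature table and the per-feature trend report, and
#' evaluates the SVM on the three regime tasks for each measure's four
#' Betti-curve features and for the activity baselines (mean activity,
#' activity variance, and both). A JSON manifest records the
#' configuration, seeds and output paths, so a run is reproducible
#' bit-for-bit from the manifest.
#'
#' @param config a [spikeTopoConfig()].
#' @param outDir output directory (created if missing).
#' @param verbose print progress.
#' @return Invisibly, a list with the accuracy table (`accuracy`), the
#'   dataset (`samples`), the trend report (`trends`) and the manifest.
#' @export
reproduceAnalysis <- function(config, outDir, verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  samples <- buildDataset(config, verbose = verbose)
  utils::write.csv(samples, file.path(outDir, "features.csv"),
    row.names = FALSE
  )
  trends <- featureTrendReport(samples)
  utils::write.csv(trends, file.path(outDir, "feature_trends.csv"),
    row.names = FALSE
  )

  sets <- c(
    lapply(config$measures, function(m) {
      paste(m, c("f1", "f2", "f3", "f4"), sep = ".")
    }),
    list("meanActivity", "varActivity", c("meanActivity", "varActivity"))
  )
  names(sets) <- c(config$measures, "baseline_mean", "baseline_var",
                   "baseline_both")
  grid <- expand.grid(
    task = 1:3, featureSet = names(sets),
    stringsAsFactors = FALSE
  )
  accuracy <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    task <- grid$task[i]
    setName <- grid$featureSet[i]
    res <- tryCatch(
      trainEval(samples, task, sets[[setName]],
        repeats = config$repeats,
        seed = config$masterSeed + 131L * i
      ),
      error = function(e) e
    )
    ok <- is(res, "ClassificationResult")
    if (verbose) {
      message(sprintf(
        "task %d / %s: %s", task, setName,
        if (ok) sprintf("%.2f%%", 100 * meanAccuracy(res)) else "FAILED"
      ))
    }
    data.frame(
      task = task, featureSet = setName,
      meanAccuracy = if (ok) meanAccuracy(res) else NA_real_,
      sdAccuracy = if (ok) stats::sd(res@accuracies) else NA_real_,
      nRepeats = config$repeats,
      status = if (ok) "ok" else conditionMessage(res)
    )
  }))
  utils::write.csv(accuracy, file.path(outDir, "accuracy.csv"),
    row.names = FALSE
  )

  md <- c(
    "# Regime classification report", "",
    sprintf(
      "- %d simulations (N=%d, %d steps, transient %d), master seed %d",
      nSimulations(config), config$N, config$tTotal, config$tTransient,
      config$masterSeed
    ),
    "", "| task | feature set | mean accuracy | sd |", "|---|---|---|---|",
    sprintf(
      "| %d | %s | %s | %s |", accuracy$task, accuracy$featureSet,
      ifelse(is.na(accuracy$meanAccuracy), "FAILED",
        sprintf("%.2f%%", 100 * accuracy$meanAccuracy)
      ),
      ifelse(is.na(accuracy$sdAccuracy), "-",
        sprintf("%.2f%%", 100 * accuracy$sdAccuracy)
      )
    )
  )
  writeLines(md, file.path(outDir, "report.md"))

  manifest <- list(
    config = unclass(config),
    masterSeed = config$masterSeed,
    simulationStreams = seq_len(nSimulations(config)),
    outputs = file.path(outDir, c(
      "features.csv", "feature_trends.csv", "accuracy.csv", "report.md"
    )),
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    accuracy = accuracy, samples = samples, trends = trends,
    manifest = manifest
  ))
}

#' Log-log avalanche CCDF plot
#'
#' Overlays the complementary cumulative size (or duration) distributions
#' of several rasters, the standard display of avalanche statistics; at
#' the critical ratio the curves are power-law-like with an exponential
#' cutoff that grows with network size.
#'
#' @param ccdfs named list of data.frames from [avalancheCCDF()].
#' @param xlab,main plot labels.
#' @return Invisibly, `NULL`.
#' @export
plotAvalancheCCDF <- function(ccdfs, xlab = "avalanche size",
                              main = "Avalanche CCDF") {
  if (!length(ccdfs)) stop("no CCDF curves supplied")
  xr <- range(unlist(lapply(ccdfs, function(d) range(d$value))))
  yr <- range(unlist(lapply(ccdfs, function(d) range(d$survival))))
  graphics::plot(NA,
    xlim = pmax(xr, .Machine$double.xmin), ylim = yr, log = "xy",
    xlab = xlab, ylab = "P(X >= x)", main = main
  )
  cols <- grDevices::hcl.colors(length(ccdfs), "Dark 3")
  for (i in seq_along(ccdfs)) {
    graphics::lines(ccdfs[[i]]$value, ccdfs[[i]]$survival,
      col = cols[i], type = "s"
    )
  }
  if (!is.null(names(ccdfs))) {
    graphics::legend("bottomleft", legend = names(ccdfs), col = cols,
      lty = 1, bty = "n"
    )
  }
  invisible(NULL)
}

#' Twelve-panel feature-versus-g plot
#'
#' Replicate-averaged value of each of the four Betti-curve features
#' (rows) for each dissimilarity measure (columns) against the inhibition
#' ratio, with the critical ratio marked.
#'
#' @param trends trend table from [featureTrendReport()].
#' @param measures measures to show as columns.
#' @param gCritical critical ratio marked by a vertical line.
#' @return Invisibly, `NULL`.
#' @export
plotFeatureTrends <- function(trends,
                              measures = c("pearson", "spike_sync",
                                           "spike_distance"),
                              gCritical = 1.5) {
  wanted <- as.vector(outer(measures, paste0("f", 1:4),
    function(m, f) paste(m, f, sep = ".")
  ))
  missing <- setdiff(wanted, unique(trends$feature))
  if (length(missing)) {
    stop(
      "trend table lacks feature columns: ",
      paste(missing, collapse = ", ")
    )
  }
  op <- graphics::par(mfrow = c(4, length(measures)),
    mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0)
  )
  on.exit(graphics::par(op))
  for (f in paste0("f", 1:4)) {
    for (m in measures) {
      d <- trends[trends$feature == paste(m, f, sep = "."), ]
      graphics::plot(d$g, d$mean,
        type = "b", pch = 16, cex = 0.6, xlab = "g", ylab = f,
        main = if (f == "f1") m else ""
      )
      suppressWarnings(graphics::arrows(d$g, d$mean - d$sd, d$g,
        d$mean + d$sd,
        length = 0.02, angle = 90, code = 3, col = "grey60"
      ))
      graphics::abline(v = gCritical, lty = 2, col = "red")
    }
  }
  invisible(NULL)
}
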