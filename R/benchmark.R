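#' Run one optimizer on one image
#'
#' Convenience wrapper chaining preprocessing, histogram computation,
#' optimization, segmentation and (optionally) the metric report — the unit
#' of work of the benchmark harness and of the command-line `threshold`
#' subcommand.
#'
#' @param image matrix, EBImage Image, or file path.
#' @param k number of thresholds.
#' @param algorithm one of \code{"scsowoa"}, \code{"scso"}, \code{"woa"},
#'   \code{"pso"}, \code{"gwo"}.
#' @param cfg a \code{HybridConfig}.
#' @param seed integer RNG seed.
#' @param computeMetrics attach a [metricReport()] (default TRUE).
#' @param preprocess run [preprocessImage()] first (default TRUE); set
#'   FALSE when the input is already an 8-bit intensity matrix.
#' @return list with \code{fit} (\linkS4class{SwarmFit}), \code{segmentation}
#'   (\linkS4class{SegmentationResult}), and \code{metrics} (one-row
#'   data.frame or NULL).
#' @export
thresholdImage <- function(image, k, algorithm = "scsowoa",
                           cfg = hybridConfig(), seed = 1L,
                           computeMetrics = TRUE, preprocess = TRUE) {
  algorithm <- match.arg(algorithm, c("scsowoa", "scso", "woa", "pso", "gwo"))
  img <- if (preprocess) preprocessImage(image) else image
  h <- computeHistogram(img)
  fit <- if (algorithm == "scsowoa") runSCSOWOA(h, k, cfg, seed = seed)
         else runBaseline(algorithm, h, k, cfg, seed = seed)
  seg <- applyThresholds(img, bestThresholds(fit))
  mets <- if (computeMetrics) metricReport(img, reconstruction(seg)) else NULL
  list(fit = fit, segmentation = seg, metrics = mets)
}

#' Benchmark optimizers over images, threshold counts and repeated runs
#'
#' Reproduces the shape of the evaluation protocol: every algorithm is run
#' \code{nRuns} times (run \code{r} seeded \code{baseSeed + r - 1}) on every
#' image for every threshold count, and per-(algorithm, k) means and sample
#' standard deviations (n-1 denominator) of the objective and any metrics
#' are tabulated. Two aggregations are reported: pooled over all images and
#' runs jointly, and per-image means averaged afterwards. Wall-clock per run
#' is recorded but intentionally never asserted on.
#'
#' @param images named list of 8-bit intensity matrices (as from
#'   [preprocessImage()] or the synthetic generators).
#' @param algorithms subset of \code{c("scsowoa", "scso", "woa", "pso",
#'   "gwo")}.
#' @param kValues integer vector of threshold counts (default
#'   \code{c(2, 4, 6, 8, 10, 12)}).
#' @param nRuns independent runs per condition (default 10).
#' @param cfg a \code{HybridConfig}.
#' @param baseSeed base RNG seed (default 1).
#' @param computeMetrics also compute PSNR/SSIM/FSIM per run (default FALSE;
#'   the objective J is always recorded).
#' @param outDir optional directory for CSV output (\code{runs.csv},
#'   \code{summary_pooled.csv}, \code{summary_by_image.csv}).
#' @return list with \code{runs} (one row per run), \code{summaryPooled},
#'   \code{summaryByImage}.
#' @export
runBenchmark <- function(images, algorithms = c("scsowoa", "scso", "woa"),
                         kValues = c(2L, 4L, 6L, 8L, 10L, 12L), nRuns = 10L,
                         cfg = hybridConfig(), baseSeed = 1L,
                         computeMetrics = FALSE, outDir = NULL) {
  stopifnot(nRuns >= 1, length(images) >= 1, !is.null(names(images)),
            all(kValues >= 1), all(kValues <= 20))
  algorithms <- match.arg(algorithms,
                          c("scsowoa", "scso", "woa", "pso", "gwo"),
                          several.ok = TRUE)
  rows <- list()
  for (imgName in names(images)) {
    img <- images[[imgName]]
    h <- computeHistogram(img)
    for (alg in algorithms) {
      for (k in kValues) {
        for (r in seq_len(nRuns)) {
          seed <- as.integer(baseSeed) + r - 1L
          t0 <- proc.time()[["elapsed"]]
          fit <- tryCatch(
            if (alg == "scsowoa") runSCSOWOA(h, k, cfg, seed = seed)
            else runBaseline(alg, h, k, cfg, seed = seed),
            error = function(e) e)
          elapsed <- proc.time()[["elapsed"]] - t0
          if (inherits(fit, "error")) {
            warning(sprintf("run failed (%s, k=%d, run %d): %s",
                            alg, k, r, conditionMessage(fit)))
            rows[[length(rows) + 1L]] <- data.frame(
              image = imgName, algorithm = alg, k = k, run = r, seed = seed,
              J = NA_real_, seconds = elapsed, failed = TRUE)
            next
          }
          row <- data.frame(image = imgName, algorithm = alg, k = k,
                            run = r, seed = seed, J = objectiveValue(fit),
                            seconds = elapsed, failed = FALSE)
          if (computeMetrics) {
            seg <- applyThresholds(img, bestThresholds(fit))
            row <- cbind(row, metricReport(img, reconstruction(seg),
                                           correlations = FALSE))
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  metricCols <- setdiff(names(runs)[vapply(runs, is.numeric, logical(1))],
                        c("k", "run", "seed"))
  agg <- function(df) {
    out <- list()
    for (alg in unique(df$algorithm)) for (k in unique(df$k)) {
      sel <- df[df$algorithm == alg & df$k == k & !df$failed, , drop = FALSE]
      if (nrow(sel) == 0L) next
      row <- data.frame(algorithm = alg, k = k, n = nrow(sel))
      for (mc in metricCols) {
        row[[paste0(mc, "_mean")]] <- mean(sel[[mc]])
        row[[paste0(mc, "_sd")]] <- stats::sd(sel[[mc]])
      }
      out[[length(out) + 1L]] <- row
    }
    do.call(rbind, out)
  }
  summaryPooled <- agg(runs)
  # per-image means first, then aggregate across images
  perImage <- stats::aggregate(
    runs[!runs$failed, metricCols, drop = FALSE],
    by = list(image = runs$image[!runs$failed],
              algorithm = runs$algorithm[!runs$failed],
              k = runs$k[!runs$failed]),
    FUN = mean)
  perImage$failed <- FALSE
  summaryByImage <- agg(perImage)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(runs, file.path(outDir, "runs.csv"), row.names = FALSE)
    utils::write.csv(summaryPooled, file.path(outDir, "summary_pooled.csv"),
                     row.names = FALSE)
    utils::write.csv(summaryByImage,
                     file.path(outDir, "summary_by_image.csv"),
                     row.names = FALSE)
  }
  list(runs = runs, summaryPooled = summaryPooled,
       summaryByImage = summaryByImage)
}

#' Component ablation: hybrid versus its two constituents
#'
#' Runs the benchmark with algorithms fixed to \code{c("scso", "woa",
#' "scsowoa")}, the comparison that isolates what each phase contributes:
#' the hybrid should match the constituents on mean objective while showing
#' equal or lower across-run spread at high threshold counts.
#'
#' @inheritParams runBenchmark
#' @return as [runBenchmark()].
#' @export
runAblation <- function(images, kValues = c(10L, 12L), nRuns = 10L,
                        cfg = hybridConfig(), baseSeed = 1L,
                        computeMetrics = FALSE, outDir = NULL) {
  runBenchmark(images, algorithms = c("scso", "woa", "scsowoa"),
               kValues = kValues, nRuns = nRuns, cfg = cfg,
               baseSeed = baseSeed, computeMetrics = computeMetrics,
               outDir = outDir)
}

#' In-memory synthetic benchmark images
#'
#' The histogram-bearing members of the fixture suite (bimodal, trimodal,
#' five-mode mixtures and the blob image) as ready-to-use matrices, for
#' benchmarking without touching disk.
#'
#' @param seed base seed, as in [makeFixtureSuite()].
#' @param size image size (default c(128, 128)).
#' @return named list of integer matrices.
#' @export
syntheticBenchmarkImages <- function(seed = 1L, size = c(128L, 128L)) {
  specs <- .fixtureSpecs()
  keep <- c("bimodal", "trimodal", "fivemode", "blob")
  out <- list()
  for (i in seq_along(specs)) {
    name <- names(specs)[i]
    if (!name %in% keep) next
    out[[name]] <- .buildFixture(name, specs[[i]], size,
                                 as.integer(seed) + i - 1L)$image
  }
  out
}

#' Serialize a histogram to CSV
#'
#' Two columns, \code{bin} (0-based gray level) and \code{probability}.
#'
#' @param hist a \linkS4class{GrayHistogram}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeHistogramCSV <- function(hist, file) {
  stopifnot(is(hist, "GrayHistogram"))
  utils::write.csv(data.frame(bin = seq_along(histProbs(hist)) - 1L,
                              probability = histProbs(hist)),
                   file, row.names = FALSE)
  invisible(file)
}
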