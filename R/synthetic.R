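#' Seeded multi-modal synthetic grayscale image
#'
#' Draws each pixel's component from a categorical distribution over the
#' mixture modes and its intensity from the component's normal truncated to
#' [0, 255] (by rejection, so no spurious mass piles up at the range ends),
#' then rounds to 8-bit. Emulates the multi-modal gray-level histograms of
#' stained tissue images — e.g. dark nuclei, mid-gray cytoplasm, bright
#' background — with fully known generating parameters, so optimizer and
#' metric behaviour can be validated against the analytic mixture density.
#'
#' @param modes data.frame (or list of 3-vectors) with columns \code{mean}
#'   (in [0, 255]), \code{sd} (>= 0) and \code{weight} (> 0, normalized to
#'   sum 1); means must be sorted ascending.
#' @param size length-2 integer image size (rows, cols), default
#'   c(256, 256).
#' @param seed integer RNG seed.
#' @return list with \code{image} (integer matrix) and \code{componentLabels}
#'   (integer matrix of generating components, 1-based).
#' @examples
#' mix <- makeMixtureImage(data.frame(mean = c(60, 180), sd = 8,
#'                                    weight = 0.5), size = c(32, 32), seed = 1)
#' table(mix$componentLabels)
#' @export
makeMixtureImage <- function(modes, size = c(256L, 256L), seed = 1L) {
  modes <- as.data.frame(modes)
  if (nrow(modes) == 0L) stop("empty modes")
  stopifnot(all(c("mean", "sd", "weight") %in% names(modes)),
            all(modes$weight > 0), all(modes$sd >= 0),
            all(modes$mean >= 0), all(modes$mean <= 255),
            !is.unsorted(modes$mean))
  w <- modes$weight / sum(modes$weight)
  npix <- prod(size)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  comp <- sample.int(nrow(modes), npix, replace = TRUE, prob = w)
  val <- numeric(npix)
  for (i in seq_len(nrow(modes))) {
    idx <- which(comp == i)
    if (length(idx) == 0L) next
    val[idx] <- .rtruncnorm(length(idx), modes$mean[i], modes$sd[i], 0, 255)
  }
  list(image = matrix(as.integer(round(val)), size[1], size[2]),
       componentLabels = matrix(comp, size[1], size[2]))
}

## truncated normal by rejection; sd = 0 degenerates to the mean
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    cand <- stats::rnorm(length(need), mean, sd)
    ok <- cand >= lower & cand <= upper
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Synthetic blobs-on-background image with exact ground-truth mask
#'
#' Places \code{nBlobs} disks of intensity \code{blobIntensity} on a uniform
#' background, adds i.i.d. Gaussian noise, rounds and clamps to 8-bit, and
#' returns the exact disk mask — a nuclei-on-tissue style fixture for
#' validating overlap metrics (Dice, Jaccard, Hausdorff) against known
#' truth.
#'
#' Disk centers and radii are drawn uniformly (radius between 6% and 12% of
#' the short image side) with every disk kept fully inside the frame.
#'
#' @param nBlobs number of disks (0 allowed: constant background).
#' @param blobIntensity,backgroundIntensity 8-bit intensities.
#' @param noiseSd Gaussian noise standard deviation (0 for noiseless).
#' @param size length-2 image size, default c(128, 128).
#' @param seed integer RNG seed.
#' @return list with \code{image} (integer matrix) and \code{foregroundMask}
#'   (logical matrix).
#' @export
makeBlobImage <- function(nBlobs = 6L, blobIntensity = 200,
                          backgroundIntensity = 60, noiseSd = 5,
                          size = c(128L, 128L), seed = 1L) {
  stopifnot(blobIntensity >= 0, blobIntensity <= 255,
            backgroundIntensity >= 0, backgroundIntensity <= 255,
            all(size >= 8), nBlobs >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  mask <- matrix(FALSE, size[1], size[2])
  rmin <- 0.06 * min(size); rmax <- 0.12 * min(size)
  rows <- row(mask); cols <- col(mask)
  for (b in seq_len(nBlobs)) {
    r <- stats::runif(1, rmin, rmax)
    cy <- stats::runif(1, r + 1, size[1] - r)
    cx <- stats::runif(1, r + 1, size[2] - r)
    mask <- mask | ((rows - cy)^2 + (cols - cx)^2 <= r^2)
  }
  img <- matrix(backgroundIntensity, size[1], size[2])
  img[mask] <- blobIntensity
  if (noiseSd > 0) img <- img + stats::rnorm(length(img), 0, noiseSd)
  img <- pmin(pmax(round(img), 0), 255)
  list(image = matrix(as.integer(img), size[1], size[2]),
       foregroundMask = mask)
}

## fixture definitions shared by makeFixtureSuite() and the test helpers
.fixtureSpecs <- function() {
  list(
    bimodal = list(type = "mixture",
                   modes = data.frame(mean = c(60, 180), sd = c(10, 10),
                                      weight = c(0.5, 0.5))),
    trimodal = list(type = "mixture",
                    modes = data.frame(mean = c(50, 128, 210),
                                       sd = c(12, 15, 10),
                                       weight = c(0.35, 0.4, 0.25))),
    fivemode = list(type = "mixture",
                    modes = data.frame(mean = c(30, 80, 130, 180, 230),
                                       sd = c(8, 10, 12, 10, 8),
                                       weight = c(0.15, 0.25, 0.25, 0.2, 0.15))),
    blob = list(type = "blob"),
    constant = list(type = "constant", value = 128L),
    twopoint = list(type = "twopoint", lo = 50L, hi = 200L)
  )
}

.buildFixture <- function(name, spec, size, seed) {
  switch(spec$type,
    mixture = makeMixtureImage(spec$modes, size = size, seed = seed),
    blob = makeBlobImage(size = size, seed = seed),
    constant = list(image = matrix(spec$value, size[1], size[2])),
    twopoint = {
      v <- rep_len(c(spec$lo, spec$hi), prod(size))
      list(image = matrix(as.integer(v), size[1], size[2]))
    })
}

#' Generate the standard synthetic fixture suite
#'
#' Writes six seeded fixtures (bimodal, trimodal, five-mode mixtures; a
#' blob image with mask; a constant image; a two-point image) as PNGs plus
#' a CSV manifest recording each fixture's generating parameters and, for
#' \code{k} in \code{oracleK}, the exhaustively optimal thresholds and
#' objective value computed with [bruteForceThresholds()]. Regeneration with
#' the same seed is bit-identical.
#'
#' @param outDir output directory (created if missing).
#' @param seed base RNG seed; fixture i uses \code{seed + i - 1}.
#' @param size image size (default c(128, 128) keeps the suite light).
#' @param oracleK integer vector of threshold counts to record exhaustive
#'   optima for (default 1:2).
#' @return the manifest data.frame, invisibly; written to
#'   \code{manifest.csv} in \code{outDir}.
#' @export
makeFixtureSuite <- function(outDir, seed = 1L, size = c(128L, 128L),
                             oracleK = 1:2) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  specs <- .fixtureSpecs()
  rows <- list()
  for (i in seq_along(specs)) {
    name <- names(specs)[i]
    fseed <- as.integer(seed) + i - 1L
    fx <- .buildFixture(name, specs[[i]], size, fseed)
    png::writePNG(fx$image / 255, file.path(outDir, paste0(name, ".png")))
    if (!is.null(fx$foregroundMask)) {
      png::writePNG(fx$foregroundMask * 1.0,
                    file.path(outDir, paste0(name, "_mask.png")))
    }
    h <- computeHistogram(fx$image)
    params <- specs[[i]]
    paramStr <- if (params$type == "mixture") {
      paste(apply(params$modes, 1, function(r)
        paste0(r[["mean"]], "/", r[["sd"]], "/", r[["weight"]])),
        collapse = ";")
    } else params$type
    for (k in oracleK) {
      bf <- bruteForceThresholds(h, k)
      rows[[length(rows) + 1L]] <- data.frame(
        fixture = name, type = params$type, seed = fseed,
        params = paramStr, k = k,
        t_star = paste(thresholdValues(bf$thresholds), collapse = ";"),
        J_star = bf$J)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
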