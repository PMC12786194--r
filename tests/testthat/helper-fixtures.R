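# Shared fixtures, all generated in code under fixed seeds.

# Two-point histogram: all mass at levels 50 and 200; single-threshold
# optimum is J = 5625 on the plateau t in [50, 199].
twoPointHist <- function() {
  p <- numeric(256)
  p[c(51, 201)] <- 0.5
  grayHistogram(p, 2)
}

# Random normalized histogram over L bins.
randomHist <- function(L = 256, seed = 1) {
  set.seed(seed)
  p <- stats::runif(L)
  grayHistogram(p / sum(p), 1000L)
}

# Seeded trimodal histogram on 32 bins (three overlapping Gaussians).
trimodalHist32 <- function(seed = 11) {
  set.seed(seed)
  x <- c(rnorm(2000, 6, 1.6), rnorm(2500, 16, 2.2), rnorm(1500, 26, 1.4))
  x <- pmin(pmax(round(x), 0), 31)
  grayHistogram(tabulate(x + 1L, 32) / length(x), length(x))
}

# The seeded image pairs whose SSIM/FSIM values were frozen against
# reference implementations (uniform-noise pair and blob/reconstruction).
frozenMetricPairAB <- function() {
  set.seed(42)
  a <- matrix(as.integer(round(runif(64 * 64, 0, 255))), 64, 64)
  b <- pmin(pmax(a + matrix(as.integer(round(rnorm(64 * 64, 0, 12))), 64, 64),
                 0L), 255L)
  list(a = a, b = b)
}

frozenMetricPairCD <- function() {
  bl <- makeBlobImage(nBlobs = 4, noiseSd = 8, size = c(96L, 96L), seed = 7)
  h <- computeHistogram(bl$image)
  bf <- bruteForceThresholds(h, 2)
  seg <- applyThresholds(bl$image, bf$thresholds)
  list(a = bl$image, b = reconstruction(seg))
}

# Total histogram variance, computed directly.
histTotalVariance <- function(h) {
  p <- histProbs(h)
  j <- seq_along(p) - 1
  mu <- sum(j * p)
  sum(p * (j - mu)^2)
}
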