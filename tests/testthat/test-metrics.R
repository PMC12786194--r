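test_that("psnr follows its closed forms and cap", {
  x <- matrix(runif(16 * 16, 0, 255), 16)
  expect_equal(psnr(x, x), 100)
  expect_equal(psnr(matrix(0, 8, 8), matrix(255, 8, 8)), 0)
  # straight-formula oracle
  set.seed(14)
  a <- matrix(sample(0:255, 256, TRUE), 16)
  b <- matrix(sample(0:255, 256, TRUE), 16)
  expect_equal(psnr(a, b), 10 * log10(255^2 / mean((a - b)^2)),
               tolerance = 1e-10)
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("psnr strictly decreases with added noise amplitude", {
  set.seed(15)
  ref <- matrix(sample(40:215, 64 * 64, TRUE), 64)
  noise <- matrix(rnorm(64 * 64), 64)
  vals <- vapply(c(5, 15, 40), function(s)
    psnr(ref, pmin(pmax(ref + s * noise, 0), 255)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ssim identity, zero-variance closed form, and reference values", {
  set.seed(16)
  x <- matrix(runif(32 * 32, 0, 255), 32)
  expect_equal(ssim(x, x), 1.0)

  C1 <- (0.01 * 255)^2
  expect_equal(ssim(matrix(100, 16, 16), matrix(150, 16, 16)),
               (2 * 100 * 150 + C1) / (100^2 + 150^2 + C1),
               tolerance = 1e-12)

  # frozen against skimage structural_similarity (gaussian_weights,
  # sigma 1.5, no sample covariance, data_range 255)
  ab <- frozenMetricPairAB()
  expect_equal(ssim(ab$a, ab$b), 0.9868131402, tolerance = 1e-6)
  cd <- frozenMetricPairCD()
  expect_equal(ssim(cd$a, cd$b), 0.8693768553, tolerance = 1e-6)

  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("fsim identity, symmetry, bounds, and reference values", {
  set.seed(17)
  x <- matrix(runif(48 * 48, 0, 255), 48)
  y <- pmin(pmax(x + matrix(rnorm(48 * 48, 0, 20), 48), 0), 255)
  expect_equal(fsim(x, x), 1.0)
  expect_equal(fsim(x, y), fsim(y, x), tolerance = 1e-12)
  v <- fsim(x, y)
  expect_true(v >= 0 && v <= 1)

  # frozen against an independent port of the published algorithm
  ab <- frozenMetricPairAB()
  expect_equal(fsim(ab$a, ab$b), 0.9872577574, tolerance = 1e-3)
  cd <- frozenMetricPairCD()
  expect_equal(fsim(cd$a, cd$b), 0.8701695683, tolerance = 1e-3)

  # constant pair: documented fallback, not NaN
  expect_equal(fsim(matrix(80, 32, 32), matrix(80, 32, 32)), 1.0)
  expect_false(is.na(fsim(matrix(80, 32, 32), matrix(120, 32, 32))))
  expect_error(fsim(matrix(0, 16, 16), matrix(0, 16, 16)), "small")
})

test_that("overlap metrics count correctly on hand-built masks", {
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE
  id <- overlapMetrics(m, m)
  expect_equal(id, list(dice = 1, jaccard = 1, hausdorff = 0))

  other <- matrix(FALSE, 6, 6); other[5:6, 5:6] <- TRUE
  dj <- overlapMetrics(m, other)
  expect_equal(dj$dice, 0)
  expect_equal(dj$jaccard, 0)

  shifted <- matrix(FALSE, 6, 6); shifted[2:3, 3:4] <- TRUE
  ov <- overlapMetrics(m, shifted)
  expect_equal(ov$dice, 0.5)
  expect_equal(ov$jaccard, 1 / 3)
  expect_equal(ov$hausdorff, 1)

  # both empty: perfect agreement by convention; one empty: 0 and NA
  e <- matrix(FALSE, 6, 6)
  expect_equal(overlapMetrics(e, e), list(dice = 1, jaccard = 1, hausdorff = 0))
  expect_warning(one <- overlapMetrics(m, e), "empty")
  expect_equal(one$dice, 0)
  expect_true(is.na(one$hausdorff))
})

test_that("dice and jaccard satisfy their algebraic identity", {
  set.seed(18)
  for (i in 1:50) {
    a <- matrix(runif(100) < runif(1, 0.2, 0.8), 10)
    b <- matrix(runif(100) < runif(1, 0.2, 0.8), 10)
    ov <- overlapMetrics(a, b)
    expect_equal(ov$dice, 2 * ov$jaccard / (1 + ov$jaccard), tolerance = 1e-12)
  }
})

test_that("hausdorff is symmetric and satisfies the triangle inequality", {
  mk <- function(r, c) { m <- matrix(FALSE, 12, 12); m[r, c] <- TRUE; m }
  A <- mk(2:4, 2:4); B <- mk(6:8, 5:7); C <- mk(9:11, 9:11)
  hAB <- overlapMetrics(A, B)$hausdorff
  hBA <- overlapMetrics(B, A)$hausdorff
  hBC <- overlapMetrics(B, C)$hausdorff
  hAC <- overlapMetrics(A, C)$hausdorff
  expect_equal(hAB, hBA)
  expect_lte(hAC, hAB + hBC + 1e-12)
})

test_that("correlation diagnostics match direct formulas and handle ties", {
  set.seed(19)
  img <- matrix(sample(0:255, 40 * 40, TRUE), 40)
  # identity and affine invariance
  cd <- correlationDiagnostics(img, img)
  expect_equal(cd$pearson_r, 1)
  expect_equal(cd$spearman_rho, 1)
  aff <- 2 * img + 3
  expect_equal(correlationDiagnostics(img, aff)$pearson_r, 1)

  # direct moment/rank oracle on a segmented image
  seg <- reconstruction(applyThresholds(img, c(85, 170)))
  cd2 <- correlationDiagnostics(img, seg)
  expect_equal(cd2$pearson_r, cor(as.numeric(img), as.numeric(seg)),
               tolerance = 1e-10)
  expect_equal(cd2$spearman_rho,
               cor(rank(as.numeric(img)), rank(as.numeric(seg))),
               tolerance = 1e-10)
  left <- as.numeric(seg[, -ncol(seg)]); right <- as.numeric(seg[, -1])
  expect_equal(cd2$neighbor_pearson, cor(left, right), tolerance = 1e-10)

  # constant input: NA with warning (one per undefined correlation)
  ws <- capture_warnings(cc <- correlationDiagnostics(img, matrix(5, 40, 40)))
  expect_true(all(grepl("constant", ws)))
  expect_true(is.na(cc$pearson_r))
  expect_true(is.na(cc$neighbor_spearman))
})

test_that("metricReport assembles all requested metrics", {
  cd <- frozenMetricPairCD()
  bl <- makeBlobImage(nBlobs = 4, noiseSd = 8, size = c(96L, 96L), seed = 7)
  rep <- metricReport(cd$a, cd$b, maskPred = cd$b > 128,
                      maskRef = bl$foregroundMask)
  expect_true(all(c("psnr", "ssim", "fsim", "pearson_r", "dice", "jaccard",
                    "hausdorff") %in% names(rep)))
  expect_equal(nrow(rep), 1L)
  expect_gt(rep$dice, 0.9)   # reconstruction recovers the blobs
})
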