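test_that("computeHistogram tallies pixels exactly", {
  img <- matrix(7L, 4, 4)
  h <- computeHistogram(img)
  expect_equal(histProbs(h)[8], 1.0)
  expect_equal(sum(histProbs(h)), 1.0)
  expect_equal(totalPixels(h), 16L)

  h2 <- computeHistogram(matrix(c(0L, 255L), 1, 2))
  expect_equal(histProbs(h2)[c(1, 256)], c(0.5, 0.5))

  # seeded random image against an independent per-bin tally
  set.seed(5)
  img3 <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  h3 <- computeHistogram(img3)
  tally <- vapply(0:255, function(v) sum(img3 == v), numeric(1)) / 64
  expect_identical(histProbs(h3), tally)
})

test_that("computeHistogram rejects bad input", {
  expect_error(computeHistogram(matrix(numeric(0), 0, 0)), "empty")
  expect_error(computeHistogram(matrix(c(1, 300), 1, 2)), "outside gray range")
  expect_error(computeHistogram(matrix(-1, 1, 1)), "outside gray range")
})

test_that("otsuObjective matches closed forms and an independent evaluator", {
  # point mass: one nonempty class, J = 0
  p <- numeric(256); p[101] <- 1
  expect_equal(objectiveValue(otsuObjective(grayHistogram(p, 10), c(50, 150))), 0)

  # two-point closed form: mu_T = 125, J = 2 * 0.5 * 75^2
  ob <- otsuObjective(twoPointHist(), 100)
  expect_equal(objectiveValue(ob), 5625)
  expect_equal(ob@globalMean, 125)

  # seeded 16-bin histogram vs a straight-from-definition evaluator
  h <- randomHist(16, seed = 9)
  straight <- function(p, tf) {
    L <- length(p); j <- 0:(L - 1)
    muT <- sum(j * p)
    bounds <- c(-1, tf, L - 1)            # class i: bounds[i] < j <= bounds[i+1]
    J <- 0
    for (i in seq_len(length(tf) + 1)) {
      sel <- j > bounds[i] & j <= bounds[i + 1]
      w <- sum(p[sel])
      if (w > 0) J <- J + w * (sum(j[sel] * p[sel]) / w - muT)^2
    }
    J
  }
  ob2 <- otsuObjective(h, thresholdSet(c(4, 9), 16))
  expect_equal(objectiveValue(ob2), straight(histProbs(h), c(4L, 9L)))
})

test_that("variance decomposition holds for random histogram/threshold pairs", {
  set.seed(21)
  for (i in 1:50) {
    L <- sample(c(16, 64, 256), 1)
    h <- randomHist(L, seed = i)
    k <- sample(1:5, 1)
    ts <- thresholdSet(runif(k, 1, L - 1), L)
    ob <- otsuObjective(h, ts)
    tot <- histTotalVariance(h)
    expect_equal(objectiveValue(ob) + ob@withinClassVariance, tot,
                 tolerance = 1e-9)
    expect_equal(sum(ob@classProbs), 1, tolerance = 1e-9)
    expect_true(all(ob@classProbs >= 0))
  }
})

test_that("objective is piecewise-constant and permutation-safe", {
  h <- randomHist(256, seed = 2)
  # same floors => bit-identical J
  j1 <- objectiveValue(otsuObjective(h, thresholdSet(c(80.1, 160.9))))
  j2 <- objectiveValue(otsuObjective(h, thresholdSet(c(80.999, 160.001))))
  expect_identical(j1, j2)
  # shuffling input order never changes J (thresholdSet sorts)
  set.seed(3)
  v <- runif(4, 1, 255)
  j3 <- objectiveValue(otsuObjective(h, thresholdSet(v)))
  j4 <- objectiveValue(otsuObjective(h, thresholdSet(rev(v))))
  j5 <- objectiveValue(otsuObjective(h, thresholdSet(sample(v))))
  expect_identical(j3, j4)
  expect_identical(j3, j5)
})

test_that("brute force finds hand-enumerable optima with lexicographic ties", {
  hu <- grayHistogram(rep(0.25, 4), 16)
  bu <- bruteForceThresholds(hu, 1)
  expect_equal(thresholdValues(bu$thresholds), 1)
  expect_equal(bu$J, 1.0)

  # tie plateau [50, 199]: smallest integer wins
  bt <- bruteForceThresholds(twoPointHist(), 1)
  expect_equal(thresholdValues(bt$thresholds), 50)
  expect_equal(bt$J, 5625)

  # full-enumeration cross-check on 32 bins, k = 2
  h <- trimodalHist32()
  bf <- bruteForceThresholds(h, 2)
  cmb <- combn(31, 2)
  Js <- apply(cmb, 2, function(tf)
    objectiveValue(otsuObjective(h, thresholdSet(tf, 32))))
  expect_equal(bf$J, max(Js))
  expect_equal(thresholdValues(bf$thresholds), cmb[, which.max(Js)])
})

test_that("brute force refuses oversized instances and refines monotonically", {
  expect_error(bruteForceThresholds(randomHist(256), 4), "too large")
  h <- trimodalHist32()
  Jk <- vapply(1:4, function(k) bruteForceThresholds(h, k)$J, numeric(1))
  expect_true(all(diff(Jk) >= 0))
})

test_that("rebinHistogram preserves mass and divides levels", {
  h <- randomHist(256, seed = 4)
  h32 <- rebinHistogram(h, 32)
  expect_equal(nLevels(h32), 32L)
  expect_equal(sum(histProbs(h32)), 1, tolerance = 1e-12)
  expect_error(rebinHistogram(h, 33), "divide")
})

test_that("histogram and threshold validity is enforced", {
  expect_error(grayHistogram(c(0.5, 0.6), 10), "sum to 1")
  expect_error(grayHistogram(c(-0.1, 1.1), 10), ">= 0")
  expect_error(new("ThresholdSet", values = c(5, 3), nLevels = 256L), "sorted")
  # constructor canonicalizes instead
  expect_equal(thresholdValues(thresholdSet(c(300, -5))), c(1, 255))
})
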