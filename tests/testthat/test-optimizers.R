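test_that("phase split follows the floor rule", {
  expect_equal(phaseSplit(hybridConfig(switchRatio = 0.6,
                                       totalIterations = 100L)),
               c(scso = 60L, woa = 40L))
  expect_equal(phaseSplit(hybridConfig(switchRatio = 0, totalIterations = 50L)),
               c(scso = 0L, woa = 50L))
  expect_equal(phaseSplit(hybridConfig(switchRatio = 1, totalIterations = 50L)),
               c(scso = 50L, woa = 0L))
  expect_equal(phaseSplit(hybridConfig(switchRatio = 0.45,
                                       totalIterations = 7L)),
               c(scso = 3L, woa = 4L))
})

test_that("sand-cat step reproduces its update rules under fixed draws", {
  cfg <- hybridConfig()
  pos <- matrix(c(10, 20), 1, 2)
  best <- c(50, 60)
  b <- c(1, 255)

  # directional-hunting rule with zero draws: identity
  st <- scsoUpdate(pos, best, cfg, b, draws = list(branch = TRUE, r1 = 0,
                                                   r2 = 0, r3 = 0))
  expect_equal(st$positions, pos)

  # attraction rule with r3 = 1: lands exactly on the best
  st <- scsoUpdate(pos, best, cfg, b, draws = list(branch = FALSE, r1 = 0,
                                                   r2 = 0, r3 = 1))
  expect_equal(st$positions[1, ], best)

  # replay: hand-trace X + r1*best - r2*X
  d <- list(branch = TRUE, r1 = 0.3, r2 = 0.7, r3 = 0)
  st <- scsoUpdate(pos, best, cfg, b, draws = d)
  expect_equal(st$positions[1, ], pos[1, ] + 0.3 * best - 0.7 * pos[1, ])

  # mean-attraction mode hand-trace
  cfgM <- hybridConfig(scsoUpdateMode = "mean_attraction")
  pos2 <- rbind(c(10, 20), c(30, 40))
  mu <- colMeans(pos2)
  d2 <- list(branch = c(TRUE, TRUE), r1 = c(0.2, 0.4), r2 = c(0.5, 0.1),
             r3 = c(0, 0))
  st2 <- scsoUpdate(pos2, best, cfgM, b, draws = d2)
  expect_equal(st2$positions[1, ],
               pos2[1, ] + 0.2 * (mu - pos2[1, ]) + 0.5 * (best - pos2[1, ]))
  expect_equal(st2$positions[2, ],
               pos2[2, ] + 0.4 * (mu - pos2[2, ]) + 0.1 * (best - pos2[2, ]))
})

test_that("orientation angle advances by its recurrence and can gate the step", {
  cfg <- hybridConfig(thetaAmplitude = 0.5, thetaFrequency = 0.5,
                      thetaPhase = 0.1)
  pos <- matrix(c(10, 20), 1, 2)
  st <- scsoUpdate(pos, c(50, 60), cfg, c(1, 255), t = 3, theta = 1.0,
                   draws = list(branch = TRUE, r1 = 0, r2 = 0, r3 = 0))
  expect_equal(st$theta, 1.0 + 0.5 * sin(0.5 * 3 + 0.1))

  # with coupling enabled, r3 is modulated by |sin(theta)|
  cfgT <- hybridConfig(scsoTheta = TRUE)
  th <- pi / 6   # |sin| = 0.5
  stT <- scsoUpdate(pos, c(50, 60), cfgT, c(1, 255), theta = th,
                    draws = list(branch = FALSE, r1 = 0, r2 = 0, r3 = 1))
  expect_equal(stT$positions[1, ], pos[1, ] + 0.5 * (c(50, 60) - pos[1, ]))
})

test_that("whale step collapses onto the best in its degenerate cases", {
  cfg <- hybridConfig()
  pos <- matrix(c(10, 20), 1, 2)
  best <- c(50, 60)
  b <- c(1, 255)

  # encircling with A = 0 (rA = 0.5 at any a): X = best exactly
  st <- woaUpdate(pos, best, a = 1.6, cfg, b,
                  draws = list(p = 0.1, rA = 0.5, rC = 0.5, l = 0,
                               randIdx = 1L))
  expect_equal(st$positions[1, ], best)

  # spiral with agent already at best: stays at best for any l
  atBest <- matrix(best, 1, 2)
  for (l in c(-0.8, 0, 0.9)) {
    st <- woaUpdate(atBest, best, a = 1, cfg, b,
                    draws = list(p = 0.9, rA = 0.2, rC = 0.2, l = l,
                                 randIdx = 1L))
    expect_equal(st$positions[1, ], best)
  }

  # spiral hand-trace: D' * exp(b l) * cos(2 pi l) + best
  st <- woaUpdate(pos, best, a = 1, cfg, b,
                  draws = list(p = 0.9, rA = 0.2, rC = 0.2, l = 0.25,
                               randIdx = 1L))
  expect_equal(st$positions[1, ],
               abs(best - pos[1, ]) * exp(0.25) * cos(pi / 2) + best)

  # pseudocode mode: search-for-prey around a random agent when |A| >= 1
  cfgP <- hybridConfig(woaBranchMode = "pseudocode")
  pos2 <- rbind(c(10, 20), c(100, 120))
  st <- woaUpdate(pos2, best, a = 2, cfgP, b,
                  draws = list(p = c(0.9, 0.9), rA = c(1, 1), rC = c(1, 1),
                               l = c(0, 0), randIdx = c(2L, 1L)))
  # A = 2, C = 2: X_i = X_rand - 2 * |2 X_rand - X_i|, then clamped
  expected1 <- pos2[2, ] - 2 * abs(2 * pos2[2, ] - pos2[1, ])
  expect_equal(st$positions[1, ], pmin(pmax(expected1, 1), 255))
})

test_that("every optimizer spends exactly N(Tmax+1) evaluations", {
  h <- trimodalHist32()
  for (cfg in list(hybridConfig(populationSize = 8L, totalIterations = 13L),
                   hybridConfig(populationSize = 5L, totalIterations = 9L,
                                switchRatio = 0),
                   hybridConfig(populationSize = 5L, totalIterations = 9L,
                                switchRatio = 1))) {
    fit <- runSCSOWOA(h, 2, cfg, seed = 4)
    expect_identical(nEvaluations(fit),
                     cfg@populationSize * (cfg@totalIterations + 1L))
  }
  cfg <- hybridConfig(populationSize = 6L, totalIterations = 11L)
  for (alg in c("pso", "gwo", "woa", "scso")) {
    fit <- runBaseline(alg, h, 2, cfg, seed = 4)
    expect_identical(nEvaluations(fit), 6L * 12L)
  }
})

test_that("best fitness is elitist, including across the phase handoff", {
  h <- trimodalHist32()
  cfg <- hybridConfig(populationSize = 10L, totalIterations = 40L)
  for (seed in 1:5) {
    fit <- runSCSOWOA(h, 3, cfg, seed = seed)
    tr <- traceFrame(fit)
    expect_true(all(diff(tr$best_fitness) >= 0))
    expect_equal(unique(tr$phase), c("SCSO", "WOA"))
    # handoff boundary: first WOA best is >= last SCSO best
    lastScso <- max(which(tr$phase == "SCSO"))
    expect_gte(tr$best_fitness[lastScso + 1], tr$best_fitness[lastScso])
  }
  for (alg in c("pso", "gwo", "woa", "scso")) {
    fit <- runBaseline(alg, h, 3, cfg, seed = 2)
    expect_true(all(diff(traceFrame(fit)$best_fitness) >= 0))
  }
})

test_that("runs are bit-reproducible from their seed", {
  h <- trimodalHist32()
  cfg <- hybridConfig(populationSize = 10L, totalIterations = 30L)
  f1 <- runSCSOWOA(h, 3, cfg, seed = 99)
  f2 <- runSCSOWOA(h, 3, cfg, seed = 99)
  expect_identical(thresholdValues(f1), thresholdValues(f2))
  expect_identical(traceFrame(f1), traceFrame(f2))
  f3 <- runSCSOWOA(h, 3, cfg, seed = 100)
  expect_false(identical(thresholdValues(f1), thresholdValues(f3)))
  # the caller's RNG state is left untouched
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(runSCSOWOA(h, 2, cfg, seed = 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("positions respect the search bounds after every iteration", {
  h <- twoPointHist()   # plateau landscape pushes agents around freely
  cfg <- hybridConfig(populationSize = 6L, totalIterations = 20L,
                      logDraws = TRUE)
  fit <- runSCSOWOA(h, 2, cfg, seed = 3)
  v <- thresholdValues(fit)
  expect_true(all(v >= 1 & v <= 255))
})

test_that("frozen PSO dynamics keep the initialization best", {
  h <- trimodalHist32()
  cfg <- hybridConfig(populationSize = 12L, totalIterations = 15L)
  fit <- runBaseline("pso", h, 2, cfg, seed = 5,
                     psoInertia = 0, psoCognitive = 0, psoSocial = 0)
  tr <- traceFrame(fit)
  expect_equal(length(unique(tr$best_fitness)), 1L)
})

test_that("the hybrid matches the exhaustive optimum on a plateau landscape", {
  h <- twoPointHist()
  for (seed in c(1, 17, 123)) {
    fit <- runSCSOWOA(h, 1, seed = seed)
    expect_equal(objectiveValue(fit), 5625)
  }
  fitW <- runBaseline("woa", h, 1, seed = 1)
  expect_equal(objectiveValue(fitW), 5625)
})

test_that("unknown baseline names are rejected", {
  expect_error(runBaseline("wdrime", trimodalHist32(), 2), "arg")
})
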