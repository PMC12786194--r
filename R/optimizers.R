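#' Configuration of the hybrid two-phase optimizer
#'
#' Holds every tunable of the SCSO exploration / WOA exploitation hybrid and
#' of the baseline optimizers: population size \eqn{N}, iteration budget
#' \eqn{T_{max}}, the switch ratio \eqn{\lambda} that allocates
#' \eqn{T_{SCSO} = \lfloor \lambda T_{max} \rfloor} iterations to the sand
#' cat phase and the remainder to the whale phase, the whale coefficient
#' schedule start \code{a0}, the logarithmic-spiral shape constant \code{b},
#' and the orientation-angle parameters of the sand cat phase.
#'
#' Two documented ambiguities in the method are exposed as modes rather than
#' silently resolved:
#' \describe{
#'   \item{\code{scsoUpdateMode}}{\code{"equation"} (default) uses the
#'     directional-hunting update \eqn{X + r_1 X^* - r_2 X};
#'     \code{"mean_attraction"} uses the mean-position form
#'     \eqn{X + r_1(\bar X - X) + r_2(X^* - X)}.}
#'   \item{\code{woaBranchMode}}{\code{"canonical"} (default) is standard
#'     WOA: a fair coin picks the spiral update, otherwise \eqn{|A|} decides
#'     between encircling the best and searching around a random agent;
#'     \code{"pseudocode"} drops the spiral and branches on \eqn{|A|} alone.}
#' }
#'
#' @param populationSize number of agents N (default 30).
#' @param totalIterations iteration budget Tmax (default 100).
#' @param switchRatio fraction \eqn{\lambda \in [0,1]} of iterations given to
#'   the SCSO phase (default 0.6).
#' @param a0 start of the linearly decreasing whale coefficient a (default 2).
#' @param spiralConstant spiral shape constant b (default 1).
#' @param scsoTheta couple the orientation angle to the SCSO step
#'   (default FALSE: the angle is advanced and recorded but does not affect
#'   movement; when TRUE the attraction draw r3 is modulated by
#'   \eqn{|\sin\theta_i|}).
#' @param thetaAmplitude,thetaFrequency,thetaPhase amplitude \eqn{\alpha},
#'   angular frequency \eqn{\omega} and phase shift \eqn{\phi} of the
#'   orientation recurrence \eqn{\theta_{t+1} = \theta_t +
#'   \alpha\sin(\omega t + \phi)}.
#' @param scsoUpdateMode,woaBranchMode see Details.
#' @param logDraws record every uniform draw in the fit's extras, enabling
#'   step-by-step replay of a run (default FALSE).
#' @return a \code{HybridConfig} object.
#' @examples
#' cfg <- hybridConfig()
#' phaseSplit(cfg)
#' @export
hybridConfig <- function(populationSize = 30L, totalIterations = 100L,
                         switchRatio = 0.6, a0 = 2, spiralConstant = 1,
                         scsoTheta = FALSE, thetaAmplitude = 0.5,
                         thetaFrequency = 0.5, thetaPhase = 0,
                         scsoUpdateMode = c("equation", "mean_attraction"),
                         woaBranchMode = c("canonical", "pseudocode"),
                         logDraws = FALSE) {
  new("HybridConfig",
      populationSize = as.integer(populationSize),
      totalIterations = as.integer(totalIterations),
      switchRatio = as.numeric(switchRatio),
      a0 = as.numeric(a0), spiralConstant = as.numeric(spiralConstant),
      scsoTheta = isTRUE(scsoTheta),
      thetaAmplitude = as.numeric(thetaAmplitude),
      thetaFrequency = as.numeric(thetaFrequency),
      thetaPhase = as.numeric(thetaPhase),
      scsoUpdateMode = match.arg(scsoUpdateMode),
      woaBranchMode = match.arg(woaBranchMode),
      logDraws = isTRUE(logDraws))
}

#' @rdname hybridConfig
#' @export
setClass("HybridConfig",
  representation(populationSize = "integer", totalIterations = "integer",
                 switchRatio = "numeric", a0 = "numeric",
                 spiralConstant = "numeric", scsoTheta = "logical",
                 thetaAmplitude = "numeric", thetaFrequency = "numeric",
                 thetaPhase = "numeric", scsoUpdateMode = "character",
                 woaBranchMode = "character", logDraws = "logical"),
  validity = function(object) {
    if (object@populationSize < 2L) return("populationSize must be >= 2")
    if (object@totalIterations < 1L) return("totalIterations must be >= 1")
    if (object@switchRatio < 0 || object@switchRatio > 1) {
      return("switchRatio must lie in [0, 1]")
    }
    TRUE
  }
)

setMethod("show", "HybridConfig", function(object) {
  sp <- phaseSplit(object)
  cat("HybridConfig: N =", object@populationSize,
      " Tmax =", object@totalIterations,
      " lambda =", object@switchRatio,
      sprintf(" (SCSO %d / WOA %d)\n", sp[["scso"]], sp[["woa"]]))
  cat("  a0 =", object@a0, " b =", object@spiralConstant,
      " scso:", object@scsoUpdateMode, " woa:", object@woaBranchMode, "\n")
})

#' Iteration split between the two phases
#'
#' \eqn{T_{SCSO} = \lfloor \lambda T_{max} \rfloor}, \eqn{T_{WOA} = T_{max}
#' - T_{SCSO}}. With the defaults (\eqn{\lambda = 0.6}, \eqn{T_{max} = 100})
#' this is 60 exploration and 40 exploitation iterations.
#'
#' @param cfg a \code{HybridConfig}.
#' @return named integer vector with elements \code{scso} and \code{woa}.
#' @export
phaseSplit <- function(cfg) {
  stopifnot(is(cfg, "HybridConfig"))
  ts <- as.integer(floor(cfg@switchRatio * cfg@totalIterations))
  c(scso = ts, woa = cfg@totalIterations - ts)
}

.clampPositions <- function(x, lower, upper) {
  x[!is.finite(x)] <- upper          # runaway agents are pulled to the bound
  pmin(pmax(x, lower), upper)
}

#' One sand-cat exploration step
#'
#' Moves every agent by one of two stochastic rules, chosen per agent by a
#' fair coin (mode \code{"equation"}): the directional hunting update
#' \eqn{X(t+1) = X + r_1 X^* - r_2 X} or the difference attraction
#' \eqn{X(t+1) = X + r_3 (X^* - X)}, with \eqn{r_1, r_2, r_3 \sim U(0,1)}
#' drawn per agent. In mode \code{"mean_attraction"} all agents use
#' \eqn{X(t+1) = X + r_1(\bar X - X) + r_2(X^* - X)} with \eqn{\bar X} the
#' population mean position. Positions are clamped to the bounds. The
#' orientation angles advance by \eqn{\theta_{t+1} = \theta_t +
#' \alpha \sin(\omega t + \phi)}; when \code{scsoTheta} is enabled the
#' attraction draw \eqn{r_3} is modulated by \eqn{|\sin\theta_i|}.
#'
#' Fixing \code{draws} replays a step deterministically, which is how the
#' step is unit-tested against a hand-traced application of the update rules.
#'
#' @param positions N x d matrix of agent positions.
#' @param best length-d best-so-far position.
#' @param cfg a \code{HybridConfig}.
#' @param bounds length-2 numeric, lower and upper position bounds.
#' @param t iteration index (drives the orientation recurrence).
#' @param theta length-N orientation angles (default all 0).
#' @param draws optional list with elements \code{branch} (logical N: TRUE =
#'   directional-hunting rule), \code{r1}, \code{r2}, \code{r3} (numeric N);
#'   when NULL, fresh uniform draws are made.
#' @return list with \code{positions}, \code{theta}, \code{draws}.
#' @examples
#' p <- matrix(c(10, 20), 1, 2)
#' st <- scsoUpdate(p, best = c(50, 60), hybridConfig(), bounds = c(1, 255),
#'                  t = 1, draws = list(branch = FALSE, r1 = 0, r2 = 0, r3 = 1))
#' st$positions   # full attraction lands on the best
#' @export
scsoUpdate <- function(positions, best, cfg, bounds, t = 1L,
                       theta = NULL, draws = NULL) {
  N <- nrow(positions)
  if (is.null(theta)) theta <- numeric(N)
  if (is.null(draws)) {
    draws <- list(branch = stats::runif(N) < 0.5, r1 = stats::runif(N),
                  r2 = stats::runif(N), r3 = stats::runif(N))
  }
  newpos <- positions
  if (cfg@scsoUpdateMode == "mean_attraction") {
    mu <- colMeans(positions)
    for (i in seq_len(N)) {
      newpos[i, ] <- positions[i, ] +
        draws$r1[i] * (mu - positions[i, ]) +
        draws$r2[i] * (best - positions[i, ])
    }
  } else {
    for (i in seq_len(N)) {
      if (draws$branch[i]) {
        newpos[i, ] <- positions[i, ] +
          draws$r1[i] * best - draws$r2[i] * positions[i, ]
      } else {
        r3 <- draws$r3[i]
        if (cfg@scsoTheta) r3 <- r3 * abs(sin(theta[i]))
        newpos[i, ] <- positions[i, ] + r3 * (best - positions[i, ])
      }
    }
  }
  theta <- theta + cfg@thetaAmplitude *
    sin(cfg@thetaFrequency * t + cfg@thetaPhase)
  list(positions = .clampPositions(newpos, bounds[1], bounds[2]),
       theta = theta, draws = draws)
}

#' One whale exploitation step
#'
#' In mode \code{"canonical"} each agent draws \eqn{p \sim U(0,1)}: with
#' \eqn{p < 0.5} it computes \eqn{A = 2 a r - a}, \eqn{C = 2 r'} and either
#' encircles the best (\eqn{X = X^* - A |C X^* - X|}, when \eqn{|A| < 1}) or
#' searches around a random other agent (\eqn{|A| \ge 1}); with \eqn{p \ge
#' 0.5} it performs the logarithmic-spiral move \eqn{X = D' e^{bl}
#' \cos(2\pi l) + X^*} with \eqn{D' = |X^* - X|}, \eqn{l \sim U(-1,1)}. In
#' mode \code{"pseudocode"} a single shared draw \eqn{r} forms both A and C
#' and the \eqn{|A|} branch alone decides encircle vs. search (no spiral).
#'
#' @param positions N x d matrix of agent positions.
#' @param best length-d best-so-far position.
#' @param a current value of the linearly decreasing coefficient.
#' @param cfg a \code{HybridConfig}.
#' @param bounds length-2 numeric position bounds.
#' @param draws optional list with \code{p}, \code{rA}, \code{rC}, \code{l}
#'   (numeric N) and \code{randIdx} (integer N, partner for the search
#'   branch); when NULL, fresh draws are made.
#' @return list with \code{positions} and \code{draws}.
#' @examples
#' p <- matrix(c(10, 20), 1, 2)
#' st <- woaUpdate(p, best = c(50, 60), a = 1, hybridConfig(),
#'                 bounds = c(1, 255),
#'                 draws = list(p = 0.2, rA = 0.5, rC = 0.5, l = 0, randIdx = 1L))
#' st$positions   # A = 0: encircling collapses onto the best
#' @export
woaUpdate <- function(positions, best, a, cfg, bounds, draws = NULL) {
  N <- nrow(positions)
  if (is.null(draws)) {
    draws <- list(p = stats::runif(N), rA = stats::runif(N),
                  rC = stats::runif(N), l = stats::runif(N, -1, 1),
                  randIdx = sample.int(N, N, replace = TRUE))
    if (cfg@woaBranchMode == "pseudocode") draws$rC <- draws$rA
  }
  b <- cfg@spiralConstant
  newpos <- positions
  for (i in seq_len(N)) {
    A <- 2 * a * draws$rA[i] - a
    C <- 2 * draws$rC[i]
    if (cfg@woaBranchMode == "canonical" && draws$p[i] >= 0.5) {
      Dp <- abs(best - positions[i, ])
      l <- draws$l[i]
      newpos[i, ] <- Dp * exp(b * l) * cos(2 * pi * l) + best
    } else if (abs(A) < 1) {
      D <- abs(C * best - positions[i, ])
      newpos[i, ] <- best - A * D
    } else {
      xr <- positions[draws$randIdx[i], ]
      D <- abs(C * xr - positions[i, ])
      newpos[i, ] <- xr - A * D
    }
  }
  list(positions = .clampPositions(newpos, bounds[1], bounds[2]),
       draws = draws)
}

## Shared run loop: init population (N evals), then Tmax iterations of
## step() followed by evaluation of all agents and a strict-improvement
## best update. Guarantees the N*(Tmax+1) evaluation budget and elitism.
.runSwarm <- function(cache, k, cfg, seed, stepFun, phases, algorithm,
                      init = NULL) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  N <- cfg@populationSize
  Tmax <- cfg@totalIterations
  lower <- 1; upper <- cache$L - 1
  X <- matrix(stats::runif(N * k, lower, upper), N, k)
  fit <- .evalPopulation(cache, X)
  nEvals <- N
  bi <- which.max(fit)
  best <- X[bi, ]; bestFit <- fit[bi]
  bestTrace <- numeric(Tmax)
  extras <- list(draws = if (cfg@logDraws) vector("list", Tmax) else NULL)
  state <- if (is.null(init)) list() else init(X, fit, best)
  for (t in seq_len(Tmax)) {
    st <- stepFun(X, fit, best, bestFit, t, state)
    X <- .clampPositions(st$positions, lower, upper)
    state <- st$state
    fit <- .evalPopulation(cache, X)
    if (anyNA(fit)) stop("NaN fitness encountered")
    nEvals <- nEvals + N
    bi <- which.max(fit)
    if (fit[bi] > bestFit) { bestFit <- fit[bi]; best <- X[bi, ] }
    if (!is.null(st$postEval)) {
      state <- st$postEval(X, fit, state)
    }
    bestTrace[t] <- bestFit
    if (cfg@logDraws) extras$draws[[t]] <- st$draws
  }
  trace <- new("FitnessTrace", bestFitness = bestTrace, phase = phases,
               nEvals = as.integer(nEvals))
  new("SwarmFit",
      thresholds = thresholdSet(best, cache$L),
      J = bestFit, trace = trace, algorithm = algorithm,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      extras = extras)
}

#' Run the adaptive hybrid SCSO-WOA optimizer
#'
#' Maximizes the Otsu between-class variance over \code{k} thresholds in two
#' phases: \eqn{T_{SCSO} = \lfloor\lambda T_{max}\rfloor} iterations of sand
#' cat exploration, then the incumbent best is carried over as one agent of
#' a freshly randomized whale population which refines it for the remaining
#' \eqn{T_{WOA}} iterations. The whale coefficient decreases linearly within
#' its phase, \eqn{a = a_0 - t a_0 / T_{WOA}}, reaching 0 at the final
#' iteration. With \eqn{\lambda = 0} the exploration phase reduces to the
#' random initialization, whose best seeds the whale phase; with
#' \eqn{\lambda = 1} the whale phase is skipped.
#'
#' The run spends exactly \eqn{N (T_{max} + 1)} objective evaluations
#' (initialization plus one per agent per iteration; the fresh whale agents
#' are first evaluated after their first move) and is bit-reproducible from
#' \code{seed}.
#'
#' @param hist a \linkS4class{GrayHistogram}.
#' @param k number of thresholds.
#' @param cfg a \code{HybridConfig}.
#' @param seed integer RNG seed for the run (the caller's RNG state is
#'   preserved).
#' @return a \linkS4class{SwarmFit}.
#' @examples
#' p <- numeric(256); p[c(51, 201)] <- 0.5
#' fit <- runSCSOWOA(grayHistogram(p, 2), k = 1, seed = 1)
#' objectiveValue(fit)   # 5625: the exhaustive optimum
#' @export
runSCSOWOA <- function(hist, k, cfg = hybridConfig(), seed = NULL) {
  stopifnot(is(hist, "GrayHistogram"), k >= 1, is(cfg, "HybridConfig"))
  k <- as.integer(k)
  cache <- .histCache(hist@probs)
  sp <- phaseSplit(cfg)
  Tscso <- sp[["scso"]]; Twoa <- sp[["woa"]]
  phases <- c(rep("SCSO", Tscso), rep("WOA", Twoa))
  lower <- 1; upper <- cache$L - 1

  stepFun <- function(X, fit, best, bestFit, t, state) {
    if (t <= Tscso) {
      st <- scsoUpdate(X, best, cfg, c(lower, upper), t = t,
                       theta = state$theta)
      state$theta <- st$theta
      list(positions = st$positions, state = state, draws = st$draws)
    } else {
      tw <- t - Tscso
      if (tw == 1L) {
        # phase handoff: fresh random whales, agent 1 carries the incumbent
        X <- matrix(stats::runif(nrow(X) * ncol(X), lower, upper),
                    nrow(X), ncol(X))
        X[1, ] <- best
      }
      a <- cfg@a0 - tw * cfg@a0 / Twoa
      st <- woaUpdate(X, best, a, cfg, c(lower, upper))
      list(positions = st$positions, state = state, draws = st$draws)
    }
  }
  .runSwarm(cache, k, cfg, seed, stepFun, phases, "scsowoa",
            init = function(X, fit, best) list(theta = numeric(nrow(X))))
}

#' Run a baseline optimizer
#'
#' Canonical single-phase metaheuristics under the same interface, bounds,
#' evaluation budget and elitism contract as [runSCSOWOA()]:
#' \describe{
#'   \item{\code{"scso"}}{the sand cat update run for all Tmax iterations.}
#'   \item{\code{"woa"}}{standard whale optimization, \eqn{a} decreasing
#'     linearly from \code{a0} to 0 over Tmax.}
#'   \item{\code{"pso"}}{particle swarm with inertia w = 0.5 and cognitive /
#'     social coefficients c1 = c2 = 2, zero initial velocities.}
#'   \item{\code{"gwo"}}{grey wolf optimizer, \eqn{a} decreasing linearly
#'     from 2 to 0, positions updated toward the mean of the three
#'     leader-attraction terms.}
#' }
#'
#' @param name one of \code{"pso"}, \code{"gwo"}, \code{"woa"}, \code{"scso"}.
#' @param hist a \linkS4class{GrayHistogram}.
#' @param k number of thresholds.
#' @param cfg a \code{HybridConfig} (N, Tmax, a0, b and mode switches apply;
#'   the switch ratio is ignored).
#' @param seed integer RNG seed.
#' @param psoInertia,psoCognitive,psoSocial PSO coefficients (defaults 0.5,
#'   2, 2).
#' @return a \linkS4class{SwarmFit}.
#' @export
runBaseline <- function(name, hist, k, cfg = hybridConfig(), seed = NULL,
                        psoInertia = 0.5, psoCognitive = 2, psoSocial = 2) {
  stopifnot(is(hist, "GrayHistogram"), k >= 1, is(cfg, "HybridConfig"))
  name <- match.arg(name, c("pso", "gwo", "woa", "scso"))
  k <- as.integer(k)
  cache <- .histCache(hist@probs)
  Tmax <- cfg@totalIterations
  lower <- 1; upper <- cache$L - 1
  phases <- rep(toupper(name), Tmax)

  stepFun <- switch(name,
    scso = function(X, fit, best, bestFit, t, state) {
      st <- scsoUpdate(X, best, cfg, c(lower, upper), t = t,
                       theta = state$theta)
      state$theta <- st$theta
      list(positions = st$positions, state = state, draws = st$draws)
    },
    woa = function(X, fit, best, bestFit, t, state) {
      a <- cfg@a0 - t * cfg@a0 / Tmax
      st <- woaUpdate(X, best, a, cfg, c(lower, upper))
      list(positions = st$positions, state = state, draws = st$draws)
    },
    pso = function(X, fit, best, bestFit, t, state) {
      N <- nrow(X); d <- ncol(X)
      r1 <- matrix(stats::runif(N * d), N, d)
      r2 <- matrix(stats::runif(N * d), N, d)
      G <- matrix(best, N, d, byrow = TRUE)
      V <- psoInertia * state$V +
        psoCognitive * r1 * (state$pbest - X) +
        psoSocial * r2 * (G - X)
      Xn <- X + V
      state$V <- V
      list(positions = Xn, state = state,
           draws = list(r1 = r1, r2 = r2),
           postEval = function(X2, fit2, st2) {
             imp <- fit2 > st2$pbestFit
             st2$pbest[imp, ] <- X2[imp, , drop = FALSE]
             st2$pbestFit[imp] <- fit2[imp]
             st2
           })
    },
    gwo = function(X, fit, best, bestFit, t, state) {
      N <- nrow(X); d <- ncol(X)
      a <- 2 - t * 2 / Tmax
      ord <- order(fit, decreasing = TRUE)
      leaders <- X[ord[seq_len(min(3L, N))], , drop = FALSE]
      if (nrow(leaders) < 3L) {
        leaders <- leaders[rep(seq_len(nrow(leaders)), length.out = 3L), ,
                           drop = FALSE]
      }
      Xn <- X
      draws <- list()
      for (i in seq_len(N)) {
        acc <- numeric(d)
        for (m in 1:3) {
          A <- 2 * a * stats::runif(d) - a
          C <- 2 * stats::runif(d)
          Dm <- abs(C * leaders[m, ] - X[i, ])
          acc <- acc + (leaders[m, ] - A * Dm)
        }
        Xn[i, ] <- acc / 3
      }
      list(positions = Xn, state = state, draws = draws)
    })

  init <- switch(name,
    scso = function(X, fit, best) list(theta = numeric(nrow(X))),
    pso = function(X, fit, best) {
      list(V = matrix(0, nrow(X), ncol(X)), pbest = X, pbestFit = fit)
    },
    function(X, fit, best) list())

  .runSwarm(cache, k, cfg, seed, stepFun, phases, name, init = init)
}
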