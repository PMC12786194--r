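## Feature similarity index (FSIM), following the published algorithm:
## phase congruency computed with a 4-scale x 4-orientation log-Gabor bank
## (minimum wavelength 6, scale multiplier 2, sigmaOnf 0.55, angular spread
## sigma pi/4/1.2, noise compensation k = 2), gradient magnitude via the
## Scharr operator, similarity constants T1 = 0.85 (phase congruency) and
## T2 = 160 (gradient).

## MATLAB-convention centered frequency coordinates for an m x n grid,
## already ifftshifted so that element [1,1] is frequency 0.
.freqGrid <- function(m, n) {
  fx <- if (n %% 2 == 0) (seq_len(n) - 1 - n / 2) / n else
    (seq_len(n) - 1 - (n - 1) / 2) / n
  fy <- if (m %% 2 == 0) (seq_len(m) - 1 - m / 2) / m else
    (seq_len(m) - 1 - (m - 1) / 2) / m
  ishift <- function(v) {
    k <- length(v)
    h <- if (k %% 2 == 0) k / 2 else (k - 1) / 2
    c(v[(h + 1):k], v[seq_len(h)])
  }
  fx <- ishift(fx); fy <- ishift(fy)
  list(x = matrix(fx, m, n, byrow = TRUE), y = matrix(fy, m, n))
}

## Phase congruency map (Kovesi's construction, parameterized as in FSIM):
## accumulates local energy (after noise-threshold subtraction) and total
## amplitude over scales and orientations; PC = sum(energy) / sum(amplitude).
.phaseCongruency <- function(im, nscale = 4L, norient = 4L,
                             minWaveLength = 6, mult = 2, sigmaOnf = 0.55,
                             dThetaOnSigma = 1.2, k = 2, epsilon = 1e-4) {
  m <- nrow(im); n <- ncol(im)
  IM <- stats::fft(im)
  g <- .freqGrid(m, n)
  radius <- sqrt(g$x^2 + g$y^2)
  radius[1, 1] <- 1
  theta <- atan2(-g$y, g$x)
  sintheta <- sin(theta); costheta <- cos(theta)
  thetaSigma <- pi / norient / dThetaOnSigma

  # low-pass to kill boundary-induced high frequencies (Kovesi's lowpassfilter)
  lp <- 1 / (1 + (radius / 0.45)^(2 * 15))

  logGabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    wavelength <- minWaveLength * mult^(s - 1)
    fo <- 1 / wavelength
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigmaOnf)^2)) * lp
    lg[1, 1] <- 0
    logGabor[[s]] <- lg
  }

  EnergyAll <- matrix(0, m, n)
  AnAll <- matrix(0, m, n)
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * thetaSigma^2))

    sumE <- matrix(0, m, n); sumO <- matrix(0, m, n)
    sumAn <- matrix(0, m, n)
    EO_e <- vector("list", nscale); EO_o <- vector("list", nscale)
    maxAn <- NULL; tau <- NULL
    for (s in seq_len(nscale)) {
      filt <- logGabor[[s]] * spread
      eo <- stats::fft(IM * filt, inverse = TRUE) / (m * n)
      e <- Re(eo); oo <- Im(eo)
      An <- sqrt(e^2 + oo^2)
      sumAn <- sumAn + An
      sumE <- sumE + e
      sumO <- sumO + oo
      EO_e[[s]] <- e; EO_o[[s]] <- oo
      if (s == 1L) tau <- stats::median(An) / sqrt(log(4))
    }
    XEnergy <- sqrt(sumE^2 + sumO^2) + epsilon
    MeanE <- sumE / XEnergy
    MeanO <- sumO / XEnergy
    Energy <- matrix(0, m, n)
    for (s in seq_len(nscale)) {
      e <- EO_e[[s]]; oo <- EO_o[[s]]
      Energy <- Energy + e * MeanE + oo * MeanO - abs(e * MeanO - oo * MeanE)
    }
    totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noiseMean <- totalTau * sqrt(pi / 2)
    noiseSigma <- totalTau * sqrt((4 - pi) / 2)
    T0 <- (noiseMean + k * noiseSigma) / 1.7
    Energy <- pmax(Energy - T0, 0)
    EnergyAll <- EnergyAll + Energy
    AnAll <- AnAll + sumAn
  }
  EnergyAll / (AnAll + epsilon)
}

.scharrGradient <- function(im) {
  dx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  dy <- t(dx)
  pad <- function(x) {
    m <- nrow(x); n <- ncol(x)
    x2 <- matrix(0, m + 2, n + 2)
    x2[2:(m + 1), 2:(n + 1)] <- x
    # replicate-free zero padding matches 'same' convolution with zeros
    x2
  }
  conv3 <- function(x, kk) {
    m <- nrow(x); n <- ncol(x)
    xp <- pad(x)
    out <- matrix(0, m, n)
    for (i in 1:3) for (j in 1:3) {
      out <- out + kk[i, j] * xp[(3 - i + 1):(3 - i + m), (3 - j + 1):(3 - j + n)]
    }
    out
  }
  gx <- conv3(im, dx); gy <- conv3(im, dy)
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index (FSIM)
#'
#' Full-reference quality metric aligned with the human visual system:
#' combines a phase-congruency similarity term (constant \code{T1}) with a
#' gradient-magnitude similarity term (constant \code{T2}, Scharr
#' gradients), weighting each pixel by the maximum of the two
#' phase-congruency maps:
#' \deqn{FSIM = \frac{\sum_x S_{PC}(x)\, S_G(x)\, PC_m(x)}{\sum_x PC_m(x)}.}
#' Images larger than about 256 pixels on the short side are average-pooled
#' down first, as in the reference algorithm.
#'
#' Degenerate inputs whose phase-congruency weight is everywhere (numerically)
#' zero — e.g. a pair of constant images — fall back to 1 for identical
#' inputs and to the unweighted mean of the similarity map otherwise, never
#' NaN.
#'
#' @param ref,test numeric matrices of equal shape on the 0..255 scale, each
#'   dimension at least 32.
#' @param T1 phase-congruency similarity constant (default 0.85).
#' @param T2 gradient similarity constant (default 160).
#' @return FSIM in [0, 1].
#' @examples
#' set.seed(1); x <- matrix(runif(64 * 64, 0, 255), 64)
#' fsim(x, x)   # 1
#' @export
fsim <- function(ref, test, T1 = 0.85, T2 = 160) {
  if (!all(dim(ref) == dim(test))) stop("shape mismatch")
  if (min(dim(ref)) < 32) stop("image too small for FSIM (min dimension 32)")
  x <- matrix(as.numeric(ref), nrow(ref))
  y <- matrix(as.numeric(test), nrow(test))
  identical_in <- isTRUE(all.equal(x, y, tolerance = 0))

  # reference-algorithm downsampling to ~256 px
  dsf <- max(1L, as.integer(round(min(dim(x)) / 256)))
  if (dsf > 1L) {
    pool <- function(im) {
      m <- (nrow(im) %/% dsf) * dsf; n <- (ncol(im) %/% dsf) * dsf
      im <- im[seq_len(m), seq_len(n), drop = FALSE]
      # dsf x dsf average pooling then subsampling
      rsum <- matrix(0, m %/% dsf, n %/% dsf)
      for (i in seq_len(dsf)) for (j in seq_len(dsf)) {
        rsum <- rsum + im[seq(i, m, by = dsf), seq(j, n, by = dsf)]
      }
      rsum / (dsf * dsf)
    }
    x <- pool(x); y <- pool(y)
  }

  PC1 <- .phaseCongruency(x)
  PC2 <- .phaseCongruency(y)
  G1 <- .scharrGradient(x)
  G2 <- .scharrGradient(y)
  Spc <- (2 * PC1 * PC2 + T1) / (PC1^2 + PC2^2 + T1)
  Sg <- (2 * G1 * G2 + T2) / (G1^2 + G2^2 + T2)
  PCm <- pmax(PC1, PC2)
  denom <- sum(PCm)
  if (denom < 1e-12) {
    if (identical_in) return(1)
    return(mean(Spc * Sg))
  }
  sum(Spc * Sg * PCm) / denom
}
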