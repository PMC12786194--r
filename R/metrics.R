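#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(255^2 / MSE)} between two 8-bit images. Identical
#' images (MSE = 0) are reported as the documented cap of 100 dB so tables
#' stay finite.
#'
#' @param ref,test numeric matrices of equal shape, 8-bit scale (0..255).
#' @param cap value returned for identical inputs (default 100).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 2, 2), matrix(255, 2, 2))   # 0 dB
#' @export
psnr <- function(ref, test, cap = 100) {
  if (!all(dim(ref) == dim(test))) stop("shape mismatch")
  mse <- mean((as.numeric(ref) - as.numeric(test))^2)
  if (mse == 0) return(cap)
  min(10 * log10(255^2 / mse), cap)
}

## separable valid-mode filtering with a 1-D kernel (used by SSIM)
.filterValid <- function(x, kern) {
  r <- (length(kern) - 1L) %/% 2L
  m <- nrow(x); n <- ncol(x)
  A <- matrix(0, m - 2L * r, m)
  for (i in seq_len(m - 2L * r)) A[i, i:(i + 2L * r)] <- kern
  B <- matrix(0, n, n - 2L * r)
  for (j in seq_len(n - 2L * r)) B[j:(j + 2L * r), j] <- kern
  A %*% x %*% B
}

#' Mean structural similarity index (SSIM)
#'
#' Classic mean-SSIM: local means, variances and covariance under an 11x11
#' Gaussian window (sigma 1.5), stability constants \eqn{C_1 = (K_1 L)^2},
#' \eqn{C_2 = (K_2 L)^2} with \eqn{K_1 = 0.01}, \eqn{K_2 = 0.03} and dynamic
#' range \eqn{L = 255}, averaged over the valid filter region. For a pair of
#' constant images the index reduces to the luminance term
#' \eqn{(2\mu_1\mu_2 + C_1)/(\mu_1^2 + \mu_2^2 + C_1)}.
#'
#' @param ref,test numeric matrices of equal shape on the 0..255 scale, each
#'   dimension at least 11.
#' @param K1,K2 stability constants (defaults 0.01, 0.03).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param windowSize odd window side length (default 11).
#' @param dynamicRange default 255.
#' @return mean SSIM, in [-1, 1].
#' @examples
#' x <- matrix(100, 16, 16)
#' ssim(x, x)   # 1
#' @export
ssim <- function(ref, test, K1 = 0.01, K2 = 0.03, sigma = 1.5,
                 windowSize = 11L, dynamicRange = 255) {
  if (!all(dim(ref) == dim(test))) stop("shape mismatch")
  if (min(dim(ref)) < windowSize) stop("image smaller than the SSIM window")
  r <- (windowSize - 1L) %/% 2L
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  x <- matrix(as.numeric(ref), nrow(ref)); y <- matrix(as.numeric(test), nrow(test))
  C1 <- (K1 * dynamicRange)^2
  C2 <- (K2 * dynamicRange)^2
  ux <- .filterValid(x, kern); uy <- .filterValid(y, kern)
  vx <- .filterValid(x * x, kern) - ux^2
  vy <- .filterValid(y * y, kern) - uy^2
  vxy <- .filterValid(x * y, kern) - ux * uy
  map <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(map)
}

#' Overlap metrics between two binary masks
#'
#' Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)}, Jaccard index
#' \eqn{|A \cap B| / |A \cup B|}, and the (symmetric) Hausdorff distance:
#' the larger of the two directed maximum nearest-neighbour Euclidean
#' distances between foreground pixel sets. Two empty masks are defined as
#' perfect agreement (dice = jaccard = 1); one empty mask gives dice =
#' jaccard = 0 and an undefined (NA, with warning) Hausdorff distance.
#'
#' @param maskA,maskB logical (or 0/1) matrices of equal shape.
#' @return named list with \code{dice}, \code{jaccard}, \code{hausdorff}.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[1:2, 2:3] <- TRUE
#' overlapMetrics(a, b)   # dice 0.5, jaccard 1/3
#' @export
overlapMetrics <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB))) stop("shape mismatch")
  a <- maskA > 0; b <- maskB > 0
  na <- sum(a); nb <- sum(b); inter <- sum(a & b)
  if (na == 0 && nb == 0) {
    return(list(dice = 1, jaccard = 1, hausdorff = 0))
  }
  dice <- 2 * inter / (na + nb)
  jac <- inter / (na + nb - inter)
  if (na == 0 || nb == 0) {
    warning("one mask empty: Hausdorff distance undefined")
    return(list(dice = dice, jaccard = jac, hausdorff = NA_real_))
  }
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  h <- sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
  list(dice = dice, jaccard = jac, hausdorff = h)
}

#' Pixel and neighbor-pixel correlation diagnostics
#'
#' Pearson and Spearman correlation between the flattened original and
#' segmented images (how faithfully global intensity relationships survive
#' segmentation) and between horizontally adjacent pixel pairs of the
#' segmented image (spatial dependency: does segmentation preserve local
#' intensity structure). Spearman uses average ranks for ties. Constant
#' input vectors have undefined correlation and are reported as NA with a
#' warning.
#'
#' @param original,segmented numeric matrices of equal shape.
#' @param vertical also pool vertically adjacent pairs into the neighbor
#'   statistics (default FALSE: horizontal only).
#' @return named list with \code{pearson_r}, \code{spearman_rho},
#'   \code{neighbor_pearson}, \code{neighbor_spearman}.
#' @export
correlationDiagnostics <- function(original, segmented, vertical = FALSE) {
  if (!all(dim(original) == dim(segmented))) stop("shape mismatch")
  x <- as.numeric(original); y <- as.numeric(segmented)
  safeCor <- function(u, v, method) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      warning("constant input: correlation undefined")
      return(NA_real_)
    }
    stats::cor(u, v, method = method)
  }
  s <- segmented
  left <- as.numeric(s[, -ncol(s), drop = FALSE])
  right <- as.numeric(s[, -1, drop = FALSE])
  if (vertical) {
    left <- c(left, as.numeric(s[-nrow(s), , drop = FALSE]))
    right <- c(right, as.numeric(s[-1, , drop = FALSE]))
  }
  list(pearson_r = safeCor(x, y, "pearson"),
       spearman_rho = safeCor(x, y, "spearman"),
       neighbor_pearson = safeCor(left, right, "pearson"),
       neighbor_spearman = safeCor(left, right, "spearman"))
}

#' Full metric report for one (image, segmentation) pair
#'
#' Convenience wrapper computing PSNR, SSIM, FSIM and the correlation
#' diagnostics between an image and its class-mean reconstruction, plus
#' Dice/Jaccard/Hausdorff when a predicted and reference mask are supplied.
#'
#' @param original 8-bit image matrix.
#' @param segmented its reconstruction (e.g.
#'   \code{reconstruction(applyThresholds(...))}).
#' @param maskPred,maskRef optional binary masks for the overlap metrics.
#' @param correlations include correlation diagnostics (default TRUE).
#' @return one-row data.frame with metric columns.
#' @export
metricReport <- function(original, segmented, maskPred = NULL, maskRef = NULL,
                         correlations = TRUE) {
  out <- data.frame(psnr = psnr(original, segmented),
                    ssim = ssim(original, segmented),
                    fsim = fsim(original, segmented))
  if (correlations) {
    cd <- suppressWarnings(correlationDiagnostics(original, segmented))
    out <- cbind(out, as.data.frame(cd))
  }
  if (!is.null(maskPred) && !is.null(maskRef)) {
    ov <- overlapMetrics(maskPred, maskRef)
    out <- cbind(out, as.data.frame(ov))
  }
  out
}
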