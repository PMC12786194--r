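#' Read and preprocess an image to the working 8-bit grayscale grid
#'
#' Standardizes any supported raster to the representation the optimizer and
#' metrics operate on: RGB is converted to luminance (0.299 R + 0.587 G +
#' 0.114 B), the image is resized to \code{targetSize} by bilinear
#' interpolation (skipped when already that size, so a conforming grayscale
#' input passes through untouched), intensities are rescaled to [0, 1] and
#' quantized back to integers 0..255 with round-half-to-even.
#'
#' @param image a file path (PNG/TIFF/JPEG, read via EBImage), an
#'   \code{EBImage::Image}, or a numeric matrix/array. Matrix values may be
#'   on [0, 1] or 0..255; arrays with a third dimension of 3 are treated as
#'   RGB.
#' @param targetSize length-2 integer, output height and width
#'   (default c(256, 256)).
#' @return integer matrix of 8-bit intensities (rows = image rows).
#' @export
preprocessImage <- function(image, targetSize = c(256L, 256L)) {
  arr <- .asIntensityArray(image)
  if (length(dim(arr)) == 3L) {
    arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  }
  if (any(dim(arr) == 0L)) stop("zero-size image")
  if (!all(dim(arr) == targetSize)) {
    img <- EBImage::Image(t(arr))     # EBImage is column-major x,y
    img <- EBImage::resize(img, w = targetSize[2], h = targetSize[1],
                           filter = "bilinear")
    arr <- t(EBImage::imageData(img))
  }
  arr <- pmin(pmax(arr, 0), 1)        # intensities normalized to [0, 1]
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

## Accepts path / EBImage::Image / matrix / 3-d array; returns values on
## [0,1] (matrices already integer-like 0..255 are divided by 255).
.asIntensityArray <- function(image) {
  if (is.character(image)) {
    if (!file.exists(image)) stop("unreadable file: ", image)
    img <- EBImage::readImage(image)
    a <- EBImage::imageData(img)
    # EBImage stores (x, y[, c]); transpose to row-major (y, x)
    if (length(dim(a)) == 2L) return(t(a))
    return(aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)))
  }
  if (is(image, "Image")) {
    a <- EBImage::imageData(image)
    if (length(dim(a)) == 2L) return(t(a))
    return(aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)))
  }
  a <- image
  if (is.null(dim(a))) stop("image must be a matrix, array, Image or path")
  if (max(a, na.rm = TRUE) > 1) a <- a / 255
  a
}

#' Segment an image with a threshold set
#'
#' Assigns pixel value \eqn{v} the class label \eqn{i} (0-based) such that
#' \eqn{\lfloor t_i \rfloor < v \le \lfloor t_{i+1} \rfloor} — the same
#' boundary convention the objective uses — and builds the class-mean
#' reconstruction: every pixel replaced by the rounded (half-to-even) mean
#' intensity of its class, computed from the image's own histogram. Empty
#' classes receive the midpoint of their bin range so the reconstruction is
#' total. Labels are monotone in intensity and the reconstruction takes at
#' most \eqn{k+1} distinct values.
#'
#' The class-mean reconstruction is the standard "segmented image" of the
#' multilevel-thresholding literature, and the unique choice for which
#' maximizing the between-class variance also maximizes the PSNR of the
#' reconstruction (its MSE equals the within-class variance).
#'
#' @param image integer matrix of 8-bit intensities (e.g. from
#'   [preprocessImage()]).
#' @param thresholds a \linkS4class{ThresholdSet} or numeric vector.
#' @param nLevels number of gray levels (default 256).
#' @return a \linkS4class{SegmentationResult}.
#' @examples
#' img <- matrix(c(50L, 200L), 1, 2)
#' seg <- applyThresholds(img, 100)
#' labelMap(seg); reconstruction(seg)
#' @export
applyThresholds <- function(image, thresholds, nLevels = 256L) {
  L <- as.integer(nLevels)
  if (!is(thresholds, "ThresholdSet")) thresholds <- thresholdSet(thresholds, L)
  tf <- unique(sort(as.integer(floor(thresholds@values))))
  v <- as.integer(image)
  lab <- findInterval(v, tf + 0.5)             # 0-based class labels
  hist <- computeHistogram(image, L)
  p <- histProbs(hist)
  jj <- seq.int(0L, L - 1L)
  binClass <- findInterval(jj, tf + 0.5) + 1L
  lo <- c(0L, tf + 1L); hi <- c(tf, L - 1L)
  reps <- vapply(seq_along(lo), function(i) {
    sel <- binClass == i
    w <- sum(p[sel])
    if (w > 0) round(sum(jj[sel] * p[sel]) / w)
    else round((lo[i] + hi[i]) / 2)
  }, numeric(1))
  rec <- matrix(reps[lab + 1L], nrow(image), ncol(image))
  new("SegmentationResult",
      labelMap = matrix(lab, nrow(image), ncol(image)),
      reconstruction = rec, thresholds = thresholds)
}

#' Write a segmentation to PNG files
#'
#' Writes the class-mean reconstruction and, optionally, a label map scaled
#' to the full gray range for visual inspection.
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @param reconstructionFile path for the reconstruction PNG.
#' @param labelFile optional path for the scaled label-map PNG.
#' @return invisibly, the paths written.
#' @export
writeSegmentation <- function(seg, reconstructionFile, labelFile = NULL) {
  png::writePNG(reconstruction(seg) / 255, reconstructionFile)
  paths <- reconstructionFile
  if (!is.null(labelFile)) {
    k <- max(labelMap(seg))
    png::writePNG(if (k > 0) labelMap(seg) / k else labelMap(seg), labelFile)
    paths <- c(paths, labelFile)
  }
  invisible(paths)
}
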