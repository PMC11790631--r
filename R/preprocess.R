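# Preprocessing chain: edge detection -> minimal-square crop -> resize ->
# optional rotation augmentation -> normalisation. Images are (H, W, 3)
# arrays on the 8-bit 0..255 scale until normalisation.

# ITU-R 601 luminance.
rgbToGray <- function(image) {
  if (length(dim(image)) == 2) return(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Single-channel 2-D convolution through the package's conv kernel, with
# replicate (edge-extend) padding so constant regions stay gradient-free at
# the image border.
convolve2d <- function(m, kernel, pad) {
  pad <- as.integer(pad)
  if (pad > 0) {
    ri <- c(rep(1L, pad), seq_len(nrow(m)), rep(nrow(m), pad))
    ci <- c(rep(1L, pad), seq_len(ncol(m)), rep(ncol(m), pad))
    m <- m[ri, ci]
  }
  x <- array(m, dim = c(dim(m), 1L, 1L))
  w <- array(kernel, dim = c(dim(kernel), 1L, 1L))
  out <- conv2d_forward_cpp(x, w, 0, 1L, 0L)
  matrix(out, nrow = dim(out)[1])
}

gaussianKernel <- function(sigma = 1.4, radius = 2L) {
  ax <- seq(-radius, radius)
  k <- outer(ax, ax, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  k / sum(k)
}

shiftMat <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  ri <- seq_len(H) - di; rj <- seq_len(W) - dj
  ok_i <- ri >= 1 & ri <= H; ok_j <- rj >= 1 & rj <= W
  out[ok_i, ok_j] <- m[ri[ok_i], rj[ok_j]]
  out
}

#' Canny edge detection
#'
#' Standard Canny chain on the image luminance: Gaussian smoothing, Sobel
#' gradients, non-maximum suppression along the quantised gradient
#' direction, then double-threshold hysteresis (weak edges survive only in
#' connected components that contain a strong edge). Thresholds are applied
#' to the Sobel gradient magnitude of the 8-bit intensity image.
#'
#' @param image (H, W, 3) array on the 0..255 scale (or an H x W matrix).
#' @param config a [PreprocessConfig-class] supplying `cannyLow`/`cannyHigh`.
#' @return logical H x W edge mask.
#' @export
detectEdges <- function(image, config = PreprocessConfig()) {
  gray <- rgbToGray(image)
  if (length(gray) == 0) stop("empty image")
  sm <- convolve2d(gray, gaussianKernel(), pad = 2L)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dcol
  gx <- convolve2d(sm, sx, pad = 1L)
  gy <- convolve2d(sm, t(sx), pad = 1L)
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag < config@cannyLow)) return(matrix(FALSE, nrow(gray), ncol(gray)))

  # Non-maximum suppression: quantise direction to 0/45/90/135 degrees.
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4  # 0=E,1=NE,2=N,3=NW
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    d <- offs[[s + 1]]
    n1 <- shiftMat(mag, d[1], d[2]); n2 <- shiftMat(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  strong <- keep & mag >= config@cannyHigh
  weak <- keep & mag >= config@cannyLow
  if (!any(strong)) return(matrix(FALSE, nrow(gray), ncol(gray)))
  lbl <- EBImage::bwlabel(weak)
  good <- unique(lbl[strong])
  matrix(lbl %in% good[good > 0], nrow(gray), ncol(gray))
}

#' Minimal-square background crop
#'
#' Crops the smallest axis-aligned square that contains the bounding box of
#' all edge pixels, centred on that bounding box. The square is clipped to
#' the image by shifting inward (never padded), its side never exceeds the
#' image, and a minimum side (default 8 px) guards against degenerate crops
#' from isolated speckle. An empty mask returns the image unchanged.
#'
#' @param image (H, W, 3) array.
#' @param mask logical H x W edge mask.
#' @param minSide minimum crop side in pixels.
#' @return the cropped (side, side, 3) array.
#' @export
minSquareCrop <- function(image, mask, minSide = 8L) {
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("mask and image dimensions differ")
  if (!any(mask)) return(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  side <- max(rows[2] - rows[1] + 1, cols[2] - cols[1] + 1, minSide)
  side <- min(side, H, W)
  r0 <- rows[1] - floor((side - (rows[2] - rows[1] + 1)) / 2)
  c0 <- cols[1] - floor((side - (cols[2] - cols[1] + 1)) / 2)
  r0 <- min(max(r0, 1), H - side + 1)
  c0 <- min(max(c0, 1), W - side + 1)
  image[r0:(r0 + side - 1), c0:(c0 + side - 1), , drop = FALSE]
}

#' Resize an image to a square target
#'
#' Bilinear resize to `targetSize` x `targetSize`; aspect ratio is not
#' preserved (inputs are already square after the minimal-square crop).
#'
#' @param image (H, W, 3) array.
#' @param targetSize side of the square output.
#' @return (targetSize, targetSize, 3) array.
#' @export
resizeImage <- function(image, targetSize) {
  if (dim(image)[1] == targetSize && dim(image)[2] == targetSize) return(image)
  out <- EBImage::resize(image, w = targetSize, h = targetSize)
  array(out, dim = c(targetSize, targetSize, dim(image)[3]))
}

#' Random rotation augmentation
#'
#' Rotates by an angle drawn uniformly from `[-maxDeg, +maxDeg]` (bilinear
#' interpolation, black fill, output size preserved). Uses R's RNG, so a
#' seeded caller gets a reproducible angle sequence. `maxDeg = 0` is the
#' identity.
#'
#' @param image (H, W, 3) array.
#' @param maxDeg rotation bound in degrees.
#' @param angle optional fixed angle (overrides the random draw).
#' @return rotated array of the same dimensions.
#' @export
augmentRotation <- function(image, maxDeg, angle = NULL) {
  stopifnot(maxDeg >= 0)
  if (is.null(angle)) {
    if (maxDeg == 0) return(image)
    angle <- stats::runif(1, -maxDeg, maxDeg)
  }
  if (angle == 0) return(image)
  out <- EBImage::rotate(image, angle, filter = "bilinear",
                         output.dim = dim(image)[2:1], bg.col = 0)
  array(out, dim = dim(image))
}

#' Per-channel normalisation
#'
#' `out = (in / 255 - mean) / std` per channel: pixel intensities are
#' rescaled to `[0, 1]` and standardised with the configured constants.
#'
#' @param image (H, W, 3) array on the 0..255 scale.
#' @param mean,std length-3 per-channel constants.
#' @return normalised (H, W, 3) array.
#' @export
normalizeImage <- function(image, mean = c(0.485, 0.456, 0.406),
                           std = c(0.229, 0.224, 0.225)) {
  if (any(std <= 0)) stop("normalisation std must be positive")
  out <- image / 255
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- (out[, , ch] - mean[ch]) / std[ch]
  out
}

#' Full preprocessing pipeline for one view pair
#'
#' Applies, independently to the front and back images: Canny edge
#' detection, minimal-square crop, resize to `targetSize`, optional random
#' rotation (only when `config@augment` is TRUE; use `lockAngles` to rotate
#' both views by the same angle) and normalisation.
#'
#' @param pair list with `front` and `back` (H, W, 3) arrays on the 0..255
#'   scale, as returned by [loadViewPair()].
#' @param config a [PreprocessConfig-class].
#' @return list with normalised `front` and `back`
#'   (targetSize, targetSize, 3) tensors plus any provenance fields of the
#'   input (`pair_id`, `class_label`).
#' @export
preprocessPipeline <- function(pair, config = PreprocessConfig()) {
  lockedAngle <- if (config@augment && config@lockAngles)
    stats::runif(1, -config@maxRotationDeg, config@maxRotationDeg) else NULL
  one <- function(img) {
    mask <- detectEdges(img, config)
    img <- minSquareCrop(img, mask)
    img <- resizeImage(img, config@targetSize)
    if (config@augment)
      img <- augmentRotation(img, config@maxRotationDeg, angle = lockedAngle)
    normalizeImage(img, config@normMean, config@normStd)
  }
  out <- pair
  out$front <- one(pair$front)
  out$back <- one(pair$back)
  out
}

# Deterministic part of the pipeline (detect/crop/resize) over a whole
# manifest, kept on the 0..255 scale so augmentation and normalisation can
# be applied per split / per epoch without repeating the edge detection.
prepCache <- function(manifest, config) {
  rec <- manifest@records
  n <- nrow(rec)
  s <- config@targetSize
  front <- array(0, dim = c(s, s, 3, n))
  back <- array(0, dim = c(s, s, 3, n))
  for (i in seq_len(n)) {
    pair <- loadViewPair(rec[i, , drop = FALSE])
    for (v in c("front", "back")) {
      img <- pair[[v]]
      img <- minSquareCrop(img, detectEdges(img, config))
      img <- resizeImage(img, s)
      if (v == "front") front[, , , i] <- img else back[, , , i] <- img
    }
  }
  list(front = front, back = back,
       labels = match(rec$class_label, manifest@classes),
       pair_id = rec$pair_id, classes = manifest@classes)
}

# Turn cached (0..255) slices into normalised network tensors.
finalizeTensors <- function(cache, idx, config, augment = FALSE) {
  sel <- function(a) a[, , , idx, drop = FALSE]
  front <- sel(cache$front); back <- sel(cache$back)
  if (augment && config@maxRotationDeg > 0) {
    for (i in seq_along(idx)) {
      angF <- stats::runif(1, -config@maxRotationDeg, config@maxRotationDeg)
      angB <- if (config@lockAngles) angF
              else stats::runif(1, -config@maxRotationDeg, config@maxRotationDeg)
      front[, , , i] <- augmentRotation(front[, , , i], config@maxRotationDeg,
                                        angle = angF)
      back[, , , i] <- augmentRotation(back[, , , i], config@maxRotationDeg,
                                       angle = angB)
    }
  }
  normTensor <- function(a) {
    a <- a / 255
    for (ch in 1:3)
      a[, , ch, ] <- (a[, , ch, ] - config@normMean[ch]) / config@normStd[ch]
    a
  }
  list(front = normTensor(front), back = normTensor(back),
       labels = cache$labels[idx], pair_id = cache$pair_id[idx],
       classes = cache$classes)
}
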