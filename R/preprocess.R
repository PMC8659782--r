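#' Resize an RGB image with bilinear interpolation
#'
#' Captures are downscaled (e.g. from 1280 x 1024 to 512 x 512) before
#' feature extraction to bound the cost of the downstream stages.
#'
#' @param img Height x width x 3 array with values in 0-255.
#' @param target `c(height, width)` of the output; both >= 32.
#' @return The resized image array.
#' @export
resize_image <- function(img, target = c(512L, 512L)) {
  check_rgb_image(img)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 32L))
    abort("`target` must be c(height, width) with both >= 32")
  if (all(dim(img)[1:2] == target)) return(img)
  e <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
  r <- EBImage::resize(e, w = target[2], h = target[1], filter = "bilinear")
  out <- aperm(EBImage::imageData(r), c(2, 1, 3)) * 255
  clamp(out, 0, 255)
}

# Normalized 1-D Gaussian taps for a given odd kernel size.  When `sigma` is
# NULL it follows the usual machine-vision default tied to kernel size:
# 0.3 * ((k - 1)/2 - 1) + 0.8.
gaussian_taps <- function(kernel, sigma = NULL) {
  r <- (kernel - 1L) / 2L
  if (is.null(sigma)) sigma <- 0.3 * (r - 1) + 0.8
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable 1-D convolution of a matrix along rows or columns with
# symmetric-reflection border handling.
convolve_1d <- function(m, taps, along = c("rows", "cols")) {
  along <- match.arg(along)
  r <- (length(taps) - 1L) / 2L
  if (r == 0L) return(m)
  if (along == "cols") return(t(convolve_1d(t(m), taps, "rows")))
  n <- nrow(m)
  idx <- c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (o in seq_along(taps))
    out <- out + taps[o] * padded[(o - 1L) + seq_len(n), , drop = FALSE]
  out
}

#' Denoise an RGB image with a normalized Gaussian filter
#'
#' Per-channel separable convolution; borders are handled by reflection.
#'
#' @param img Height x width x 3 array, values 0-255.
#' @param kernel Odd kernel size (>= 1); `kernel = 1` is the identity.
#' @param sigma Gaussian standard deviation in pixels; defaults to
#'   `0.3 * ((kernel - 1)/2 - 1) + 0.8`.
#' @return The filtered image array.
#' @export
gaussian_denoise <- function(img, kernel = 5L, sigma = NULL) {
  check_rgb_image(img)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    abort("`kernel` must be odd and >= 1")
  if (kernel == 1L) return(img)
  taps <- gaussian_taps(kernel, sigma)
  out <- img
  for (ch in 1:3)
    out[, , ch] <- convolve_1d(convolve_1d(img[, , ch], taps, "rows"),
                               taps, "cols")
  out
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R 601 luma weights 0.299, 0.587, 0.114.
#'
#' @param img Height x width x 3 array, values 0-255.
#' @return Height x width numeric matrix in 0-255.
#' @export
rgb_to_gray <- function(img) {
  check_rgb_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Otsu threshold of a grayscale image
#'
#' Returns the level `t` in 0-254 that maximizes the between-class variance of
#' the split into pixels `<= t` and `> t`, computed on the 8-bit histogram of
#' the rounded intensities.  Among tied maxima the smallest `t` is returned.
#'
#' @param gray Numeric matrix with values in 0-255 and at least two distinct
#'   rounded levels.
#' @return Integer threshold in 0-254.
#' @export
#' @examples
#' g <- matrix(c(10, 10, 200, 200), 2)
#' otsu_threshold(g)
otsu_threshold <- function(gray) {
  v <- round(clamp(as.numeric(gray), 0, 255))
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    abort("degenerate histogram: image has a single intensity level")
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)[1:255]
  mu_t <- cumsum(p * levels)
  mu_total <- mu_t[256]
  mu0 <- mu_t[1:255]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_total * w0[valid] - mu0[valid])^2 /
    (w0[valid] * w1[valid])
  which.max(sigma_b) - 1L  # which.max takes the first (smallest t) on ties
}

#' Morphologically clean a binary mask
#'
#' Opening then closing with a square structuring element removes speckle
#' noise smaller than the kernel and seals narrow gaps; enclosed background
#' holes are then filled.
#'
#' @param mask {0,1} matrix, foreground = specimen.
#' @param kernel Odd structuring-element side (>= 3).
#' @return The cleaned {0,1} matrix.
#' @export
morphological_clean <- function(mask, kernel = 5L) {
  check_mask(mask)
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) abort("`kernel` must be odd and >= 3")
  brush <- EBImage::makeBrush(kernel, shape = "box")
  m <- t(mask)
  m <- EBImage::closing(EBImage::opening(m, brush), brush)
  m <- EBImage::fillHull(m)
  out <- t(EBImage::imageData(m))
  matrix(as.numeric(out > 0), nrow(mask), ncol(mask))
}

# Foreground polarity: of the two sides of the threshold, the specimen is the
# side with the smaller total intensity (mean intensity x area) - the bright
# uniform background dominates the other side.
binarize <- function(gray, threshold) {
  low <- gray <= threshold
  sum_low <- sum(gray[low])
  sum_high <- sum(gray[!low])
  fg <- if (sum_low <= sum_high) low else !low
  matrix(as.numeric(fg), nrow(gray), ncol(gray))
}

# Retain only the largest 8-connected foreground component.
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(t(mask))
  lab <- t(EBImage::imageData(lab))
  if (max(lab) <= 1L) return(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  matrix(as.numeric(lab == keep), nrow(mask), ncol(mask))
}

#' Preprocess a raw capture into image, grayscale and specimen mask
#'
#' The full chain: bilinear resize, Gaussian denoising, grayscale conversion,
#' Otsu binarization (specimen = the low-total-intensity side), morphological
#' opening/closing with hole filling, and retention of the largest connected
#' component.
#'
#' @param img Height x width x 3 array, values 0-255.
#' @param config Optional list overriding `resize_to` (c(height, width),
#'   default 512 x 512), `gaussian_kernel` (5), `gaussian_sigma` (from kernel)
#'   and `morph_kernel` (5).
#' @return A list with `rgb` (resized + filtered image), `gray` and `mask`.
#' @export
preprocess <- function(img, config = list()) {
  cfg <- modifyList(
    list(resize_to = c(512L, 512L), gaussian_kernel = 5L,
         gaussian_sigma = NULL, morph_kernel = 5L),
    config
  )
  rgb <- resize_image(img, cfg$resize_to)
  rgb <- gaussian_denoise(rgb, cfg$gaussian_kernel, cfg$gaussian_sigma)
  gray <- rgb_to_gray(rgb)
  t0 <- tryCatch(otsu_threshold(gray), error = function(e)
    abort("segmentation failure: image is uniform, no specimen found"))
  mask <- binarize(gray, t0)
  mask <- morphological_clean(mask, cfg$morph_kernel)
  mask <- largest_component(mask)
  if (sum(mask) == 0)
    abort("segmentation failure: empty foreground after cleaning")
  list(rgb = rgb, gray = gray, mask = mask)
}
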