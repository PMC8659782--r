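#' Color moments of a channel
#'
#' Low-order statistics used as compact color descriptors: the mean, then the
#' square root of the second central moment (reported as `var`), the signed
#' cube root of the third central moment (`s`, skewness) and the fourth root
#' of the fourth central moment minus 3 (`k`, kurtosis).  All central moments
#' are averaged over N (the pixel count), and each statistic is returned on
#' the intensity scale by taking the matching root, so the four moments of a
#' channel share one unit.
#'
#' @param values Non-empty numeric vector of channel intensities.
#' @return Named numeric vector `c(mean, var, s, k)`.
#' @export
#' @examples
#' color_moments(c(0, 2))  # c(1, 1, 0, -2)
color_moments <- function(values) {
  if (length(values) == 0L || !is.numeric(values))
    abort("`values` must be a non-empty numeric vector")
  mu <- mean(values)
  d <- values - mu
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  c(mean = mu,
    var = sqrt(m2),
    s = sign(m3) * abs(m3)^(1 / 3),
    k = m4^(1 / 4) - 3)
}

#' Extract the 24 color-moment features of a specimen
#'
#' Converts the image to HSV, rescales H, S and V to 0-255 so all six
#' channels share one unit scale, and computes the four color moments of each
#' of R, G, B, H, S, V over the foreground pixels only (the uniform
#' background would otherwise dominate the statistics).
#'
#' @param img Height x width x 3 array, values 0-255.
#' @param mask Non-empty {0,1} foreground matrix of matching size.
#' @return A one-row tibble with 24 columns named `Rmean`, `Rvar`, `Rs`,
#'   `Rk`, ..., `Vk` (channel order R, G, B, H, S, V).
#' @export
extract_color_features <- function(img, mask) {
  check_rgb_image(img)
  check_mask(mask)
  if (!all(dim(mask) == dim(img)[1:2]))
    abort("`mask` and `img` sizes differ")
  fg <- which(mask == 1)
  if (length(fg) == 0L) abort("empty mask")
  r <- img[, , 1][fg]
  g <- img[, , 2][fg]
  b <- img[, , 3][fg]
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255) * 255
  channels <- list(R = r, G = g, B = b,
                   H = hsv[1, ], S = hsv[2, ], V = hsv[3, ])
  out <- purrr::imap(channels, function(v, nm) {
    m <- color_moments(v)
    stats::setNames(as.list(m), paste0(nm, names(m)))
  })
  tibble::as_tibble(do.call(c, unname(out)))
}
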