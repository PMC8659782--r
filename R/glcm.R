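#' Gray-level co-occurrence matrix of a masked grayscale image
#'
#' Quantizes intensities uniformly over 0-255 into `levels` bins (so features
#' are comparable across images regardless of their own dynamic range) and
#' counts symmetric pixel pairs at the given offset: distance `d` along
#' direction `theta`, with both endpoints inside the mask.  Counts are
#' accumulated in both orders, then normalized to sum to one.
#'
#' @param gray Numeric matrix, values 0-255.
#' @param mask Optional {0,1} matrix restricting pairs to the specimen;
#'   defaults to the whole image.
#' @param d Pair distance in pixels (>= 1).
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @param levels Number of gray levels (2-256); 64 by default.
#' @return An object of class `glcm`: the `levels` x `levels` probability
#'   matrix with attributes `d`, `theta`, `levels`.
#' @export
#' @examples
#' g <- matrix(c(0, 0, 255, 255), nrow = 1)
#' compute_glcm(g, d = 1, theta = 0, levels = 2)
compute_glcm <- function(gray, mask = NULL, d = 2L, theta = 0,
                         levels = 64L) {
  stopifnot(is.matrix(gray), d >= 1, levels >= 2, levels <= 256)
  if (!theta %in% c(0, 45, 90, 135))
    abort("`theta` must be one of 0, 45, 90, 135 degrees")
  if (is.null(mask)) mask <- matrix(1, nrow(gray), ncol(gray))
  check_mask(mask)
  d <- as.integer(d)
  levels <- as.integer(levels)
  q <- matrix(pmin(floor(clamp(gray, 0, 255) * levels / 256), levels - 1L),
              nrow(gray), ncol(gray))
  # (row, col) offset per direction; symmetric accumulation makes the
  # sign convention immaterial
  off <- switch(as.character(theta),
                "0"   = c(0L, d),
                "45"  = c(-d, d),
                "90"  = c(-d, 0L),
                "135" = c(-d, -d))
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(r0) == 0L || length(c0) == 0L)
    abort("degenerate texture: no valid pixel pair at this offset")
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + off[1], c0 + off[2], drop = FALSE]
  ok <- (mask[r0, c0, drop = FALSE] == 1) &
    (mask[r0 + off[1], c0 + off[2], drop = FALSE] == 1)
  if (!any(ok)) abort("degenerate texture: no valid pixel pair inside mask")
  idx <- a[ok] * levels + b[ok] + 1L
  counts <- matrix(tabulate(idx, nbins = levels^2), levels, levels,
                   byrow = TRUE)
  counts <- counts + t(counts)
  g <- counts / sum(counts)
  structure(g, class = "glcm", d = d, theta = theta, levels = levels)
}

#' Haralick-style texture statistics of a co-occurrence matrix
#'
#' The seven statistics: homogeneity `sum f/(1+(i-j)^2)`, contrast
#' `sum (i-j)^2 f`, dissimilarity `sum |i-j| f`, entropy `-sum f log10 f`
#' (base-10 logarithm; empty cells contribute zero), energy `sum f^2`,
#' correlation `sum (i-mu_x)(j-mu_y) f / (sigma_x sigma_y)` with marginal
#' means and standard deviations (1 when a marginal variance vanishes, e.g.
#' for a constant image), and auto-correlation `sum i j f`.  Indices run from
#' 0 to levels-1.
#'
#' @param g A `glcm` object (any non-negative matrix summing to one works).
#' @return A one-row tibble with columns `Homogeneity`, `Contrast`,
#'   `Dissimilarity`, `Entropy`, `Energy`, `Correlation`,
#'   `Auto_Correlation`.
#' @export
glcm_features <- function(g) {
  f <- unclass(g)
  stopifnot(is.matrix(f), nrow(f) == ncol(f))
  L <- nrow(f)
  i <- matrix(0:(L - 1), L, L)          # row index
  j <- t(i)                              # column index
  pos <- f > 0
  px <- rowSums(f)
  py <- colSums(f)
  mu_x <- sum((0:(L - 1)) * px)
  mu_y <- sum((0:(L - 1)) * py)
  sd_x <- sqrt(sum((0:(L - 1) - mu_x)^2 * px))
  sd_y <- sqrt(sum((0:(L - 1) - mu_y)^2 * py))
  corr <- if (sd_x < 1e-12 || sd_y < 1e-12) 1 else
    sum((i - mu_x) * (j - mu_y) * f) / (sd_x * sd_y)
  tibble::tibble(
    Homogeneity = sum(f / (1 + (i - j)^2)),
    Contrast = sum((i - j)^2 * f),
    Dissimilarity = sum(abs(i - j) * f),
    Entropy = -sum(f[pos] * log10(f[pos])),
    Energy = sum(f^2),
    Correlation = corr,
    Auto_Correlation = sum(i * j * f)
  )
}

#' Extract the seven averaged texture features of a specimen
#'
#' Computes the co-occurrence matrix at distance `d` and `levels` gray levels
#' for each direction in `thetas` and returns the arithmetic mean of each
#' texture statistic over the directions.  With `window` set, the masked
#' bounding box is instead tiled into `window` x `window` blocks and the
#' feature is the mean over blocks that contain valid pairs.
#'
#' @param gray Numeric matrix, values 0-255.
#' @param mask Non-empty {0,1} matrix.
#' @param d Pair distance in pixels.
#' @param levels Number of gray levels.
#' @param thetas Directions in degrees to average over.
#' @param window Optional block side in pixels for windowed extraction;
#'   `NULL` (the default) computes one global matrix per direction.
#' @return A one-row tibble with the seven texture columns.
#' @export
extract_texture_features <- function(gray, mask, d = 2L, levels = 64L,
                                     thetas = c(0, 45, 90, 135),
                                     window = NULL) {
  check_mask(mask)
  if (sum(mask) == 0) abort("empty mask")
  one_region <- function(g, m) {
    per_dir <- purrr::map(thetas, function(th)
      glcm_features(compute_glcm(g, m, d = d, theta = th, levels = levels)))
    dplyr::summarise(dplyr::bind_rows(per_dir),
                     dplyr::across(dplyr::everything(), mean))
  }
  if (is.null(window)) return(one_region(gray, mask))
  window <- as.integer(window)
  stopifnot(window > d)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  feats <- list()
  for (r in seq(rows[1], rows[2], by = window)) {
    for (cc in seq(cols[1], cols[2], by = window)) {
      ri <- r:min(r + window - 1L, rows[2])
      ci <- cc:min(cc + window - 1L, cols[2])
      sub <- tryCatch(one_region(gray[ri, ci, drop = FALSE],
                                 mask[ri, ci, drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(sub)) feats[[length(feats) + 1L]] <- sub
    }
  }
  if (length(feats) == 0L) abort("degenerate texture: no valid window")
  dplyr::summarise(dplyr::bind_rows(feats),
                   dplyr::across(dplyr::everything(), mean))
}
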