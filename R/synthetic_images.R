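#' Specification of the synthetic root-image generator
#'
#' Describes how the four commercial grades differ jointly in size, shape
#' irregularity, surface color and surface texture on a bright uniform
#' background, emulating top-view captures of single taproots in a light box.
#' Per-grade silhouette size (major-axis length) strictly decreases from
#' grade I to IV while lobedness (shape irregularity), surface darkness,
#' color noise and texture amplitude increase, mirroring how smaller,
#' gnarlier, darker roots sit lower in the standard.
#'
#' @param canvas Side of the square canvas in pixels (>= 128).
#' @param major_mean,major_sd Per-grade mean and spread (px) of the blob
#'   major-axis length, grades I-IV; means must strictly decrease.  Defaults
#'   scale with `canvas`.
#' @param lobes 4 x 2 integer matrix of per-grade (min, max) radial lobe
#'   counts.
#' @param lobe_amp Relative amplitude of the radial lobes.
#' @param base_color 4 x 3 matrix of per-grade surface RGB (0-255).
#' @param color_noise Per-grade per-channel Gaussian noise scale.
#' @param texture_amp,texture_freq Per-grade amplitude (intensity units) and
#'   spatial frequency (cycles/px) of the sinusoidal surface shading.
#' @param background Background gray level (0-255); light gray keeps the
#'   specimen/background contrast high so Otsu thresholding is well posed.
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(canvas = 512L,
                                 major_mean = canvas * c(0.66, 0.55, 0.45, 0.37),
                                 major_sd = canvas * 0.02,
                                 lobes = cbind(c(2L, 3L, 4L, 5L),
                                               c(3L, 4L, 6L, 8L)),
                                 lobe_amp = 0.08,
                                 base_color = rbind(c(196, 168, 120),
                                                    c(182, 150, 102),
                                                    c(166, 132, 88),
                                                    c(150, 116, 76)),
                                 color_noise = c(6, 8, 10, 12),
                                 texture_amp = c(6, 10, 14, 18),
                                 texture_freq = c(0.04, 0.06, 0.09, 0.12),
                                 background = 230) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 1L || canvas < 128L)
    abort("`canvas` must be a single integer >= 128 (square canvas)")
  if (length(major_mean) != 4L || any(diff(major_mean) >= 0))
    abort("`major_mean` must strictly decrease from grade I to IV")
  stopifnot(
    all(major_mean > 0), all(major_sd > 0), all(lobes >= 1),
    all(lobes[, 2] >= lobes[, 1]), lobe_amp > 0,
    nrow(base_color) == 4L, all(base_color >= 0 & base_color <= 255),
    all(color_noise > 0), all(texture_amp > 0), all(texture_freq > 0),
    background >= 0, background <= 255
  )
  structure(
    list(canvas = canvas, major_mean = major_mean, major_sd = major_sd,
         lobes = lobes, lobe_amp = lobe_amp, base_color = base_color,
         color_noise = color_noise, texture_amp = texture_amp,
         texture_freq = texture_freq, background = background),
    class = "synthetic_image_spec"
  )
}

#' Generate one synthetic root image
#'
#' Renders a single lobed, star-convex blob (a superellipse core modulated by
#' sinusoidal radial lobes) on a uniform light-gray background, with
#' grade-conditional size, lobe count, surface color, color noise and
#' sinusoidal texture shading.  Also draws a root weight consistent with the
#' requested grade, so `assign_grade()` on the returned weight recovers it.
#' Identical `(spec, grade, seed)` give bit-identical output.
#'
#' @param spec A [synthetic_image_spec()].
#' @param grade Grade label, one of `"I"`..`"IV"`.
#' @param seed Integer seed controlling every random draw.
#' @return A list with `image` (height x width x 3 array, 0-255), `mask`
#'   (ground-truth {0,1} foreground matrix), `weight_g` and `grade`.
#' @export
#' @examples
#' root <- generate_root_image(synthetic_image_spec(canvas = 128), "II", seed = 1)
#' dim(root$image)
generate_root_image <- function(spec, grade, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  grade <- as.character(grade)
  if (!grade %in% GRADE_LEVELS) abort("`grade` must be one of I, II, III, IV")
  gi <- match(grade, GRADE_LEVELS)
  n <- spec$canvas

  withr::with_seed(as.integer(seed), {
    major <- rnorm(1, spec$major_mean[gi], spec$major_sd)
    major <- clamp(major, 0.5 * spec$major_mean[gi], 1.4 * spec$major_mean[gi])
    a <- major / 2                        # semi-major axis
    aspect <- runif(1, 0.55, 0.8)
    b <- a * aspect
    k <- sample(spec$lobes[gi, 1]:spec$lobes[gi, 2], 1L)
    phase <- runif(1, 0, 2 * pi)
    angle <- runif(1, 0, pi)
    jitter <- runif(2, -0.02, 0.02) * n
    cx <- n / 2 + jitter[1]
    cy <- n / 2 + jitter[2]

    r_max <- a * (1 + spec$lobe_amp)
    if (r_max + max(abs(jitter)) >= n / 2 - 1)
      abort("blob would exceed the canvas; enlarge `canvas` or shrink `major_mean`")

    xs <- matrix(rep(seq_len(n), each = n), n) - cx   # column coordinate
    ys <- matrix(rep(seq_len(n), times = n), n) - cy  # row coordinate
    xr <- cos(angle) * xs + sin(angle) * ys
    yr <- -sin(angle) * xs + cos(angle) * ys
    phi <- atan2(yr, xr)
    dist <- sqrt(xr^2 + yr^2)
    m <- 2.5  # superellipse exponent: slightly boxier than an ellipse
    r_se <- (abs(cos(phi) / a)^m + abs(sin(phi) / b)^m)^(-1 / m)
    r_phi <- r_se * (1 + spec$lobe_amp * cos(k * phi + phase))
    mask <- matrix(as.numeric(dist <= r_phi), n, n)

    img <- array(spec$background, dim = c(n, n, 3))
    fg <- which(mask == 1)
    n_fg <- length(fg)
    if (n_fg == 0L) abort("degenerate spec: empty foreground")
    theta_t <- runif(1, 0, pi)
    phase_t <- runif(1, 0, 2 * pi)
    shading <- spec$texture_amp[gi] *
      sin(2 * pi * spec$texture_freq[gi] *
            (cos(theta_t) * xs[fg] + sin(theta_t) * ys[fg]) + phase_t)
    # radial brightness falloff gives the blob a rounded look
    falloff <- -12 * (dist[fg] / r_phi[fg])^2
    for (ch in 1:3) {
      vals <- spec$base_color[gi, ch] + shading + falloff +
        rnorm(n_fg, 0, spec$color_noise[gi])
      plane <- img[, , ch]
      plane[fg] <- round(clamp(vals, 0, 255))
      img[, , ch] <- plane
    }
    weight <- draw_grade_weight(grade)
    list(image = img, mask = mask, weight_g = weight,
         grade = grade_factor(grade))
  })
}

#' Generate a balanced, grade-labelled synthetic image dataset
#'
#' @param spec A [synthetic_image_spec()].
#' @param n_per_grade Number of images per grade (>= 1).
#' @param seed Master seed; each image uses a sub-seed derived from it, so the
#'   dataset is reproducible and images are independent.
#' @return A tibble with list-columns `image` and `mask`, plus `sample_id`,
#'   `grade`, `weight_g` and the per-image `seed`.
#' @export
generate_image_dataset <- function(spec, n_per_grade, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  n_per_grade <- as.integer(n_per_grade)
  if (n_per_grade < 1L) abort("`n_per_grade` must be >= 1")
  grades <- rep(GRADE_LEVELS, each = n_per_grade)
  seeds <- vapply(seq_along(grades),
                  function(i) derive_seed(seed, paste0("image-", i)), 1L)
  rows <- purrr::map2(grades, seeds,
                      function(g, s) generate_root_image(spec, g, seed = s))
  tibble::tibble(
    sample_id = sprintf("root_%03d", seq_along(grades)),
    image = purrr::map(rows, "image"),
    mask = purrr::map(rows, "mask"),
    grade = grade_factor(grades),
    weight_g = purrr::map_dbl(rows, "weight_g"),
    seed = seeds
  )
}

#' Write an image dataset to disk as PNGs plus a CSV manifest
#'
#' Images are written as 8-bit RGB PNGs, ground-truth masks as single-channel
#' 0/255 PNGs, and a `manifest.csv` records filename, grade, weight and seed.
#'
#' @param dataset A tibble from [generate_image_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_image_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble::tibble(
    filename = paste0(dataset$sample_id, ".png"),
    mask = paste0(dataset$sample_id, "_mask.png"),
    grade = as.character(dataset$grade),
    weight_g = dataset$weight_g,
    seed = dataset$seed
  )
  for (i in seq_len(nrow(dataset))) {
    png::writePNG(dataset$image[[i]] / 255,
                  file.path(dir, manifest$filename[i]))
    png::writePNG(dataset$mask[[i]], file.path(dir, manifest$mask[i]))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image dataset written by [write_image_dataset()]
#'
#' @param dir Directory containing PNGs and `manifest.csv`.
#' @return A tibble like [generate_image_dataset()]'s.
#' @export
read_image_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  imgs <- purrr::map(man$filename, function(f) {
    arr <- png::readPNG(file.path(dir, f))
    round(arr * 255)
  })
  masks <- purrr::map(man$mask, function(f) {
    m <- png::readPNG(file.path(dir, f))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
  })
  tibble::tibble(
    sample_id = sub("\\.png$", "", man$filename),
    image = imgs, mask = masks, grade = grade_factor(man$grade),
    weight_g = man$weight_g, seed = man$seed
  )
}
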