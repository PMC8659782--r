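# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

oracle_color_moments <- function(values) {
  n <- length(values)
  mu <- 0
  for (v in values) mu <- mu + v / n
  m2 <- m3 <- m4 <- 0
  for (v in values) {
    m2 <- m2 + (v - mu)^2 / n
    m3 <- m3 + (v - mu)^3 / n
    m4 <- m4 + (v - mu)^4 / n
  }
  c(mean = mu, var = m2^(1 / 2),
    s = sign(m3) * abs(m3)^(1 / 3), k = m4^(1 / 4) - 3)
}

# Symmetric co-occurrence probabilities by explicit pixel-pair enumeration.
oracle_glcm <- function(gray, mask, d, theta, levels) {
  q <- floor(pmin(pmax(gray, 0), 255) * levels / 256)
  q <- pmin(q, levels - 1)
  off <- list("0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
              "135" = c(-d, -d))[[as.character(theta)]]
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (mask[r, cc] != 1 || mask[r2, c2] != 1) next
      i <- q[r, cc] + 1; j <- q[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(f) {
  L <- nrow(f)
  hom <- con <- dis <- ent <- ene <- aut <- 0
  mu_x <- mu_y <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- f[i + 1, j + 1]
    hom <- hom + p / (1 + (i - j)^2)
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    if (p > 0) ent <- ent - p * log10(p)
    ene <- ene + p^2
    aut <- aut + i * j * p
    mu_x <- mu_x + i * p
    mu_y <- mu_y + j * p
  }
  v_x <- v_y <- cor_num <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- f[i + 1, j + 1]
    v_x <- v_x + (i - mu_x)^2 * p
    v_y <- v_y + (j - mu_y)^2 * p
    cor_num <- cor_num + (i - mu_x) * (j - mu_y) * p
  }
  corr <- if (sqrt(v_x) < 1e-12 || sqrt(v_y) < 1e-12) 1 else
    cor_num / (sqrt(v_x) * sqrt(v_y))
  c(Homogeneity = hom, Contrast = con, Dissimilarity = dis, Entropy = ent,
    Energy = ene, Correlation = corr, Auto_Correlation = aut)
}

# Exhaustive Otsu: try every split t and maximize between-class variance.
oracle_otsu <- function(gray) {
  v <- round(pmin(pmax(as.numeric(gray), 0), 255))
  best_t <- -1
  best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

jaccard <- function(a, b) sum(a * b) / sum(pmax(a, b))

# A solid rectangular mask inside an h x w canvas.
rect_mask <- function(h, w, top, left, height, width) {
  m <- matrix(0, h, w)
  m[top:(top + height - 1), left:(left + width - 1)] <- 1
  m
}

# Rasterised square rotated by `angle` (radians) about the canvas center.
rotated_square_mask <- function(canvas, side, angle) {
  ctr <- canvas / 2
  xs <- matrix(rep(seq_len(canvas), each = canvas), canvas) - ctr
  ys <- matrix(rep(seq_len(canvas), times = canvas), canvas) - ctr
  xr <- cos(angle) * xs + sin(angle) * ys
  yr <- -sin(angle) * xs + cos(angle) * ys
  matrix(as.numeric(abs(xr) <= side / 2 & abs(yr) <= side / 2),
         canvas, canvas)
}

# Small synthetic image spec that keeps image tests fast.
small_image_spec <- function(canvas = 160) synthetic_image_spec(canvas = canvas)

# Planted fixture matching the selection study conditions.
planted_fixture <- function(seed, ...) {
  generate_feature_table(planted_table_spec(seed = seed, ...))
}

# Two separated Gaussian blobs per grade in 2-D, as a feature table.
blob_table <- function(n_per_class = 25, classes = c("I", "II"), sep = 6,
                       seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(classes), function(i) {
      tibble::tibble(
        x1 = rnorm(n_per_class, sep * i), x2 = rnorm(n_per_class, -sep * i),
        grade = factor(classes[i], levels = c("I", "II", "III", "IV")))
    })
    dplyr::bind_rows(rows)
  })
}
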