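#' @keywords internal
"_PACKAGE"

#' @useDynLib rootgrader, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif rbinom sd wilcox.test lm add1 drop1 predict
#' @importFrom utils head modifyList
NULL

# Grade labels, best (largest roots) first.
GRADE_LEVELS <- c("I", "II", "III", "IV")

grade_factor <- function(x) factor(as.character(x), levels = GRADE_LEVELS)

# Numeric coding used wherever a regression treats grade as a response:
# I -> 1 ... IV -> 4.
grade_code <- function(grade) {
  if (is.numeric(grade)) return(as.numeric(grade))
  g <- grade_factor(grade)
  if (anyNA(g)) abort("grade labels must be one of I, II, III, IV")
  as.numeric(g)
}

# Deterministic sub-seed for a named pipeline stage, so adding a stage never
# perturbs the random stream of earlier stages.  Polynomial string hash mod a
# Mersenne prime; always a valid 32-bit seed.
derive_seed <- function(master, stage) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

check_rgb_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    abort(sprintf("`%s` must be a height x width x 3 array", arg))
  if (dim(img)[1] < 32L || dim(img)[2] < 32L)
    abort(sprintf("`%s` must be at least 32 x 32", arg))
  rng <- range(img)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    abort(sprintf("`%s` values must lie in [0, 255]", arg))
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    abort(sprintf("`%s` must be a {0,1} matrix", arg))
  invisible(mask)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Feature columns of a feature table: everything except identifiers/label.
feature_columns <- function(table) {
  setdiff(names(table), c("sample_id", "grade", "weight_g", "seed"))
}

root_mean_square <- function(e) sqrt(mean(e^2))
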