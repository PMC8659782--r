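#' Specification of a planted-signal feature table
#'
#' Defines a synthetic samples x features table in which the grade label is
#' carried only by a known set of informative columns, with the remaining
#' columns independent noise.  These tables are the ground-truth fixtures for
#' the IRIV / VISSA / stepwise selectors: a selector is judged by how many of
#' the planted informative columns it recovers and how few noise columns it
#' keeps.
#'
#' Construction: each sample gets a grade code y in {1,2,3,4} (balanced);
#' informative column j equals `w_j * y` plus Gaussian noise of standard
#' deviation `noise_sd`, with distinct fixed weights `w_j`, so the label is a
#' thresholded linear function of the informative columns (and exactly linear
#' when `noise_sd = 0`); noise columns are independent standard normal draws.
#'
#' @param n_samples Number of rows (>= 4 x `n_classes`).
#' @param n_informative,n_noise Counts of informative and noise columns
#'   (their sum must be >= 1).
#' @param noise_sd Standard deviation of the noise added to informative
#'   columns (label units; y spans 1-4).
#' @param n_classes Number of grade classes (fixed at 4 grades by default).
#' @param seed Integer seed.
#' @return An object of class `planted_table_spec`.
#' @export
planted_table_spec <- function(n_samples = 200L, n_informative = 5L,
                               n_noise = 35L, noise_sd = 0.5,
                               n_classes = 4L, seed = 1L) {
  stopifnot(n_informative >= 0, n_noise >= 0, n_informative + n_noise >= 1,
            noise_sd >= 0, n_classes >= 2, n_classes <= 4)
  if (n_samples < 4L * n_classes)
    abort("`n_samples` must be at least 4 x `n_classes`")
  structure(
    list(n_samples = as.integer(n_samples),
         n_informative = as.integer(n_informative),
         n_noise = as.integer(n_noise), noise_sd = noise_sd,
         n_classes = as.integer(n_classes), seed = as.integer(seed)),
    class = "planted_table_spec"
  )
}

#' Generate a planted-signal feature table
#'
#' @param spec A [planted_table_spec()].
#' @return A tibble with `sample_id`, feature columns `inf_*` and `noise_*`,
#'   and a `grade` factor.  The planted informative column names are recorded
#'   in `attr(, "informative")`.
#' @export
#' @examples
#' tab <- generate_feature_table(planted_table_spec(n_samples = 40, seed = 2))
#' attr(tab, "informative")
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "planted_table_spec"))
  p_inf <- spec$n_informative
  p_noise <- spec$n_noise
  n <- spec$n_samples
  withr::with_seed(spec$seed, {
    y <- sample(rep(seq_len(spec$n_classes), length.out = n))
    cols <- list()
    if (p_inf > 0) {
      w <- seq(0.6, 1.4, length.out = p_inf)
      for (j in seq_len(p_inf))
        cols[[paste0("inf_", j)]] <- w[j] * y + rnorm(n, 0, spec$noise_sd)
    }
    if (p_noise > 0) {
      for (j in seq_len(p_noise))
        cols[[paste0("noise_", j)]] <- rnorm(n)
    }
    out <- tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)),
                          !!!cols,
                          grade = grade_factor(GRADE_LEVELS[y]))
    attr(out, "informative") <- names(cols)[seq_len(p_inf)]
    out
  })
}
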