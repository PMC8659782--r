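#' Commercial grading standard for Panax notoginseng taproots
#'
#' The market grades taproots by per-root weight and by "head count", the
#' number of roots per 500 g.  Grade I is the largest and most valuable.
#' Weight floors strictly decrease and head-count ceilings strictly increase
#' from grade I to IV.
#'
#' @return A tibble with columns `grade` (factor I-IV), `min_weight_g`
#'   (per-root weight floor in grams) and `max_heads` (maximum roots per
#'   500 g).
#' @export
#' @examples
#' grading_standard()
grading_standard <- function() {
  tibble::tibble(
    grade        = grade_factor(GRADE_LEVELS),
    min_weight_g = c(25.0, 17.0, 12.5, 8.5),
    max_heads    = c(20L, 30L, 40L, 60L)
  )
}

#' Assign a commercial grade from root weight
#'
#' A root of at least 25 g is grade I, at least 17 g grade II, at least
#' 12.5 g grade III and at least 8.5 g grade IV.  Lighter roots are below
#' standard and ungradable.
#'
#' @param weight_g Numeric vector of per-root weights in grams; must be
#'   positive.
#' @return Factor of grades with levels `I`, `II`, `III`, `IV`.
#' @export
#' @examples
#' assign_grade(c(25, 17, 12.5, 8.5))
assign_grade <- function(weight_g) {
  if (!is.numeric(weight_g) || any(!is.finite(weight_g)) || any(weight_g <= 0))
    abort("`weight_g` must be positive and finite")
  std <- grading_standard()
  if (any(weight_g < min(std$min_weight_g)))
    abort(sprintf(
      "weight below the grade-IV floor (%.1f g): root is below standard",
      min(std$min_weight_g)
    ))
  idx <- vapply(weight_g, function(w) which(w >= std$min_weight_g)[1], 1L)
  std$grade[idx]
}

# Draw a weight whose assigned grade is `grade`: uniform between the grade's
# floor and the next grade's floor (grade I: floor to 1.5 x floor, the
# standard being open above).
draw_grade_weight <- function(grade, n = 1L) {
  std <- grading_standard()
  i <- match(as.character(grade), as.character(std$grade))
  lo <- std$min_weight_g[i]
  hi <- if (i == 1L) 1.5 * lo else std$min_weight_g[i - 1L]
  runif(n, lo, hi)
}
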