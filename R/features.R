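#' Canonical feature names and fusion subsets
#'
#' The pipeline's fused feature vector has 40 named entries in one fixed
#' order: 9 shape/size descriptors, 24 color moments (R, G, B, H, S, V by
#' mean/var/s/k) and 7 texture statistics.  The fusion subsets follow the
#' standard comparison layout: shape only (9), shape + texture (16),
#' shape + color (33) and all (40).
#'
#' @param subset One of `"all"`, `"shape"`, `"color"`, `"texture"`,
#'   `"shape_texture"`, `"shape_color"`.
#' @return Character vector of canonical column names.
#' @export
#' @examples
#' length(feature_names())            # 40
#' length(feature_names("shape_texture"))  # 16
feature_names <- function(subset = c("all", "shape", "color", "texture",
                                     "shape_texture", "shape_color")) {
  subset <- match.arg(subset)
  shape <- c("A", "Perimeter", "Rect_w", "Rect_h", "Min_w", "Min_h",
             "E", "Duty", "Radius")
  color <- as.vector(t(outer(c("R", "G", "B", "H", "S", "V"),
                             c("mean", "var", "s", "k"), paste0)))
  texture <- c("Homogeneity", "Contrast", "Dissimilarity", "Entropy",
               "Energy", "Correlation", "Auto_Correlation")
  switch(subset,
         all = c(shape, color, texture),
         shape = shape,
         color = color,
         texture = texture,
         shape_texture = c(shape, texture),
         shape_color = c(shape, color))
}

#' Extract the fused 40-feature vector from one image
#'
#' Runs the full preprocessing chain, then concatenates shape (9), color (24)
#' and texture (7) features in the canonical column order.
#'
#' @param img Height x width x 3 array, values 0-255.
#' @param config Preprocessing/extraction overrides: the [preprocess()] keys
#'   plus `glcm_d` (2), `glcm_levels` (64) and `glcm_window` (NULL).
#' @return A one-row tibble with the 40 canonical feature columns.
#' @export
extract_features <- function(img, config = list()) {
  cfg <- modifyList(list(glcm_d = 2L, glcm_levels = 64L, glcm_window = NULL),
                    config)
  pre <- preprocess(img, cfg)
  dplyr::bind_cols(
    extract_shape_features(pre$mask),
    extract_color_features(pre$rgb, pre$mask),
    extract_texture_features(pre$gray, pre$mask, d = cfg$glcm_d,
                             levels = cfg$glcm_levels,
                             window = cfg$glcm_window)
  )[, feature_names("all")]
}

#' Extract a feature table from an image dataset
#'
#' @param dataset Tibble with list-column `image` plus `sample_id` and
#'   `grade` (as produced by [generate_image_dataset()] or
#'   [read_image_dataset()]).
#' @param config Passed to [extract_features()].
#' @return A tibble: `sample_id`, the 40 canonical feature columns, `grade`.
#' @export
extract_feature_table <- function(dataset, config = list()) {
  feats <- purrr::map(dataset$image, extract_features, config = config)
  dplyr::bind_cols(
    tibble::tibble(sample_id = dataset$sample_id),
    dplyr::bind_rows(feats),
    tibble::tibble(grade = grade_factor(dataset$grade))
  )
}

#' Restrict a feature table to a fusion subset
#'
#' @param table A feature table.
#' @param subset A subset name accepted by [feature_names()].
#' @return The table with only the subset's feature columns (identifier and
#'   grade columns are kept).
#' @export
fusion_subset <- function(table, subset = "all") {
  wanted <- feature_names(subset)
  missing <- setdiff(wanted, names(table))
  if (length(missing) > 0L)
    abort(sprintf("table lacks canonical columns: %s",
                  paste(missing, collapse = ", ")))
  keep <- intersect(c("sample_id", wanted, "grade"), names(table))
  table[, keep]
}

#' Write and read feature tables as CSV
#'
#' Values are serialized at 15 significant digits so tables round-trip to
#' within floating-point display precision.
#'
#' @param table A feature table.
#' @param path CSV file path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` returns the tibble with `grade` as a factor.
#' @export
write_feature_csv <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(raw)
  if ("grade" %in% names(out)) out$grade <- grade_factor(out$grade)
  out
}
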