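# End-to-end orchestration: synthesize/ingest -> preprocess + extract ->
# split -> select -> tune -> train -> evaluate.

#' Pipeline configuration
#'
#' @param input Data source: a [synthetic_image_spec()] (images are
#'   generated), a feature table (data frame), a path to a feature CSV, or a
#'   path to an image-dataset directory written by [write_image_dataset()].
#' @param n_per_grade Images per grade when `input` is a synthetic spec.
#' @param fusion Fusion subset: `"shape"` (9 features), `"shape_texture"`
#'   (16), `"shape_color"` (33) or `"all"` (40).
#' @param selection Feature selector: `"none"`, `"iriv"`, `"vissa"` or
#'   `"sra"`.
#' @param classifier `"svm"`, `"elm"` or `"bp"`.
#' @param tuner `"none"`, `"gwo"`, `"ga"` or `"pso"` (SVM only).
#' @param split Training fraction of the stratified split.
#' @param seed Master seed; every stochastic stage uses a sub-seed derived
#'   from it and the stage name, so adding a stage never perturbs earlier
#'   stages.
#' @param svm_cost,svm_gamma Untuned SVM parameters (gamma defaults to
#'   1/n_features).
#' @param tune_pop,tune_iters Population and iterations for the tuner.
#' @param extract_config Overrides passed to [extract_features()].
#' @param out_dir Optional directory for the JSON run report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = synthetic_image_spec(),
                            n_per_grade = 100L,
                            fusion = c("all", "shape", "shape_texture",
                                       "shape_color"),
                            selection = c("iriv", "none", "vissa", "sra"),
                            classifier = c("svm", "elm", "bp"),
                            tuner = c("gwo", "none", "ga", "pso"),
                            split = 0.7, seed = 1L, svm_cost = 1,
                            svm_gamma = NULL, tune_pop = 20L,
                            tune_iters = 100L, extract_config = list(),
                            out_dir = NULL) {
  cfg <- list(input = input, n_per_grade = as.integer(n_per_grade),
              fusion = match.arg(fusion), selection = match.arg(selection),
              classifier = match.arg(classifier), tuner = match.arg(tuner),
              split = split, seed = as.integer(seed), svm_cost = svm_cost,
              svm_gamma = svm_gamma, tune_pop = as.integer(tune_pop),
              tune_iters = as.integer(tune_iters),
              extract_config = extract_config, out_dir = out_dir)
  if (cfg$tuner != "none" && cfg$classifier != "svm")
    abort("tuners apply to the SVM classifier only")
  structure(cfg, class = "pipeline_config")
}

# Resolve the configured input into a feature table.
resolve_features <- function(cfg) {
  input <- cfg$input
  if (inherits(input, "synthetic_image_spec")) {
    dataset <- generate_image_dataset(input, cfg$n_per_grade,
                                      seed = derive_seed(cfg$seed, "synth"))
    return(extract_feature_table(dataset, cfg$extract_config))
  }
  if (is.character(input)) {
    if (dir.exists(input)) {
      dataset <- read_image_dataset(input)
      return(extract_feature_table(dataset, cfg$extract_config))
    }
    return(read_feature_csv(input))
  }
  if (is.data.frame(input)) return(tibble::as_tibble(input))
  abort("unsupported `input`: use a synthetic spec, table, CSV or directory")
}

train_classifier <- function(cfg, train_tab, cost, gamma) {
  switch(cfg$classifier,
         svm = train_svm(train_tab, cost = cost, gamma = gamma),
         elm = train_elm(train_tab, seed = derive_seed(cfg$seed, "elm")),
         bp = train_bp(train_tab, seed = derive_seed(cfg$seed, "bp")))
}

#' Run the full grading pipeline
#'
#' Executes the configured stages in order: data synthesis or ingestion,
#' feature extraction, fusion subsetting, stratified splitting, feature
#' selection on the training set, hyperparameter tuning on the training set,
#' final training and evaluation on both sides of the split.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` with the configuration echo, feature counts before
#'   and after selection, selected names, tuned (c, g), train/test
#'   evaluation reports and stage timings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      abort(sprintf("stage `%s` failed: %s", stage, conditionMessage(e))))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  features <- clock("features", resolve_features(config))
  features <- clock("fusion", fusion_subset(features, config$fusion))
  n_before <- length(feature_columns(features))
  split <- clock("split", stratified_split(
    features, config$split, seed = derive_seed(config$seed, "split")))

  sel <- NULL
  if (config$selection != "none") {
    sel_seed <- derive_seed(config$seed, "selection")
    sel <- clock("selection", switch(config$selection,
      iriv = iriv_select(split$train, seed = sel_seed),
      vissa = vissa_select(split$train, seed = sel_seed),
      sra = sra_select(split$train, seed = sel_seed)))
    keep <- intersect(c("sample_id", sel$selected, "grade"), names(features))
    split$train <- split$train[, keep]
    split$test <- split$test[, keep]
  }
  n_after <- length(feature_columns(split$train))

  tuned <- NULL
  cost <- config$svm_cost
  gamma <- config$svm_gamma
  if (config$tuner != "none") {
    tuned <- clock("tune", tune_svm(
      split$train, algorithm = config$tuner, pop = config$tune_pop,
      iters = config$tune_iters, seed = derive_seed(config$seed, "tune")))
    cost <- unname(tuned$best[1])
    gamma <- unname(tuned$best[2])
  }
  model <- clock("train", train_classifier(config, split$train, cost, gamma))
  train_report <- clock("evaluate_train", evaluate(model, split$train))
  test_report <- clock("evaluate_test", evaluate(model, split$test))

  report <- structure(
    list(config = config, n_features_before = n_before,
         n_features_after = n_after,
         selected = if (is.null(sel)) feature_columns(split$train) else
           sel$selected,
         selection = sel, tuning = tuned,
         cost = cost, gamma = gamma, model = model,
         train_report = train_report, test_report = test_report,
         timings = unlist(timings),
         version = as.character(utils::packageVersion("rootgrader"))),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  features: %d -> %d (%s selection)\n", x$n_features_before,
              x$n_features_after, x$config$selection))
  if (!is.null(x$tuning))
    cat(sprintf("  tuned (c, g) = (%.4g, %.4g) by %s\n", x$cost, x$gamma,
                x$tuning$algorithm))
  cat(sprintf("  train accuracy: %.3f%%   test accuracy: %.3f%%\n",
              x$train_report$accuracy, x$test_report$accuracy))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes `run_report.json` (configuration echo, feature counts, selected
#' names, tuned parameters, accuracies and confusion matrices; timings are
#' excluded so reports from identical seeds are byte-identical).
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  payload <- list(
    config = list(fusion = cfg$fusion, selection = cfg$selection,
                  classifier = cfg$classifier, tuner = cfg$tuner,
                  split = cfg$split, seed = cfg$seed),
    n_features_before = report$n_features_before,
    n_features_after = report$n_features_after,
    selected = report$selected,
    cost = report$cost, gamma = report$gamma,
    train_accuracy = report$train_report$accuracy,
    test_accuracy = report$test_report$accuracy,
    train_confusion = report$train_report$confusion,
    test_confusion = report$test_report$confusion,
    version = report$version
  )
  path <- file.path(dir, "run_report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Compare fusion subsets on one shared split
#'
#' Trains and evaluates the configured classifier on each fusion subset,
#' with a single seeded stratified split shared by all subsets so the
#' comparison is paired.
#'
#' @param config A [pipeline_config()]; its `selection` and `tuner` are
#'   ignored here (the comparison is between raw fusion subsets).
#' @param subsets Character vector of at least two subset names (a single
#'   subset gives a one-row table).
#' @return A tibble with one row per subset: `fusion`, `n_features`,
#'   `train_accuracy`, `test_accuracy`.
#' @export
compare_fusions <- function(config,
                            subsets = c("shape", "shape_texture",
                                        "shape_color", "all")) {
  stopifnot(inherits(config, "pipeline_config"), length(subsets) >= 1L)
  features <- resolve_features(config)
  split <- stratified_split(features, config$split,
                            seed = derive_seed(config$seed, "split"))
  purrr::map_dfr(subsets, function(s) {
    tr <- fusion_subset(split$train, s)
    te <- fusion_subset(split$test, s)
    model <- train_classifier(config, tr, config$svm_cost, config$svm_gamma)
    tibble::tibble(
      fusion = s,
      n_features = length(feature_columns(tr)),
      train_accuracy = evaluate(model, tr)$accuracy,
      test_accuracy = evaluate(model, te)$accuracy
    )
  })
}
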