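# Pipeline configuration and the two batch entry points: feature
# extraction over an image directory and train/evaluate over a feature
# table. A thin command-line wrapper lives in inst/cli/tumortexture.R.

#' Pipeline configuration
#'
#' Bundles every tunable of the extraction + classification pipeline. The
#' reference configuration (all defaults) produces the 1547-feature
#' composite vector.
#'
#' @param glcm A [glcm_config()].
#' @param lbp List with `sampling_points` (8) and `radius` (1); only the
#'   reference LBP configuration is supported.
#' @param include_nonlinear Add the log-transform block (default `FALSE`).
#' @param nonlinear_mode `"append"` (length 1552) or `"substitute"` the raw
#'   GLCM block (length 1547).
#' @param svm List with `C` (cost, default 1) and `seed`.
#' @param split A [split_spec()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(glcm = glcm_config(),
                            lbp = list(sampling_points = 8L, radius = 1L),
                            include_nonlinear = FALSE,
                            nonlinear_mode = c("append", "substitute"),
                            svm = list(C = 1.0, seed = 1L),
                            split = split_spec()) {
  structure(list(glcm = glcm, lbp = lbp,
                 include_nonlinear = isTRUE(include_nonlinear),
                 nonlinear_mode = match.arg(nonlinear_mode),
                 svm = svm, split = split),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Lossless round trip; unknown keys are rejected so stale config files
#' cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return [pipeline_config()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("glcm", "lbp", "include_nonlinear", "nonlinear_mode", "svm",
             "split")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  gl <- raw$glcm %||% list()
  sp <- raw$split %||% list()
  pipeline_config(
    glcm = do.call(glcm_config, gl),
    lbp = raw$lbp %||% list(sampling_points = 8L, radius = 1L),
    include_nonlinear = raw$include_nonlinear %||% FALSE,
    nonlinear_mode = raw$nonlinear_mode %||% "append",
    svm = raw$svm %||% list(C = 1.0, seed = 1L),
    split = do.call(split_spec, sp))
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  out <- list(glcm = unclass(config$glcm), lbp = config$lbp,
              include_nonlinear = config$include_nonlinear,
              nonlinear_mode = config$nonlinear_mode,
              svm = config$svm, split = unclass(config$split))
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract composite features for a directory of images
#'
#' Images are discovered either through a `manifest.csv`
#' (columns `source_id`/`path`, `label`) in `input_dir` or, failing that,
#' from class-named subdirectories. Unreadable images are skipped with a
#' warning and counted. The resulting [feature_table()] is written as CSV.
#'
#' @param input_dir Directory of images.
#' @param output_csv Output feature-table path.
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-100-image progress lines.
#' @return The [feature_table()], invisibly; attribute `skipped` counts
#'   unreadable files.
#' @export
run_extract <- function(input_dir, output_csv,
                        config = pipeline_config(), quiet = FALSE) {
  manifest <- file.path(input_dir, "manifest.csv")
  if (file.exists(manifest)) {
    mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    path_col <- if ("path" %in% names(mf)) mf$path else mf$source_id
    files <- file.path(input_dir, path_col)
    labels <- mf$label
    ids <- if ("source_id" %in% names(mf)) mf$source_id else basename(files)
  } else {
    subdirs <- list.dirs(input_dir, recursive = FALSE)
    files <- unlist(lapply(subdirs, list.files, full.names = TRUE,
                           pattern = "\\.(png|tif|tiff|jpe?g)$",
                           ignore.case = TRUE))
    if (length(files) == 0L)
      stop("no images found under ", input_dir, call. = FALSE)
    labels <- basename(dirname(files))
    ids <- basename(files)
  }
  if (length(files) == 0L)
    stop("no images found under ", input_dir, call. = FALSE)

  rows <- list(); kept_lab <- c(); kept_id <- c(); skipped <- 0L
  for (i in seq_along(files)) {
    v <- tryCatch(
      composite_vector(load_grayscale(files[i], config$glcm$levels), config),
      error = function(e) {
        warning("skipping ", files[i], ": ", conditionMessage(e))
        NULL
      })
    if (is.null(v)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- v
    kept_lab <- c(kept_lab, labels[i]); kept_id <- c(kept_id, ids[i])
    if (!quiet && length(rows) %% 100L == 0L)
      message(length(rows), " images processed")
  }
  if (length(rows) == 0L) stop("no readable images", call. = FALSE)
  tab <- feature_table(kept_id, kept_lab, do.call(rbind, rows))
  write_feature_table(tab, output_csv)
  attr(tab, "skipped") <- skipped
  invisible(tab)
}

#' Train and evaluate a linear SVM on a feature table
#'
#' Runs the stratified split, fits the one-vs-rest linear SVM, evaluates
#' the held-out fraction, and writes a metrics JSON (with a provenance
#' block echoing the configuration and package version), the confusion
#' matrix as CSV, and per-class ROC points as CSV. Deterministic for a
#' fixed configuration.
#'
#' @param table_path Path to a feature-table CSV.
#' @param output_dir Directory for `metrics.json`, `confusion.csv`,
#'   `roc_<class>.csv`.
#' @param config A [pipeline_config()].
#' @return The [evaluate()] result, invisibly.
#' @export
run_train_eval <- function(table_path, output_dir,
                           config = pipeline_config()) {
  tab <- read_feature_table(table_path)
  if (length(unique(tab$label)) < 2L)
    stop("feature table has fewer than 2 classes", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  parts <- stratified_split(tab, config$split)
  model <- fit_linear_svm(parts$train, C = config$svm$C,
                          seed = config$svm$seed)
  ev <- evaluate(model, parts$test)

  report <- list(
    provenance = list(
      package = "tumortexture",
      version = as.character(utils::packageVersion("tumortexture")),
      seed = config$split$seed,
      config = list(include_nonlinear = config$include_nonlinear,
                    nonlinear_mode = config$nonlinear_mode,
                    svm_C = config$svm$C,
                    test_fraction = config$split$test_fraction,
                    folds = config$split$folds)),
    n_train = nrow(parts$train), n_test = nrow(parts$test),
    micro_accuracy = ev$metrics$micro_accuracy,
    macro = as.list(ev$metrics$macro),
    per_class = ev$metrics$per_class,
    auc = as.list(ev$roc$auc),
    micro_auc = ev$roc$micro$auc)
  jsonlite::write_json(report, file.path(output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(ev$confusion, file.path(output_dir, "confusion.csv"))
  for (k in names(ev$roc$per_class)) {
    r <- ev$roc$per_class[[k]]
    if (length(r$fpr) > 1L)
      utils::write.csv(data.frame(fpr = r$fpr, tpr = r$tpr),
                       file.path(output_dir, paste0("roc_", k, ".csv")),
                       row.names = FALSE)
  }
  invisible(ev)
}
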