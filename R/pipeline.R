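#' Run configuration
#'
#' Assembles the JSON-serializable configuration consumed by the pipeline
#' commands. Unknown keys in a configuration file are rejected so typos fail
#' loudly rather than silently falling back to defaults.
#'
#' @param cohort a \code{cohort_spec}.
#' @param features a \code{feature_config}.
#' @param model a \code{model_config}.
#' @param guide a \code{guide_spiral}.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_spec(), features = feature_config(),
                       model = model_config(), guide = guide_spiral()) {
  structure(list(cohort = cohort, features = features, model = model,
                 guide = guide), class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Any subset of the sections \code{cohort}, \code{features}, \code{model},
#' \code{guide} (and their fields) may be present; missing fields take the
#' package defaults. Unknown sections or fields are an error.
#'
#' @param path JSON file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("cohort", "features", "model", "guide")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  apply_fields <- function(ctor, fields, sub = NULL) {
    fields <- as.list(fields)
    if (!is.null(sub)) for (nm in names(sub))
      fields[[nm]] <- do.call(sub[[nm]]$ctor, as.list(fields[[nm]]))
    ok <- names(formals(ctor))
    bad <- setdiff(names(fields), ok)
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    do.call(ctor, fields)
  }
  run_config(
    cohort = if (is.null(raw$cohort)) cohort_spec() else
      apply_fields(cohort_spec, raw$cohort,
                   sub = list(non_cts_params = list(ctor = group_params),
                              cts_params = list(ctor = group_params))),
    features = if (is.null(raw$features)) feature_config() else
      apply_fields(feature_config, raw$features),
    model = if (is.null(raw$model)) model_config() else
      apply_fields(model_config, raw$model),
    guide = if (is.null(raw$guide)) guide_spiral() else
      apply_fields(guide_spiral, raw$guide))
}

#' Simulate a cohort to disk
#'
#' Writes one recording CSV per subject plus a manifest CSV
#' (\code{subject_id, label, file, seed}) and a JSON snapshot of the
#' configuration actually used.
#'
#' @param config a \code{run_config}.
#' @param out_dir output directory (created if missing).
#' @param seed optional integer overriding \code{config$cohort$seed}.
#' @return path of the manifest CSV, invisibly.
#' @export
cmd_simulate <- function(config = run_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$cohort$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- simulate_cohort(config$cohort, config$guide)
  files <- vapply(recs, function(r) {
    f <- file.path(out_dir, paste0(r$subject_id, ".csv"))
    write_recording(r, f)
    basename(f)
  }, "")
  manifest <- data.frame(
    subject_id = vapply(recs, `[[`, "", "subject_id"),
    label = vapply(recs, `[[`, "", "label"),
    file = files,
    seed = vapply(seq_along(recs), function(i)
      derive_seed(config$cohort$seed, i), integer(1)))
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  snapshot_config(config, file.path(out_dir, "run_config.json"))
  invisible(mpath)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

snapshot_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Extract feature bundles for every recording in a directory
#'
#' Reads each recording CSV (every \code{*.csv} except the manifest), extracts
#' the four-set feature bundle, and writes one row per subject to
#' \code{features.csv}. Subjects whose extraction fails are reported via
#' \code{message()} and skipped.
#'
#' @param config a \code{run_config}.
#' @param in_dir directory produced by \code{\link{cmd_simulate}} (or any
#'   directory of recording CSVs).
#' @param out_file output CSV path (default \code{features.csv} in
#'   \code{in_dir}).
#' @return path of the features CSV, invisibly.
#' @export
cmd_features <- function(config = run_config(), in_dir,
                         out_file = file.path(in_dir, "features.csv")) {
  paths <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
  paths <- paths[!basename(paths) %in% c("manifest.csv", "features.csv")]
  if (!length(paths)) stop("no recording CSVs found in ", in_dir)
  bundles <- list()
  for (p in paths) {
    b <- tryCatch(
      extract_bundle(read_recording(p), config$guide, config$features),
      error = function(e) {
        message("skipping ", basename(p), ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(b)) bundles[[length(bundles) + 1L]] <- b
  }
  if (!length(bundles)) stop("no recording could be featurized")
  write_bundles(bundles, out_file)
  invisible(out_file)
}

#' Evaluate the screening classifier over all feature-set combinations
#'
#' Reads a features CSV, runs the 15-combination LOOCV/ROC grid, and writes
#' the results table (\code{combinations.csv}), the ROC points of every
#' combination (\code{roc_points.csv}) and a JSON report with the chosen
#' cutoffs and configuration.
#'
#' @param config a \code{run_config}.
#' @param features_file CSV from \code{\link{cmd_features}}.
#' @param out_dir output directory (created if missing).
#' @param permute_labels if TRUE, labels are randomly permuted (seeded by the
#'   cohort seed) before evaluation -- a null run that should give near-chance
#'   AUCs.
#' @return the \code{screen_grid}, invisibly.
#' @export
cmd_evaluate <- function(config = run_config(), features_file, out_dir,
                         permute_labels = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundles <- read_bundles(features_file)
  if (permute_labels) {
    labs <- vapply(bundles, `[[`, "", "label")
    labs <- with_seed(config$cohort$seed, sample(labs))
    for (i in seq_along(bundles)) bundles[[i]]$label <- labs[i]
  }
  grid <- combination_grid(bundles, config$model)
  gout <- as.data.frame(grid)
  gout[c("sensitivity", "specificity", "accuracy")] <-
    lapply(gout[c("sensitivity", "specificity", "accuracy")],
           function(v) round(v, 6))
  gout$auc <- round(gout$auc, 6)
  utils::write.csv(gout, file.path(out_dir, "combinations.csv"),
                   row.names = FALSE, quote = FALSE)
  fits <- attr(grid, "fits")
  roc_rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
    if (is.null(fits[[i]])) return(NULL)
    roc <- fits[[i]]$report$roc
    cbind(combination = grid$combination[i], roc)
  }))
  utils::write.csv(roc_rows, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE, quote = FALSE)
  report <- list(
    model = unclass(config$model),
    permuted = permute_labels,
    combinations = lapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      if (is.null(f)) return(list(combination = grid$combination[i],
                                  failed = TRUE))
      list(combination = grid$combination[i], auc = f$report$auc,
           cutoff = f$report$cutoff,
           sensitivity = f$report$sensitivity,
           specificity = f$report$specificity,
           accuracy = f$report$accuracy)
    }))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(grid)
}
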