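#' Write a cohort to disk (recordings + manifest)
#'
#' Writes every recording with [write_recording()] and a `manifest.csv`
#' mapping each file to its subject metadata (gender, the five binary
#' Fried components) — one row per recording file.
#'
#' @param cohort A list with `subjects` and `recordings` as returned by
#'   [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect Recording file dialect, `"csv_long"` or `"json"`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("csv_long", "json")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "csv_long") "csv" else "json"
  recs <- cohort$recordings
  paths <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    fn <- sprintf("%s_%s_%d.%s", recs$subject_id[i], recs$exercise[i],
                  recs$repetition[i], ext)
    write_recording(recs$recording[[i]], file.path(dir, fn), dialect)
    paths[i] <- fn
  }
  manifest <- dplyr::left_join(
    tibble::tibble(subject_id = recs$subject_id, exercise = recs$exercise,
                   repetition = recs$repetition, path = paths,
                   dialect = dialect),
    cohort$subjects[, c("subject_id", "gender", "age",
                        "WL", "WK", "PE", "SL", "LA")],
    by = "subject_id")
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' @param manifest Path to a `manifest.csv` written by [write_cohort()]
#'   (columns `subject_id`, `exercise`, `repetition`, `path`, `dialect`,
#'   `gender`, `age`, `WL`, `WK`, `PE`, `SL`, `LA`; paths relative to the
#'   manifest).
#' @param on_error `"abort"` stops on the first unreadable recording;
#'   `"skip"` drops it and logs the reason (attribute `"read_log"`).
#' @return A list with `subjects` (labelled via [label_cohort()]) and
#'   `recordings`, shaped like the output of [generate_cohort()].
#' @export
read_cohort <- function(manifest, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(manifest)) {
    abort(paste0("No such manifest: ", manifest),
          class = "frailmotion_io_error")
  }
  m <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "exercise", "repetition", "path", "dialect",
            "gender", "WL", "WK", "PE", "SL", "LA")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0) {
    abort(paste0("Manifest lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "frailmotion_format_error")
  }
  base <- dirname(manifest)
  read_log <- list()
  recs <- lapply(seq_len(nrow(m)), function(i) {
    tryCatch(
      read_recording(file.path(base, m$path[i]), dialect = m$dialect[i],
                     subject_id = m$subject_id[i], exercise = m$exercise[i],
                     repetition = m$repetition[i]),
      error = function(e) {
        if (on_error == "abort") stop(e)
        read_log[[length(read_log) + 1]] <<- tibble::tibble(
          subject_id = m$subject_id[i], exercise = m$exercise[i],
          repetition = m$repetition[i], reason = conditionMessage(e))
        NULL
      })
  })
  ok <- !vapply(recs, is.null, logical(1))
  subjects <- label_cohort(dplyr::distinct(
    m[, c("subject_id", "gender", intersect("age", names(m)),
          "WL", "WK", "PE", "SL", "LA")]))
  structure(
    list(subjects = subjects,
         recordings = tibble::tibble(subject_id = m$subject_id[ok],
                                     exercise = m$exercise[ok],
                                     repetition = m$repetition[ok],
                                     recording = recs[ok])),
    read_log = if (length(read_log)) dplyr::bind_rows(read_log) else
      tibble::tibble(subject_id = character(0), exercise = character(0),
                     repetition = integer(0), reason = character(0)))
}

#' Pipeline configuration
#'
#' A flat key-value configuration driving the three pipeline commands.
#' Every field is validated against the ranges of the owning stage; fields
#' not supplied take the package defaults. Configurations can be read from
#' a YAML file with [read_pipeline_config()]; command-line flags (see the
#' `frailmotion` script in `inst/cli/`) override file values.
#'
#' @param out_dir Working directory for generated data and results.
#' @param ... Overrides of the default fields (see Details in the methods
#'   vignette): `n_per_class`, `classes`, `period_ratio`,
#'   `amplitude_ratio`, `noise_ratio`, `frame_rate`, `dialect`,
#'   `exercises`, `families`, `aggregation`, `nb`, `ns`, `label`,
#'   `classifiers`, `k`, `n_iter`, `holdout_frac`, `repeats`,
#'   `n_subjects`, `n_cycles`, `min_prominence`, `window`, `sigma`,
#'   `durations`, `seed`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = ".", ...) {
  defaults <- list(
    out_dir = out_dir, manifest = NULL, features_csv = NULL,
    n_per_class = 50L, classes = c("healthy", "pre_frail"),
    period_ratio = 1.5, amplitude_ratio = 0.7, noise_ratio = 1.5,
    frame_rate = 30, p_female = 0.65, dialect = "csv_long",
    exercises = exercise_types(),
    families = c("SA", "ED", "JCD", "JTA"),
    aggregation = default_aggregation(), nb = 20L, ns = 150L,
    label = "frailty_class",
    classifiers = classifier_kinds(),
    k = 5L, n_iter = 50L, holdout_frac = 0.25, repeats = 10L,
    n_cycles = 1L, min_prominence = 0.2,
    window = NULL, sigma = NULL, durations = NULL, n_subjects = NULL,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "frailmotion_validation_error")
  }
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_per_class >= 1, cfg$nb >= 1, cfg$ns >= 1,
            cfg$k >= 5, cfg$k <= 10, cfg$n_iter >= 1,
            cfg$holdout_frac > 0, cfg$holdout_frac < 1,
            cfg$repeats >= 1, cfg$min_prominence >= 0,
            cfg$min_prominence < 1)
  lapply(cfg$exercises, assert_exercise)
  if (!cfg$label %in% c("frailty_class", "gender")) {
    abort("label must be frailty_class or gender",
          class = "frailmotion_validation_error")
  }
  bad <- setdiff(cfg$families, c("SA", "ED", "JCD", "JTA"))
  if (length(bad) > 0) {
    abort(paste0("Unknown family: ", paste(bad, collapse = ", ")),
          class = "frailmotion_validation_error")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with flat keys matching [pipeline_config()]
#'   fields.
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$aggregation) && !is.null(names(vals$aggregation))) {
    vals$aggregation <- unlist(vals$aggregation)
  }
  vals <- utils::modifyList(vals, list(...), keep.null = TRUE)
  do.call(pipeline_config, vals)
}

provenance <- function(cfg, extra = list()) {
  c(list(package = "frailmotion",
         version = as.character(utils::packageVersion("frailmotion")),
         config_hash = rlang::hash(unclass(cfg)),
         seed = cfg$seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

#' Pipeline command: simulate a synthetic cohort to disk
#'
#' Generates a cohort under the configured class profiles and writes the
#' recordings, the manifest and a provenance block. A null specification
#' (identical class profiles) is flagged in the log.
#'
#' @param config A `pipeline_config`.
#' @return The manifest path, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$period_ratio == 1 && config$amplitude_ratio == 1 &&
      config$noise_ratio == 1) {
    message("note: null cohort specification (identical class profiles)")
  }
  spec <- cohort_spec(
    n_per_class = config$n_per_class, classes = config$classes,
    profiles = class_profiles(period_ratio = config$period_ratio,
                              amplitude_ratio = config$amplitude_ratio,
                              noise_ratio = config$noise_ratio),
    exercises = config$exercises, frame_rate = config$frame_rate,
    p_female = config$p_female,
    durations = config$durations, seed = config$seed)
  cohort <- generate_cohort(spec)
  dir <- file.path(config$out_dir, "cohort")
  mpath <- write_cohort(cohort, dir, dialect = config$dialect)
  jsonlite::write_json(provenance(config, list(command = "simulate",
                                               manifest = mpath)),
                       file.path(config$out_dir, "simulate_provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("simulated %d subjects -> %s",
                  nrow(cohort$subjects), mpath))
  invisible(mpath)
}

#' Pipeline command: extract the feature table from recordings
#'
#' Reads the manifest, runs smoothing, cycle isolation and feature
#' extraction on every recording (recordings failing cycle detection are
#' skipped with a logged reason), aggregates into the subjects-by-features
#' CSV and writes the extraction log. Histogram ranges are fitted over the
#' extracted subjects and recorded in the provenance block.
#'
#' @param config A `pipeline_config`; `config$manifest` defaults to
#'   `out_dir/cohort/manifest.csv`.
#' @return The feature CSV path, invisibly.
#' @export
cmd_extract <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  mpath <- config$manifest %||% file.path(config$out_dir, "cohort",
                                          "manifest.csv")
  cohort <- read_cohort(mpath, on_error = "skip")
  ts <- extract_track_sets(cohort$recordings, families = config$families,
                           window = config$window, sigma = config$sigma,
                           n_cycles = config$n_cycles,
                           min_prominence = config$min_prominence)
  log <- dplyr::bind_rows(attr(cohort, "read_log"), attr(ts, "log"))
  feats <- build_feature_table(ts, exercises = config$exercises,
                               aggregation = config$aggregation,
                               nb = config$nb)
  feats <- dplyr::left_join(
    feats,
    cohort$subjects[, c("subject_id", "gender", "frailty_class")],
    by = "subject_id")
  fpath <- file.path(config$out_dir, "features.csv")
  readr::write_csv(feats, fpath)
  readr::write_csv(log, file.path(config$out_dir, "extract_log.csv"))
  jsonlite::write_json(
    provenance(config, list(command = "extract",
                            n_subjects = nrow(feats),
                            n_features = length(feature_columns(feats)),
                            n_skipped = nrow(log),
                            hist_ranges_fit = "all extracted subjects")),
    file.path(config$out_dir, "extract_provenance.json"),
    auto_unbox = TRUE, pretty = TRUE)
  if (nrow(log) > 0) {
    warn(sprintf("%d recording(s) skipped during extraction", nrow(log)))
  }
  message(sprintf("extracted %d x %d feature table -> %s",
                  nrow(feats), length(feature_columns(feats)), fpath))
  invisible(fpath)
}

#' Pipeline command: train, tune and evaluate the classifiers
#'
#' Runs [run_experiment()] on the extracted feature CSV and writes the
#' per-repeat report (CSV), its per-cell summary (JSON) and a provenance
#' block.
#'
#' @param config A `pipeline_config`; `config$features_csv` defaults to
#'   `out_dir/features.csv`.
#' @return The `experiment_report`, invisibly.
#' @export
cmd_train_eval <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  fpath <- config$features_csv %||% file.path(config$out_dir, "features.csv")
  if (!file.exists(fpath)) {
    abort(paste0("No feature CSV at ", fpath, "; run cmd_extract() first"),
          class = "frailmotion_io_error")
  }
  feats <- readr::read_csv(fpath, show_col_types = FALSE, progress = FALSE)
  if (!config$label %in% names(feats)) {
    abort(paste0("Feature table lacks label column `", config$label, "`"),
          class = "frailmotion_validation_error")
  }
  subjects <- feats[, c("subject_id",
                        intersect(c("gender", "frailty_class"),
                                  names(feats)))]
  features <- feats[, !names(feats) %in% c("gender", "frailty_class")]
  report <- run_experiment(
    features, subjects, label = config$label,
    classifiers = config$classifiers, ns = config$ns,
    n_subjects = config$n_subjects,
    k = config$k, n_iter = config$n_iter,
    holdout_frac = config$holdout_frac, repeats = config$repeats,
    seed = config$seed)
  rpath <- file.path(config$out_dir, "report.csv")
  readr::write_csv(tibble::as_tibble(report), rpath)
  jsonlite::write_json(
    list(provenance = provenance(config, list(command = "train_eval")),
         summary = glance(report)),
    file.path(config$out_dir, "report_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("report with %d rows -> %s", nrow(report), rpath))
  invisible(report)
}
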