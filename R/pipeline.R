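# Configuration, event-table I/O and end-to-end orchestration.

#' Load the CSV event schema
#'
#' Reads an event table with header
#' `patient_id,date,kind,key,value,unit`. Missing header columns are fatal;
#' malformed rows (unparseable date, non-numeric lab value, unknown kind)
#' are dropped and collected into an error report attached as
#' `attr(x, "row_errors")` with their line numbers.
#'
#' @param path CSV file path.
#' @return Event data frame (`date` parsed to `Date`), with a `row_errors`
#'   attribute (zero-row data frame when everything parsed).
#' @export
load_events <- function(path) {
  ev <- utils::read.csv(path, colClasses = "character")
  need <- c("patient_id", "date", "kind", "key", "value", "unit")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols) > 0L)
    stop("events CSV is missing header column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(ev)) + 1L  # header is line 1
  date <- as.Date(ev$date, format = "%Y-%m-%d")
  bad_date <- is.na(date)
  bad_kind <- !(ev$kind %in% c("visit", "lab", "icd10", "text"))
  bad_lab <- ev$kind == "lab" &
    is.na(suppressWarnings(as.numeric(ev$value)))
  bad <- bad_date | bad_kind | bad_lab
  errors <- data.frame(
    line = line[bad],
    reason = ifelse(bad_date[bad], "unparseable date",
                    ifelse(bad_kind[bad], "unknown kind",
                           "non-numeric lab value")),
    stringsAsFactors = FALSE)
  ev <- ev[!bad, , drop = FALSE]
  ev$date <- date[!bad]
  rownames(ev) <- NULL
  attr(ev, "row_errors") <- errors
  ev
}

#' Load the companion patients table
#'
#' @param path CSV with columns `patient_id`, `birth_year`, `gender` and
#'   optionally `center_id`, `y_true`, `s_observed`, `anchor_date`.
#' @return Data frame.
#' @export
load_patients <- function(path) {
  pt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "birth_year", "gender")
  missing_cols <- setdiff(need, names(pt))
  if (length(missing_cols) > 0L)
    stop("patients CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if ("anchor_date" %in% names(pt)) pt$anchor_date <- as.Date(pt$anchor_date)
  pt
}

#' Build a run configuration
#'
#' All tunables of the pipeline in one validated object: cohort generation,
#' feature engineering (10 bins, 5% prevalence threshold), the model
#' variant and adapter, PU wrapper fractions, and the evaluation design.
#'
#' @param cohort A [cohort_config()] (synthetic mode) or a list
#'   `list(events = path, patients = path)` (real-data mode).
#' @param variant Model variant.
#' @param adapter Adapter name.
#' @param n_bins,prevalence_threshold Feature-engineering settings.
#' @param spy_frac,noise_tol,holdout_frac PU wrapper settings (fractions in
#'   (0, 1)).
#' @param k,reps,threshold Evaluation settings.
#' @param seed Top-level seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       variant = c("baseline", "elkan_noto", "spy"),
                       adapter = "xgboost", n_bins = 10L,
                       prevalence_threshold = .DEFAULT_PREVALENCE_THRESHOLD,
                       spy_frac = .DEFAULT_SPY_FRAC,
                       noise_tol = .DEFAULT_NOISE_TOL,
                       holdout_frac = .DEFAULT_HOLDOUT_FRAC,
                       k = 10L, reps = 10L,
                       threshold = .DEFAULT_DECISION_THRESHOLD, seed = 1L) {
  variant <- match.arg(variant)
  for (fr in c(spy_frac = spy_frac, noise_tol = noise_tol,
               holdout_frac = holdout_frac)) {
    if (!is.finite(fr) || fr <= 0 || fr >= 1)
      stop("PU fractions must lie in (0, 1)", call. = FALSE)
  }
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  cfg <- list(cohort = cohort, variant = variant, adapter = adapter,
              n_bins = as.integer(n_bins),
              prevalence_threshold = prevalence_threshold,
              spy_frac = spy_frac, noise_tol = noise_tol,
              holdout_frac = holdout_frac, k = as.integer(k),
              reps = as.integer(reps), threshold = threshold,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / parse a run configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON by file extension. `read_run_config()`
#' round-trips `write_run_config()` output exactly for synthetic-cohort
#' configurations.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `write_run_config()`: the path, invisibly; `read_run_config()`:
#'   a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (inherits(x$cohort, "cohort_config")) {
    cc <- unclass(x$cohort)
    cc$study_start <- format(cc$study_start)
    cc$study_end <- format(cc$study_end)
    x$cohort <- c(list(mode = "synthetic"), cc)
  } else {
    x$cohort <- c(list(mode = "real"), x$cohort)
  }
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  co <- x$cohort
  cohort <- if (identical(co$mode, "synthetic")) {
    cohort_config(
      n_unlabeled = co$n_unlabeled,
      n_labeled_positive = co$n_labeled_positive,
      hidden_positive_rate = co$hidden_positive_rate,
      n_centers = co$n_centers, window_days = co$window_days,
      visit_rate_case = co$visit_rate_case,
      visit_rate_control = co$visit_rate_control,
      code_specs = as.data.frame(co$code_specs),
      parameter_specs = as.data.frame(co$parameter_specs),
      study_start = as.Date(co$study_start),
      study_end = as.Date(co$study_end), seed = co$seed)
  } else {
    list(events = co$events, patients = co$patients)
  }
  run_config(cohort = cohort, variant = x$variant, adapter = x$adapter,
             n_bins = x$n_bins,
             prevalence_threshold = x$prevalence_threshold,
             spy_frac = x$spy_frac, noise_tol = x$noise_tol,
             holdout_frac = x$holdout_frac, k = x$k, reps = x$reps,
             threshold = x$threshold, seed = x$seed)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full screening pipeline
#'
#' Orchestrates every stage end to end: cohort acquisition (synthetic
#' generation or CSV load), putative-case flagging, two-year window
#' extraction, raw feature aggregation, the class-balanced univariate
#' screen with FDR control, and repeated stratified cross-validation of the
#' configured model variant. All artifacts (windows manifest, feature
#' matrix + schema, univariate table, CV report files, reproducibility
#' manifest) are written under `output_dir` when given. Identical config
#' and seed give identical artifacts.
#'
#' @param config A `run_config`.
#' @param output_dir Output directory, or `NULL` to skip writing.
#' @return List of class `pipeline_result`: `cohort`, `windows_manifest`,
#'   `raw`, `matrix`, `univariate`, `cv`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("cohort", {
    if (inherits(config$cohort, "cohort_config")) {
      generate_cohort(config$cohort)
    } else {
      ev <- load_events(config$cohort$events)
      pt <- load_patients(config$cohort$patients)
      structure(list(patients = pt, events = ev), class = "pu_cohort")
    }
  })
  # flag putative cases from the record itself (text regex + ICD codes)
  flags <- stage("case_finding", {
    sp <- split(cohort$events, cohort$events$patient_id)
    flagged <- vapply(sp, flag_putative_positive, logical(1))
    names(flagged)[flagged]
  })
  cohort$patients$s_observed <- ifelse(
    cohort$patients$patient_id %in% flags, "labeled_positive", "unlabeled")
  # real-data mode may not carry diagnosis dates: anchor flagged patients at
  # their earliest flagging event
  if (!"anchor_date" %in% names(cohort$patients))
    cohort$patients$anchor_date <- as.Date(NA)
  need_anchor <- cohort$patients$s_observed == "labeled_positive" &
    is.na(cohort$patients$anchor_date)
  if (any(need_anchor)) {
    ev <- cohort$events
    is_flag <- (ev$kind == "icd10" &
                  Reduce(`|`, lapply(.PMF_FLAG_CODES,
                                     function(cd) icd_matches(ev$key, cd)))) |
      (ev$kind == "text" & grepl(.PMF_FLAG_REGEX, ev$value))
    first_flag <- tapply(ev$date[is_flag], ev$patient_id[is_flag], min)
    idx <- which(need_anchor)
    cohort$patients$anchor_date[idx] <-
      as.Date(first_flag[cohort$patients$patient_id[idx]],
              origin = "1970-01-01")
  }
  windows <- stage("windows",
                   build_windows(cohort, seed = config$seed + 1L))
  raw <- stage("features", build_raw_features(windows, cohort$patients))
  fm <- stage("feature_matrix",
              build_feature_matrix(raw, n_bins = config$n_bins,
                                   prevalence_threshold =
                                     config$prevalence_threshold))
  uni <- stage("univariate", run_univariate(raw$x, raw$label))
  cv <- stage("evaluation",
              run_cv(raw, variant = config$variant,
                     adapter = config$adapter, k = config$k,
                     reps = config$reps, threshold = config$threshold,
                     seed = config$seed,
                     prevalence_threshold = config$prevalence_threshold,
                     holdout_frac = config$holdout_frac,
                     spy_frac = config$spy_frac,
                     noise_tol = config$noise_tol))
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("pmfscreen")),
                   n_patients = nrow(cohort$patients),
                   n_labeled_positive = length(flags),
                   n_features = ncol(fm$x))
  result <- structure(
    list(cohort = cohort, windows_manifest = windows_manifest(windows),
         raw = raw, matrix = fm, univariate = uni, cv = cv,
         manifest = manifest),
    class = "pipeline_result")
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(result$windows_manifest,
                     file.path(output_dir, "windows.csv"), row.names = FALSE)
    utils::write.csv(cbind(patient_id = fm$patient_id, label = fm$label,
                           fm$x),
                     file.path(output_dir, "feature_matrix.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fm$meta, file.path(output_dir, "feature_schema.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    utils::write.csv(uni, file.path(output_dir, "univariate.csv"),
                     row.names = FALSE)
    write_cv_report(cv, output_dir)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d patients, %d features, variant %s\n",
              x$manifest$n_patients, x$manifest$n_features, x$cv$variant))
  print(x$cv)
  invisible(x)
}
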