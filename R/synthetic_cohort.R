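#' Reference CBC parameter specifications
#'
#' Returns the generative specification for the 22 complete-blood-count (CBC)
#' parameters used throughout the package: per-parameter control and case
#' medians, a log-scale dispersion, and the missingness behaviour of
#' "optional" parameters (those not reported by every analyser/laboratory).
#' Medians and ranges follow published per-patient summaries for a large
#' unlabeled control population and a confirmed-PMF cohort; values are drawn
#' from a log-normal family whose median is the class median, so the
#' generator reproduces those medians by construction.
#'
#' The dispersion is derived once from the published control range as
#' `log(max/min)/6` (a +/- 3 sigma reading of the extremes), with zero minima
#' floored at `median/50` to keep the log family defined.
#'
#' @return A data frame with one row per parameter and columns `name`,
#'   `unit`, `control_median`, `case_median`, `dispersion`, `optional_flag`,
#'   `missing_rate`.
#' @export
#' @examples
#' head(cbc_parameter_specs())
cbc_parameter_specs <- function() {
  # name, unit, control median, control min, control max, case median, optional
  tab <- list(
    list("RBC_blood_t_l",          "T/l",  4.41,  2.88,   5.51,   3.67, FALSE),
    list("HGB_blood_g_dl",         "g/dl", 13.30, 8.60,   16.60,  10.20, FALSE),
    list("HCT_blood_percentage",   "%",    39.50, 26.20,  48.70,  33.60, TRUE),
    list("MCV_blood_fl",           "fl",   89.50, 77.10,  102.00, 91.55, TRUE),
    list("MCH_blood_pg",           "pg",   30.20, 24.40,  34.50,  29.02, TRUE),
    list("MCHC_blood_g_dl",        "g/dl", 33.60, 30.80,  35.90,  31.65, TRUE),
    list("RDW_CV_blood_percentage","%",    13.60, 11.90,  19.90,  19.45, TRUE),
    list("WBC_blood_g_l",          "G/l",  7.67,  3.55,   19.33,  8.00,  FALSE),
    list("NEUT_blood_g_l",         "G/l",  4.68,  1.58,   15.48,  5.53,  FALSE),
    list("LYMPH_blood_g_l",        "G/l",  1.67,  0.50,   3.82,   1.46,  FALSE),
    list("MONO_blood_g_l",         "G/l",  0.60,  0.22,   1.55,   0.72,  FALSE),
    list("BASO_blood_g_l",         "G/l",  0.03,  0.00,   0.10,   0.08,  FALSE),
    list("EO_blood_g_l",           "G/l",  0.11,  0.00,   0.54,   0.12,  FALSE),
    list("NEUT_blood_percentage",  "%",    64.30, 35.01,  89.00,  64.90, FALSE),
    list("LYMPH_blood_percentage", "%",    23.60, 4.90,   49.15,  16.75, FALSE),
    list("MONO_blood_percentage",  "%",    8.10,  3.00,   15.40,  7.60,  FALSE),
    list("EO_blood_percentage",    "%",    1.50,  0.00,   6.90,   1.80,  FALSE),
    list("BASO_blood_percentage",  "%",    0.40,  0.00,   1.30,   1.00,  FALSE),
    list("PLT_blood_g_l",          "G/l",  233.00, 73.50, 468.00, 416.00, FALSE),
    list("PDW_blood_fl",           "fl",   12.30, 9.10,   18.40,  13.30, TRUE),
    list("MPV_blood_fl",           "fl",   10.25, 7.40,   12.65,  11.05, TRUE),
    list("PLCR_blood_percentage",  "%",    28.80, 15.70,  46.60,  33.60, TRUE)
  )
  name <- vapply(tab, `[[`, character(1), 1L)
  unit <- vapply(tab, `[[`, character(1), 2L)
  cmed <- vapply(tab, `[[`, numeric(1), 3L)
  cmin <- vapply(tab, `[[`, numeric(1), 4L)
  cmax <- vapply(tab, `[[`, numeric(1), 5L)
  pmed <- vapply(tab, `[[`, numeric(1), 6L)
  opt  <- vapply(tab, `[[`, logical(1), 7L)
  floor_min <- pmax(cmin, cmed / 50)
  data.frame(
    name = name,
    unit = unit,
    control_median = cmed,
    case_median = pmed,
    dispersion = log(cmax / floor_min) / 6,
    optional_flag = opt,
    missing_rate = ifelse(opt, 0.3, 0),
    stringsAsFactors = FALSE
  )
}

#' Default ICD-10 code emission specification
#'
#' Code-level generative defaults for the seven ICD-10 feature codes carried
#' through the pipeline. `control_rate` is the per-window Bernoulli emission
#' probability for negatives; for positives the emission *odds* are
#' multiplied by `case_odds_multiplier`. The anemia code D64.8 and the
#' diagnostic-observation code Z03 carry an eight-fold odds increase in
#' cases, mirroring the strongest code-level effects seen in confirmed-PMF
#' cohorts; the remainder are common primary-care codes with little or no
#' class signal.
#'
#' @return Data frame with columns `code`, `control_rate`,
#'   `case_odds_multiplier`.
#' @export
default_code_specs <- function() {
  data.frame(
    code = c("D64.8", "Z03", "I10", "E11", "E78", "Z00", "M54"),
    control_rate = c(0.03, 0.03, 0.20, 0.10, 0.08, 0.10, 0.06),
    case_odds_multiplier = c(8, 8, 1.2, 1.2, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Default ICD-10 to phenotype mapping
#'
#' Two-column table mapping ICD-10 codes to the five higher-level phenotypes
#' used as phenotype features (a PheWAS-style rollup). Codes absent from the
#' table remain unmapped.
#'
#' @return Data frame with columns `code`, `phenotype`.
#' @export
default_phewas_mapping <- function() {
  data.frame(
    code = c("D64.8", "Z03", "I10", "E11", "E78"),
    phenotype = c("anemias", "diagnostic_observation", "hypertension",
                  "type2_diabetes", "hyperlipidemia"),
    stringsAsFactors = FALSE
  )
}

#' Cohort generation configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. Defaults
#' describe a desk-scale cohort: one hundredth of the reference population
#' scale (1,100 unlabeled patients instead of 110,000, still spread over 10
#' centers) with 5 labeled positives per center, class-specific visit rates
#' matching published per-window visit medians (3 control vs 5 case visits
#' per two-year window), and a 2% latent-positive rate among unlabeled
#' records so that a desk-scale cohort still contains a usable number of
#' hidden positives.
#'
#' @param n_unlabeled Number of unlabeled patients.
#' @param n_labeled_positive Number of labeled positive patients (>= 1).
#' @param hidden_positive_rate Fraction of unlabeled patients that are latent
#'   positives, in `[0, 1)`.
#' @param n_centers Number of medical centers patients are spread over.
#' @param window_days Length of the analysis window in days.
#' @param visit_rate_case,visit_rate_control Expected visits per year.
#' @param code_specs Data frame as returned by [default_code_specs()].
#' @param parameter_specs Data frame as returned by [cbc_parameter_specs()].
#' @param study_start,study_end Calendar bounds for anchor (diagnosis /
#'   window-end) dates.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_unlabeled = 1100L,
                          n_labeled_positive = 50L,
                          hidden_positive_rate = 0.02,
                          n_centers = 10L,
                          window_days = .DEFAULT_WINDOW_DAYS,
                          visit_rate_case = 2.5,
                          visit_rate_control = 1.5,
                          code_specs = default_code_specs(),
                          parameter_specs = cbc_parameter_specs(),
                          study_start = as.Date("2015-01-01"),
                          study_end = as.Date("2022-12-31"),
                          seed = 1L) {
  cfg <- list(
    n_unlabeled = as.integer(n_unlabeled),
    n_labeled_positive = as.integer(n_labeled_positive),
    hidden_positive_rate = hidden_positive_rate,
    n_centers = as.integer(n_centers),
    window_days = as.integer(window_days),
    visit_rate_case = visit_rate_case,
    visit_rate_control = visit_rate_control,
    code_specs = code_specs,
    parameter_specs = parameter_specs,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Full-scale cohort configuration
#'
#' The reference-population scale (110,000 unlabeled, 67 labeled positives
#' over 10 centers). Expensive to simulate; shipped for completeness.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_config_full_scale <- function(...) {
  cohort_config(n_unlabeled = 110000L, n_labeled_positive = 67L, ...)
}

validate_cohort_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.finite(cfg$n_unlabeled) || cfg$n_unlabeled < 0)
    stop_field("n_unlabeled", "must be a non-negative count")
  if (!is.finite(cfg$n_labeled_positive) || cfg$n_labeled_positive < 1)
    stop_field("n_labeled_positive", "must be >= 1")
  if (!is.numeric(cfg$hidden_positive_rate) ||
      cfg$hidden_positive_rate < 0 || cfg$hidden_positive_rate >= 1)
    stop_field("hidden_positive_rate", "must lie in [0, 1)")
  if (cfg$n_centers < 1) stop_field("n_centers", "must be >= 1")
  if (cfg$window_days < 1) stop_field("window_days", "must be >= 1")
  if (cfg$visit_rate_case < 0) stop_field("visit_rate_case", "must be >= 0")
  if (cfg$visit_rate_control < 0)
    stop_field("visit_rate_control", "must be >= 0")
  if (!is.data.frame(cfg$code_specs) ||
      !all(c("code", "control_rate", "case_odds_multiplier") %in%
           names(cfg$code_specs)))
    stop_field("code_specs", "needs columns code, control_rate, case_odds_multiplier")
  if (any(cfg$code_specs$control_rate < 0 | cfg$code_specs$control_rate > 1))
    stop_field("code_specs", "control_rate must lie in [0, 1]")
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$", cfg$code_specs$code)
  if (any(bad))
    stop_field("code_specs",
               paste("codes not ICD-10-like:",
                     paste(cfg$code_specs$code[bad], collapse = ", ")))
  ps <- cfg$parameter_specs
  if (!is.data.frame(ps) ||
      !all(c("name", "control_median", "case_median", "dispersion",
             "optional_flag", "missing_rate") %in% names(ps)))
    stop_field("parameter_specs", "missing required columns")
  if (any(ps$control_median <= 0 | ps$case_median <= 0))
    stop_field("parameter_specs", "medians must be positive for the log family")
  if (any(ps$dispersion <= 0))
    stop_field("parameter_specs", "dispersion must be positive")
  if (any(ps$missing_rate < 0 | ps$missing_rate > 1))
    stop_field("parameter_specs", "missing_rate must lie in [0, 1]")
  if (!is.finite(cfg$seed)) stop_field("seed", "must be a finite integer")
  invisible(cfg)
}

#' Sample a laboratory-value trajectory for one parameter
#'
#' Values are drawn from a log-normal family whose median equals the class
#' median of `spec` (control median for negatives, case median for latent or
#' labeled positives) with log-scale standard deviation `spec$dispersion`.
#' Optional parameters are independently dropped per visit with probability
#' `spec$missing_rate`. Percentage-type parameters are clipped to `[0, 100]`.
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param spec One row of [cbc_parameter_specs()] (as list or 1-row data
#'   frame).
#' @param visit_dates Vector of `Date`s, one candidate measurement per visit.
#' @param case Logical; draw from the case distribution?
#' @return Data frame with columns `date`, `value` (one row per retained
#'   visit; zero rows when everything is dropped).
#' @export
sample_parameter_trajectory <- function(spec, visit_dates, case = FALSE) {
  spec <- as.list(spec)
  med <- if (isTRUE(case)) spec$case_median else spec$control_median
  if (!is.finite(med) || med <= 0)
    stop(sprintf("parameter '%s': non-positive median for log-normal family",
                 spec$name), call. = FALSE)
  n <- length(visit_dates)
  if (n == 0L)
    return(data.frame(date = as.Date(character()), value = numeric()))
  keep <- stats::runif(n) >= spec$missing_rate
  dates <- visit_dates[keep]
  m <- length(dates)
  if (m == 0L)
    return(data.frame(date = as.Date(character()), value = numeric()))
  values <- exp(stats::rnorm(m, mean = log(med), sd = spec$dispersion))
  if (identical(spec$unit, "%")) values <- pmin(pmax(values, 0), 100)
  data.frame(date = dates, value = values)
}

#' Emit ICD-10 code events for one patient window
#'
#' Each code in `code_specs` is emitted at most once per window, Bernoulli
#' with probability `control_rate` for negatives; for positives the emission
#' odds are multiplied by `case_odds_multiplier`. Emitted codes receive a
#' uniformly sampled date inside `[window_start, anchor_date)`.
#'
#' @param code_specs Data frame as [default_code_specs()].
#' @param case Logical; use the case odds?
#' @param window_start,anchor_date `Date`s bounding the window (half-open).
#' @return Data frame with columns `date`, `code` (zero rows possible).
#' @export
assign_codes <- function(code_specs, case, window_start, anchor_date) {
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$", code_specs$code)
  if (any(bad))
    stop(paste("codes not ICD-10-like:",
               paste(code_specs$code[bad], collapse = ", ")), call. = FALSE)
  p <- code_specs$control_rate
  if (isTRUE(case)) {
    odds <- p / (1 - p) * code_specs$case_odds_multiplier
    p <- ifelse(is.finite(odds), odds / (1 + odds), 1)
    p[code_specs$control_rate == 0] <- 0  # zero base rate stays zero
  }
  emit <- stats::runif(length(p)) < p
  n_days <- max(1L, as.integer(anchor_date - window_start))
  offsets <- sample.int(n_days, sum(emit), replace = TRUE)
  data.frame(
    date = anchor_date - offsets,
    code = code_specs$code[emit],
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic positive-unlabeled longitudinal cohort
#'
#' Simulates a multi-center EHR population with the positive-unlabeled (PU)
#' structure the screening analysis assumes: a small set of labeled
#' positives (confirmed cases carrying a diagnosis marker on their anchor
#' date) and a large unlabeled pool in which a configurable fraction are
#' latent positives. Latent positives use the case distributions for labs,
#' visits, and codes but carry no diagnosis marker and remain
#' `s_observed = "unlabeled"` — the selected-completely-at-random (SCAR)
#' labeling mechanism underpinning Elkan-Noto calibration.
#'
#' Per patient, visit counts are Poisson at the class-specific yearly rate
#' over the window, lab values follow [sample_parameter_trajectory()], and
#' codes follow [assign_codes()]. Labeled positives additionally receive an
#' ICD-10 `D47.1` event and a free-text note matching the case-finding regex
#' on the anchor (diagnosis) date itself, which the half-open analysis
#' window excludes from features.
#'
#' @param config A [cohort_config()].
#' @return An object of class `pu_cohort`: list with `patients` (one row per
#'   patient: `patient_id`, `center_id`, `birth_year`, `gender`, `y_true`,
#'   `s_observed`, `anchor_date`) and `events` (CSV-schema event table:
#'   `patient_id`, `date`, `kind`, `key`, `value`, `unit`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_unlabeled = 50,
#'                                         n_labeled_positive = 5, seed = 1))
#' table(cohort$patients$s_observed)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_pos <- config$n_labeled_positive
  n_unl <- config$n_unlabeled
  n <- n_pos + n_unl

  s_observed <- c(rep("labeled_positive", n_pos), rep("unlabeled", n_unl))
  latent <- stats::runif(n_unl) < config$hidden_positive_rate
  y_true <- c(rep("positive", n_pos),
              ifelse(latent, "positive", "negative"))
  center_id <- sprintf("C%02d", (seq_len(n) - 1L) %% config$n_centers + 1L)
  patient_id <- sprintf("P%06d", seq_len(n))

  span <- as.integer(config$study_end - config$study_start)
  anchor_date <- config$study_start + sample.int(span + 1L, n, replace = TRUE) - 1L
  is_case <- y_true == "positive"
  # ages loosely match published cohort demographics (controls matched to cases)
  age <- ifelse(is_case,
                pmin(pmax(round(stats::rnorm(n, 69, 10)), 40), 88),
                pmin(pmax(round(stats::rnorm(n, 63, 12)), 28), 86))
  birth_year <- as.integer(format(anchor_date, "%Y")) - age
  gender <- ifelse(stats::runif(n) < ifelse(is_case, 0.5373, 0.5165), "F", "M")

  years <- config$window_days / 365.25
  rate <- ifelse(is_case, config$visit_rate_case, config$visit_rate_control)

  # visits: homogeneous Poisson counts per patient, days uniform in-window
  n_visits <- stats::rpois(n, rate * years)
  vpid <- rep.int(seq_len(n), n_visits)
  vdate <- anchor_date[vpid] - sample.int(config$window_days,
                                          length(vpid), replace = TRUE)
  blocks <- list()
  if (length(vpid) > 0L)
    blocks[[1L]] <- data.frame(
      pid = vpid, date = vdate, kind = "visit", key = "visit", value = "",
      unit = "", stringsAsFactors = FALSE)

  # labs: per parameter, one candidate draw per visit; optional parameters
  # independently dropped per visit at their missing rate
  for (j in seq_len(nrow(config$parameter_specs))) {
    sp <- as.list(config$parameter_specs[j, ])
    keep <- stats::runif(length(vpid)) >= sp$missing_rate
    pid <- vpid[keep]
    med <- ifelse(is_case[pid], sp$case_median, sp$control_median)
    vals <- exp(stats::rnorm(length(pid), mean = log(med),
                             sd = sp$dispersion))
    if (identical(sp$unit, "%")) vals <- pmin(pmax(vals, 0), 100)
    if (length(pid) > 0L)
      blocks[[length(blocks) + 1L]] <- data.frame(
        pid = pid, date = vdate[keep], kind = "lab", key = sp$name,
        value = format(vals, digits = 15, trim = TRUE, scientific = FALSE),
        unit = sp$unit, stringsAsFactors = FALSE)
  }

  # ICD-10 codes: at most one emission per code per window, odds multiplied
  # for positives
  for (j in seq_len(nrow(config$code_specs))) {
    cs <- config$code_specs[j, ]
    p0 <- cs$control_rate
    odds <- p0 / (1 - p0) * cs$case_odds_multiplier
    p1 <- if (p0 == 0) 0 else if (is.finite(odds)) odds / (1 + odds) else 1
    p <- ifelse(is_case, p1, p0)
    emit <- which(stats::runif(n) < p)
    if (length(emit) > 0L)
      blocks[[length(blocks) + 1L]] <- data.frame(
        pid = emit,
        date = anchor_date[emit] - sample.int(config$window_days,
                                              length(emit), replace = TRUE),
        kind = "icd10", key = cs$code, value = "", unit = "",
        stringsAsFactors = FALSE)
  }

  # labeled positives carry their diagnosis marker on the anchor day itself
  lp <- which(s_observed == "labeled_positive")
  if (length(lp) > 0L)
    blocks[[length(blocks) + 1L]] <- data.frame(
    pid = rep(lp, 2L), date = rep(anchor_date[lp], 2L),
    kind = rep(c("icd10", "text"), each = length(lp)),
    key = rep(c("D47.1", "diagnosis_note"), each = length(lp)),
    value = rep(c("", "rozpoznanie: mielofibroza"), each = length(lp)),
    unit = "", stringsAsFactors = FALSE)

  events <- do.call(rbind, blocks)
  events$patient_id <- patient_id[events$pid]
  events <- events[order(events$pid, events$date, events$kind, events$key),
                   c("patient_id", "date", "kind", "key", "value", "unit")]
  rownames(events) <- NULL

  patients <- data.frame(
    patient_id = patient_id, center_id = center_id, birth_year = birth_year,
    gender = gender, y_true = y_true, s_observed = s_observed,
    anchor_date = anchor_date, stringsAsFactors = FALSE)
  structure(list(patients = patients, events = events, config = config),
            class = "pu_cohort")
}

#' @export
print.pu_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf(
    "<pu_cohort> %d patients (%d labeled positive, %d unlabeled of which %d latent positive), %d events\n",
    nrow(p), sum(p$s_observed == "labeled_positive"),
    sum(p$s_observed == "unlabeled"),
    sum(p$s_observed == "unlabeled" & p$y_true == "positive"),
    nrow(x$events)))
  invisible(x)
}

#' Write a synthetic cohort to the CSV event schema
#'
#' Emits `events.csv` (columns `patient_id,date,kind,key,value,unit`) and
#' `patients.csv` (demographics plus labels) under `dir`, the same schema
#' [load_events()] and [load_patients()] read back.
#'
#' @param cohort A `pu_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pu_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ef <- file.path(dir, "events.csv")
  pf <- file.path(dir, "patients.csv")
  ev <- cohort$events
  ev$date <- format(ev$date, "%Y-%m-%d")
  utils::write.csv(ev, ef, row.names = FALSE)
  pt <- cohort$patients
  pt$anchor_date <- format(pt$anchor_date, "%Y-%m-%d")
  utils::write.csv(pt, pf, row.names = FALSE)
  invisible(c(events = ef, patients = pf))
}
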