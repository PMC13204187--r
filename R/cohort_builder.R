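# Case-finding, analysis-window extraction, stratified control matching and
# leakage-code exclusion: the steps that turn raw event tables into labeled
# two-year analysis windows.

icd_root <- function(code) substr(code, 1L, 3L)

icd_matches <- function(keys, code) {
  keys == code | startsWith(keys, paste0(code, "."))
}

#' Flag a putative case record
#'
#' A patient record is flagged as a putative case when any free-text event
#' matches the word-boundary pattern `\\b[mM]ielofibroz` (Polish clinical
#' spelling of myelofibrosis) or any ICD-10 event carries one of the
#' case-finding codes C94, C94.4, D47, D47.1, D47.4. A bare root (C94, D47)
#' also matches all of its subcodes.
#'
#' @param events Event data frame with columns `kind`, `key`, `value`.
#' @return `TRUE`/`FALSE`; an empty event table gives `FALSE`.
#' @export
#' @examples
#' ev <- data.frame(kind = "text", key = "note",
#'                  value = "rozpoznanie: mielofibroza")
#' flag_putative_positive(ev)
flag_putative_positive <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(FALSE)
  txt <- events$value[events$kind == "text"]
  if (length(txt) > 0L && any(grepl(.PMF_FLAG_REGEX, txt))) return(TRUE)
  keys <- events$key[events$kind == "icd10"]
  if (length(keys) == 0L) return(FALSE)
  any(vapply(.PMF_FLAG_CODES, function(cd) any(icd_matches(keys, cd)),
             logical(1)))
}

#' Sample a control anchor date
#'
#' Controls have no diagnosis date, so a window-end ("anchor") date is drawn
#' uniformly over the calendar days between the patient's first event and
#' their last visit, guaranteeing the window ends no later than the last
#' visit. Uses the current RNG state.
#'
#' @param events Event data frame for one patient.
#' @return A `Date`.
#' @export
sample_control_anchor <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    stop("cannot place a window for a patient with zero events", call. = FALSE)
  visits <- events$date[events$kind == "visit"]
  last <- if (length(visits) > 0L) max(visits) else max(events$date)
  first <- min(events$date)
  span <- as.integer(last - first)
  first + sample.int(span + 1L, 1L) - 1L
}

#' Extract a patient's analysis window
#'
#' Restricts a patient's events to the half-open interval
#' `[anchor_date - window_days, anchor_date)`. The anchor is the diagnosis
#' date for positives; for controls pass `anchor_date = NULL` to sample one
#' via [sample_control_anchor()]. Events on the anchor day itself are
#' excluded so same-day diagnostic results cannot leak into features. The
#' effective span may be shorter than `window_days` when the record starts
#' late; that is not an error.
#'
#' @param events Event data frame for one patient (columns `patient_id`,
#'   `date`, `kind`, `key`, `value`, `unit`).
#' @param anchor_date `Date` or `NULL` (controls).
#' @param window_days Window length in days.
#' @param label `"positive"` or `"unlabeled"`.
#' @return A list of class `cohort_window`: `patient_id`, `anchor_date`,
#'   `window_start`, `label`, `events` (the retained rows, date-sorted).
#' @export
extract_window <- function(events, anchor_date = NULL,
                           window_days = .DEFAULT_WINDOW_DAYS,
                           label = c("unlabeled", "positive")) {
  label <- match.arg(label)
  if (is.null(events) || nrow(events) == 0L)
    stop("cannot place a window for a patient with zero events", call. = FALSE)
  if (is.null(anchor_date)) anchor_date <- sample_control_anchor(events)
  anchor_date <- as.Date(anchor_date)
  window_start <- anchor_date - window_days
  keep <- events$date >= window_start & events$date < anchor_date
  ev <- events[keep, , drop = FALSE]
  ev <- ev[order(ev$date, ev$kind, ev$key), , drop = FALSE]
  rownames(ev) <- NULL
  structure(
    list(patient_id = if (nrow(events)) events$patient_id[1L] else NA_character_,
         anchor_date = anchor_date, window_start = window_start,
         label = label, events = ev),
    class = "cohort_window")
}

#' Build analysis windows for a whole cohort
#'
#' Applies [extract_window()] per patient: labeled positives anchor at their
#' recorded anchor (diagnosis) date; unlabeled patients get a sampled anchor.
#' Patients with zero events are dropped with a message (they carry no
#' usable history).
#'
#' @param cohort A `pu_cohort`, or a list with `patients` and `events` in
#'   the same schema.
#' @param window_days Window length in days.
#' @param seed Integer seed controlling the control-anchor sampling.
#' @return List of `cohort_window` objects.
#' @export
build_windows <- function(cohort, window_days = .DEFAULT_WINDOW_DAYS,
                          seed = 1L) {
  set.seed(seed)
  ev_split <- split(cohort$events, cohort$events$patient_id)
  pts <- cohort$patients
  out <- vector("list", nrow(pts))
  kept <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    pev <- ev_split[[pts$patient_id[i]]]
    if (is.null(pev) || nrow(pev) == 0L) next
    if (pts$s_observed[i] == "labeled_positive") {
      out[[i]] <- extract_window(pev, anchor_date = pts$anchor_date[i],
                                 window_days = window_days,
                                 label = "positive")
    } else {
      out[[i]] <- extract_window(pev, anchor_date = NULL,
                                 window_days = window_days,
                                 label = "unlabeled")
    }
    kept[i] <- TRUE
  }
  if (any(!kept))
    message(sum(!kept), " patient(s) without events dropped from windowing")
  out[kept]
}

#' Stratified age/gender control matching
#'
#' Samples `n_total` controls from `candidates` so that the joint
#' distribution over strata (age decade x gender) matches the positive
#' cohort's stratum shares. Per-stratum quotas are apportioned by the
#' largest-remainder rule and sampled without replacement.
#'
#' @param candidates Data frame with `patient_id`, `age`, `gender`.
#' @param positives Data frame with `age`, `gender` for the positive cohort.
#' @param n_total Number of controls to draw.
#' @param seed Integer seed.
#' @return Character vector of sampled `patient_id`s.
#' @export
sample_matched_controls <- function(candidates, positives, n_total, seed = 1L) {
  if (n_total > nrow(candidates))
    stop("n_total exceeds the candidate pool size", call. = FALSE)
  stratum <- function(df) paste0(df$gender, ":", (df$age %/% 10L) * 10L)
  pos_s <- stratum(positives)
  cand_s <- stratum(candidates)
  shares <- table(pos_s) / length(pos_s)
  exact <- as.numeric(shares) * n_total
  quota <- floor(exact)
  rem <- n_total - sum(quota)
  if (rem > 0L) {
    extra <- order(exact - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  names(quota) <- names(shares)
  set.seed(seed)
  picked <- character(0)
  for (s in names(quota)) {
    q <- quota[[s]]
    if (q == 0L) next
    pool <- candidates$patient_id[cand_s == s]
    if (length(pool) == 0L)
      stop(sprintf("stratum '%s' has positive mass but zero candidates", s),
           call. = FALSE)
    if (length(pool) < q)
      stop(sprintf("stratum '%s' has only %d candidates for a quota of %d",
                   s, length(pool), q), call. = FALSE)
    picked <- c(picked, sample(pool, q))
  }
  picked
}

#' Remove diagnosis-leaking ICD-10 codes
#'
#' Drops every code whose 3-character root is D45, D46, D47, in D70-D77, or
#' in C81-C96 — codes so indicative of hematologic malignancy that keeping
#' them as features would leak the label. Subcodes inherit their root's
#' fate; all other codes pass through unchanged.
#'
#' @param code_keys Character vector of ICD-10 codes.
#' @return The retained codes, in input order.
#' @export
#' @examples
#' exclude_leakage_codes(c("D47.1", "C90.0", "Z03", "E11"))
exclude_leakage_codes <- function(code_keys) {
  roots <- icd_root(code_keys)
  banned <- c(.LEAKAGE_SINGLE_ROOTS, .LEAKAGE_D_RANGE, .LEAKAGE_C_RANGE)
  code_keys[!(roots %in% banned)]
}

#' Windows manifest
#'
#' One-row-per-window summary table (patient, label, anchor, start, number
#' of retained events), the artifact the pipeline writes alongside features.
#'
#' @param windows List of `cohort_window`s.
#' @return Data frame.
#' @export
windows_manifest <- function(windows) {
  data.frame(
    patient_id = vapply(windows, `[[`, character(1), "patient_id"),
    label = vapply(windows, `[[`, character(1), "label"),
    anchor_date = as.Date(vapply(windows, function(w)
      format(w$anchor_date), character(1))),
    window_start = as.Date(vapply(windows, function(w)
      format(w$window_start), character(1))),
    n_events = vapply(windows, function(w) nrow(w$events), integer(1)),
    stringsAsFactors = FALSE)
}
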