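# Modeling-matrix construction: longitudinal aggregation, control-anchored
# decile binning, binary presence features, prevalence filtering, phenotype
# mapping, and Weight-of-Evidence encoding.

.AGG_SUFFIXES <- c("p25", "p50", "p75", "min", "max", "var", "absdiff", "mono")

#' Aggregate a time-ordered measurement series
#'
#' Summarizes one patient's repeated measurements of one parameter into the
#' eight longitudinal aggregates used as features: 25th/50th/75th
#' percentiles (linear interpolation), minimum, maximum, sample variance
#' (divisor n-1; 0 for a single value), absolute first-to-last difference,
#' and monotonicity of change (`TRUE` iff the last value exceeds the first;
#' ties and singletons give `FALSE`).
#'
#' @param values Numeric vector in time order. An empty series returns all
#'   fields missing rather than an error.
#' @return Named numeric vector `p25, p50, p75, min, max, var, absdiff,
#'   mono` (monotonicity coded 0/1).
#' @export
#' @examples
#' aggregate_series(c(1, 2, 3))
aggregate_series <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    out <- rep(NA_real_, 8L)
    names(out) <- .AGG_SUFFIXES
    return(out)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = .QUANTILE_TYPE,
                       names = FALSE)
  v <- if (length(values) > 1L) stats::var(values) else 0
  c(p25 = q[1L], p50 = q[2L], p75 = q[3L],
    min = min(values), max = max(values), var = v,
    absdiff = abs(values[length(values)] - values[1L]),
    mono = as.numeric(values[length(values)] > values[1L]))
}

#' Fit control-anchored decile bins
#'
#' Computes interior bin edges per feature at the control-group percentiles
#' 10, 20, ..., 90 (linear interpolation), defining 10 intervals anchored in
#' the typical physiological ranges of the large control population.
#' Duplicate edges (heavy ties) collapse, so degenerate features may have
#' fewer effective bins.
#'
#' @param control_values Data frame (or matrix) of control-group feature
#'   values, one column per feature to bin.
#' @param n_bins Number of intervals (default 10).
#' @return Object of class `binning_model`: list with `edges` (named list
#'   of length-`n_bins - 1` numeric vectors) and `n_bins`.
#' @export
fit_bins <- function(control_values, n_bins = 10L) {
  control_values <- as.data.frame(control_values)
  probs <- seq_len(n_bins - 1L) / n_bins
  too_few <- character(0)
  edges <- lapply(control_values, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < n_bins) return(NULL)
    stats::quantile(v, probs, type = .QUANTILE_TYPE, names = FALSE)
  })
  too_few <- names(edges)[vapply(edges, is.null, logical(1))]
  if (length(too_few) > 0L)
    stop("fewer than ", n_bins, " non-missing control values for feature(s): ",
         paste(too_few, collapse = ", "), call. = FALSE)
  structure(list(edges = edges, n_bins = as.integer(n_bins)),
            class = "binning_model")
}

#' Assign values to fitted bins
#'
#' The bin index is the count of edges strictly below the value (0-based,
#' 0 to `n_bins - 1`); a value equal to an edge falls in the lower interval.
#' Missing values stay missing.
#'
#' @param values Numeric vector.
#' @param edges Numeric edge vector from [fit_bins()].
#' @return Integer bin indices (with `NA` preserved).
#' @export
apply_bins <- function(values, edges) {
  # findInterval with left-open intervals counts edges strictly below each
  # value, which is the tie rule (edge values fall in the lower interval)
  as.integer(findInterval(values, edges, left.open = TRUE))
}

apply_binning_model <- function(x, model, columns = names(model$edges)) {
  for (cn in columns) {
    if (!cn %in% names(x)) next
    x[[cn]] <- apply_bins(x[[cn]], model$edges[[cn]])
  }
  x
}

#' Prevalence filter for optional and binary features
#'
#' A feature passes only if it is present in at least `threshold` of the
#' positive rows AND at least `threshold` of the control rows (inclusive).
#' Presence means value 1 for binary features and a non-missing value for
#' aggregates of optional parameters. Aggregates of mandatory CBC
#' parameters and demographics are exempt and always retained.
#'
#' @param x Feature data frame.
#' @param meta Feature metadata as produced by [build_raw_features()]
#'   (columns `column`, `kind`, `exempt`).
#' @param labels Binary vector, 1 = positive row, 0 = control row.
#' @param threshold Minimum presence fraction (default 0.05).
#' @return Character vector of retained column names (in schema order).
#' @export
prevalence_filter <- function(x, meta, labels,
                              threshold = .DEFAULT_PREVALENCE_THRESHOLD) {
  stopifnot(nrow(x) == length(labels))
  if (sum(labels == 1) < 1L || sum(labels == 0) < 1L)
    stop("prevalence_filter needs at least one positive and one control row",
         call. = FALSE)
  keep <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    cn <- meta$column[i]
    if (isTRUE(meta$exempt[i])) { keep[i] <- TRUE; next }
    v <- x[[cn]]
    present <- if (meta$kind[i] == "binary") !is.na(v) & v == 1 else !is.na(v)
    keep[i] <- mean(present[labels == 1]) >= threshold &&
      mean(present[labels == 0]) >= threshold
  }
  meta$column[keep]
}

#' Map an ICD-10 code to a higher-level phenotype
#'
#' Exact-match lookup in a two-column code-to-phenotype table, falling back
#' to a 3-character root match (the query's root against the table's code
#' roots). Unmatched codes return `NA`.
#'
#' @param codes Character vector of ICD-10 codes.
#' @param mapping Data frame with columns `code`, `phenotype`.
#' @return Character vector of phenotypes, `NA` where unmapped.
#' @export
map_phewas <- function(codes, mapping) {
  stopifnot(all(c("code", "phenotype") %in% names(mapping)))
  dup <- mapping[duplicated(mapping$code) | duplicated(mapping$code, fromLast = TRUE), ]
  if (nrow(dup) > 0L) {
    conf <- tapply(dup$phenotype, dup$code, function(p) length(unique(p)) > 1L)
    if (any(conf))
      stop("conflicting duplicate mapping rows for code(s): ",
           paste(names(conf)[conf], collapse = ", "), call. = FALSE)
  }
  exact <- mapping$phenotype[match(codes, mapping$code)]
  need_root <- is.na(exact)
  if (any(need_root)) {
    root_hit <- mapping$phenotype[match(icd_root(codes[need_root]),
                                        icd_root(mapping$code))]
    exact[need_root] <- root_hit
  }
  exact
}

#' Weight-of-Evidence encoding
#'
#' Encodes categorical (binned) columns by the smoothed log-ratio of
#' class-conditional category frequencies:
#' `WoE(b) = ln(((pos_b + s)/(pos_tot + s*k)) / ((neg_b + s)/(neg_tot + s*k)))`
#' with pseudo-count `s = 0.5` and `k` the number of categories, so empty
#' cells stay finite. Missing values form their own category. Fit on
#' training rows only and applied to new rows via [woe_apply()] (unseen
#' categories encode as 0).
#'
#' @param x Data frame of categorical/binned columns.
#' @param labels Binary vector (1 = positive).
#' @param smoothing Pseudo-count (default 0.5).
#' @return List with `encoded` (numeric data frame) and `tables` (per-column
#'   category-to-WoE lookup).
#' @export
woe_transform <- function(x, labels, smoothing = .WOE_SMOOTHING) {
  if (length(unique(labels)) < 2L)
    stop("woe_transform requires both classes in `labels`", call. = FALSE)
  pos_tot <- sum(labels == 1)
  neg_tot <- sum(labels == 0)
  tables <- lapply(x, function(v) {
    cat <- ifelse(is.na(v), "<missing>", as.character(v))
    cats <- sort(unique(cat))
    k <- length(cats)
    pos_b <- vapply(cats, function(cc) sum(cat == cc & labels == 1), numeric(1))
    neg_b <- vapply(cats, function(cc) sum(cat == cc & labels == 0), numeric(1))
    woe <- log(((pos_b + smoothing) / (pos_tot + smoothing * k)) /
                 ((neg_b + smoothing) / (neg_tot + smoothing * k)))
    data.frame(category = cats, woe = woe, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  list(encoded = woe_apply(x, tables), tables = tables)
}

#' Apply a fitted Weight-of-Evidence table
#'
#' @param x Data frame of categorical/binned columns.
#' @param tables The `tables` element from [woe_transform()].
#' @return Numeric data frame; categories unseen at fit time encode as 0.
#' @export
woe_apply <- function(x, tables) {
  out <- x
  for (cn in names(tables)) {
    if (!cn %in% names(x)) next
    cat <- ifelse(is.na(x[[cn]]), "<missing>", as.character(x[[cn]]))
    w <- tables[[cn]]$woe[match(cat, tables[[cn]]$category)]
    w[is.na(w)] <- 0
    out[[cn]] <- w
  }
  out
}

#' Closed-form feature schema count
#'
#' Each CBC parameter contributes one measured-within-window indicator plus
#' eight longitudinal aggregates; phenotypes and ICD-10 codes contribute one
#' binary each; demographics contribute age and gender. With the default
#' schema (22 parameters, 5 phenotypes, 7 codes) this gives 212 columns.
#'
#' @param n_parameters,n_phenotypes,n_codes,n_demographics Schema sizes.
#' @return Integer column count.
#' @export
feature_schema_count <- function(n_parameters = 22L, n_phenotypes = 5L,
                                 n_codes = 7L, n_demographics = 2L) {
  as.integer(n_parameters * (1L + length(.AGG_SUFFIXES)) + n_phenotypes +
               n_codes + n_demographics)
}

#' Extract raw (un-binned) features from analysis windows
#'
#' One row per window: per-parameter aggregates on the raw measurement
#' scale plus a measured indicator, binary ICD-10 code and phenotype
#' presence (leakage codes removed first), and demographics (age at anchor,
#' gender). No binning, filtering or imputation happens here; missing stays
#' missing.
#'
#' @param windows List of `cohort_window`s.
#' @param patients Patient table with `patient_id`, `birth_year`, `gender`.
#' @param parameter_names CBC parameter names (defaults to the 22 reference
#'   parameters).
#' @param feature_codes ICD-10 codes exposed as binary features (leakage
#'   codes are excluded automatically).
#' @param mapping Code-to-phenotype table ([default_phewas_mapping()]).
#' @param optional_parameters Names of parameters subject to the prevalence
#'   filter (aggregates of the rest are exempt).
#' @return List of class `raw_features`: `x` (data frame), `meta` (column
#'   metadata: `column`, `kind`, `parameter`, `exempt`), `patient_id`,
#'   `label` (1 = positive window).
#' @export
build_raw_features <- function(windows, patients,
                               parameter_names = cbc_parameter_specs()$name,
                               feature_codes = default_code_specs()$code,
                               mapping = default_phewas_mapping(),
                               optional_parameters =
                                 cbc_parameter_specs()$name[cbc_parameter_specs()$optional_flag]) {
  feature_codes <- exclude_leakage_codes(feature_codes)
  phenos <- sort(unique(mapping$phenotype))
  n <- length(windows)

  agg_cols <- as.vector(t(outer(parameter_names, .AGG_SUFFIXES,
                                function(p, s) paste0(p, "__", s))))
  measured_cols <- paste0(parameter_names, "__measured")
  code_cols <- paste0("icd_", gsub("\\.", "_", feature_codes))
  pheno_cols <- paste0("pheno_", phenos)
  all_cols <- c(measured_cols, agg_cols, pheno_cols, code_cols, "age", "gender_F")

  x <- matrix(NA_real_, nrow = n, ncol = length(all_cols),
              dimnames = list(NULL, all_cols))
  pid <- character(n)
  label <- integer(n)
  pt_idx <- match(vapply(windows, `[[`, character(1), "patient_id"),
                  patients$patient_id)

  for (i in seq_len(n)) {
    w <- windows[[i]]
    pid[i] <- w$patient_id
    label[i] <- as.integer(w$label == "positive")
    ev <- w$events
    labs <- ev[ev$kind == "lab", , drop = FALSE]
    for (p in parameter_names) {
      v <- suppressWarnings(as.numeric(labs$value[labs$key == p]))
      x[i, paste0(p, "__measured")] <- as.numeric(length(v) > 0L)
      x[i, paste0(p, "__", .AGG_SUFFIXES)] <- aggregate_series(v)
    }
    keys <- exclude_leakage_codes(ev$key[ev$kind == "icd10"])
    for (j in seq_along(feature_codes))
      x[i, code_cols[j]] <- as.numeric(any(icd_matches(keys, feature_codes[j])))
    mapped <- map_phewas(keys, mapping)
    for (ph in phenos)
      x[i, paste0("pheno_", ph)] <- as.numeric(any(!is.na(mapped) & mapped == ph))
    bi <- pt_idx[i]
    x[i, "age"] <- as.integer(format(w$anchor_date, "%Y")) - patients$birth_year[bi]
    x[i, "gender_F"] <- as.numeric(patients$gender[bi] == "F")
  }

  meta <- data.frame(
    column = all_cols,
    kind = c(rep("binary", length(measured_cols)),
             rep("aggregate", length(agg_cols)),
             rep("binary", length(pheno_cols) + length(code_cols)),
             rep("demographic", 2L)),
    parameter = c(parameter_names,
                  rep(parameter_names, each = length(.AGG_SUFFIXES)),
                  rep(NA_character_, length(pheno_cols) + length(code_cols) + 2L)),
    stringsAsFactors = FALSE)
  # mandatory-parameter aggregates and demographics are exempt from the
  # prevalence filter; optional-parameter features and binaries are not
  meta$exempt <- meta$kind == "demographic" |
    (!is.na(meta$parameter) & !(meta$parameter %in% optional_parameters))

  structure(list(x = as.data.frame(x), meta = meta, patient_id = pid,
                 label = label),
            class = "raw_features")
}

#' Build the model feature matrix
#'
#' Turns raw window features into the modeling matrix: aggregate columns are
#' replaced by their control-anchored decile bin indices (raw aggregates
#' remain available in `raw` for univariate analysis), the prevalence filter
#' is applied, and the schema is returned alongside. When `binning` is
#' `NULL` it is fitted on the control rows of `raw` itself; inside
#' cross-validation pass a model fitted on training controls only.
#'
#' @param raw A `raw_features` object.
#' @param binning A `binning_model` or `NULL`.
#' @param prevalence_threshold Presence threshold for optional/binary
#'   features.
#' @param n_bins Bin count when fitting.
#' @return List of class `feature_matrix`: `x` (data frame; bin indices,
#'   0/1 binaries, numeric demographics, `NA` sentinel), `meta`, `binning`,
#'   `patient_id`, `label`.
#' @export
build_feature_matrix <- function(raw, binning = NULL,
                                 prevalence_threshold = .DEFAULT_PREVALENCE_THRESHOLD,
                                 n_bins = 10L) {
  stopifnot(inherits(raw, "raw_features"))
  agg_cols <- raw$meta$column[raw$meta$kind == "aggregate"]
  if (is.null(binning)) {
    controls <- raw$x[raw$label == 0, agg_cols, drop = FALSE]
    binning <- fit_bins(controls, n_bins = n_bins)
  }
  x <- apply_binning_model(raw$x, binning, columns = agg_cols)
  kept <- prevalence_filter(x, raw$meta, raw$label,
                            threshold = prevalence_threshold)
  meta <- raw$meta[raw$meta$column %in% kept, , drop = FALSE]
  meta$kind[meta$kind == "aggregate"] <- "aggregate_binned"
  structure(list(x = x[, kept, drop = FALSE], meta = meta, binning = binning,
                 patient_id = raw$patient_id, label = raw$label),
            class = "feature_matrix")
}
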