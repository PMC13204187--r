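# Manual-review table fixtures and their arithmetic: the published clinical
# review of flagged patients, used to ground the screening-workflow numbers
# (medium/high-risk counts, confirmed diagnoses among flagged patients).

#' Load the shipped manual-review tables
#'
#' Two risk-by-diagnostic-status count grids from the clinical review of
#' model-flagged patients: the consensus subset flagged by every model
#' variant, and the remaining flags of the best-performing traditional
#' model.
#'
#' @return Named list of data frames (`consensus`, `remaining`), each with
#'   a `risk` column and count columns `confirmed`, `excluded`, `unknown`,
#'   `suspected`.
#' @export
review_tables <- function() {
  read1 <- function(f) utils::read.csv(
    system.file("extdata", f, package = "pmfscreen", mustWork = TRUE),
    stringsAsFactors = FALSE, check.names = FALSE)
  list(consensus = read1("review_table_consensus.csv"),
       remaining = read1("review_table_remaining.csv"))
}

#' Summarize manual-review tables
#'
#' Exact integer sums over one or more risk-by-status review grids: the
#' grand total of reviewed patients, per-status column totals, per-risk row
#' totals, and the number of patients judged at medium or high risk.
#'
#' @param fixtures A single review data frame or a (possibly named) list of
#'   them, each with a `risk` column followed by count columns.
#' @return List: `total`, `column_totals` (named), `row_totals` (named by
#'   risk level), `medium_high_total`.
#' @export
#' @examples
#' review_table_summaries(review_tables())
review_table_summaries <- function(fixtures) {
  if (is.data.frame(fixtures)) fixtures <- list(fixtures)
  for (tb in fixtures) {
    cnt <- as.matrix(tb[, setdiff(names(tb), "risk"), drop = FALSE])
    if (any(cnt < 0) || any(cnt != round(cnt)))
      stop("review tables must contain non-negative integer counts",
           call. = FALSE)
  }
  count_cols <- setdiff(names(fixtures[[1L]]), "risk")
  col_tot <- stats::setNames(numeric(length(count_cols)), count_cols)
  row_tot <- numeric(0)
  mh <- 0
  for (tb in fixtures) {
    cnt <- as.matrix(tb[, count_cols, drop = FALSE])
    col_tot <- col_tot + colSums(cnt)
    rt <- rowSums(cnt)
    names(rt) <- tb$risk
    for (rn in names(rt))
      row_tot[rn] <- (if (rn %in% names(row_tot)) row_tot[rn] else 0) + rt[rn]
    mh <- mh + sum(cnt[tb$risk %in% c("Medium", "High"), ])
  }
  list(total = sum(col_tot), column_totals = col_tot, row_totals = row_tot,
       medium_high_total = mh)
}
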