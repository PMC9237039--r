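#' MAD-based outlier fence
#'
#' Flags observations lying more than `k` median absolute deviations from
#' the median. The MAD here is the raw `median(|v - median(v)|)` with no
#' normal-consistency scaling, and the fence is inclusive: values exactly
#' at `k * MAD` are kept. When the MAD is zero (over half the values tied
#' at the median) only values equal to the median are kept.
#'
#' Applied per site-species pool of phenology dates across years when
#' screening observational records.
#'
#' @param values numeric vector (>= 3 finite values required).
#' @param k fence multiplier (default 2.5).
#' @return logical keep-mask, same length as `values`; `NA` inputs are
#'   not kept.
#' @examples
#' mad_outlier_filter(c(100, 101, 102, 103, 200))  # drops 200
#' @export
mad_outlier_filter <- function(values, k = 2.5) {
  fin <- is.finite(values)
  if (sum(fin) == 0) stop("empty-input: no finite values", call. = FALSE)
  if (sum(fin) < 3) stop("empty-input: need >= 3 finite values", call. = FALSE)
  med <- median(values[fin])
  mad_raw <- median(abs(values[fin] - med))
  keep <- fin & if (mad_raw == 0) values == med else
    abs(values - med) <= k * mad_raw
  keep & !is.na(keep)
}

#' Bare-land mask from annual mean NDVI
#'
#' A site (or pixel) is retained only if the mean over years of its annual
#' mean NDVI is at least 0.1; sparser cover is treated as bare land and
#' excluded. The boundary is inclusive: exactly 0.1 is retained.
#'
#' @param series an NDVI [daily_series()] spanning >= 1 full year.
#' @param threshold retention threshold (default 0.1).
#' @return logical scalar: retain this site.
#' @export
ndvi_bareland_mask <- function(series, threshold = 0.1) {
  if (nrow(series) == 0) stop("empty-input: empty series", call. = FALSE)
  annual <- tapply(series$value, series$year, mean, na.rm = TRUE)
  mean(annual) >= threshold
}

#' Minimum record-length filter
#'
#' Retains a site(-species) record only if it has at least `min_years`
#' years with a valid SOS and, when `min_daily_records_per_year` is given,
#' strictly more than that many daily observations in every retained year
#' (years failing the daily-count rule are dropped first, then the year
#' count is applied).
#'
#' @param records data.frame with at least `site_id`, `year`, `sos`
#'   columns (and optionally `species` and `n_daily`, the number of daily
#'   observations backing each site-year).
#' @param min_years minimum years with valid SOS (>= 2).
#' @param min_daily_records_per_year optional strict lower bound on
#'   `n_daily`.
#' @return list with `records` (retained rows) and `report`, a
#'   [filter_report()] whose counts reconcile exactly.
#' @export
record_length_filter <- function(records, min_years,
                                 min_daily_records_per_year = NULL) {
  stopifnot(min_years >= 2)
  n_input <- nrow(records)
  grp <- if ("species" %in% names(records))
    interaction(records$site_id, records$species, drop = TRUE)
  else factor(records$site_id)
  valid <- !is.na(records$sos)
  if (!is.null(min_daily_records_per_year)) {
    stopifnot("n_daily" %in% names(records))
    valid <- valid & records$n_daily > min_daily_records_per_year
  }
  n_sparse <- sum(!valid)
  yrs_per_grp <- tapply(valid, grp, sum)
  keep_grp <- names(yrs_per_grp)[yrs_per_grp >= min_years]
  keep <- valid & (as.character(grp) %in% keep_grp)
  n_short <- sum(valid & !keep)
  out <- records[keep, , drop = FALSE]
  rep <- filter_report(n_input = n_input, n_removed_short_record = n_short,
                       n_removed_mask = n_sparse, n_retained = nrow(out))
  list(records = out, report = rep)
}

#' Filter audit report
#'
#' Bookkeeping for every screening step: input count, counts removed per
#' rule, retained count. The constructor enforces exact reconciliation
#' (`n_input = n_retained + sum of removals`).
#'
#' @param n_input,n_removed_outlier,n_removed_mask,n_removed_short_record,n_retained
#'   non-negative counts.
#' @param detail optional per-site data.frame carried along.
#' @return a `filter_report` list.
#' @export
filter_report <- function(n_input, n_removed_outlier = 0L, n_removed_mask = 0L,
                          n_removed_short_record = 0L, n_retained,
                          detail = NULL) {
  counts <- c(n_input, n_removed_outlier, n_removed_mask,
              n_removed_short_record, n_retained)
  stopifnot(all(counts >= 0))
  if (n_input != n_retained + n_removed_outlier + n_removed_mask +
      n_removed_short_record)
    stop("filter-report: counts do not reconcile", call. = FALSE)
  structure(list(n_input = n_input, n_removed_outlier = n_removed_outlier,
                 n_removed_mask = n_removed_mask,
                 n_removed_short_record = n_removed_short_record,
                 n_retained = n_retained, detail = detail),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter report:", x$n_input, "in /", x$n_retained, "retained",
      sprintf("(outlier %d, mask %d, short-record %d)\n",
              x$n_removed_outlier, x$n_removed_mask,
              x$n_removed_short_record))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(n_input = x$n_input, n_removed_outlier = x$n_removed_outlier,
             n_removed_mask = x$n_removed_mask,
             n_removed_short_record = x$n_removed_short_record,
             n_retained = x$n_retained)
}
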