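#' Month-by-SMU mean catch matrix
#'
#' Sums reported catch (pounds) within each year x month x SMU cell, then
#' averages the annual sums across the supplied year range. Year x cell
#' combinations with no reported catch count as zero in the average, so the
#' mean reflects the full period rather than only years with fishing.
#'
#' @param catch Catch records with columns `year`, `month`, `smu_id`,
#'   `pounds` (see [read_catch()]).
#' @param year_range Integer vector of years to average over; defaults to the
#'   full range present in `catch`.
#' @param smu_ids,months SMU ids and months defining the matrix extent;
#'   default to those present in `catch`.
#' @return `data.table` with `month`, `smu_id`, `mean_catch_lb` covering the
#'   full month x SMU grid (zeros included).
#' @export
mean_catch_matrix <- function(catch, year_range = NULL, smu_ids = NULL,
                              months = 1:12) {
  ct <- as.data.table(catch)
  if (nrow(ct) && any(ct$pounds < 0))
    stop("negative catch", call. = FALSE)
  if (is.null(year_range))
    year_range <- if (nrow(ct)) seq(min(ct$year), max(ct$year)) else integer(0)
  if (is.null(smu_ids)) smu_ids <- sort(unique(ct$smu_id))
  ct <- ct[year %in% year_range]
  n_years <- max(length(year_range), 1L)
  grid <- CJ(month = months, smu_id = smu_ids)
  sums <- ct[, .(total = sum(pounds)), by = .(month, smu_id)]
  out <- merge(grid, sums, by = c("month", "smu_id"), all.x = TRUE)
  out[is.na(total), total := 0]
  out[, mean_catch_lb := total / n_years]
  out[, total := NULL]
  setorder(out, month, smu_id)
  out[]
}

#' Cumulative rank percentiles of a catch matrix
#'
#' Assigns each nonzero cell of the mean catch matrix its cumulative
#' distributional rank among the nonzero cells: the fraction of nonzero cells
#' with value less than or equal to the cell's value. Ties share the common
#' (maximal-count) percentile, so the matrix maximum is always 1.0 and a
#' matrix of equal nonzero values degenerates to all 1.0. Zero cells are
#' excluded from the calculation and receive `NA`.
#'
#' @param matrix Output of [mean_catch_matrix()] (columns `month`, `smu_id`,
#'   `mean_catch_lb`).
#' @return The matrix with a `percentile` column added (fraction in (0, 1],
#'   `NA` for zero cells).
#' @export
percentile_ranks <- function(matrix) {
  m <- as.data.table(matrix)
  nz <- m$mean_catch_lb[m$mean_catch_lb > 0]
  if (length(nz) == 0L) {
    warning("all-zero catch matrix: all percentiles NA", call. = FALSE)
    m[, percentile := NA_real_]
    return(m[])
  }
  n <- length(nz)
  m[, percentile := ifelse(mean_catch_lb > 0,
                           vapply(mean_catch_lb,
                                  function(v) sum(nz <= v) / n, numeric(1)),
                           NA_real_)]
  m[]
}

#' Risk days: residency times catch percentile
#'
#' The risk-days statistic for a month x SMU cell is the product of the mean
#' monthly residency (days, from [summarize_residency()]) and the catch rank
#' percentile of that cell (as a fraction). Cells with zero catch (`NA`
#' percentile) contribute zero risk regardless of residency — the refuge
#' case. The result is ordered west to east within month order when SMU
#' metadata is supplied.
#'
#' @param monthly_summary Output of [summarize_residency()].
#' @param percentiles Output of [percentile_ranks()].
#' @param smus Optional `smu_set` used to order output west to east.
#' @return `data.table` with `month`, `smu_id`, `mean_days`, `percentile`,
#'   `risk_days`.
#' @export
compute_risk_days <- function(monthly_summary, percentiles, smus = NULL) {
  ms <- as.data.table(monthly_summary)
  pc <- as.data.table(percentiles)
  extra <- setdiff(unique(ms$smu_id), unique(pc$smu_id))
  if (length(extra))
    stop("SMUs present in residency summary but not in catch matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  out <- merge(ms[, .(month, smu_id, mean_days)],
               pc[, .(month, smu_id, percentile)],
               by = c("month", "smu_id"), all.x = TRUE)
  out[, risk_days := ifelse(is.na(percentile) | mean_days == 0, 0,
                            mean_days * percentile)]
  if (!is.null(smus)) {
    ordtab <- smus$table[, .(smu_id, district)]
    out <- merge(out, ordtab, by = "smu_id", all.x = TRUE)
    setorder(out, month, district, smu_id)
    out[, district := NULL]
  } else setorder(out, month, smu_id)
  out[]
}
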