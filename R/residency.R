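#' Allocate detection histories to month-by-SMU residency
#'
#' Every day between a tag's first and last valid detection is attributed to a
#' calendar month and an SMU. For each pair of consecutive detections, at
#' receivers in SMUs A and B, the time gap is split evenly at its temporal
#' midpoint: the first half accrues to A and the second half to B (when A = B
#' the whole interval accrues to A). Each accrued sub-interval is then
#' partitioned across calendar-month boundaries, so that per tag the total
#' allocated time equals the full first-to-last detection span, with no bias
#' toward a particular SMU ordering.
#'
#' @param detections QC-flagged detection table; only rows with
#'   `is_valid == TRUE` are used (pass an unfiltered table with `is_valid`
#'   all `TRUE` to skip QC).
#' @param receiver_map `data.table`/data.frame with columns `receiver_id`,
#'   `smu_id` (e.g. the output of [assign_smu()]).
#' @param tz Timezone used to evaluate calendar-month boundaries
#'   (default `"UTC"`).
#' @return `data.table` with columns `tag_id`, `year`, `month`, `smu_id`,
#'   `days` (non-negative real); one row per occupied tag x month x SMU cell.
#' @export
allocate_residency <- function(detections, receiver_map, tz = "UTC") {
  det <- as.data.table(detections)
  det <- det[is.na(is_valid) | is_valid %in% TRUE]
  rmap <- as.data.table(receiver_map)[, .(receiver_id, smu_id)]
  unknown <- setdiff(unique(det$receiver_id), rmap$receiver_id)
  if (length(unknown))
    stop("detections at receivers with no SMU assignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  det <- merge(det, rmap, by = "receiver_id", sort = FALSE)
  setorder(det, tag_id, timestamp)
  if (det[, is.unsorted(timestamp), by = tag_id][, any(V1)])
    stop("detections not sorted by timestamp within tag", call. = FALSE)

  # consecutive-pair intervals with midpoint split on SMU change
  pairs <- det[, {
    n <- .N
    if (n < 2L) {
      list(start = numeric(0), end = numeric(0), smu = character(0))
    } else {
      t <- as.numeric(timestamp)
      t1 <- t[-n]; t2 <- t[-1L]
      s1 <- smu_id[-n]; s2 <- smu_id[-1L]
      mid <- (t1 + t2) / 2
      same <- s1 == s2
      list(
        start = c(t1[same], t1[!same], mid[!same]),
        end   = c(t2[same], mid[!same], t2[!same]),
        smu   = c(s1[same], s1[!same], s2[!same])
      )
    }
  }, by = tag_id]
  pairs <- pairs[end > start]
  if (nrow(pairs) == 0L)
    return(data.table(tag_id = character(0), year = integer(0),
                      month = integer(0), smu_id = character(0),
                      days = numeric(0)))
  out <- .split_months(pairs, tz = tz)
  res <- out[, .(days = sum(days)), by = .(tag_id, year, month, smu_id)]
  setorder(res, tag_id, year, month, smu_id)
  res[]
}

# Partition [start, end) intervals (numeric epoch seconds) across
# calendar-month boundaries in `tz`. Returns tag_id, year, month, smu_id, days.
.split_months <- function(pairs, tz = "UTC") {
  p <- copy(pairs)
  st <- as.POSIXct(p$start, origin = "1970-01-01", tz = tz)
  en <- as.POSIXct(p$end, origin = "1970-01-01", tz = tz)
  slt <- as.POSIXlt(st, tz = tz)
  elt <- as.POSIXlt(en, tz = tz)
  ym_s <- (slt$year + 1900L) * 12L + slt$mon          # month index of start
  ym_e <- (elt$year + 1900L) * 12L + elt$mon
  # end falling exactly on a month boundary belongs to the previous month
  end_on_boundary <- elt$mday == 1L & elt$hour == 0L & elt$min == 0L &
    elt$sec == 0
  ym_e_eff <- ym_e - as.integer(end_on_boundary)
  within <- ym_s >= ym_e_eff

  res_within <- data.table(
    tag_id = p$tag_id[within],
    year = ym_s[within] %/% 12L,
    month = ym_s[within] %% 12L + 1L,
    smu_id = p$smu[within],
    days = (p$end[within] - p$start[within]) / 86400
  )

  idx <- which(!within)
  if (length(idx)) {
    res_span <- rbindlist(lapply(idx, function(i) {
      # month boundaries strictly inside (start, end)
      first_b <- as.POSIXct(sprintf("%04d-%02d-01",
                                    (ym_s[i] + 1L) %/% 12L,
                                    (ym_s[i] + 1L) %% 12L + 1L), tz = tz)
      bounds <- seq(first_b, en[i], by = "month")
      bounds <- bounds[as.numeric(bounds) > p$start[i] &
                       as.numeric(bounds) < p$end[i]]
      cuts <- c(p$start[i], as.numeric(bounds), p$end[i])
      seg_start <- cuts[-length(cuts)]
      seg_lt <- as.POSIXlt(as.POSIXct(seg_start, origin = "1970-01-01",
                                      tz = tz), tz = tz)
      data.table(
        tag_id = p$tag_id[i],
        year = seg_lt$year + 1900L,
        month = seg_lt$mon + 1L,
        smu_id = p$smu[i],
        days = diff(cuts) / 86400
      )
    }))
    res <- rbind(res_within, res_span)
  } else res <- res_within
  res[days > 0]
}

#' Summarize residency into monthly means and proportions
#'
#' Averages per-tag residency across individual fish and years. For each
#' calendar month, the mean days in an SMU is the mean over all (tag, year)
#' pairs that were at large during any part of that month (pairs with no time
#' in that SMU contribute zeros). Proportions rescale the means to sum to 1
#' within each month, absorbing the slight variation in month lengths.
#'
#' @param records Residency records from [allocate_residency()].
#' @param at_large Optional `data.table` (`tag_id`, `year`, `month`) listing
#'   at-large tag-months; by default derived from `records` (a tag-year is at
#'   large in every month it has any allocated time).
#' @return `data.table` with `month`, `smu_id`, `mean_days`, `proportion`.
#' @export
summarize_residency <- function(records, at_large = NULL) {
  rec <- as.data.table(records)
  if (nrow(rec) == 0L) {
    warning("summarize_residency: empty input", call. = FALSE)
    return(data.table(month = integer(0), smu_id = character(0),
                      mean_days = numeric(0), proportion = numeric(0)))
  }
  if (is.null(at_large))
    at_large <- unique(rec[, .(tag_id, year, month)])
  at_large <- as.data.table(at_large)
  n_al <- at_large[, .(n_at_large = uniqueN(paste(tag_id, year))),
                   by = month]
  tot <- rec[, .(total_days = sum(days)), by = .(month, smu_id)]
  summ <- merge(tot, n_al, by = "month")
  summ[, mean_days := total_days / n_at_large]
  summ[, proportion := mean_days / sum(mean_days), by = month]
  summ[, c("total_days", "n_at_large") := NULL]
  setorder(summ, month, smu_id)
  summ[]
}

#' Mean detections per at-large tag by month and SMU
#'
#' Counts valid detections per tag x month x SMU and averages over the tags at
#' large in each month (tags at large but undetected in an SMU contribute
#' zero counts), giving the spatio-temporal detection summary used for the
#' seasonal trend.
#'
#' @inheritParams allocate_residency
#' @return `data.table` with `month`, `smu_id`, `mean_detections`.
#' @export
detection_summary <- function(detections, receiver_map) {
  det <- as.data.table(detections)
  det <- det[is.na(is_valid) | is_valid %in% TRUE]
  rmap <- as.data.table(receiver_map)[, .(receiver_id, smu_id)]
  det <- merge(det, rmap, by = "receiver_id", sort = FALSE)
  if (nrow(det) == 0L)
    return(data.table(month = integer(0), smu_id = character(0),
                      mean_detections = numeric(0)))
  lt <- as.POSIXlt(det$timestamp, tz = "UTC")
  det[, `:=`(year = lt$year + 1900L, month = lt$mon + 1L)]
  # at-large months per tag-year: all months between first and last detection
  spans <- det[, .(t0 = min(timestamp), t1 = max(timestamp)), by = tag_id]
  al <- spans[, {
    m0 <- as.POSIXlt(t0, tz = "UTC"); m1 <- as.POSIXlt(t1, tz = "UTC")
    i <- seq((m0$year + 1900L) * 12L + m0$mon,
             (m1$year + 1900L) * 12L + m1$mon)
    list(year = i %/% 12L, month = i %% 12L + 1L)
  }, by = tag_id]
  n_al <- al[, .(n_at_large = uniqueN(paste(tag_id, year))), by = month]
  counts <- det[, .(n_det = .N), by = .(month, smu_id)]
  out <- merge(counts, n_al, by = "month")
  out[, mean_detections := n_det / n_at_large]
  out[, c("n_det", "n_at_large") := NULL]
  setorder(out, month, smu_id)
  out[]
}

#' Fit the descriptive seasonal trend in ordinal SMU position
#'
#' Models the west-to-east ordinal code of the SMU where detections occurred
#' as a function of month, with individual fish as random intercepts and
#' observations weighted by detection counts (accounting for changing numbers
#' of fish at large). Detections are aggregated to tag x month x SMU cells;
#' each cell contributes its SMU's ordinal code weighted by its detection
#' count. Two month parameterizations are available: `"harmonic"` (first and
#' second annual harmonics, the default for cyclic seasonal migration) and
#' `"linear"` (a single slope on a continuous month index, useful for drift
#' scenarios).
#'
#' If the weighted mixed fit is singular or fails, the function falls back to
#' an unweighted fixed-effects fit with a warning, flagged in the result.
#'
#' @inheritParams allocate_residency
#' @param smus `smu_set` providing `ordinal_code` per SMU.
#' @param form `"harmonic"` or `"linear"` month parameterization.
#' @return Object of class `trend_fit`: list with `method`, `backend`
#'   (`"lmer"`/`"lm"`), `fallback` flag, `coefficients`, `vcov`, `band`
#'   (fitted ordinal curve with 95% confidence band, per month for the
#'   harmonic form, per month index for the linear form), `ranef_var`
#'   (tag random-intercept variance), and the fitted `model`.
#' @export
fit_seasonal_trend <- function(detections, receiver_map, smus,
                               form = c("harmonic", "linear")) {
  form <- match.arg(form)
  det <- as.data.table(detections)
  det <- det[is.na(is_valid) | is_valid %in% TRUE]
  rmap <- as.data.table(receiver_map)[, .(receiver_id, smu_id)]
  det <- merge(det, rmap, by = "receiver_id", sort = FALSE)
  det <- merge(det, smus$table[, .(smu_id, ordinal_code)], by = "smu_id",
               sort = FALSE)
  lt <- as.POSIXlt(det$timestamp, tz = "UTC")
  det[, `:=`(year = lt$year + 1900L, month = lt$mon + 1L)]
  cells <- det[, .(w = .N), by = .(tag_id, year, month, ordinal_code)]
  if (uniqueN(cells$tag_id) < 2L || uniqueN(cells$month) < 2L)
    stop("fit_seasonal_trend needs >= 2 tags and >= 2 months", call. = FALSE)
  y0 <- min(cells$year)
  cells[, month_index := (year - y0) * 12L + month]
  cells[, `:=`(s1 = sin(2 * pi * month / 12), c1 = cos(2 * pi * month / 12),
               s2 = sin(4 * pi * month / 12), c2 = cos(4 * pi * month / 12))]
  fixed <- if (form == "harmonic") "s1 + c1 + s2 + c2" else "month_index"

  fml <- as.formula(paste("ordinal_code ~", fixed, "+ (1 | tag_id)"))
  fallback <- FALSE
  fit <- tryCatch({
    m <- lme4::lmer(fml, data = cells, weights = cells$w, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
    if (lme4::isSingular(m, tol = 1e-4)) NULL else m
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular or failed mixed fit; falling back to unweighted ",
            "fixed-effects fit", call. = FALSE)
    fallback <- TRUE
    fit <- stats::lm(as.formula(paste("ordinal_code ~", fixed)), data = cells)
  }
  beta <- if (fallback) coef(fit) else lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  ranef_var <- if (fallback) NA_real_ else
    as.numeric(lme4::VarCorr(fit)$tag_id[1, 1])

  # prediction band over the month axis (fixed effects only)
  if (form == "harmonic") {
    grid <- data.table(month = seq(1, 12, by = 0.25))
    X <- cbind(1, sin(2 * pi * grid$month / 12), cos(2 * pi * grid$month / 12),
               sin(4 * pi * grid$month / 12), cos(4 * pi * grid$month / 12))
  } else {
    grid <- data.table(month_index = seq(min(cells$month_index),
                                         max(cells$month_index), by = 0.25))
    X <- cbind(1, grid$month_index)
  }
  eta <- drop(X %*% beta)
  se <- sqrt(pmax(0, rowSums((X %*% V) * X)))
  grid[, `:=`(fit = eta, lwr = eta - 1.96 * se, upr = eta + 1.96 * se)]

  structure(list(method = form, backend = if (fallback) "lm" else "lmer",
                 fallback = fallback, coefficients = beta, vcov = V,
                 ranef_var = ranef_var, band = grid[], model = fit,
                 data = cells[]),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> ", x$method, " month terms, backend ", x$backend,
      if (x$fallback) " (fixed-effects fallback)", "\n", sep = "")
  print(round(x$coefficients, 4))
  if (!is.na(x$ranef_var))
    cat("tag random-intercept variance:", round(x$ranef_var, 4), "\n")
  invisible(x)
}
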