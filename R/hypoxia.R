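#' Classify dissolved-oxygen readings
#'
#' Hypoxia is defined as bottom dissolved oxygen strictly below the threshold
#' (default 2.0 mg/L); readings at or above the threshold are normoxic and
#' missing readings are `"unknown"`.
#'
#' @param do_mg_l Numeric vector of dissolved-oxygen readings (mg/L).
#' @param threshold Hypoxia threshold in mg/L (default 2.0, strict `<`).
#' @return Character vector in `{"hypoxic", "normoxic", "unknown"}`.
#' @export
classify_do <- function(do_mg_l, threshold = 2.0) {
  if (any(!is.na(do_mg_l) & do_mg_l < 0))
    stop("do_mg_l must be non-negative", call. = FALSE)
  out <- ifelse(is.na(do_mg_l), "unknown",
                ifelse(do_mg_l < threshold, "hypoxic", "normoxic"))
  out
}

#' Extract censored between-SMU transitions
#'
#' Scans each tag's valid detections within the stratified window for pairs of
#' consecutive detections in different SMUs. Pairs separated by `max_days` or
#' more are censored (longer gaps are uninformative about the conditions that
#' triggered the move). Each transition is coded by the rank difference of its
#' district ordinals (positive = eastward, zero = latitudinal within a
#' district) and by the dissolved-oxygen category of the origin SMU on the
#' start date.
#'
#' @inheritParams allocate_residency
#' @param smus `smu_set` providing `district` per SMU.
#' @param do_smu Daily SMU dissolved-oxygen table (columns `date`,
#'   `location_id` = smu_id, `do_mg_l`); rows with `location_type` other than
#'   `"smu"` are ignored if that column is present.
#' @param stratified_months Integer months defining the stratified window
#'   (default June-October).
#' @param max_days Censoring limit in days (default 21, strict `<`).
#' @param threshold Hypoxia threshold passed to [classify_do()].
#' @return `data.table` of transitions: `tag_id`, `t_start`, `t_end`,
#'   `from_smu`, `to_smu`, `from_district`, `to_district`, `rank_diff`,
#'   `duration_days`, `initial_condition`. The number of transitions with
#'   unknown initial DO is attached as attribute `n_unknown_do`.
#' @export
extract_transitions <- function(detections, receiver_map, smus, do_smu,
                                stratified_months = 6:10, max_days = 21,
                                threshold = 2.0) {
  det <- as.data.table(detections)
  det <- det[is.na(is_valid) | is_valid %in% TRUE]
  rmap <- as.data.table(receiver_map)[, .(receiver_id, smu_id)]
  det <- merge(det, rmap, by = "receiver_id", sort = FALSE)
  lt <- as.POSIXlt(det$timestamp, tz = "UTC")
  det <- det[(lt$mon + 1L) %in% stratified_months]
  setorder(det, tag_id, timestamp)
  empty <- data.table(tag_id = character(0),
                      t_start = as.POSIXct(character(), tz = "UTC"),
                      t_end = as.POSIXct(character(), tz = "UTC"),
                      from_smu = character(0), to_smu = character(0),
                      from_district = integer(0), to_district = integer(0),
                      rank_diff = integer(0), duration_days = numeric(0),
                      initial_condition = character(0))
  if (nrow(det) < 2L) {
    attr(empty, "n_unknown_do") <- 0L
    return(empty)
  }
  tr <- det[, {
    n <- .N
    if (n < 2L) NULL else {
      keep <- smu_id[-n] != smu_id[-1L]
      list(t_start = timestamp[-n][keep], t_end = timestamp[-1L][keep],
           from_smu = smu_id[-n][keep], to_smu = smu_id[-1L][keep])
    }
  }, by = tag_id]
  if (nrow(tr) == 0L) {
    attr(empty, "n_unknown_do") <- 0L
    return(empty)
  }
  tr[, duration_days := as.numeric(difftime(t_end, t_start, units = "days"))]
  tr <- tr[duration_days < max_days]
  dist <- smus$table[, .(smu_id, district)]
  tr <- merge(tr, dist[, .(from_smu = smu_id, from_district = district)],
              by = "from_smu", sort = FALSE)
  tr <- merge(tr, dist[, .(to_smu = smu_id, to_district = district)],
              by = "to_smu", sort = FALSE)
  tr[, rank_diff := to_district - from_district]
  do_tab <- as.data.table(do_smu)
  if ("location_type" %in% names(do_tab))
    do_tab <- do_tab[location_type == "smu"]
  do_tab <- do_tab[, .(from_smu = as.character(location_id),
                       date = as.Date(date), do_mg_l)]
  do_tab <- do_tab[, .(do_mg_l = mean(do_mg_l, na.rm = TRUE)),
                   by = .(from_smu, date)]
  tr[, date := as.Date(t_start, tz = "UTC")]
  tr <- merge(tr, do_tab, by = c("from_smu", "date"), all.x = TRUE,
              sort = FALSE)
  tr[, initial_condition := classify_do(do_mg_l, threshold)]
  n_unknown <- sum(tr$initial_condition == "unknown")
  tr[, c("date", "do_mg_l") := NULL]
  setcolorder(tr, c("tag_id", "t_start", "t_end", "from_smu", "to_smu",
                    "from_district", "to_district", "rank_diff",
                    "duration_days", "initial_condition"))
  setorder(tr, tag_id, t_start)
  attr(tr, "n_unknown_do") <- n_unknown
  tr[]
}

#' Rank-difference quantiles by dissolved-oxygen category
#'
#' Summarizes the distribution of longitudinal district rank differences for
#' transitions under each initial dissolved-oxygen category by its quartiles
#' and extremes.
#'
#' @param transitions Output of [extract_transitions()].
#' @param categories Categories to report (default hypoxic and normoxic;
#'   transitions with unknown initial conditions are excluded from
#'   contrasts).
#' @return `data.table` with `initial_condition`, `n`, `min`, `q25`,
#'   `median`, `q75`, `max`. Empty categories are omitted with a warning.
#' @export
rank_diff_quantiles <- function(transitions,
                                categories = c("hypoxic", "normoxic")) {
  tr <- as.data.table(transitions)[initial_condition %in% categories]
  absent <- setdiff(categories, unique(tr$initial_condition))
  if (length(absent))
    warning("no transitions in category: ", paste(absent, collapse = ", "),
            call. = FALSE)
  if (nrow(tr) == 0L)
    return(data.table(initial_condition = character(0), n = integer(0),
                      min = numeric(0), q25 = numeric(0), median = numeric(0),
                      q75 = numeric(0), max = numeric(0)))
  out <- tr[, {
    q <- quantile(rank_diff, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                  type = 7)
    list(n = .N, min = q[1], q25 = q[2], median = q[3], q75 = q[4],
         max = q[5])
  }, by = initial_condition]
  setorder(out, initial_condition)
  out[]
}

#' Match tag detections with logger dissolved-oxygen readings
#'
#' Restricts to depth-bearing detections at logger-equipped receivers,
#' collapses each tag's detections to one representative per day (the day's
#' first detection), and joins the logger's daily dissolved-oxygen reading.
#' Each tag-day yields the difference between receiver bottom depth and tag
#' depth (negative differences — apparent sub-bottom positions from
#' detection-at-a-distance and sensor noise — are retained as-is). Each pair
#' of successive tag-days additionally yields a movement indicator: pairs on
#' different receivers are moves carrying the change in tag depth and in
#' logger dissolved oxygen (later minus earlier, category from the earlier
#' receiver); pairs on the same receiver are non-moves. Pair fields are
#' attached to the earlier day's row (`NA` on each tag's last day).
#'
#' @inheritParams allocate_residency
#' @param do_logger Daily logger dissolved-oxygen table (columns `date`,
#'   `location_id` = receiver_id, `do_mg_l`); rows with `location_type` other
#'   than `"receiver"` are ignored if that column is present.
#' @param receivers Receiver table with `bottom_depth_m` and `has_logger`.
#' @param threshold Hypoxia threshold passed to [classify_do()].
#' @return `data.table` with one row per tag-day: `tag_id`, `day`,
#'   `receiver_id`, `tag_depth_m`, `receiver_depth_m`, `depth_diff_m`,
#'   `do_mg_l`, `category`, `moved`, `delta_depth_m`, `delta_do_mg_l`. The
#'   count of skipped depth-less detections is attached as attribute
#'   `n_skipped_no_depth`.
#' @export
match_loggers <- function(detections, do_logger, receivers, threshold = 2.0) {
  det <- as.data.table(detections)
  det <- det[is.na(is_valid) | is_valid %in% TRUE]
  rec <- as.data.table(receivers)
  logrec <- rec[has_logger %in% TRUE, .(receiver_id, bottom_depth_m)]
  det <- det[receiver_id %in% logrec$receiver_id]
  n_skip <- sum(is.na(det$tag_depth_m))
  det <- det[!is.na(tag_depth_m)]
  if (nrow(det) == 0L) {
    out <- data.table(tag_id = character(0), day = as.Date(character()),
                      receiver_id = character(0), tag_depth_m = numeric(0),
                      receiver_depth_m = numeric(0), depth_diff_m = numeric(0),
                      do_mg_l = numeric(0), category = character(0),
                      moved = logical(0), delta_depth_m = numeric(0),
                      delta_do_mg_l = numeric(0))
    attr(out, "n_skipped_no_depth") <- n_skip
    return(out)
  }
  det[, day := as.Date(timestamp, tz = "UTC")]
  setorder(det, tag_id, timestamp)
  daily <- det[, .SD[1L], by = .(tag_id, day)]  # first detection of the day
  daily <- merge(daily, logrec, by = "receiver_id", sort = FALSE)
  do_tab <- as.data.table(do_logger)
  if ("location_type" %in% names(do_tab))
    do_tab <- do_tab[location_type == "receiver"]
  do_tab <- do_tab[, .(do_mg_l = mean(do_mg_l, na.rm = TRUE)),
                   by = .(receiver_id = as.character(location_id),
                          day = as.Date(date))]
  daily <- merge(daily, do_tab, by = c("receiver_id", "day"), all.x = TRUE,
                 sort = FALSE)
  daily[, category := classify_do(do_mg_l, threshold)]
  daily[, `:=`(receiver_depth_m = bottom_depth_m,
               depth_diff_m = bottom_depth_m - tag_depth_m)]
  setorder(daily, tag_id, day)
  daily[, `:=`(
    moved = c(receiver_id[-1L] != receiver_id[-.N], NA),
    delta_depth_m = c(tag_depth_m[-1L] - tag_depth_m[-.N], NA),
    delta_do_mg_l = c(do_mg_l[-1L] - do_mg_l[-.N], NA)
  ), by = tag_id]
  daily[moved %in% FALSE, `:=`(delta_depth_m = NA_real_,
                               delta_do_mg_l = NA_real_)]
  out <- daily[, .(tag_id, day, receiver_id, tag_depth_m, receiver_depth_m,
                   depth_diff_m, do_mg_l, category, moved, delta_depth_m,
                   delta_do_mg_l)]
  attr(out, "n_skipped_no_depth") <- n_skip
  out[]
}

#' Long-format movement metrics for category comparison
#'
#' Reshapes logger matches into the four metric observation sets compared
#' between dissolved-oxygen categories: (A) difference between receiver and
#' tag depth per tag-day; (B) change in tag depth between successive tag-days
#' on different receivers; (C) change in logger dissolved oxygen across the
#' same pairs; (D) the 0/1 moved indicator per successive tag-day pair. Rows
#' with unknown category are dropped.
#'
#' @param matches Output of [match_loggers()].
#' @return `data.table` with columns `metric` (one of `"depth_diff"`,
#'   `"delta_depth"`, `"delta_do"`, `"moved"`), `tag_id`, `category`,
#'   `value`.
#' @export
movement_metrics <- function(matches) {
  m <- as.data.table(matches)
  if (nrow(m) == 0L) {
    warning("movement_metrics: empty input", call. = FALSE)
    return(data.table(metric = character(0), tag_id = character(0),
                      category = character(0), value = numeric(0)))
  }
  a <- m[category != "unknown" & !is.na(depth_diff_m),
         .(metric = "depth_diff", tag_id, category, value = depth_diff_m)]
  pairs <- m[!is.na(moved) & category != "unknown"]
  b <- pairs[moved %in% TRUE & !is.na(delta_depth_m),
             .(metric = "delta_depth", tag_id, category,
               value = delta_depth_m)]
  cc <- pairs[moved %in% TRUE & !is.na(delta_do_mg_l),
              .(metric = "delta_do", tag_id, category,
                value = delta_do_mg_l)]
  d <- pairs[, .(metric = "moved", tag_id, category,
                 value = as.numeric(moved))]
  out <- rbind(a, b, cc, d)
  out[]
}
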