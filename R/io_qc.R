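#' Read and validate pipeline input tables
#'
#' Readers for the five plain-text inputs of the exploitation-risk pipeline:
#' tag detections, receiver stations, tagged-fish metadata, commercial catch,
#' and daily bottom dissolved-oxygen readings, plus the SMU polygon layer
#' (GeoJSON). All timestamps are parsed as UTC instants; schema violations
#' raise errors naming the offending column, and unparseable timestamps raise
#' row-level errors.
#'
#' @param path Path to a CSV file (or GeoJSON file for [read_smus()]).
#' @return A `data.table` with typed columns (see Details), or for
#'   [read_smus()] an object of class `smu_set`.
#'
#' @details Expected columns:
#' \describe{
#'   \item{detections.csv}{`tag_id`, `receiver_id`, `timestamp_utc`
#'     (ISO-8601), `tag_depth_m` (blank allowed).}
#'   \item{receivers.csv}{`receiver_id`, `lon`, `lat`, `bottom_depth_m`,
#'     `has_logger`.}
#'   \item{tags.csv}{`tag_id`, `release_site`, `release_time_utc`,
#'     `total_length_mm`, `tag_model`, `battery_days`, `fate_override`
#'     (blank allowed).}
#'   \item{catch.csv}{`year`, `month`, `smu_id`, `pounds`.}
#'   \item{do_daily.csv}{`date`, `location_type` (`smu` or `receiver`),
#'     `location_id`, `do_mg_l`, `temp_c` (blank allowed).}
#' }
#' @name readers
NULL

.require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", file, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.parse_utc <- function(x, file, col) {
  x <- trimws(as.character(x))
  # accept "2019-11-01T00:00:00", with optional trailing "Z", or space-separated
  xs <- sub("Z$", "", sub("T", " ", x, fixed = TRUE))
  out <- as.POSIXct(rep(NA_real_, length(xs)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(xs[idx], fmt, tz = "UTC"), tz = "UTC")
  }
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop("unparseable timestamp in ", file, " column ", col, " at row(s) ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  out
}

#' @rdname readers
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .require_cols(df, c("tag_id", "receiver_id", "timestamp_utc"), path)
  dt <- data.table(
    tag_id = as.character(df$tag_id),
    receiver_id = as.character(df$receiver_id),
    timestamp = if (nrow(df)) .parse_utc(df$timestamp_utc, path, "timestamp_utc")
                else as.POSIXct(character(), tz = "UTC"),
    tag_depth_m = if ("tag_depth_m" %in% names(df))
      suppressWarnings(as.numeric(df$tag_depth_m)) else NA_real_,
    is_valid = NA
  )
  setorder(dt, tag_id, timestamp)
  dt[]
}

#' @rdname readers
#' @export
read_receivers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("receiver_id", "lon", "lat", "bottom_depth_m",
                      "has_logger"), path)
  dt <- as.data.table(df)
  dt[, receiver_id := as.character(receiver_id)]
  dt[, has_logger := as.logical(has_logger)]
  if (any(!is.finite(dt$bottom_depth_m) | dt$bottom_depth_m <= 0))
    stop("receivers: bottom_depth_m must be positive", call. = FALSE)
  dt[]
}

#' @rdname readers
#' @export
read_tags <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("tag_id", "release_site", "release_time_utc",
                      "total_length_mm", "tag_model", "battery_days"), path)
  dt <- as.data.table(df)
  dt[, tag_id := as.character(tag_id)]
  dt[, release_time := .parse_utc(release_time_utc, path, "release_time_utc")]
  dt[, release_time_utc := NULL]
  if (!"fate_override" %in% names(dt)) dt[, fate_override := NA_character_]
  dt[fate_override == "", fate_override := NA_character_]
  dt[]
}

#' @rdname readers
#' @export
read_catch <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("year", "month", "smu_id", "pounds"), path)
  dt <- as.data.table(df)
  if (any(dt$pounds < 0)) stop("catch: negative pounds", call. = FALSE)
  dt[, smu_id := as.character(smu_id)]
  dt[]
}

#' @rdname readers
#' @export
read_do <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("date", "location_type", "location_id", "do_mg_l"), path)
  dt <- as.data.table(df)
  dt[, date := as.Date(date)]
  dt[, location_id := as.character(location_id)]
  if (!"temp_c" %in% names(dt)) dt[, temp_c := NA_real_]
  if (any(!is.na(dt$do_mg_l) & dt$do_mg_l < 0))
    stop("do_daily: negative do_mg_l", call. = FALSE)
  dt[]
}

#' @rdname readers
#' @export
read_smus <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("smus: expected a GeoJSON FeatureCollection", call. = FALSE)
  feats <- gj$features
  tab <- rbindlist(lapply(feats, function(f) {
    p <- f$properties
    for (k in c("smu_id", "district", "jurisdiction", "ordinal_code"))
      if (is.null(p[[k]]))
        stop("smus: feature missing property ", k, call. = FALSE)
    data.table(smu_id = as.character(p$smu_id),
               district = as.integer(p$district),
               jurisdiction = as.character(p$jurisdiction),
               ordinal_code = as.integer(p$ordinal_code))
  }))
  polys <- lapply(feats, function(f) {
    g <- f$geometry
    if (is.null(g$type) || g$type != "Polygon")
      stop("smus: geometries must be Polygon", call. = FALSE)
    ring <- g$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    colnames(m) <- c("x", "y")
    m
  })
  names(polys) <- tab$smu_id
  if (anyDuplicated(tab$ordinal_code))
    stop("smus: ordinal_code values must be unique", call. = FALSE)
  structure(list(table = tab[], polygons = polys), class = "smu_set")
}

#' @export
print.smu_set <- function(x, ...) {
  cat("<smu_set> ", nrow(x$table), " spatial management units\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Read the full input bundle
#'
#' Convenience wrapper that reads all six pipeline inputs, reports row counts,
#' and flags detections that reference unknown receivers (rows are retained
#' but listed in the returned `unknown_receivers` attribute).
#'
#' @param paths Named list/vector with elements `detections`, `receivers`,
#'   `tags`, `smus`, and optionally `catch` and `do`.
#' @param quiet Suppress row-count messages.
#' @return Named list of validated tables: `detections`, `receivers`, `tags`,
#'   `smus`, and (if supplied) `catch`, `do`.
#' @export
read_inputs <- function(paths, quiet = FALSE) {
  paths <- as.list(paths)
  for (k in c("detections", "receivers", "tags", "smus")) {
    if (is.null(paths[[k]])) stop("read_inputs: missing path for ", k)
    if (!file.exists(paths[[k]])) stop("read_inputs: file not found: ",
                                       paths[[k]], call. = FALSE)
  }
  out <- list(
    detections = read_detections(paths$detections),
    receivers = read_receivers(paths$receivers),
    tags = read_tags(paths$tags),
    smus = read_smus(paths$smus)
  )
  if (!is.null(paths$catch)) out$catch <- read_catch(paths$catch)
  if (!is.null(paths$do)) out$do <- read_do(paths$do)
  unknown <- setdiff(unique(out$detections$receiver_id),
                     out$receivers$receiver_id)
  if (length(unknown)) {
    warning("detections reference unknown receiver_id(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  attr(out$detections, "unknown_receivers") <- unknown
  if (!quiet) {
    for (k in names(out)) {
      n <- if (inherits(out[[k]], "smu_set")) nrow(out[[k]]$table)
           else nrow(out[[k]])
      message(sprintf("read %s: %d rows", k, n))
    }
  }
  out
}

#' Flag false detections by the minimum-lag criterion
#'
#' A detection is considered valid if at least one other detection of the same
#' tag on the same receiver occurred within `min_lag_max_s` seconds of it
#' (before or after). Isolated pings with no such companion are flagged as
#' likely false detections. Flagged rows are retained, never dropped.
#'
#' @param detections Detection table from [read_detections()].
#' @param min_lag_max_s Maximum allowed minimum lag, seconds (default 3600).
#' @return The detection table with `is_valid` filled in, sorted by
#'   (tag_id, timestamp).
#' @export
filter_false_detections <- function(detections, min_lag_max_s = 3600) {
  if (!is.numeric(min_lag_max_s) || length(min_lag_max_s) != 1L ||
      !is.finite(min_lag_max_s) || min_lag_max_s <= 0)
    stop("min_lag_max_s must be a positive number", call. = FALSE)
  det <- as.data.table(detections)
  if (nrow(det) == 0L) {
    det[, is_valid := logical(0)]
    return(det[])
  }
  setorder(det, tag_id, receiver_id, timestamp)
  det[, `:=`(
    lag_prev = c(Inf, diff(as.numeric(timestamp))),
    lag_next = c(diff(as.numeric(timestamp)), Inf)
  ), by = .(tag_id, receiver_id)]
  det[, min_lag := pmin(lag_prev, lag_next)]
  det[, is_valid := min_lag <= min_lag_max_s]
  det[, c("lag_prev", "lag_next", "min_lag") := NULL]
  setorder(det, tag_id, timestamp, receiver_id)
  det[]
}

#' Classify tag fates
#'
#' Partitions every tag in the metadata table into `retained` or
#' `excluded(<reason>)`. Tags with no valid detections are
#' `excluded("never_detected")`; tags whose first-to-last valid-detection span
#' is shorter than `min_days` are `excluded("short_span")`; tags carrying a
#' non-blank `fate_override` in the metadata (e.g. `"harvested"`) are excluded
#' with that reason. Downstream analyses consume retained tags only.
#'
#' @param detections QC-flagged detection table (see
#'   [filter_false_detections()]).
#' @param tag_meta Tag metadata from [read_tags()].
#' @param min_days Minimum detection span in days (default 35).
#' @return `data.table` with one row per tag: `tag_id`, `fate`
#'   (`"retained"`/`"excluded"`), `reason` (`NA` for retained), `span_days`,
#'   `n_valid`.
#' @export
classify_tag_fates <- function(detections, tag_meta, min_days = 35) {
  det <- as.data.table(detections)
  meta <- as.data.table(tag_meta)
  orphan <- setdiff(unique(det$tag_id), meta$tag_id)
  if (length(orphan))
    stop("tags present in detections but absent from tag_meta: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  valid <- det[is_valid %in% TRUE]
  span <- valid[, .(
    span_days = as.numeric(difftime(max(timestamp), min(timestamp),
                                    units = "days")),
    n_valid = .N
  ), by = tag_id]
  fates <- merge(meta[, .(tag_id, fate_override =
                            if ("fate_override" %in% names(meta))
                              fate_override else NA_character_)],
                 span, by = "tag_id", all.x = TRUE)
  fates[is.na(n_valid), n_valid := 0L]
  fates[, `:=`(fate = "retained", reason = NA_character_)]
  fates[n_valid == 0L, `:=`(fate = "excluded", reason = "never_detected")]
  fates[n_valid > 0L & span_days < min_days,
        `:=`(fate = "excluded", reason = "short_span")]
  fates[!is.na(fate_override),
        `:=`(fate = "excluded", reason = fate_override)]
  fates[, fate_override := NULL]
  setorder(fates, tag_id)
  fates[]
}

# squared distance from point p to segment ab
.pt_seg_d2 <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  wx <- px - ax; wy <- py - ay
  L2 <- vx * vx + vy * vy
  t <- if (L2 > 0) pmin(1, pmax(0, (wx * vx + wy * vy) / L2)) else 0
  dx <- wx - t * vx; dy <- wy - t * vy
  dx * dx + dy * dy
}

.on_ring_boundary <- function(px, py, ring, tol) {
  n <- nrow(ring)
  for (i in seq_len(n - 1L)) {
    if (.pt_seg_d2(px, py, ring[i, 1], ring[i, 2],
                   ring[i + 1L, 1], ring[i + 1L, 2]) <= tol * tol)
      return(TRUE)
  }
  FALSE
}

#' Assign receivers to spatial management units
#'
#' Point-in-polygon assignment of each receiver to exactly one SMU. Receivers
#' falling on a shared boundary are assigned deterministically to the SMU with
#' the smaller district ordinal (the westward unit), ties broken by
#' lexicographic `smu_id`; each such resolution is reported via `message()`.
#' A receiver outside all polygons is an error naming the receiver.
#'
#' @param receivers Receiver table from [read_receivers()].
#' @param smus An `smu_set` from [read_smus()] or [build_lake()].
#' @param boundary_tol Distance tolerance (same units as the polygon
#'   coordinates) for the on-boundary test.
#' @return The receiver table with an `smu_id` column added.
#' @export
assign_smu <- function(receivers, smus, boundary_tol = 1e-9) {
  rec <- as.data.table(receivers)
  tab <- smus$table
  polys <- smus$polygons
  pts <- cbind(rec$lon, rec$lat)
  n <- nrow(rec)
  hit <- matrix(FALSE, n, length(polys))
  for (j in seq_along(polys)) {
    ring <- polys[[j]]
    inside <- mgcv::in.out(ring, pts)
    onb <- vapply(seq_len(n), function(i)
      .on_ring_boundary(pts[i, 1], pts[i, 2], ring, boundary_tol), logical(1))
    hit[, j] <- inside | onb
  }
  assigned <- character(n)
  ord <- order(tab$district, tab$smu_id)  # westward-first tie order
  for (i in seq_len(n)) {
    cand <- which(hit[i, ])
    if (!length(cand))
      stop("receiver ", rec$receiver_id[i],
           " falls outside all SMU polygons", call. = FALSE)
    pick <- ord[ord %in% cand][1L]
    if (length(cand) > 1L)
      message("receiver ", rec$receiver_id[i],
              " on shared boundary; assigned westward SMU ",
              tab$smu_id[pick])
    assigned[i] <- tab$smu_id[pick]
  }
  rec[, smu_id := assigned]
  stopifnot(sum(!is.na(rec$smu_id)) == n)
  rec[]
}
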