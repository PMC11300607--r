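# Independent oracles used to cross-check the package's implementations.
library(data.table)

# Brute-force minimum-lag scan: a detection is valid iff any other detection
# of the same tag on the same receiver lies within window_s of it.
oracle_min_lag <- function(det, window_s) {
  n <- nrow(det)
  valid <- logical(n)
  ts <- as.numeric(det$timestamp)
  for (i in seq_len(n)) {
    same <- det$tag_id == det$tag_id[i] &
      det$receiver_id == det$receiver_id[i]
    same[i] <- FALSE
    valid[i] <- any(abs(ts[same] - ts[i]) <= window_s)
  }
  valid
}

# Winding-number point-in-polygon (closed ring, last vertex repeats first).
oracle_point_in_poly <- function(px, py, ring) {
  wn <- 0
  n <- nrow(ring) - 1L
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    if (y1 <= py) {
      if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0)
        wn <- wn + 1
    } else {
      if (y2 <= py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0)
        wn <- wn - 1
    }
  }
  wn != 0
}

# Fine-grid residency oracle: discretize each between-detection interval and
# assign every grid cell to the SMU of the temporally nearest bounding
# detection, then tally days per month x SMU.
oracle_grid_residency <- function(times, smus, step_s = 600) {
  stopifnot(!is.unsorted(times))
  cells <- list()
  for (i in seq_len(length(times) - 1L)) {
    t1 <- as.numeric(times[i]); t2 <- as.numeric(times[i + 1L])
    if (t2 <= t1) next
    edges <- unique(c(seq(t1, t2, by = step_s), t2))
    mids <- (head(edges, -1) + edges[-1]) / 2
    durs <- diff(edges)
    smu <- ifelse(mids - t1 <= t2 - mids, smus[i], smus[i + 1L])
    lt <- as.POSIXlt(as.POSIXct(mids, origin = "1970-01-01", tz = "UTC"),
                     tz = "UTC")
    cells[[i]] <- data.table(year = lt$year + 1900L, month = lt$mon + 1L,
                             smu_id = smu, days = durs / 86400)
  }
  rbindlist(cells)[, .(days = sum(days)), by = .(year, month, smu_id)]
}

# Sort-based quantile oracle (type 7, as stats::quantile default).
oracle_quantiles <- function(x) {
  s <- sort(x)
  n <- length(s)
  sapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  })
}

# Random detection track in a toy two-SMU world, for allocation properties.
random_track <- function(n_det = 30, n_smu = 3,
                         start = as.POSIXct("2021-01-15 00:00:00",
                                            tz = "UTC")) {
  times <- start + cumsum(c(0, runif(n_det - 1, 60, 86400 * 20)))
  data.table(
    tag_id = "T1",
    receiver_id = paste0("R", sample.int(n_smu, n_det, replace = TRUE)),
    timestamp = times,
    tag_depth_m = NA_real_,
    is_valid = TRUE
  )
}

toy_receiver_map <- function(n_smu = 3) {
  data.table(receiver_id = paste0("R", seq_len(n_smu)),
             smu_id = paste0("S", seq_len(n_smu)))
}

# Minimal detection table constructor.
det_tab <- function(tag, rec, times, depth = NA_real_, valid = TRUE) {
  data.table(tag_id = tag, receiver_id = rec,
             timestamp = as.POSIXct(times, tz = "UTC"),
             tag_depth_m = depth, is_valid = valid)
}

# Small fast scenario for pipeline-level tests.
small_config <- function(...) {
  scenario_config(n_fish = 12L, n_months = 6L, detection_p = 0.4,
                  transmit_interval_s = 14400, ...)
}
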