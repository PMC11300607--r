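rmap <- toy_receiver_map(3)

test_that("gap splitting follows the temporal-midpoint rule", {
  # single SMU across one month
  d <- det_tab("T1", "R1", c("2021-03-01 00:00:00", "2021-03-31 00:00:00"))
  r <- allocate_residency(d, rmap)
  expect_equal(r$days, 30)
  expect_equal(r$smu_id, "S1")
  expect_equal(r$month, 3L)

  # A, A, B, B with a 10-day gap: midpoint Mar 15 splits it
  d2 <- det_tab("T1", c("R1", "R1", "R2", "R2"),
                c("2021-03-01 00:00:00", "2021-03-10 00:00:00",
                  "2021-03-20 00:00:00", "2021-03-31 00:00:00"))
  r2 <- allocate_residency(d2, rmap)
  expect_equal(r2[smu_id == "S1", days], 14)
  expect_equal(r2[smu_id == "S2", days], 16)
  # agrees with the fine-grid nearest-bounding-detection oracle
  orc <- oracle_grid_residency(d2$timestamp, c("S1", "S1", "S2", "S2"))
  expect_equal(r2[order(smu_id), days], orc[order(smu_id), days],
               tolerance = 1e-6)

  # cross-month gap: A Jan 30 -> B Feb 3, midpoint Feb 1 00:00
  d3 <- det_tab("T1", c("R1", "R2"),
                c("2021-01-30 00:00:00", "2021-02-03 00:00:00"))
  r3 <- allocate_residency(d3, rmap)
  expect_equal(r3[month == 1L, .(smu_id, days)],
               data.table::data.table(smu_id = "S1", days = 2))
  expect_equal(r3[month == 2L, .(smu_id, days)],
               data.table::data.table(smu_id = "S2", days = 2))
})

test_that("allocation conserves the detection span and respects month caps", {
  set.seed(21)
  for (i in 1:50) {
    d <- random_track(n_det = sample(5:40, 1))
    r <- allocate_residency(d, rmap)
    span <- as.numeric(difftime(max(d$timestamp), min(d$timestamp),
                                units = "days"))
    expect_lt(abs(sum(r$days) - span), 1e-6)
    month_len <- as.numeric(as.Date(ISOdate(r$year + (r$month == 12),
                                            r$month %% 12 + 1, 1)) -
                              as.Date(ISOdate(r$year, r$month, 1)))
    expect_true(all(r[, sum(days), by = .(year, month, smu_id)]$V1 <=
                      month_len + 1e-9))
  }
})

test_that("allocation equals the fine-grid oracle on random tracks", {
  set.seed(31)
  for (i in 1:50) {
    d <- random_track(n_det = sample(4:25, 1))
    r <- allocate_residency(d, rmap)
    smus <- rmap$smu_id[match(d$receiver_id, rmap$receiver_id)]
    orc <- oracle_grid_residency(d$timestamp, smus)
    cmp <- merge(r, orc, by = c("year", "month", "smu_id"), all = TRUE,
                 suffixes = c("", ".orc"))
    cmp[is.na(days), days := 0]
    cmp[is.na(days.orc), days.orc := 0]
    expect_lt(max(abs(cmp$days - cmp$days.orc)), 1 / 24)
  }
})

test_that("allocation is invariant to input row order", {
  set.seed(41)
  d <- random_track(n_det = 25)
  r1 <- allocate_residency(d, rmap)
  r2 <- allocate_residency(d[sample(.N)], rmap)
  expect_equal(r1, r2)
})

test_that("unknown receivers in detections are an error", {
  d <- det_tab("T1", "NOPE", "2021-03-01 00:00:00")
  expect_error(allocate_residency(d, rmap), "NOPE")
})

test_that("monthly summaries average over at-large tag-years", {
  rec <- data.table::data.table(
    tag_id = c("A", "B"), year = 2021L, month = 5L, smu_id = "S2",
    days = c(10, 20))
  s <- summarize_residency(rec)
  expect_equal(s$mean_days, 15)
  expect_equal(s$proportion, 1)

  # one tag, one year: records pass through verbatim
  one <- summarize_residency(rec[1])
  expect_equal(one$mean_days, 10)

  # proportions sum to 1 per month with several SMUs
  rec2 <- data.table::data.table(
    tag_id = "A", year = 2021L, month = c(5L, 5L, 6L),
    smu_id = c("S1", "S2", "S1"), days = c(12, 19, 30))
  s2 <- summarize_residency(rec2)
  expect_equal(s2[, sum(proportion), by = month]$V1, c(1, 1))

  expect_warning(e <- summarize_residency(rec[0]), "empty")
  expect_equal(nrow(e), 0L)
})

test_that("detection summaries count zeros for at-large tags", {
  # tag A: 10 detections in June on R3; tag B at large in June, none there
  dA <- det_tab("A", "R3", as.POSIXct("2021-06-10", tz = "UTC") + 1:10 * 60)
  dB <- det_tab("B", "R1", c("2021-05-20 00:00:00", "2021-07-20 00:00:00"))
  s <- detection_summary(rbind(dA, dB), rmap)
  expect_equal(s[month == 6L & smu_id == "S3", mean_detections], 5)
  one <- detection_summary(dA, rmap)
  expect_equal(one[month == 6L & smu_id == "S3", mean_detections], 10)

  # random fixture vs a brute-force tally
  set.seed(51)
  d <- random_track(60)[, tag_id := sample(c("A", "B"), .N, TRUE)]
  s2 <- detection_summary(d, rmap)
  lt <- as.POSIXlt(d$timestamp, tz = "UTC")
  d[, `:=`(month = lt$mon + 1L, year = lt$year + 1900L,
           smu = rmap$smu_id[match(receiver_id, rmap$receiver_id)])]
  spans <- d[, .(t0 = min(timestamp), t1 = max(timestamp)), by = tag_id]
  for (k in seq_len(nrow(s2))) {
    mo <- s2$month[k]
    n_al <- 0L
    for (i in seq_len(nrow(spans))) {
      months_i <- unique(format(seq(spans$t0[i], spans$t1[i], by = "day"),
                                "%Y-%m"))
      months_i <- unique(c(months_i, format(spans$t1[i], "%Y-%m")))
      n_al <- n_al + sum(as.integer(substr(months_i, 6, 7)) == mo)
    }
    cnt <- nrow(d[month == mo & smu == s2$smu_id[k]])
    expect_equal(s2$mean_detections[k], cnt / n_al)
  }
})

test_that("seasonal trend model recovers drift and degenerates sanely", {
  lake <- build_lake(scenario_config())
  rm8 <- lake$receivers[, .(receiver_id, smu_id)]

  # all detections in one SMU: constant fit at that ordinal (fallback path)
  rec1 <- lake$receivers[smu_id == "2 S"]$receiver_id[1]
  d <- data.table::rbindlist(lapply(c("A", "B"), function(tg)
    det_tab(tg, rec1, as.POSIXct("2021-01-15", tz = "UTC") +
              seq(0, 200, by = 10) * 86400)))
  f <- suppressWarnings(fit_seasonal_trend(d, rm8, lake$smus))
  ord2s <- lake$smus$table[smu_id == "2 S", ordinal_code]
  expect_equal(unname(f$band$fit), rep(ord2s, nrow(f$band)), tolerance = 1e-8)

  # equal weights reproduce the unweighted fixed-effect estimates
  set.seed(61)
  tags <- paste0("T", 1:6)
  obs <- data.table::CJ(tag_id = tags, month = 1:10)
  obs[, ord := pmin(8L, pmax(1L, round(2 + 0.5 * month +
                                         rnorm(.N, 0, 0.7))))]
  mkdet <- function(w) data.table::rbindlist(lapply(seq_len(nrow(obs)),
    function(i) {
      rid <- lake$receivers[smu_id == lake$smus$table[
        ordinal_code == obs$ord[i], smu_id]]$receiver_id[1]
      det_tab(obs$tag_id[i], rid,
              as.POSIXct(sprintf("2021-%02d-15", obs$month[i]), tz = "UTC") +
                seq_len(w) * 60)
    }))
  f1 <- fit_seasonal_trend(mkdet(1), rm8, lake$smus, form = "linear")
  expect_equal(unname(f1$coefficients["month_index"]), 0.5, tolerance = 0.15)

  # drift recovery: slope inside its 95% CI in >= 90% of 100 seeded runs
  first_rec <- sapply(lake$smus$table$smu_id, function(s)
    lake$receivers[smu_id == s]$receiver_id[1])
  names(first_rec) <- as.character(lake$smus$table$ordinal_code)
  hits <- 0L
  set.seed(71)
  for (r in 1:100) {
    cells <- data.table::CJ(tag = 1:8, month = 1:8)
    b <- rnorm(8, 0, 0.5)
    cells[, ord := pmin(8L, pmax(1L, round(2 + 0.5 * month + b[tag] +
                                             rnorm(.N, 0, 0.5))))]
    d <- data.table::data.table(
      tag_id = paste0("T", cells$tag),
      receiver_id = first_rec[as.character(cells$ord)],
      timestamp = as.POSIXct(sprintf("2021-%02d-15", cells$month),
                             tz = "UTC"),
      tag_depth_m = NA_real_, is_valid = TRUE)
    f <- suppressWarnings(fit_seasonal_trend(d, rm8, lake$smus,
                                             form = "linear"))
    est <- unname(f$coefficients["month_index"])
    se <- sqrt(f$vcov["month_index", "month_index"])
    if (abs(est - 0.5) <= 1.96 * se) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
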