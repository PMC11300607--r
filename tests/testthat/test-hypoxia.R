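lake8 <- build_lake(scenario_config())
rmap8 <- lake8$receivers[, .(receiver_id, smu_id)]

smu_do <- function(smu, dates, do) {
  data.table::data.table(date = as.Date(dates), location_type = "smu",
                         location_id = smu, do_mg_l = do)
}

test_that("dissolved-oxygen classification is strict at the threshold", {
  expect_equal(classify_do(1.9), "hypoxic")
  expect_equal(classify_do(2.0), "normoxic")
  expect_equal(classify_do(8.0), "normoxic")
  expect_equal(classify_do(NA_real_), "unknown")
  expect_error(classify_do(-0.1), "non-negative")

  # raising the threshold never converts a hypoxic call to normoxic
  set.seed(7)
  x <- runif(200, 0, 10)
  for (th in c(1, 2, 3, 5)) {
    lo <- classify_do(x, th)
    hi <- classify_do(x, th + 1)
    expect_true(all(!(lo == "hypoxic" & hi == "normoxic")))
  }
})

test_that("transitions are censored, coded by district rank, and DO-labelled", {
  rid <- function(smu) lake8$receivers[smu_id == smu]$receiver_id[1]
  d <- det_tab("T1",
               c(rid("2 S"), rid("3 S"),        # +1, 5-day gap
                 rid("3 N"),                     # lateral, 2-day gap
                 rid("1 S")),                    # 25-day gap: censored
               c("2021-07-01 00:00:00", "2021-07-06 00:00:00",
                 "2021-07-08 00:00:00", "2021-08-02 00:00:00"))
  do_tab <- rbind(smu_do("2 S", "2021-07-01", 1.2),
                  smu_do("3 S", "2021-07-06", 6.0))
  tr <- extract_transitions(d, rmap8, lake8$smus, do_tab)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$rank_diff, c(1L, 0L))
  expect_equal(tr$initial_condition, c("hypoxic", "normoxic"))
  expect_true(all(tr$duration_days < 21))

  # an exactly-21-day gap is censored (strict rule)
  d21 <- det_tab("T1", c(rid("2 S"), rid("3 S")),
                 c("2021-07-01 00:00:00", "2021-07-22 00:00:00"))
  expect_equal(nrow(extract_transitions(d21, rmap8, lake8$smus, do_tab)), 0L)

  # missing DO for the origin date -> unknown, counted in coverage attr
  dna <- det_tab("T1", c(rid("1 S"), rid("2 S")),
                 c("2021-07-01 00:00:00", "2021-07-03 00:00:00"))
  trna <- extract_transitions(dna, rmap8, lake8$smus, do_tab)
  expect_equal(trna$initial_condition, "unknown")
  expect_equal(attr(trna, "n_unknown_do"), 1L)

  # detections outside the stratified window produce no transitions
  dw <- det_tab("T1", c(rid("2 S"), rid("3 S")),
                c("2021-02-01 00:00:00", "2021-02-03 00:00:00"))
  expect_equal(nrow(extract_transitions(dw, rmap8, lake8$smus, do_tab)), 0L)
})

test_that("reversing a transition's endpoints negates its rank difference", {
  set.seed(17)
  rid_by_smu <- sapply(lake8$smus$table$smu_id, function(s)
    lake8$receivers[smu_id == s]$receiver_id[1])
  do_all <- smu_do(rep(lake8$smus$table$smu_id, each = 40),
                   rep(seq(as.Date("2021-06-01"), by = "day",
                           length.out = 40),
                       times = nrow(lake8$smus$table)),
                   runif(40 * 8, 0, 9))
  for (i in 1:20) {
    s <- sample(lake8$smus$table$smu_id, 2)
    t0 <- as.POSIXct("2021-06-05 00:00:00", tz = "UTC") + runif(1, 0, 20) * 86400
    fwd <- det_tab("T1", rid_by_smu[s], c(t0, t0 + 3 * 86400))
    rev <- det_tab("T1", rid_by_smu[rev(s)], c(t0, t0 + 3 * 86400))
    rf <- extract_transitions(fwd, rmap8, lake8$smus, do_all)
    rb <- extract_transitions(rev, rmap8, lake8$smus, do_all)
    expect_equal(rf$rank_diff, -rb$rank_diff)
  }
})

test_that("rank-difference quantiles match a sort-based oracle", {
  tr <- data.table::data.table(
    rank_diff = rep(2L, 5), initial_condition = "hypoxic")
  q <- rank_diff_quantiles(tr, categories = "hypoxic")
  expect_equal(q$median, 2)

  sym <- data.table::data.table(rank_diff = c(-1L, 0L, 1L),
                                initial_condition = "normoxic")
  expect_equal(rank_diff_quantiles(sym, "normoxic")$median, 0)

  set.seed(27)
  rnd <- data.table::data.table(
    rank_diff = sample(-3:3, 100, TRUE),
    initial_condition = sample(c("hypoxic", "normoxic"), 100, TRUE))
  q2 <- rank_diff_quantiles(rnd)
  for (cat in q2$initial_condition) {
    o <- oracle_quantiles(rnd[initial_condition == cat, rank_diff])
    expect_equal(unlist(q2[initial_condition == cat,
                           .(min, q25, median, q75, max)],
                        use.names = FALSE), o)
  }

  expect_warning(rank_diff_quantiles(sym), "hypoxic")
})

test_that("logger matching computes depth differences and movement deltas", {
  # two logger receivers in district 2/3 with known bottom depths
  logrec <- lake8$receivers[has_logger %in% TRUE][1:2]
  r1 <- logrec$receiver_id[1]; r2 <- logrec$receiver_id[2]
  b1 <- logrec$bottom_depth_m[1]; b2 <- logrec$bottom_depth_m[2]
  rec_fix <- data.table::copy(lake8$receivers)
  rec_fix[receiver_id == r1, bottom_depth_m := 18.7]

  d <- det_tab("T1", c(r1, r1, r2, r2),
               c("2021-07-01 06:00:00", "2021-07-01 09:00:00",  # same day
                 "2021-07-02 05:00:00", "2021-07-03 07:00:00"),
               depth = c(17.0, 12.0, 15.0, 16.5))
  do_log <- data.table::data.table(
    date = as.Date(c("2021-07-01", "2021-07-02", "2021-07-03")),
    location_type = "receiver",
    location_id = c(r1, r2, r2),
    do_mg_l = c(1.5, 6.0, 5.5))
  m <- match_loggers(d, do_log, rec_fix)
  expect_equal(nrow(m), 3L)  # three tag-days, first detection of day kept
  d1 <- m[day == as.Date("2021-07-01")]
  expect_equal(d1$tag_depth_m, 17.0)            # first of day, not 12.0
  expect_equal(d1$depth_diff_m, 18.7 - 17.0)    # +1.7 m demersal offset
  expect_equal(d1$category, "hypoxic")
  expect_true(d1$moved)                          # r1 -> r2 next tag-day
  expect_equal(d1$delta_depth_m, 15.0 - 17.0)
  expect_equal(d1$delta_do_mg_l, 6.0 - 1.5)
  d2 <- m[day == as.Date("2021-07-02")]
  expect_false(d2$moved)                         # same receiver next day
  expect_true(is.na(d2$delta_depth_m))           # no deltas without movement
  expect_true(is.na(m[day == as.Date("2021-07-03"), moved]))

  # depth-less detections at logger receivers are skipped with a count
  dnd <- rbind(d, det_tab("T1", r1, "2021-07-04 06:00:00", depth = NA_real_))
  m2 <- match_loggers(dnd, do_log, rec_fix)
  expect_equal(attr(m2, "n_skipped_no_depth"), 1L)
  expect_equal(nrow(m2), 3L)
})

test_that("movement metrics produce the four long-format observation sets", {
  m <- data.table::data.table(
    tag_id = "T1",
    day = as.Date("2021-07-01") + 0:4,
    receiver_id = c("a", "b", "b", "c", "c"),
    tag_depth_m = c(17, 15, 15.5, 14, 14),
    receiver_depth_m = 18, depth_diff_m = 18 - c(17, 15, 15.5, 14, 14),
    do_mg_l = c(1.5, 1.8, 1.9, 6, 6),
    category = c("hypoxic", "hypoxic", "hypoxic", "normoxic", "normoxic"),
    moved = c(TRUE, FALSE, TRUE, FALSE, NA),
    delta_depth_m = c(-2, NA, -1.5, NA, NA),
    delta_do_mg_l = c(0.3, NA, 4.1, NA, NA))
  mm <- movement_metrics(m)
  # 2 of 3 hypoxic-initial pairs moved
  mv <- mm[metric == "moved"]
  expect_equal(mean(mv[category == "hypoxic", value]), 2 / 3)
  expect_equal(nrow(mv), 4L)
  expect_equal(mm[metric == "delta_do" & category == "hypoxic", value],
               c(0.3, 4.1))
  expect_equal(nrow(mm[metric == "depth_diff"]), 5L)

  # no between-receiver pairs: delta metrics empty, depth_diff populated
  m2 <- data.table::copy(m)[, `:=`(moved = c(FALSE, FALSE, FALSE, FALSE, NA),
                                   delta_depth_m = NA_real_,
                                   delta_do_mg_l = NA_real_)]
  mm2 <- movement_metrics(m2)
  expect_equal(nrow(mm2[metric %in% c("delta_depth", "delta_do")]), 0L)
  expect_equal(nrow(mm2[metric == "depth_diff"]), 5L)
  expect_true(all(mm2[metric == "moved", value] == 0))

  # raw 3-of-4 moved proportion under hypoxic initial conditions
  m3 <- data.table::data.table(
    tag_id = "T1", day = as.Date("2021-07-01") + 0:3,
    receiver_id = c("a", "b", "c", "c"), tag_depth_m = 15,
    receiver_depth_m = 18, depth_diff_m = 3, do_mg_l = 1,
    category = "hypoxic",
    moved = c(TRUE, TRUE, TRUE, FALSE),
    delta_depth_m = c(0.1, 0.1, 0.1, NA),
    delta_do_mg_l = c(0.1, 0.1, 0.1, NA))
  mm3 <- movement_metrics(m3)
  expect_equal(mean(mm3[metric == "moved", value]), 0.75)
})
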