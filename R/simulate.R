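#' Scenario configuration for the synthetic study generator
#'
#' Returns the default configuration of the simulated lake study, optionally
#' overridden. The defaults describe a four-district lake split north/south
#' into 8 SMUs, a seeded seasonal west-east-west migration with a November
#' spawning aggregation in district 1, central-basin (districts 2-3) summer
#' hypoxia, a detection process with ~1 km effective range and +/- 0.9 m
#' depth-sensor noise, and a commercial catch matrix dominated by a November
#' district-1-south trap-net spike.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `scenario_config`.
#'
#' @details Key defaults:
#' \describe{
#'   \item{n_fish}{99 tagged fish, released at the spawning grounds on
#'     `start_date`.}
#'   \item{start_date, n_months}{`"2019-11-01"`, 12 months (one full annual
#'     migration cycle beginning at the November spawn).}
#'   \item{district_width_km, lake_height_km}{60 and 80 km; each district is
#'     split at mid-height into a south and a north SMU.}
#'   \item{receiver_spacing_km}{15 km systematic grid.}
#'   \item{detection_p, transmit_interval_s}{0.5 per transmission, 7200 s
#'     (12 transmissions/day), yielding realistic per-fish detection
#'     totals.}
#'   \item{depth_sensor_sd_m}{0.9 m Gaussian depth-sensor noise.}
#'   \item{hypoxia}{onset month 7, end month 9, districts 2-3, severity 1
#'     (bottom DO dips to ~1 mg/L at peak; severity 0 disables hypoxia).}
#'   \item{avoidance_strength}{5: eastward daily transition probability from
#'     a hypoxic SMU is multiplied by (1 + avoidance_strength).}
#'   \item{migration_schedule}{month -> target district (NA = undirected
#'     summer walk within the stratified season, when any eastward shift
#'     emerges from hypoxia avoidance alone).}
#'   \item{p_frac_never, p_frac_short}{0.08 never detected and 0.21 silenced
#'     before 35 days, exercising fate classification (~29% excluded).}
#' }
#' @export
scenario_config <- function(...) {
  cfg <- list(
    n_fish = 99L,
    start_date = "2019-11-01",
    n_months = 12L,
    district_width_km = 60,
    lake_height_km = 80,
    receiver_spacing_km = 15,
    district_depth_m = c(7.4, 18.5, 18.5, 24.4),
    detection_p = 0.5,
    transmit_interval_s = 7200,
    detection_range_km = 1,
    depth_sensor_sd_m = 0.9,
    logger_noise_sd = 0.3,
    hypoxia = list(onset_month = 7L, end_month = 9L, districts = c(2L, 3L),
                   severity = 1),
    avoidance_strength = 5,
    migration_schedule = c(`1` = 2, `2` = 2, `3` = 3, `4` = 3, `5` = 3,
                           `6` = NA, `7` = NA, `8` = NA, `9` = NA, `10` = NA,
                           `11` = 1, `12` = 2),
    bout_window_s = 7200,   # within-day detection bout length
    p_false_per_day = 0.01, # isolated spurious ping at a random receiver
    p_move = 0.25,          # undirected months: one-step move probability
    p_toward = 0.55,        # directed months: step toward target district
    p_away = 0.03,          # directed months: step away from target
    p_row_switch = 0.04,    # daily chance of a latitudinal (N/S) move
    p_row_return = 0.30,    # pull back toward the fish's home row
    south_home_frac = 0.72, # fraction of fish homed to the south row
    p_frac_never = 0.08,
    p_frac_short = 0.21,
    thresholds = list(do = 2.0, fate_days = 35, censor_days = 21,
                      min_lag_s = 3600),
    stratified_months = 6:10,
    catch_sigma = 0.5,
    catch_years = 2019:2022
  )
  over <- list(...)
  for (k in names(over)) {
    if (!k %in% names(cfg)) stop("unknown scenario option: ", k)
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(over[[k]]))
      utils::modifyList(cfg[[k]], over[[k]]) else over[[k]]
  }
  stopifnot(cfg$detection_p >= 0, cfg$detection_p <= 1,
            cfg$n_fish >= 1, cfg$n_months >= 1)
  structure(cfg, class = c("scenario_config", "list"))
}

# independent per-component RNG streams derived from the master seed
.subseed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 1000003) %% 2147483629 + 1
}

.sim_days <- function(cfg) {
  start <- as.Date(cfg$start_date)
  end <- seq(start, by = "month", length.out = cfg$n_months + 1L)[cfg$n_months + 1L]
  seq(start, end - 1, by = "day")
}

#' Build the synthetic lake: SMU polygons and receiver grid
#'
#' Lays out 8 rectangular SMUs (districts 1-4 west to east, each split into a
#' south and a north unit), a systematic receiver grid at the configured
#' spacing, and assigns dissolved-oxygen loggers to all central-basin
#' (districts 2-3) receivers. Coordinates are planar kilometres; the `lon`
#' and `lat` receiver columns carry x and y km.
#'
#' @param config A [scenario_config()].
#' @return List with `smus` (an `smu_set`) and `receivers` (a receiver table
#'   with `smu_id` already assigned).
#' @export
build_lake <- function(config = scenario_config()) {
  w <- config$district_width_km
  h <- config$lake_height_km
  sp <- config$receiver_spacing_km
  if (sp > w || sp > h / 2)
    stop("receiver_spacing_km exceeds district extent", call. = FALSE)
  rows <- c("S", "N")
  tab <- CJ(district = 1:4, row = rows, sorted = FALSE)
  setorder(tab, district, -row)  # S before N within district
  tab[, smu_id := paste(district, row)]
  tab[, jurisdiction := ifelse(row == "S", "OH", "ON")]
  tab[, ordinal_code := seq_len(.N)]
  polys <- lapply(seq_len(nrow(tab)), function(i) {
    d <- tab$district[i]
    y0 <- if (tab$row[i] == "S") 0 else h / 2
    m <- cbind(x = c((d - 1) * w, d * w, d * w, (d - 1) * w, (d - 1) * w),
               y = c(y0, y0, y0 + h / 2, y0 + h / 2, y0))
    m
  })
  names(polys) <- tab$smu_id
  smus <- structure(list(
    table = tab[, .(smu_id, district, jurisdiction, ordinal_code)],
    polygons = polys), class = "smu_set")

  gx <- seq(sp / 2, 4 * w, by = sp)
  gy <- seq(sp / 2, h, by = sp)
  rec <- CJ(lon = gx, lat = gy)
  rec[, receiver_id := sprintf("R%03d", seq_len(.N))]
  rec[, district := pmin(4L, as.integer(lon %/% w) + 1L)]
  rec[, row := ifelse(lat < h / 2, "S", "N")]
  rec[, smu_id := paste(district, row)]
  # deeper toward the lake's long axis, per-district mean depth
  rec[, bottom_depth_m := config$district_depth_m[district] *
        (0.85 + 0.3 * (1 - abs(lat - h / 2) / (h / 2)))]
  rec[, has_logger := district %in% c(2L, 3L)]
  rec[, c("district", "row") := NULL]
  setcolorder(rec, c("receiver_id", "lon", "lat", "bottom_depth_m",
                     "has_logger", "smu_id"))
  list(smus = smus, receivers = rec[])
}

#' Simulate the daily bottom dissolved-oxygen field
#'
#' Produces one reading per SMU-day (the forecast-style input) and one per
#' logger-receiver-day (the SMU value plus logger noise). Central-basin
#' districts decline below the hypoxia threshold between the onset and end
#' months following a half-sine severity curve scaled by
#' `hypoxia$severity`; outer districts stay normoxic.
#'
#' @param config A [scenario_config()].
#' @param lake Output of [build_lake()].
#' @param seed Integer seed (component stream derived from it).
#' @return `data.table` with `date`, `location_type` (`"smu"`/`"receiver"`),
#'   `location_id`, `do_mg_l`, `temp_c`.
#' @export
simulate_do_field <- function(config = scenario_config(), lake, seed = 1L) {
  set.seed(.subseed(seed, 1L))
  days <- .sim_days(config)
  hx <- config$hypoxia
  tab <- lake$smus$table
  grid <- CJ(smu_id = tab$smu_id, date = days)
  grid <- merge(grid, tab[, .(smu_id, district)], by = "smu_id")
  mon <- as.POSIXlt(grid$date)$mon + 1L
  frac <- (mon - hx$onset_month + 0.5) / (hx$end_month - hx$onset_month + 1)
  dip <- ifelse(mon >= hx$onset_month & mon <= hx$end_month,
                sin(pi * pmin(pmax(frac, 0), 1)), 0)
  base <- c(7.5, 8.5, 8.5, 9)[grid$district]
  affected <- grid$district %in% hx$districts
  grid[, do_mg_l := pmax(0, base - ifelse(affected, hx$severity * 7.5 * dip, 0) +
                           rnorm(.N, 0, 0.35))]
  grid[, temp_c := 22 - 0.4 * c(7.4, 18.5, 18.5, 24.4)[district] / 2 +
         rnorm(.N, 0, 0.5)]
  smu_rows <- grid[, .(date, location_type = "smu", location_id = smu_id,
                       do_mg_l = round(do_mg_l, 3),
                       temp_c = round(temp_c, 2))]
  # logger readings: SMU daily value plus sensor noise, at logger receivers
  logrec <- lake$receivers[has_logger %in% TRUE, .(receiver_id, smu_id)]
  lg <- merge(grid[, .(smu_id, date, do_mg_l)], logrec, by = "smu_id",
              allow.cartesian = TRUE)
  lg[, do_mg_l := pmax(0, do_mg_l + rnorm(.N, 0, config$logger_noise_sd))]
  log_rows <- lg[, .(date, location_type = "receiver",
                     location_id = receiver_id,
                     do_mg_l = round(do_mg_l, 3), temp_c = NA_real_)]
  out <- rbind(smu_rows, log_rows)
  setorder(out, location_type, location_id, date)
  out[]
}

#' Simulate daily fish tracks
#'
#' Each fish performs a daily Markov walk on the district ordinal. In months
#' with a migration target the fish steps toward the target district with
#' probability `p_toward`; in stratified months the walk is undirected
#' (`p_move` split evenly east/west) except that the eastward step
#' probability from a currently hypoxic SMU is multiplied by
#' `(1 + avoidance_strength)`. Latitudinal (N/S) moves occur independently at
#' a small daily rate, pulled back toward each fish's home row. True depth
#' follows the local bottom depth minus a demersal offset with small noise.
#'
#' @param config A [scenario_config()].
#' @param lake Output of [build_lake()].
#' @param do_field Output of [simulate_do_field()].
#' @param seed Integer seed.
#' @return `data.table` ground-truth track: `tag_id`, `date`, `district`,
#'   `row`, `smu_id`, `depth_m`.
#' @export
simulate_tracks <- function(config = scenario_config(), lake, do_field,
                            seed = 1L) {
  set.seed(.subseed(seed, 2L))
  days <- .sim_days(config)
  nf <- config$n_fish
  nd <- length(days)
  tags <- sprintf("F%03d", seq_len(nf))

  # hypoxia lookup: is SMU s hypoxic on day d?
  do_smu <- as.data.table(do_field)[location_type == "smu"]
  hyp <- do_smu[, .(date, smu_id = location_id,
                    hypoxic = do_mg_l < config$thresholds$do)]
  hypw <- dcast(hyp, date ~ smu_id, value.var = "hypoxic")
  hyp_dates <- as.character(hypw$date)
  hypM <- as.matrix(hypw[, !"date"])
  rownames(hypM) <- hyp_dates

  home_row <- ifelse(runif(nf) < config$south_home_frac, "S", "N")
  district <- rep(1L, nf)       # released at the district-1 spawning grounds
  row <- home_row
  depth_tab <- lake$receivers[, .(mean_depth = mean(bottom_depth_m)),
                              by = smu_id]
  depth_lookup <- setNames(depth_tab$mean_depth, depth_tab$smu_id)
  sched <- config$migration_schedule

  out_district <- matrix(0L, nd, nf)
  out_row <- matrix("", nd, nf)
  mons <- as.POSIXlt(days)$mon + 1L
  day_chr <- as.character(days)
  for (i in seq_len(nd)) {
    m <- mons[i]
    target <- sched[[as.character(m)]]
    smu_now <- paste(district, row)
    is_hyp <- hypM[day_chr[i], smu_now]
    is_hyp[is.na(is_hyp)] <- FALSE
    if (is.na(target)) {
      p_east <- rep(config$p_move / 2, nf)
      p_west <- rep(config$p_move / 2, nf)
      p_east <- ifelse(is_hyp, pmin(0.95, p_east *
                                      (1 + config$avoidance_strength)), p_east)
    } else {
      p_east <- ifelse(district < target, config$p_toward,
                       ifelse(district > target, config$p_away,
                              config$p_away))
      p_west <- ifelse(district > target, config$p_toward,
                       ifelse(district < target, config$p_away,
                              config$p_away))
    }
    p_east[district == 4L] <- 0
    p_west[district == 1L] <- 0
    u <- runif(nf)
    step <- ifelse(u < p_east, 1L, ifelse(u < p_east + p_west, -1L, 0L))
    district <- pmin(4L, pmax(1L, district + step))
    p_sw <- ifelse(row == home_row, config$p_row_switch, config$p_row_return)
    flip <- runif(nf) < p_sw
    row <- ifelse(flip, ifelse(row == "S", "N", "S"), row)
    out_district[i, ] <- district
    out_row[i, ] <- row
  }
  tr <- data.table(
    tag_id = rep(tags, each = nd),
    date = rep(days, nf),
    district = as.integer(out_district),
    row = as.vector(out_row)
  )
  tr[, smu_id := paste(district, row)]
  tr[, depth_m := pmax(1, depth_lookup[smu_id] - 1.5 + rnorm(.N, 0, 0.5))]
  tr[]
}

#' Simulate the acoustic detection process
#'
#' Locates each fish-day at the receiver of its current SMU nearest to the
#' fish's persistent latent position, then draws detections per transmission
#' (`86400 / transmit_interval_s` transmissions per day, each detected with
#' probability `detection_p`). Recorded tag depth adds Gaussian sensor noise
#' (`depth_sensor_sd_m`). A configured fraction of tags is never detected and
#' another fraction falls silent before the fate threshold, exercising tag
#' fate classification downstream.
#'
#' @param tracks Output of [simulate_tracks()].
#' @param lake Output of [build_lake()].
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return List with `detections` (tag_id, receiver_id, timestamp,
#'   tag_depth_m, is_valid = NA) and `tag_meta`.
#' @export
simulate_detections <- function(tracks, lake, config = scenario_config(),
                                seed = 1L) {
  set.seed(.subseed(seed, 3L))
  rec <- lake$receivers
  tr <- as.data.table(tracks)
  tags <- sort(unique(tr$tag_id))
  nf <- length(tags)
  h <- config$lake_height_km
  w <- config$district_width_km

  # persistent per-fish latent offsets inside an SMU rectangle
  xjit <- runif(nf, 0.1, 0.9)
  yjit <- runif(nf, 0.1, 0.9)
  names(xjit) <- names(yjit) <- tags

  tr[, `:=`(fx = (district - 1 + xjit[tag_id]) * w,
            fy = (ifelse(row == "S", 0, h / 2) + yjit[tag_id] * h / 2))]
  # nearest receiver within the current SMU
  recs_by_smu <- split(rec, rec$smu_id)
  tr[, receiver_id := {
    rs <- recs_by_smu[[.BY$smu_id]]
    d2 <- outer(fx, rs$lon, "-")^2 + outer(fy, rs$lat, "-")^2
    rs$receiver_id[max.col(-d2)]
  }, by = smu_id]

  n_tx <- max(1L, as.integer(86400 / config$transmit_interval_s))
  tr[, n_hit := rbinom(.N, n_tx, config$detection_p)]

  # tag fates: some never transmit usefully, some fall silent early
  u <- runif(nf)
  never <- u < config$p_frac_never
  short <- !never & u < config$p_frac_never + config$p_frac_short
  cutoff_days <- ifelse(short, runif(nf, 3, config$thresholds$fate_days - 1),
                        Inf)
  names(cutoff_days) <- tags
  start <- as.Date(config$start_date)
  tr[, day_index := as.numeric(date - start)]
  tr[tag_id %in% tags[never], n_hit := 0L]
  tr[day_index >= cutoff_days[tag_id], n_hit := 0L]

  # detections cluster in a within-day bout while the fish is in range
  hits <- tr[n_hit > 0L]
  bw <- min(config$bout_window_s, 86400)
  hits[, bout0 := runif(.N, 0, 86400 - bw)]
  det <- hits[rep(seq_len(.N), n_hit)]
  det[, timestamp := as.POSIXct(as.character(date), tz = "UTC") + bout0 +
        runif(.N, 0, bw)]
  det[, tag_depth_m := pmax(0, depth_m + rnorm(.N, 0, config$depth_sensor_sd_m))]
  det <- det[, .(tag_id, receiver_id, timestamp, tag_depth_m, is_valid = NA)]

  # occasional isolated spurious pings at random receivers (false detections)
  alive <- tr[!(tag_id %in% tags[never]) & day_index < cutoff_days[tag_id]]
  fd <- alive[runif(.N) < config$p_false_per_day]
  if (nrow(fd)) {
    fd[, receiver_id := sample(rec$receiver_id, .N, replace = TRUE)]
    fd[, timestamp := as.POSIXct(as.character(date), tz = "UTC") +
         runif(.N, 0, 86399.9)]
    fd[, tag_depth_m := pmax(0, depth_m + rnorm(.N, 0,
                                                config$depth_sensor_sd_m))]
    det <- rbind(det, fd[, .(tag_id, receiver_id, timestamp, tag_depth_m,
                             is_valid = NA)])
  }
  setorder(det, tag_id, timestamp)

  meta <- data.table(
    tag_id = tags,
    release_site = "district-1 spawning reef",
    release_time = as.POSIXct(paste(config$start_date, "00:00:00"),
                              tz = "UTC"),
    total_length_mm = round(pmax(350, rnorm(nf, 550, 50))),
    tag_model = "V13-TP",
    battery_days = 584L,
    fate_override = NA_character_
  )
  list(detections = det[], tag_meta = meta[])
}

#' Simulate the commercial catch records
#'
#' Draws yearly month-by-SMU catches (pounds) from a Poisson-lognormal model
#' around the configured intensity profile. The default profile mirrors the
#' reported Lake Erie demersal-gear mean catch matrix mapped onto the
#' synthetic SMUs (see [lake_erie_catch_matrix()]), so the November
#' district-1-south cell has the largest expected value by construction and
#' several month x SMU cells are structural zeros (refuges).
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @param profile Optional `data.table` (`month`, `smu_id`, `intensity`)
#'   overriding the default intensity profile.
#' @return `data.table` of catch records: `year`, `month`, `smu_id`,
#'   `pounds`.
#' @export
simulate_catch <- function(config = scenario_config(), seed = 1L,
                           profile = NULL) {
  set.seed(.subseed(seed, 4L))
  if (is.null(profile)) profile <- default_catch_profile()
  prof <- as.data.table(profile)
  years <- config$catch_years
  out <- prof[rep(seq_len(.N), length(years))]
  out[, year := rep(years, each = nrow(prof))]
  sig <- config$catch_sigma
  lambda <- out$intensity * rlnorm(nrow(out), -sig^2 / 2, sig)
  out[, pounds := ifelse(intensity <= 0, 0, rpois(.N, pmin(lambda, 1e7)))]
  out[, intensity := NULL]
  setcolorder(out, c("year", "month", "smu_id", "pounds"))
  out[pounds > 0][]
}

#' Default synthetic catch intensity profile
#'
#' The bundled Lake Erie 2019-2022 demersal-gear mean catch matrix with its
#' eight SMU columns mapped west-to-east onto the synthetic lake's SMUs
#' (`"1 S"`, `"1 N"`, ..., `"4 N"`).
#'
#' @return `data.table` with `month`, `smu_id`, `intensity` (pounds).
#' @export
default_catch_profile <- function() {
  real <- lake_erie_catch_matrix()
  map <- c("1 OH" = "1 S", "1 ON" = "1 N", "2 OH" = "2 S", "2 ON" = "2 N",
           "3 OH/PA" = "3 S", "3 ON" = "3 N", "4 NY/PA" = "4 S",
           "4 ON" = "4 N")
  prof <- as.data.table(real)
  prof[, smu_id := map[smu_id]]
  setnames(prof, "mean_catch_lb", "intensity")
  prof[, .(month, smu_id, intensity)]
}

#' Generate a complete seeded synthetic study
#'
#' Runs every generator stage and returns the bundle consumed by the analysis
#' pipeline together with its ground truth. The master seed fully determines
#' all outputs; each component draws from an independent stream derived from
#' it.
#'
#' @param config A [scenario_config()].
#' @param seed Integer master seed.
#' @return List: `config`, `seed`, `smus`, `receivers`, `do` (DO readings),
#'   `tracks` (true daily SMU and depth per fish), `detections`, `tag_meta`,
#'   `catch`, and `true_occupancy` (true days per tag x year x month x SMU).
#' @export
simulate_scenario <- function(config = scenario_config(), seed = 1L) {
  lake <- build_lake(config)
  do_field <- simulate_do_field(config, lake, seed)
  tracks <- simulate_tracks(config, lake, do_field, seed)
  dd <- simulate_detections(tracks, lake, config, seed)
  catch <- simulate_catch(config, seed)
  lt <- as.POSIXlt(tracks$date)
  occ <- tracks[, .(tag_id, year = lt$year + 1900L, month = lt$mon + 1L,
                    smu_id)][, .(days = .N), by = .(tag_id, year, month, smu_id)]
  list(config = config, seed = seed, smus = lake$smus,
       receivers = lake$receivers, do = do_field, tracks = tracks,
       detections = dd$detections, tag_meta = dd$tag_meta, catch = catch,
       true_occupancy = occ[])
}

#' Write a synthetic scenario bundle to disk
#'
#' Writes the exact CSV/GeoJSON dialects consumed by [read_inputs()], plus
#' ground-truth files for tests (`true_tracks.csv`, `true_occupancy.csv`).
#'
#' @param bundle Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(detections = file.path(dir, "detections.csv"),
         receivers = file.path(dir, "receivers.csv"),
         tags = file.path(dir, "tags.csv"),
         smus = file.path(dir, "smus.geojson"),
         catch = file.path(dir, "catch.csv"),
         do = file.path(dir, "do_daily.csv"),
         true_tracks = file.path(dir, "true_tracks.csv"),
         true_occupancy = file.path(dir, "true_occupancy.csv"))
  det <- bundle$detections[, .(
    tag_id, receiver_id,
    timestamp_utc = format(timestamp, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
    tag_depth_m = round(tag_depth_m, 3))]
  fwrite(det, p["detections"])
  fwrite(bundle$receivers[, .(receiver_id, lon, lat,
                              bottom_depth_m = round(bottom_depth_m, 2),
                              has_logger)], p["receivers"])
  tags <- bundle$tag_meta[, .(
    tag_id, release_site,
    release_time_utc = format(release_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    total_length_mm, tag_model, battery_days, fate_override)]
  fwrite(tags, p["tags"])
  write_smus_geojson(bundle$smus, p["smus"])
  fwrite(bundle$catch, p["catch"])
  fwrite(bundle$do, p["do"])
  fwrite(bundle$tracks[, .(tag_id, date, smu_id, depth_m = round(depth_m, 3))],
         p["true_tracks"])
  fwrite(bundle$true_occupancy, p["true_occupancy"])
  invisible(p)
}

#' Write an `smu_set` as GeoJSON
#'
#' @param smus An `smu_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_smus_geojson <- function(smus, path) {
  feats <- lapply(seq_len(nrow(smus$table)), function(i) {
    ring <- smus$polygons[[smus$table$smu_id[i]]]
    list(
      type = "Feature",
      properties = list(smu_id = smus$table$smu_id[i],
                        district = smus$table$district[i],
                        jurisdiction = smus$table$jurisdiction[i],
                        ordinal_code = smus$table$ordinal_code[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)), function(j)
                        c(ring[j, 1], ring[j, 2]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
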