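test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_participants = 1), class = "modesense_config_error")
  expect_error(sim_config(mode_mix = c(walk = 0.7, bike = 0.7,
                                       public_transport = -0.2,
                                       private_motorized = -0.2)),
               class = "modesense_config_error")
  expect_error(sim_config(mode_mix = c(walk = 0.5, bike = 0.1,
                                       public_transport = 0.1,
                                       private_motorized = 0.1)),
               class = "modesense_config_error")
  expect_error(sim_config(participant_heterogeneity =
                            list(resting_hr_sd = -1, walk_speed_sd = 0,
                                 accel_log_sd = 0)),
               class = "modesense_config_error")
})

test_that("same config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_participants = 2, n_days = 1, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$timetable, b$timetable)
  expect_identical(a$gps, b$gps)
  expect_identical(a$accel, b$accel)
  expect_identical(a$rr, b$rr)
  expect_identical(a$participants, b$participants)
})

test_that("zero trips per day yields a single all-day activity_place episode", {
  cfg <- sim_config(n_participants = 2, n_days = 2, seed = 3, trips_per_day = 0)
  co <- generate_cohort(cfg, sensors = FALSE)
  expect_true(all(co$timetable$mode == "activity_place"))
  # one episode per participant-day spanning the whole waking window
  expect_equal(nrow(co$timetable), 2L * 2L)
  expect_true(all(co$timetable$end_minute - co$timetable$start_minute ==
                  cfg$day_minutes))
})

test_that("episodes tile each day without overlap, transport flanked by places", {
  cfg <- sim_config(n_participants = 6, n_days = 2, seed = 9)
  tt <- generate_cohort(cfg, sensors = FALSE)$timetable
  for (key in split(tt, by = c("participant_id", "day"))) {
    data.table::setorder(key, start_minute)
    expect_true(all(key$start_minute < key$end_minute))
    # no holes, no overlaps: each episode starts where the previous ended
    expect_equal(key$start_minute[-1L], key$end_minute[-nrow(key)])
    expect_equal(sum(key$end_minute - key$start_minute), cfg$day_minutes)
    # first and last episodes of the day are activity places
    expect_equal(key$mode[1L], "activity_place")
    expect_equal(key$mode[nrow(key)], "activity_place")
    # a multi-stage trip is consecutive transport episodes between places
    if (any(!is.na(key$trip_id)))
      for (tid in unique(stats::na.omit(key$trip_id))) {
        idx <- which(!is.na(key$trip_id) & key$trip_id == tid)
        expect_equal(idx, seq(min(idx), max(idx)))
        expect_true(all(key$mode[idx] %in% transport_levels()))
      }
  }
})

test_that("schedule calibration hits the trips/day and time-on-trips targets", {
  cfg <- sim_config(n_participants = 60, n_days = 7, seed = 17)
  tt <- generate_cohort(cfg, sensors = FALSE)$timetable
  # median daily trip count within +-20% of 5.1
  trips <- tt[!is.na(trip_id),
              .(n = data.table::uniqueN(trip_id)),
              by = .(participant_id, day)]
  expect_gt(median(trips$n), 5.1 * 0.8)
  expect_lt(median(trips$n), 5.1 * 1.2)
  # median fraction of follow-up on trips within +-20% of 0.069
  frac <- tt[, .(f = sum((end_minute - start_minute)[mode != "activity_place"]) /
                   sum(end_minute - start_minute)), by = participant_id]
  expect_gt(median(frac$f), 0.069 * 0.8)
  expect_lt(median(frac$f), 0.069 * 1.2)
  # activity place is the majority class by a wide margin
  expect_gt(median(1 - frac$f), 0.85)
})

test_that("GPS simulation matches the mode signatures", {
  cfg <- sim_config(n_participants = 2, n_days = 1, seed = 21)
  eff <- neutral_effects()
  set.seed(1)
  # activity place: all speeds below 1 km/h under default noise
  g_place <- simulate_gps(make_episode("activity_place"),
                          default_mode_signatures()[mode == "activity_place"],
                          eff, cfg)
  expect_true(all(g_place$speed < 1))
  expect_true(all(g_place$sat_used <= g_place$sat_in_view))
  expect_true(all(g_place$hdop > 0 & g_place$vdop > 0 & g_place$pdop > 0))
  # public transport PDOP exceeds walking PDOP on average (underground mix)
  set.seed(2)
  pool <- function(m) unlist(lapply(1:10, function(i)
    simulate_gps(make_episode(m), default_mode_signatures()[mode == m],
                 eff, cfg)$pdop))
  expect_gt(mean(pool("public_transport")), mean(pool("walk")))
  # bike speeds centre on the configured signature mean across episodes
  set.seed(3)
  sig <- default_mode_signatures()[mode == "bike"]
  sp <- vapply(1:40, function(i)
    mean(simulate_gps(make_episode("bike"), sig, eff, cfg)$speed), numeric(1))
  expect_lt(abs(mean(sp) - sig$speed_mean), 2 * sig$speed_sd / sqrt(40) + 0.5)
})

test_that("accelerometer simulation: walk > bike, lfe >= standard, no steps at rest", {
  cfg <- sim_config(n_participants = 2, n_days = 1, seed = 21)
  eff <- neutral_effects()
  set.seed(4)
  vm <- function(d) sqrt(d$counts_axis1^2 + d$counts_axis2^2 + d$counts_axis3^2)
  pool <- function(m) data.table::rbindlist(lapply(1:8, function(i)
    simulate_accel(make_episode(m), default_mode_signatures()[mode == m],
                   eff, cfg)))
  aw <- pool("walk"); ab <- pool("bike"); ap <- pool("activity_place")
  expect_gt(mean(vm(aw[filter_variant == "standard"])),
            mean(vm(ab[filter_variant == "standard"])))
  expect_true(all(ap$steps == 0))
  # lfe counts dominate standard counts epoch-wise, per axis
  for (d in list(aw, ab, ap)) {
    s <- d[filter_variant == "standard"]; l <- d[filter_variant == "lfe"]
    expect_true(all(l$counts_axis1 >= s$counts_axis1))
    expect_true(all(l$counts_axis2 >= s$counts_axis2))
    expect_true(all(l$counts_axis3 >= s$counts_axis3))
  }
})

test_that("RR simulation: intensity ordering, zero-noise exactness, time conservation", {
  eff <- neutral_effects()
  set.seed(5)
  cfg <- sim_config(n_participants = 2, n_days = 1, seed = 21)
  hrm <- function(m) mean(60000 / data.table::rbindlist(lapply(1:8, function(i)
    simulate_rr(make_episode(m), default_mode_signatures()[mode == m],
                eff, cfg)))$rr_ms)
  hr_bike <- hrm("bike"); hr_walk <- hrm("walk"); hr_place <- hrm("activity_place")
  expect_gt(hr_bike, hr_walk)
  expect_gt(hr_walk, hr_place)
  # zero noise, resting RR 1000 ms: every interval is exactly 1000 ms
  cfg0 <- sim_config(n_participants = 2, n_days = 1, seed = 1, rr_rest_ms = 1000,
                     hr_noise = list(minute_sd = 0, sdnn_base = 0,
                                     sdnn_slope = 0, sdnn_min = 0),
                     participant_heterogeneity = list(resting_hr_sd = 0,
                                                      walk_speed_sd = 0,
                                                      accel_log_sd = 0))
  sig0 <- default_mode_signatures()[mode == "activity_place"]
  sig0$hr_elev_mean <- 0; sig0$hr_elev_sd <- 0
  eff0 <- neutral_effects(); eff0$resting_hr <- 60
  r0 <- simulate_rr(make_episode("activity_place", 0L, 5L), sig0, eff0, cfg0)
  expect_true(all(r0$rr_ms == 1000))
  expect_equal(nrow(r0), 5L * 60L)   # 60 beats fill each minute exactly
  # beats per minute approximate 60000 / mean RR
  set.seed(6)
  r1 <- simulate_rr(make_episode("walk", 0L, 30L),
                    default_mode_signatures()[mode == "walk"], eff, cfg)
  expect_equal(nrow(r1) / 30, 60000 / mean(r1$rr_ms), tolerance = 0.05)
})

test_that("sensor streams cover scheduled minutes minus wear gaps", {
  cfg <- sim_config(n_participants = 3, n_days = 1, seed = 13, wear_gap_rate = 0)
  co <- generate_cohort(cfg)
  m0 <- as.numeric(as.POSIXct(cfg$start_date, tz = "UTC")) / 60
  for (p in co$participants$participant_id) {
    sched_min <- m0 + co$timetable[participant_id == p,
                                   unlist(Map(seq, start_minute, end_minute - 1L))]
    gps_min <- unique(floor(as.numeric(co$gps[participant_id == p, timestamp]) / 60))
    expect_setequal(gps_min, sched_min)
  }
})
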