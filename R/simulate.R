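## Synthetic multi-sensor cohort generator.
##
## A cohort is a set of participants followed over several days. Each waking
## day is tiled by episodes: stays at activity places alternating with trips,
## each trip made of one or more trip stages with a single transport mode.
## Three sensor streams (GPS fixes, 5-s accelerometer epochs, RR intervals)
## are generated per episode, with participant-level random effects and
## per-sensor non-wear gaps.

## Integer split of `total` into length(weights) parts, each >= min_each,
## proportional to weights; parts sum exactly to total.
split_int <- function(total, weights, min_each = 1L) {
  k <- length(weights)
  if (k == 0L) return(integer(0))
  if (total < k * min_each) {
    # not enough room: give min_each until exhausted
    out <- rep(0L, k)
    out[seq_len(min(k, total %/% max(min_each, 1L)))] <- min_each
    out[1] <- out[1] + total - sum(out)
    return(out)
  }
  rem <- total - k * min_each
  w <- weights / sum(weights)
  raw <- w * rem
  fl <- floor(raw)
  extra <- rem - sum(fl)
  add <- rep(0L, k)
  if (extra > 0) add[order(raw - fl, decreasing = TRUE)[seq_len(extra)]] <- 1L
  as.integer(min_each + fl + add)
}

#' Draw participant-level random effects
#'
#' One draw per participant of the Gaussian random effects that induce
#' between-participant heterogeneity: resting heart rate, habitual walking
#' speed, and a multiplicative accelerometer count intensity. Also draws
#' body weight and GPS anchor coordinates.
#'
#' @param cfg A [sim_config()].
#' @return A `data.table` with one row per participant.
#' @export
draw_participant_effects <- function(cfg) {
  n <- cfg$n_participants
  het <- cfg$participant_heterogeneity
  data.table::data.table(
    participant_id = sprintf("P%03d", seq_len(n)),
    resting_hr = 60000 / cfg$rr_rest_ms + rnorm(n, 0, het$resting_hr_sd),
    walk_speed_shift = rnorm(n, 0, het$walk_speed_sd),
    accel_mult = exp(rnorm(n, 0, het$accel_log_sd)),
    body_weight_kg = pmax(45, rnorm(n, cfg$body_weight_mean, cfg$body_weight_sd)),
    base_lat = 48.85 + rnorm(n, 0, 0.08),
    base_lon = 2.35 + rnorm(n, 0, 0.12),
    elev_base = rnorm(n, 60, 15)
  )
}

#' Generate the episode schedule for one participant-day
#'
#' Tiles one waking day with episodes: activity-place stays alternating with
#' trips; each trip comprises one or more trip stages, each with one
#' transport mode (consecutive stages of a trip never share a mode). Trip
#' counts are Poisson around `trips_per_day`; trip durations are gamma
#' distributed with mean chosen so the expected fraction of the day on trips
#' matches `time_on_trips_frac`. With zero trips the whole day is a single
#' activity-place episode.
#'
#' @param effects One row of [draw_participant_effects()] (currently unused
#'   by the schedule itself, carried for extensibility).
#' @param day_index 1-based follow-up day.
#' @param cfg A [sim_config()].
#' @return A `data.table` of episodes with `start_minute`/`end_minute`
#'   offsets within the day window (half-open, `[start, end)`), `mode`, and
#'   `trip_id` (NA for activity places).
#' @export
generate_schedule <- function(effects, day_index, cfg) {
  D <- cfg$day_minutes
  n_trips <- if (cfg$trips_per_day <= 0) 0L else rpois(1L, cfg$trips_per_day)
  # room check: each trip >= 3 min, each of n+1 places >= 4 min
  n_trips <- min(n_trips, max(0L, (D - 4L) %/% 14L))
  if (n_trips == 0L) {
    return(data.table::data.table(start_minute = 0L, end_minute = D,
                                  mode = "activity_place", trip_id = NA_integer_))
  }
  mean_trip <- D * cfg$time_on_trips_frac / max(cfg$trips_per_day, 1e-9)
  durs <- pmin(90L, pmax(3L, as.integer(round(
    rgamma(n_trips, shape = 2, scale = mean_trip / 2)))))
  # shrink if trips + minimal places overflow the day
  while (sum(durs) > D - 4L * (n_trips + 1L)) durs <- pmax(3L, durs - 1L)
  place_durs <- split_int(D - sum(durs), runif(n_trips + 1L) + 0.25, 4L)
  eps <- vector("list", 2L * n_trips + 1L)
  cursor <- 0L
  for (i in seq_len(n_trips)) {
    eps[[2L * i - 1L]] <- data.table::data.table(
      start_minute = cursor, end_minute = cursor + place_durs[i],
      mode = "activity_place", trip_id = NA_integer_)
    cursor <- cursor + place_durs[i]
    n_stages <- 1L + rpois(1L, max(0, cfg$stages_per_trip - 1))
    n_stages <- min(n_stages, durs[i] %/% 1L)
    stage_durs <- split_int(durs[i], runif(n_stages) + 0.3, 1L)
    modes <- character(n_stages)
    for (s in seq_len(n_stages)) {
      m <- sample(names(cfg$mode_mix), 1L, prob = cfg$mode_mix)
      if (s > 1L && m == modes[s - 1L] && length(cfg$mode_mix) > 1L) {
        keep <- setdiff(names(cfg$mode_mix), m)
        m <- sample(keep, 1L, prob = cfg$mode_mix[keep])
      }
      modes[s] <- m
    }
    starts <- cursor + cumsum(c(0L, stage_durs[-n_stages]))
    eps[[2L * i]] <- data.table::data.table(
      start_minute = as.integer(starts),
      end_minute = as.integer(starts + stage_durs),
      mode = modes, trip_id = i)
    cursor <- cursor + durs[i]
  }
  eps[[2L * n_trips + 1L]] <- data.table::data.table(
    start_minute = cursor, end_minute = D,
    mode = "activity_place", trip_id = NA_integer_)
  data.table::rbindlist(eps)
}

## Non-wear minutes (offsets within the day window) for one sensor-day:
## a Poisson number of contiguous gap episodes with exponential durations,
## calibrated so the expected union is about wear_gap_rate * day_minutes.
draw_wear_gap_minutes <- function(cfg) {
  if (cfg$wear_gap_rate <= 0) return(integer(0))
  k <- rpois(1L, cfg$wear_gap_episodes_per_day)
  if (k == 0L) return(integer(0))
  mean_dur <- cfg$wear_gap_rate * cfg$day_minutes / cfg$wear_gap_episodes_per_day
  durs <- pmax(1L, as.integer(round(stats::rexp(k, 1 / mean_dur))))
  starts <- as.integer(floor(runif(k, 0, cfg$day_minutes)))
  out <- unlist(lapply(seq_len(k), function(i)
    seq.int(starts[i], min(starts[i] + durs[i] - 1L, cfg$day_minutes - 1L))))
  sort(unique(out))
}

sig_row <- function(cfg, m) {
  s <- cfg$mode_signatures
  s[which(s$mode == m), ]
}

#' Simulate GPS fixes for one episode
#'
#' Fix-level speed is drawn around an episode-level mean speed (itself drawn
#' from the mode signature, plus the participant walking-speed effect for
#' walk episodes), with mode-specific within-minute jitter so that e.g.
#' stop-and-go motorized travel shows high within-minute speed dispersion.
#' During public transport, with probability `p_underground` the episode is
#' treated as underground: all three dilution-of-precision values are
#' inflated by `dop_factor` and satellites in view are reduced, so fewer
#' fixes pass the downstream quality filter.
#'
#' @param episode List/row with `start_minute`, `end_minute` (absolute minute
#'   indices) and `mode`.
#' @param signature One row of the mode signature table.
#' @param effects One row of [draw_participant_effects()].
#' @param cfg A [sim_config()].
#' @param minutes Absolute minute indices to generate (default: all episode
#'   minutes); used to apply non-wear gaps.
#' @return A `data.table` of GPS fixes.
#' @export
simulate_gps <- function(episode, signature, effects, cfg, minutes = NULL) {
  if (is.null(minutes))
    minutes <- seq.int(episode$start_minute, episode$end_minute - 1L)
  n_min <- length(minutes)
  empty <- data.table::data.table(
    participant_id = character(0), timestamp = as.POSIXct(character(0), tz = "UTC"),
    lat = numeric(0), lon = numeric(0), elevation = numeric(0),
    speed = numeric(0), hdop = numeric(0), vdop = numeric(0), pdop = numeric(0),
    sat_in_view = integer(0), sat_used = integer(0))
  if (n_min == 0L) return(empty)
  fpm <- max(1L, as.integer(round(60 * cfg$gps_hz)))
  n <- n_min * fpm
  shift <- if (episode$mode == "walk") effects$walk_speed_shift else 0
  ep_speed <- max(0.02, rnorm(1, signature$speed_mean + shift, signature$speed_sd))
  # minute-to-minute speed variation (stops, lights) scales with the mode's
  # within-minute jitter: stop-and-go modes also vary more across minutes
  minute_speed <- pmax(0, rnorm(n_min, ep_speed, 0.5 * signature$speed_jitter * ep_speed))
  speed <- pmax(0, rnorm(n, rep(minute_speed, each = fpm),
                         signature$speed_jitter * ep_speed))
  deg <- cfg$metro_gps_degradation
  underground <- episode$mode == "public_transport" &&
    runif(1) < deg$p_underground
  f <- if (underground) deg$dop_factor else 1
  hdop <- rlnorm(n, log(1.1 * f), 0.35)
  vdop <- rlnorm(n, log(1.6 * f), 0.35)
  pdop <- rlnorm(n, log(1.9 * f), 0.35)
  sat_in_view <- pmax(1L, rpois(n, 12) - if (underground) deg$sat_reduction else 0L)
  sat_used <- rbinom(n, sat_in_view, 0.85)
  heading <- runif(1, 0, 2 * pi)
  step_deg <- speed * (cfg$epoch_s / 3600) / 111.32
  lat <- effects$base_lat + cumsum(step_deg * cos(heading))
  lon <- effects$base_lon +
    cumsum(step_deg * sin(heading)) / cos(effects$base_lat * pi / 180)
  origin <- as.POSIXct(cfg$start_date, tz = "UTC")
  ts <- origin + rep(minutes * 60, each = fpm) + rep.int(seq.int(0L, by = as.integer(60 / fpm), length.out = fpm), n_min)
  data.table::data.table(
    participant_id = effects$participant_id, timestamp = ts,
    lat = lat, lon = lon,
    elevation = rnorm(n, effects$elev_base, 4), speed = speed,
    hdop = hdop, vdop = vdop, pdop = pdop,
    sat_in_view = as.integer(sat_in_view), sat_used = as.integer(sat_used))
}

#' Simulate accelerometer epochs for one episode
#'
#' Hip-worn count intensity follows the mode signature scaled by the
#' participant's intensity random effect: walking yields high counts and
#' steps, biking low counts despite high effort, motorized modes low
#' vibration-level counts. Both count-processing variants are emitted per
#' epoch; the low-frequency-extension (`lfe`) variant adds non-negative
#' low-intensity counts (more for near-sedentary epochs), so `lfe` counts
#' are epoch-wise greater than or equal to `standard` counts.
#'
#' @inheritParams simulate_gps
#' @return A `data.table` of 5-s epochs, both filter variants.
#' @export
simulate_accel <- function(episode, signature, effects, cfg, minutes = NULL) {
  if (is.null(minutes))
    minutes <- seq.int(episode$start_minute, episode$end_minute - 1L)
  n_min <- length(minutes)
  if (n_min == 0L) return(data.table::data.table(
    participant_id = character(0), timestamp = as.POSIXct(character(0), tz = "UTC"),
    filter_variant = character(0), counts_axis1 = integer(0),
    counts_axis2 = integer(0), counts_axis3 = integer(0), steps = integer(0)))
  epm <- as.integer(60 / cfg$epoch_s)
  n <- n_min * epm
  ep_cnt <- max(2, rnorm(1, signature$counts_mean * effects$accel_mult,
                         signature$counts_sd))
  a1 <- as.integer(round(pmax(0, rnorm(n, ep_cnt, 0.35 * ep_cnt + 5))))
  a2 <- as.integer(round(pmax(0, a1 * 0.7 + rnorm(n, 0, 0.15 * ep_cnt + 3))))
  a3 <- as.integer(round(pmax(0, a1 * 0.55 + rnorm(n, 0, 0.15 * ep_cnt + 3))))
  steps <- if (signature$steps_rate > 0) rpois(n, signature$steps_rate) else rep(0L, n)
  # lfe adds low-intensity movement, mostly to near-sedentary epochs
  lam <- ifelse(a1 * (60 / cfg$epoch_s) < 600, 8, 1)
  l1 <- a1 + rpois(n, lam); l2 <- a2 + rpois(n, lam); l3 <- a3 + rpois(n, lam)
  origin <- as.POSIXct(cfg$start_date, tz = "UTC")
  ts <- origin + rep(minutes * 60, each = epm) +
    rep.int(seq.int(0L, by = as.integer(cfg$epoch_s), length.out = epm), n_min)
  data.table::rbindlist(list(
    data.table::data.table(participant_id = effects$participant_id,
                           timestamp = ts, filter_variant = "standard",
                           counts_axis1 = a1, counts_axis2 = a2,
                           counts_axis3 = a3, steps = as.integer(steps)),
    data.table::data.table(participant_id = effects$participant_id,
                           timestamp = ts, filter_variant = "lfe",
                           counts_axis1 = as.integer(l1),
                           counts_axis2 = as.integer(l2),
                           counts_axis3 = as.integer(l3),
                           steps = as.integer(steps))))
}

#' Simulate RR intervals for one episode
#'
#' Minute-level heart rate is the participant's resting rate plus an
#' episode-level mode elevation (biking highest, walking intermediate,
#' motorized travel and activity places near rest) plus minute noise. RR
#' intervals within a minute are Gaussian around 60000/HR ms with a true
#' within-minute SD that decreases with elevation; beats are emitted until
#' the minute is filled, so beat counts conserve time.
#'
#' @inheritParams simulate_gps
#' @return A `data.table` of RR intervals (`rr_ms`, beat `timestamp`).
#' @export
simulate_rr <- function(episode, signature, effects, cfg, minutes = NULL) {
  if (is.null(minutes))
    minutes <- seq.int(episode$start_minute, episode$end_minute - 1L)
  n_min <- length(minutes)
  if (n_min == 0L) return(data.table::data.table(
    participant_id = character(0), timestamp = as.POSIXct(character(0), tz = "UTC"),
    rr_ms = numeric(0)))
  hn <- cfg$hr_noise
  elev <- max(0, rnorm(1, signature$hr_elev_mean, signature$hr_elev_sd))
  hr <- pmax(35, effects$resting_hr + elev + rnorm(n_min, 0, hn$minute_sd))
  mean_rr <- 60000 / hr
  sdnn_true <- max(hn$sdnn_min, hn$sdnn_base - hn$sdnn_slope * elev)
  nb <- pmax(1L, as.integer(round(hr)))
  grp <- rep.int(seq_len(n_min), nb)
  rr <- pmax(250, rnorm(sum(nb), mean_rr[grp], sdnn_true))
  dt <- data.table::data.table(grp = grp, rr_ms = rr)
  dt[, `:=`(off = cumsum(rr_ms)), by = grp]
  dt <- dt[dt$off <= 60000, ]
  origin <- as.POSIXct(cfg$start_date, tz = "UTC")
  data.table::data.table(
    participant_id = effects$participant_id,
    timestamp = origin + minutes[dt$grp] * 60 + round(dt$off / 1000, 3),
    rr_ms = dt$rr_ms)
}

#' Generate a full synthetic cohort
#'
#' Draws participant random effects, tiles every participant-day with an
#' episode schedule, and simulates the three sensor streams over the
#' scheduled minutes minus per-sensor non-wear gaps. Deterministic given the
#' config and its seed.
#'
#' @param cfg A [sim_config()].
#' @param sensors If `FALSE`, only the timetable and participant table are
#'   generated (much faster; used for schedule calibration).
#' @return A list of class `sim_cohort` with elements `timetable`, `gps`,
#'   `accel`, `rr`, `participants`, and `config`.
#' @export
generate_cohort <- function(cfg, sensors = TRUE) {
  validate_sim_config(cfg)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  parts <- draw_participant_effects(cfg)
  tt_list <- list(); gps_list <- list(); acc_list <- list(); rr_list <- list()
  for (p in seq_len(cfg$n_participants)) {
    eff <- parts[p, ]
    for (d in seq_len(cfg$n_days)) {
      day0 <- (d - 1L) * 1440L + cfg$wake_start_min
      sched <- generate_schedule(eff, d, cfg)
      sched[, `:=`(start_minute = start_minute + day0,
                   end_minute = end_minute + day0)]
      sched[, `:=`(participant_id = eff$participant_id, day = d)]
      tt_list[[length(tt_list) + 1L]] <- sched
      if (!sensors) next
      gaps <- lapply(1:3, function(i) draw_wear_gap_minutes(cfg) + day0)
      for (e in seq_len(nrow(sched))) {
        ep <- as.list(sched[e, ])
        sig <- sig_row(cfg, ep$mode)
        all_min <- seq.int(ep$start_minute, ep$end_minute - 1L)
        g <- simulate_gps(ep, sig, eff, cfg, setdiff(all_min, gaps[[1]]))
        a <- simulate_accel(ep, sig, eff, cfg, setdiff(all_min, gaps[[2]]))
        r <- simulate_rr(ep, sig, eff, cfg, setdiff(all_min, gaps[[3]]))
        if (nrow(g)) gps_list[[length(gps_list) + 1L]] <- g
        if (nrow(a)) acc_list[[length(acc_list) + 1L]] <- a
        if (nrow(r)) rr_list[[length(rr_list) + 1L]] <- r
      }
    }
  }
  timetable <- data.table::rbindlist(tt_list)
  origin <- as.POSIXct(cfg$start_date, tz = "UTC")
  timetable[, `:=`(start_time = origin + start_minute * 60,
                   end_time = origin + end_minute * 60)]
  data.table::setcolorder(timetable, c("participant_id", "day", "start_minute",
                                       "end_minute", "start_time", "end_time",
                                       "mode", "trip_id"))
  out <- list(
    timetable = timetable,
    gps = if (sensors) data.table::rbindlist(gps_list) else NULL,
    accel = if (sensors) data.table::rbindlist(acc_list) else NULL,
    rr = if (sensors) data.table::rbindlist(rr_list) else NULL,
    participants = parts, config = cfg)
  class(out) <- "sim_cohort"
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic multi-sensor cohort\n")
  cat(sprintf("  participants: %d, days: %d, episodes: %d\n",
              x$config$n_participants, x$config$n_days, nrow(x$timetable)))
  if (!is.null(x$gps))
    cat(sprintf("  gps fixes: %d, accel epoch rows: %d, rr intervals: %d\n",
                nrow(x$gps), nrow(x$accel), nrow(x$rr)))
  invisible(x)
}
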