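#' Default per-mode sensor signatures
#'
#' One row per outcome class, giving the distributional parameters the
#' simulator uses for that class. Speeds are in km/h; `speed_sd` is the
#' between-episode SD and `speed_jitter` the within-minute coefficient of
#' variation of fix-level speed. Accelerometer counts are per-axis-1 5-s
#' epoch (between-episode SD in `counts_sd`); `steps_rate` is steps per 5-s
#' epoch while walking. `hr_elev_mean`/`hr_elev_sd` give the heart-rate
#' elevation above the participant's resting rate, in bpm.
#'
#' The defaults encode the qualitative structure minute-level transport
#' prediction relies on: near-zero speed at activity places; high hip-worn
#' counts and steps while walking; low hip counts but strong heart-rate
#' elevation while biking; overlapping, stop-and-go speed profiles for
#' public transport and private motorized vehicles.
#'
#' @return A `data.table` with one row per class in [mode_levels()] order.
#' @export
default_mode_signatures <- function() {
  data.table::data.table(
    mode         = MODE_LEVELS,
    speed_mean   = c(0.12, 13,  26,   18,   4.8),
    speed_sd     = c(0.03, 5,   14,   9,    1.5),
    speed_jitter = c(0.30, 0.25, 0.55, 0.70, 0.15),
    counts_mean  = c(20,  45,  20,   30,   170),
    counts_sd    = c(20,  30,  18,   25,   50),
    steps_rate   = c(0,   0,   0,    0,    9),
    hr_elev_mean = c(3,   45,  5,    8,    25),
    hr_elev_sd   = c(2,   12,  4,    5,    8)
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults are calibrated to the descriptive statistics
#' of a week-long urban multi-sensor follow-up: a median of about 5.1 trips
#' per day, about 1.7 trip stages per trip, and about 6.9% of follow-up time
#' spent on trips; activity places dominate the remaining time.
#'
#' @param n_participants Number of participants (>= 2; leave-one-out needs 2).
#' @param n_days Follow-up days per participant.
#' @param seed Integer master seed; the same config + seed reproduces the
#'   cohort exactly.
#' @param trips_per_day Target median number of daily trips (Poisson mean).
#' @param stages_per_trip Target mean stages per trip; stage count is drawn as
#'   `1 + Poisson(stages_per_trip - 1)`.
#' @param time_on_trips_frac Target fraction of follow-up time spent on trips.
#' @param mode_mix Named probability vector over the four transport modes,
#'   used to draw the mode of each trip stage; must sum to 1.
#' @param mode_signatures Per-mode signature table, see
#'   [default_mode_signatures()].
#' @param metro_gps_degradation List with `dop_factor` (multiplier on all
#'   three DOPs during public transport, emulating underground travel),
#'   `sat_reduction` (satellites-in-view decrement) and `p_underground`
#'   (probability that a public-transport stage is affected).
#' @param participant_heterogeneity List of SDs for Gaussian participant-level
#'   random effects: `resting_hr_sd` (bpm), `walk_speed_sd` (km/h), and
#'   `accel_log_sd` (log-scale SD of a multiplicative count-intensity
#'   effect). Setting all to 0 removes between-participant heterogeneity.
#' @param wear_gap_rate Expected non-wear fraction of the waking window, per
#'   sensor (independent across sensors). Non-wear is drawn as a small number
#'   of contiguous gap episodes per day.
#' @param wear_gap_episodes_per_day Mean number of non-wear episodes per
#'   sensor-day.
#' @param gps_hz GPS fix rate in fixes per second (default 1 fix / 5 s).
#' @param epoch_s Accelerometer epoch length, fixed at 5 s.
#' @param rr_rest_ms Resting RR interval in ms (resting HR = 60000 / this).
#' @param hr_noise List with `minute_sd` (bpm SD of minute-level HR noise),
#'   `sdnn_base` and `sdnn_slope`: the true within-minute RR SD is
#'   `max(sdnn_min, sdnn_base - sdnn_slope * elevation)` ms.
#' @param day_minutes Length of the simulated waking wear window, in minutes.
#'   Participants remove all devices outside this window (overnight), so each
#'   simulated day contributes at most `day_minutes` minutes.
#' @param wake_start_min Start of the waking window, minutes after midnight.
#' @param start_date Date of follow-up day 1 (a Monday by default, so days 6
#'   and 7 of a week-long follow-up fall on the weekend).
#' @param body_weight_mean,body_weight_sd Body weight distribution (kg).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_participants = 126,
                       n_days = 7,
                       seed = 1L,
                       trips_per_day = 5.1,
                       stages_per_trip = 1.7,
                       time_on_trips_frac = 0.069,
                       mode_mix = c(walk = 0.45, bike = 0.10,
                                    public_transport = 0.20,
                                    private_motorized = 0.25),
                       mode_signatures = default_mode_signatures(),
                       metro_gps_degradation = list(dop_factor = 3,
                                                    sat_reduction = 5,
                                                    p_underground = 0.6),
                       participant_heterogeneity = list(resting_hr_sd = 7,
                                                        walk_speed_sd = 1.2,
                                                        accel_log_sd = 0.5),
                       wear_gap_rate = 0.32,
                       wear_gap_episodes_per_day = 3,
                       gps_hz = 1 / 5,
                       epoch_s = 5,
                       rr_rest_ms = 968,
                       hr_noise = list(minute_sd = 1.5, sdnn_base = 45,
                                       sdnn_slope = 0.4, sdnn_min = 8),
                       day_minutes = 840,
                       wake_start_min = 420,
                       start_date = as.Date("2015-01-05"),
                       body_weight_mean = 75,
                       body_weight_sd = 12) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    seed = as.integer(seed), trips_per_day = trips_per_day,
    stages_per_trip = stages_per_trip,
    time_on_trips_frac = time_on_trips_frac, mode_mix = mode_mix,
    mode_signatures = data.table::as.data.table(mode_signatures),
    metro_gps_degradation = metro_gps_degradation,
    participant_heterogeneity = participant_heterogeneity,
    wear_gap_rate = wear_gap_rate,
    wear_gap_episodes_per_day = wear_gap_episodes_per_day,
    gps_hz = gps_hz, epoch_s = epoch_s, rr_rest_ms = rr_rest_ms,
    hr_noise = hr_noise, day_minutes = as.integer(day_minutes),
    wake_start_min = as.integer(wake_start_min),
    start_date = as.Date(start_date),
    body_weight_mean = body_weight_mean, body_weight_sd = body_weight_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

config_error <- function(msg) {
  stop(structure(class = c("modesense_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object.
#' @return The config, invisibly, if valid; otherwise a classed
#'   `modesense_config_error` is thrown.
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$n_participants < 2L)
    config_error("n_participants must be >= 2 (leave-one-out requires at least 2)")
  if (cfg$n_days < 1L) config_error("n_days must be >= 1")
  if (any(cfg$mode_mix < 0) || any(cfg$mode_mix > 1))
    config_error("mode_mix probabilities must lie in [0, 1]")
  if (abs(sum(cfg$mode_mix) - 1) > 1e-8)
    config_error("mode_mix must sum to 1")
  if (!all(names(cfg$mode_mix) %in% TRANSPORT_LEVELS))
    config_error("mode_mix names must be transport modes")
  if (cfg$trips_per_day < 0) config_error("trips_per_day must be >= 0")
  if (cfg$stages_per_trip < 1) config_error("stages_per_trip must be >= 1")
  if (cfg$time_on_trips_frac < 0 || cfg$time_on_trips_frac > 1)
    config_error("time_on_trips_frac must lie in [0, 1]")
  het <- cfg$participant_heterogeneity
  if (any(unlist(het) < 0)) config_error("heterogeneity SDs must be >= 0")
  if (cfg$wear_gap_rate < 0 || cfg$wear_gap_rate >= 1)
    config_error("wear_gap_rate must lie in [0, 1)")
  if (cfg$rr_rest_ms <= 0) config_error("rr_rest_ms must be > 0")
  sig <- cfg$mode_signatures
  if (!setequal(sig$mode, MODE_LEVELS))
    config_error("mode_signatures must have one row per outcome class")
  if (any(sig$speed_sd < 0) || any(sig$counts_sd < 0) || any(sig$hr_elev_sd < 0))
    config_error("signature SDs must be >= 0")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML file mirrors the arguments of [sim_config()]; unspecified keys
#' take their defaults. `mode_signatures` may be given as a list of per-mode
#' maps.
#'
#' @param path Path to a YAML file.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mode_mix)) raw$mode_mix <- unlist(raw$mode_mix)
  if (!is.null(raw$mode_signatures))
    raw$mode_signatures <- data.table::rbindlist(
      lapply(raw$mode_signatures, data.table::as.data.table))
  if (!is.null(raw$start_date)) raw$start_date <- as.Date(raw$start_date)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg A `sim_config` object.
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$start_date <- as.character(out$start_date)
  out$mode_mix <- as.list(out$mode_mix)
  sig <- out$mode_signatures
  out$mode_signatures <- lapply(seq_len(nrow(sig)), function(i) as.list(sig[i]))
  yaml::write_yaml(out, path)
  invisible(path)
}
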