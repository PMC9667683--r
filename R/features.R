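## Minute-level feature engineering: GPS quality filtering and summary
## statistics, accelerometer epoch derivations (vector magnitude, METs,
## MVPA/sedentary flags), heart-rate variability, and time features.

## Fast type-7 (linear interpolation) quantile for a single probability.
q7 <- function(x, p) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(as.numeric(x))
  xs <- sort(x)
  h <- (n - 1) * p
  lo <- floor(h)
  as.numeric(xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1]))
}

#' Seven summary statistics
#'
#' The per-minute aggregation applied to every raw GPS and accelerometer
#' quantity: mean, median, sample standard deviation (n-1), minimum, maximum,
#' and the 10th and 90th percentiles (linear interpolation between order
#' statistics). An empty input yields all seven as `NA`; a single value
#' yields `NA` for the SD.
#'
#' @param values Numeric vector.
#' @return Named numeric vector `mean, median, sd, min, max, p10, p90`.
#' @export
summarize7 <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    return(c(mean = NA_real_, median = NA_real_, sd = NA_real_, min = NA_real_,
             max = NA_real_, p10 = NA_real_, p90 = NA_real_))
  c(mean = mean(values), median = median(values), sd = sd(values),
    min = min(values), max = max(values),
    p10 = q7(values, 0.1), p90 = q7(values, 0.9))
}

SUM7_NAMES <- c("mean", "median", "sd", "min", "max", "p10", "p90")

#' GPS fix quality filter
#'
#' Keeps a fix if and only if HDOP < 6, VDOP < 7 and PDOP < 8 (strict
#' inequalities); order is preserved.
#'
#' @param fixes `data.table`/data.frame of GPS fixes with `hdop`, `vdop`,
#'   `pdop` columns.
#' @return The retained fixes.
#' @export
filter_gps_quality <- function(fixes) {
  fixes <- data.table::as.data.table(fixes)
  fixes[fixes$hdop < 6 & fixes$vdop < 7 & fixes$pdop < 8, ]
}

#' The default predictor catalogue
#'
#' The ordered list of minute-level predictors: 51 GPS variables (seven
#' summary statistics of speed, elevation, HDOP, VDOP, PDOP, satellites in
#' view and used, plus the count of quality-filtered fixes and the fraction
#' of raw fixes passing the filter), 55 accelerometer variables (per filter
#' variant: seven summaries of vector-magnitude counts and of METs, the step
#' sum and the MVPA and sedentary epoch counts; plus per-axis summaries for
#' the standard variant), 12 heart-rate-variability variables, and 2 time
#' variables.
#'
#' @return A `data.table` with columns `name`, `source`, `summary`, ordered
#'   deterministically; attribute `"catalogue_version"` identifies it.
#' @export
feature_catalogue <- function() {
  gps_vars <- c("speed", "elevation", "hdop", "vdop", "pdop",
                "sat_in_view", "sat_used")
  gps <- c(paste0(rep(gps_vars, each = 7L), "_", SUM7_NAMES),
           "gps_n_valid_fixes", "gps_frac_valid")
  acc <- character(0)
  for (v in c("std", "lfe")) {
    acc <- c(acc,
             paste0("vm_", v, "_", SUM7_NAMES),
             paste0("mets_", v, "_", SUM7_NAMES),
             paste0(c("steps_sum_", "mvpa_epochs_", "sedentary_epochs_"), v))
  }
  acc <- c(acc, paste0(rep(paste0("axis", 1:3), each = 7L), "_std_", SUM7_NAMES))
  hr <- paste0("hr_", c("mean_rr", "median_rr", "sdnn", "rmssd", "sdsd",
                        "pnn50", "cv_rr", "mean_hr", "sd_hr", "min_hr",
                        "max_hr", "n_beats"))
  tim <- c("time_of_day", "weekend_flag")
  cat <- data.table::data.table(
    name = c(gps, acc, hr, tim),
    source = c(rep("gps", length(gps)), rep("accel", length(acc)),
               rep("hr", length(hr)), rep("time", length(tim))),
    summary = c(rep("minute summary of GPS quantity", length(gps)),
                rep("minute summary of accelerometer quantity", length(acc)),
                rep("minute heart-rate-variability statistic", length(hr)),
                rep("clock/calendar variable", length(tim))))
  stopifnot(!anyDuplicated(cat$name))
  data.table::setattr(cat, "catalogue_version", "modesense-catalogue-v1")
  cat
}

## minute index (minutes since the epoch / cohort origin) from POSIXct
minute_of <- function(timestamp) as.integer(floor(as.numeric(timestamp) / 60))

## grouped seven-statistic summaries of several columns, wide output
## named <var>_<stat>, one row per (participant_id, minute)
grouped_sum7 <- function(dt, vars) {
  sub <- dt[, c("participant_id", "minute", vars), with = FALSE]
  for (v in vars) data.table::set(sub, j = v, value = as.numeric(sub[[v]]))
  long <- data.table::melt(sub, id.vars = c("participant_id", "minute"),
                           variable.name = "variable", value.name = "value",
                           variable.factor = FALSE)
  st <- long[, {
    xs <- sort.int(value, method = "radix")
    n <- length(xs)
    qq <- function(p) {
      h <- (n - 1) * p
      lo <- floor(h)
      xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])
    }
    .(mean = mean(xs), median = qq(0.5),
      sd = if (n > 1L) sd(xs) else NA_real_,
      min = xs[1L], max = xs[n], p10 = qq(0.1), p90 = qq(0.9))
  }, by = .(participant_id, minute, variable)]
  wide <- data.table::dcast(
    data.table::melt(st, id.vars = c("participant_id", "minute", "variable"),
                     variable.name = "stat", variable.factor = FALSE),
    participant_id + minute ~ variable + stat, sep = "_")
  data.table::setkey(wide, participant_id, minute)
  wide
}

#' Minute-level GPS features
#'
#' Applies the DOP quality filter, then computes the seven summary statistics
#' of speed, elevation, the three DOPs and the two satellite counts over the
#' retained fixes of each minute, plus the number of retained fixes and the
#' fraction of raw fixes passing the filter. Minutes with zero retained
#' fixes are absent from the output (all their GPS features are missing and
#' the GPS sensor is treated as absent for that minute).
#'
#' @param fixes Raw GPS fixes (`participant_id`, `timestamp`, `speed`,
#'   `elevation`, `hdop`, `vdop`, `pdop`, `sat_in_view`, `sat_used`).
#' @return A `data.table` keyed by `participant_id`, `minute` with 51
#'   feature columns.
#' @export
gps_minute_features <- function(fixes) {
  fixes <- data.table::as.data.table(fixes)
  fixes[, minute := minute_of(timestamp)]
  raw_n <- fixes[, .(n_raw = .N), by = .(participant_id, minute)]
  valid <- filter_gps_quality(fixes)
  if (nrow(valid) == 0L) {
    out <- grouped_sum7(fixes[0L], c("speed", "elevation", "hdop", "vdop",
                                     "pdop", "sat_in_view", "sat_used"))
    out[, `:=`(gps_n_valid_fixes = integer(0), gps_frac_valid = numeric(0))]
    return(out)
  }
  wide <- grouped_sum7(valid, c("speed", "elevation", "hdop", "vdop", "pdop",
                                "sat_in_view", "sat_used"))
  nv <- valid[, .(gps_n_valid_fixes = .N), by = .(participant_id, minute)]
  wide <- merge(wide, nv, by = c("participant_id", "minute"))
  wide <- merge(wide, raw_n, by = c("participant_id", "minute"))
  wide[, gps_frac_valid := gps_n_valid_fixes / n_raw]
  wide[, n_raw := NULL]
  data.table::setkey(wide, participant_id, minute)
  wide
}

#' Epoch-level accelerometer derivations
#'
#' For each 5-s epoch computes the vector-magnitude counts
#' `sqrt(a1^2 + a2^2 + a3^2)`, the MET value from an affine equation on
#' vector-magnitude counts-per-minute (epoch counts are scaled by
#' 60/epoch_s before applying it), energy expenditure in kcal/min
#' (`METs * 3.5 * weight / 200`), the moderate-to-vigorous flag
#' (`METs >= mvpa_met_cut`), and the sedentary flag (axis-1
#' counts-per-minute-equivalent below `sedentary_cpm_cut`).
#'
#' The default MET equation coefficients (slope 0.000863 per count/min,
#' intercept 0.668876) follow the vector-magnitude energy-expenditure
#' calibration literature and are exposed so users can substitute their own.
#'
#' @param epochs `data.table` of accelerometer epochs (`counts_axis1..3`).
#' @param body_weight_kg Positive body weight in kg.
#' @param epoch_s Epoch length in seconds (default 5).
#' @param met_slope,met_intercept MET equation coefficients.
#' @param mvpa_met_cut MVPA threshold in METs (default 3).
#' @param sedentary_cpm_cut Sedentary threshold on axis-1 counts/min
#'   (default 100).
#' @return The input with columns `vm_counts`, `mets`, `kcal_min`,
#'   `mvpa_flag`, `sedentary_flag` appended.
#' @export
accel_epoch_derivations <- function(epochs, body_weight_kg, epoch_s = 5,
                                    met_slope = 0.000863,
                                    met_intercept = 0.668876,
                                    mvpa_met_cut = 3,
                                    sedentary_cpm_cut = 100) {
  if (any(body_weight_kg <= 0))
    stop("body_weight_kg must be > 0", call. = FALSE)
  epochs <- data.table::as.data.table(epochs)
  scale <- 60 / epoch_s
  epochs[, vm_counts := sqrt(counts_axis1^2 + counts_axis2^2 + counts_axis3^2)]
  epochs[, mets := met_slope * vm_counts * scale + met_intercept]
  epochs[, kcal_min := mets * 3.5 * body_weight_kg / 200]
  epochs[, mvpa_flag := mets >= mvpa_met_cut]
  epochs[, sedentary_flag := counts_axis1 * scale < sedentary_cpm_cut]
  epochs[]
}

#' Minute-level accelerometer features
#'
#' Per filter variant (`standard`, `lfe`): the seven summary statistics of
#' vector-magnitude counts and of METs, the step sum, and the number of MVPA
#' and sedentary epochs; plus, for the standard variant only, the seven
#' summaries of each axis's counts. Minutes missing either variant are
#' absent from the output (accelerometer treated as absent).
#'
#' @param epochs Raw accelerometer epochs, both filter variants.
#' @param body_weight_kg Body weight used in the MET/kcal derivations.
#' @param ... Passed to [accel_epoch_derivations()].
#' @return A `data.table` keyed by `participant_id`, `minute` with 55
#'   feature columns.
#' @export
accel_minute_features <- function(epochs, body_weight_kg, ...) {
  epochs <- accel_epoch_derivations(epochs, body_weight_kg, ...)
  epochs[, minute := minute_of(timestamp)]
  per_variant <- function(v, tag) {
    sub <- epochs[filter_variant == v]
    w <- grouped_sum7(sub, c("vm_counts", "mets"))
    data.table::setnames(
      w, setdiff(names(w), c("participant_id", "minute")),
      function(nm) sub("^(vm_counts)_", paste0("vm_", tag, "_"),
                       sub("^(mets)_", paste0("mets_", tag, "_"), nm)))
    extra <- sub[, .(steps_sum = sum(steps), mvpa_epochs = sum(mvpa_flag),
                     sedentary_epochs = sum(sedentary_flag)),
                 by = .(participant_id, minute)]
    data.table::setnames(extra, c("steps_sum", "mvpa_epochs", "sedentary_epochs"),
                         paste0(c("steps_sum_", "mvpa_epochs_", "sedentary_epochs_"), tag))
    merge(w, extra, by = c("participant_id", "minute"))
  }
  std <- per_variant("standard", "std")
  lfe <- per_variant("lfe", "lfe")
  axes <- grouped_sum7(epochs[filter_variant == "standard"],
                       c("counts_axis1", "counts_axis2", "counts_axis3"))
  data.table::setnames(
    axes, setdiff(names(axes), c("participant_id", "minute")),
    function(nm) sub("^counts_(axis[123])_", "\\1_std_", nm))
  out <- merge(merge(std, lfe, by = c("participant_id", "minute")),
               axes, by = c("participant_id", "minute"))
  data.table::setkey(out, participant_id, minute)
  out
}

#' Minute-level heart-rate-variability features
#'
#' Twelve statistics of the RR intervals falling in each minute: mean and
#' median RR (ms), SDNN (SD of intervals), RMSSD (root mean square of
#' successive differences), SDSD (SD of successive differences), pNN50
#' (fraction of successive differences exceeding 50 ms), the coefficient of
#' variation of RR, and the mean, SD, min and max of the per-beat heart rate
#' (60000/RR, bpm), plus the beat count. Minutes with fewer than three
#' intervals have all variability measures missing.
#'
#' @param rr `data.table` of RR intervals (`participant_id`, `timestamp`,
#'   `rr_ms`); all `rr_ms` must be positive.
#' @return A `data.table` keyed by `participant_id`, `minute` with 12
#'   feature columns.
#' @export
hrv_minute_features <- function(rr) {
  rr <- data.table::as.data.table(rr)
  if (nrow(rr) && any(rr$rr_ms <= 0))
    stop("rr_ms must be > 0", call. = FALSE)
  rr[, minute := minute_of(timestamp)]
  out <- rr[order(timestamp),
    {
      d <- diff(rr_ms)
      hr <- 60000 / rr_ms
      enough <- .N >= 3L
      .(hr_mean_rr = mean(rr_ms), hr_median_rr = median(rr_ms),
        hr_sdnn = if (enough) sd(rr_ms) else NA_real_,
        hr_rmssd = if (enough) sqrt(mean(d^2)) else NA_real_,
        hr_sdsd = if (enough) sd(d) else NA_real_,
        hr_pnn50 = if (enough) mean(abs(d) > 50) else NA_real_,
        hr_cv_rr = if (enough) sd(rr_ms) / mean(rr_ms) else NA_real_,
        hr_mean_hr = mean(hr),
        hr_sd_hr = if (enough) sd(hr) else NA_real_,
        hr_min_hr = min(hr), hr_max_hr = max(hr),
        hr_n_beats = as.numeric(.N))
    },
    by = .(participant_id, minute)]
  data.table::setkey(out, participant_id, minute)
  out
}

#' Time features
#'
#' @param timestamp POSIXct vector (UTC clock of the cohort).
#' @return A `data.table` with `time_of_day` (minutes since midnight,
#'   0-1439) and `weekend_flag` (1 for Saturday/Sunday).
#' @export
time_features <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  data.table::data.table(
    time_of_day = lt$hour * 60L + lt$min,
    weekend_flag = as.integer(lt$wday %in% c(0L, 6L)))
}
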