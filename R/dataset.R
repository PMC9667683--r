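## Assembly of the labelled minute-level dataset: per-sensor minute feature
## tables are inner-joined (a minute is retained only when all three sensors
## contributed data), time features are added, and the true mode label is
## assigned from the episode timetable by largest overlap with the minute.

#' Assign episode labels to minutes
#'
#' Each minute `[60 m, 60 m + 60)` seconds receives the mode of the episode
#' with the largest time overlap with that minute; ties go to the episode
#' that starts earlier. Works for second-resolution timetables; for
#' minute-aligned timetables this reduces to the covering episode.
#'
#' @param minutes `data.table` with `participant_id` and `minute` columns.
#' @param timetable Episode table with `participant_id`, `start_time`,
#'   `end_time` (POSIXct) and `mode`.
#' @return The input with a `label` column appended; minutes covered by no
#'   episode raise a structural error (the timetable must tile follow-up).
#' @export
label_minutes <- function(minutes, timetable) {
  minutes <- data.table::as.data.table(minutes)
  tt <- data.table::as.data.table(timetable)
  tt[, `:=`(start_s = as.numeric(start_time), end_s = as.numeric(end_time))]
  if (any(tt$end_s <= tt$start_s))
    stop("timetable episodes must satisfy start < end", call. = FALSE)
  tt[, episode_idx := seq_len(.N)]
  # expand each episode to the minutes it touches
  span <- tt[, .(minute = seq.int(as.integer(floor(start_s[1] / 60)),
                                  as.integer(ceiling(end_s[1] / 60)) - 1L)),
             by = .(participant_id, episode_idx, start_s, end_s, mode)]
  span[, minute := as.integer(minute)]
  span[, overlap_s := pmin(end_s, (minute + 1) * 60) - pmax(start_s, minute * 60)]
  span <- span[overlap_s > 0]
  data.table::setorder(span, participant_id, minute, -overlap_s, start_s)
  lab <- span[, .SD[1L], by = .(participant_id, minute)][,
    .(participant_id, minute, label = mode)]
  out <- merge(minutes, lab, by = c("participant_id", "minute"),
               all.x = TRUE, sort = TRUE)
  if (anyNA(out$label))
    stop(sprintf(
      "%d minute(s) fall outside all timetable episodes; the timetable must tile follow-up",
      sum(is.na(out$label))), call. = FALSE)
  out
}

#' Build the labelled minute-level dataset
#'
#' Computes the three per-sensor minute feature tables, merges them (keeping
#' only minutes where GPS, accelerometer and heart-rate data are all
#' present), adds the time features, and assigns the true mode label from
#' the timetable.
#'
#' @param cohort A `sim_cohort`, or a list with elements `gps`, `accel`,
#'   `rr`, `timetable`, and `participants` (which must carry
#'   `body_weight_kg`).
#' @param catalogue Feature catalogue (default [feature_catalogue()]);
#'   defines the column order of the result.
#' @param keep_all If `TRUE`, returns the full outer join with per-sensor
#'   presence flags (`gps_present`, `accel_present`, `hr_present`) instead
#'   of dropping incomplete minutes.
#' @param ... Passed to [accel_minute_features()] (MET equation etc.).
#' @return A `data.table` with columns `participant_id`, `minute` (the
#'   minute index on the epoch clock, `floor(seconds / 60)`, so indices are
#'   comparable across participants and gaps are detectable), `timestamp`,
#'   `label`, then the catalogue features in order.
#' @export
build_minute_dataset <- function(cohort, catalogue = feature_catalogue(),
                                 keep_all = FALSE, ...) {
  parts <- data.table::as.data.table(cohort$participants)
  if (!"body_weight_kg" %in% names(parts))
    stop("participants table must contain body_weight_kg", call. = FALSE)

  gps <- gps_minute_features(cohort$gps)

  acc_in <- data.table::as.data.table(cohort$accel)
  weights <- stats::setNames(parts$body_weight_kg, parts$participant_id)
  acc <- data.table::rbindlist(lapply(
    split(acc_in, by = "participant_id"),
    function(sub) accel_minute_features(sub, weights[[sub$participant_id[1L]]], ...)))

  hr <- hrv_minute_features(cohort$rr)

  gps[, gps_present := TRUE]
  acc[, accel_present := TRUE]
  hr[, hr_present := TRUE]
  merged <- merge(gps, acc, by = c("participant_id", "minute"), all = TRUE)
  merged <- merge(merged, hr, by = c("participant_id", "minute"), all = TRUE)
  for (fl in c("gps_present", "accel_present", "hr_present"))
    merged[is.na(get(fl)), (fl) := FALSE]
  if (!keep_all)
    merged <- merged[gps_present & accel_present & hr_present]

  merged[, timestamp := as.POSIXct(minute * 60, origin = "1970-01-01", tz = "UTC")]
  merged <- cbind(merged, time_features(merged$timestamp))
  merged <- label_minutes(merged, cohort$timetable)

  feature_cols <- catalogue$name
  missing_cols <- setdiff(feature_cols, names(merged))
  if (length(missing_cols))
    stop(sprintf("feature columns missing from merged table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  keep <- c("participant_id", "minute", "timestamp", "label",
            if (keep_all) c("gps_present", "accel_present", "hr_present"),
            feature_cols)
  out <- merged[, ..keep]
  data.table::setkey(out, participant_id, minute)
  out[]
}
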