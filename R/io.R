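## CSV interchange for the four stream tables. All files are UTF-8 CSVs with
## ISO-8601 UTC timestamps (millisecond precision for RR beat times);
## missing values are written as empty fields.

TS_FMT <- "%Y-%m-%dT%H:%M:%OS3Z"

format_ts <- function(ts) format(ts, TS_FMT, tz = "UTC")

#' Parse ISO-8601 timestamps
#'
#' Accepts `...Z`, explicit offsets (`+02:00` or `+0200`), and naive
#' timestamps (taken as the cohort clock, UTC); fractional seconds are
#' preserved. All results are expressed on the cohort's UTC clock.
#'
#' @param x Character vector.
#' @return POSIXct (UTC).
#' @export
parse_timestamp <- function(x) {
  x <- as.character(x)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  has_offset <- grepl("[+-][0-9]{4}$", x)
  x[!has_offset] <- paste0(x[!has_offset], "+0000")
  x <- sub("^([0-9-]+) ", "\\1T", x)  # allow space separator
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  if (anyNA(out) && !anyNA(x))
    stop("unparseable ISO-8601 timestamp(s), e.g. ", x[which(is.na(out))[1L]],
         call. = FALSE)
  out
}

check_columns <- function(dt, required, file) {
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(dt)
}

read_stream <- function(path, required, ts_cols = "timestamp") {
  dt <- data.table::fread(path, colClasses = list(character = ts_cols),
                          na.strings = c("", "NA"))
  check_columns(dt, required, basename(path))
  for (cl in intersect(ts_cols, names(dt)))
    data.table::set(dt, j = cl, value = parse_timestamp(dt[[cl]]))
  dt
}

GPS_COLS <- c("participant_id", "timestamp", "lat", "lon", "elevation",
              "speed", "hdop", "vdop", "pdop", "sat_in_view", "sat_used")
ACCEL_COLS <- c("participant_id", "timestamp", "filter_variant",
                "counts_axis1", "counts_axis2", "counts_axis3", "steps")
RR_COLS <- c("participant_id", "timestamp", "rr_ms")
TT_COLS <- c("participant_id", "start_time", "end_time", "mode")

#' Write / read a synthetic cohort as CSV files
#'
#' Writes `fixes.csv`, `epochs.csv`, `rr.csv`, `timetable.csv` and
#' `participants.csv` (plus `config.yaml` when the cohort carries its
#' config) into a directory; `read_cohort()` reads them back. Reading then
#' writing is an identity up to the millisecond timestamp precision of the
#' CSV format.
#'
#' @param cohort A `sim_cohort` (or compatible list of tables).
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   `sim_cohort`-shaped list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(dt, file, ts_cols) {
    dt <- data.table::copy(data.table::as.data.table(dt))
    for (cl in intersect(ts_cols, names(dt)))
      data.table::set(dt, j = cl, value = format_ts(dt[[cl]]))
    data.table::fwrite(dt, file.path(dir, file), na = "")
  }
  w(cohort$gps, "fixes.csv", "timestamp")
  w(cohort$accel, "epochs.csv", "timestamp")
  w(cohort$rr, "rr.csv", "timestamp")
  w(cohort$timetable, "timetable.csv", c("start_time", "end_time"))
  data.table::fwrite(data.table::as.data.table(cohort$participants),
                     file.path(dir, "participants.csv"), na = "")
  if (!is.null(cohort$config))
    write_sim_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- list(
    gps = read_stream(file.path(dir, "fixes.csv"), GPS_COLS),
    accel = read_stream(file.path(dir, "epochs.csv"), ACCEL_COLS),
    rr = read_stream(file.path(dir, "rr.csv"), RR_COLS),
    timetable = read_stream(file.path(dir, "timetable.csv"), TT_COLS,
                            ts_cols = c("start_time", "end_time")),
    participants = data.table::fread(file.path(dir, "participants.csv")))
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) out$config <- read_sim_config(cfg_path)
  class(out) <- "sim_cohort"
  out
}

#' Write / read the labelled minute dataset
#'
#' Column order is `participant_id, minute, timestamp, label`, then the
#' catalogue features in order; missing values are empty fields.
#'
#' @param minutes Minute dataset from [build_minute_dataset()].
#' @param path CSV path.
#' @return `read_minutes()` returns the `data.table`.
#' @export
write_minutes <- function(minutes, path) {
  dt <- data.table::copy(data.table::as.data.table(minutes))
  data.table::set(dt, j = "timestamp", value = format_ts(dt$timestamp))
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}

#' @rdname write_minutes
#' @export
read_minutes <- function(path) {
  read_stream(path, c("participant_id", "minute", "timestamp", "label"))
}
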