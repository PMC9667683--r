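test_that("summarize7 matches hand values and the brute-force oracle", {
  expect_equal(summarize7(c(5, 5, 5)),
               c(mean = 5, median = 5, sd = 0, min = 5, max = 5, p10 = 5, p90 = 5))
  s <- summarize7(c(0, 10))
  expect_equal(unname(s["mean"]), 5)
  expect_equal(unname(s["sd"]), sqrt(50), tolerance = 1e-12)  # 7.0711, n-1
  s10 <- summarize7(1:10)
  expect_equal(unname(s10["p10"]), 1.9)
  expect_equal(unname(s10["p90"]), 9.1)
  expect_true(all(is.na(summarize7(numeric(0)))))
  set.seed(1)
  for (i in 1:50) {
    x <- rnorm(sample(1:40, 1)) * 10
    expect_equal(summarize7(x), sum7_oracle(x), tolerance = 1e-12)
  }
})

test_that("GPS quality filter applies strict DOP thresholds", {
  fx <- data.table::data.table(
    hdop = c(5.9, 6.0, 1.0, 5.0), vdop = c(6.9, 1.0, 7.0, 1.0),
    pdop = c(7.9, 1.0, 1.0, 8.0))
  kept <- filter_gps_quality(fx)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$hdop, 5.9)  # boundary fix (5.9, 6.9, 7.9) is kept
  expect_equal(nrow(filter_gps_quality(fx[0])), 0L)
  # order preserved
  fx2 <- data.table::data.table(hdop = c(1, 2, 3), vdop = 1, pdop = 1)
  expect_equal(filter_gps_quality(fx2)$hdop, c(1, 2, 3))
})

test_that("GPS minute features: constants, pass fraction, group size", {
  ts <- as.POSIXct("2015-01-05 08:00:00", tz = "UTC") + seq(0, 55, by = 5)
  fx <- data.table::data.table(
    participant_id = "P001", timestamp = ts, speed = 5, elevation = 60,
    hdop = 1, vdop = 1, pdop = 1, sat_in_view = 10L, sat_used = 9L)
  f <- gps_minute_features(fx)
  for (st in c("mean", "median", "min", "max", "p10", "p90"))
    expect_equal(f[[paste0("speed_", st)]], 5)
  expect_equal(f$speed_sd, 0)
  expect_equal(f$gps_n_valid_fixes, 12L)
  expect_equal(f$gps_frac_valid, 1)
  # 10 raw fixes, 8 passing
  fx2 <- data.table::copy(fx)[1:10]
  fx2$hdop[1:2] <- 99
  f2 <- gps_minute_features(fx2)
  expect_equal(f2$gps_frac_valid, 0.8)
  expect_equal(f2$gps_n_valid_fixes, 8L)
  # catalogue group size is 51 GPS variables
  cat51 <- feature_catalogue()[source == "gps", name]
  expect_length(cat51, 51L)
  expect_setequal(setdiff(names(f), c("participant_id", "minute")), cat51)
})

test_that("accelerometer epoch derivations follow the MET equation", {
  zero <- data.table::data.table(counts_axis1 = 0L, counts_axis2 = 0L,
                                 counts_axis3 = 0L)
  d0 <- accel_epoch_derivations(data.table::copy(zero), 75)
  expect_equal(d0$mets, 0.668876)        # equation intercept at zero counts
  expect_true(d0$sedentary_flag)
  expect_false(d0$mvpa_flag)
  # vm counts-per-minute solving METs = 3 exactly puts MVPA at the boundary
  vm_cpm <- (3 - 0.668876) / 0.000863
  ep <- data.table::data.table(counts_axis1 = vm_cpm / 12, counts_axis2 = 0,
                               counts_axis3 = 0)
  d1 <- accel_epoch_derivations(data.table::copy(ep), 75)
  expect_equal(d1$mets, 3, tolerance = 1e-12)
  expect_true(d1$mvpa_flag)
  # METs = 1 at weight 200/3.5 kg gives exactly 1 kcal/min
  vm1 <- (1 - 0.668876) / 0.000863
  ep1 <- data.table::data.table(counts_axis1 = vm1 / 12, counts_axis2 = 0,
                                counts_axis3 = 0)
  d2 <- accel_epoch_derivations(data.table::copy(ep1), 200 / 3.5)
  expect_equal(d2$kcal_min, 1, tolerance = 1e-12)
  expect_error(accel_epoch_derivations(zero, 0), "body_weight")
  # METs are affine increasing in vm counts
  grid <- data.table::data.table(counts_axis1 = seq(0, 3000, by = 100),
                                 counts_axis2 = 0, counts_axis3 = 0)
  dg <- accel_epoch_derivations(grid, 75)
  expect_true(all(diff(dg$mets) > 0))
})

test_that("accelerometer minute features: sums, counts, group size", {
  ts <- as.POSIXct("2015-01-05 08:00:00", tz = "UTC") + seq(0, 55, by = 5)
  mk <- function(variant) data.table::data.table(
    participant_id = "P001", timestamp = ts, filter_variant = variant,
    counts_axis1 = 2L, counts_axis2 = 1L, counts_axis3 = 1L, steps = 2L)
  eps <- rbind(mk("standard"), mk("lfe"))
  f <- accel_minute_features(eps, 75)
  expect_equal(f$steps_sum_std, 24L)
  expect_equal(f$sedentary_epochs_std, 12L)   # all epochs sedentary
  expect_equal(f$mvpa_epochs_std, 0L)
  cat55 <- feature_catalogue()[source == "accel", name]
  expect_length(cat55, 55L)
  expect_setequal(setdiff(names(f), c("participant_id", "minute")), cat55)
})

test_that("HRV minute features match hand computations", {
  base <- as.POSIXct("2015-01-05 08:00:00", tz = "UTC")
  mk <- function(rr) data.table::data.table(
    participant_id = "P001", timestamp = base + cumsum(rr) / 1000, rr_ms = rr)
  f1 <- hrv_minute_features(mk(rep(1000, 30)))
  expect_equal(f1$hr_mean_hr, 60)
  expect_equal(f1$hr_sdnn, 0)
  expect_equal(f1$hr_rmssd, 0)
  expect_equal(f1$hr_pnn50, 0)
  expect_equal(f1$hr_n_beats, 30)
  f2 <- hrv_minute_features(mk(c(1000, 900, 1000)))
  expect_equal(f2$hr_rmssd, 100)              # sqrt(mean(100^2, 100^2))
  expect_equal(f2$hr_pnn50, 1)                # both successive diffs > 50 ms
  expect_equal(f2$hr_sdsd, sd(c(-100, 100)))
  # fewer than 3 intervals: variability missing, means retained
  f3 <- hrv_minute_features(mk(c(1000, 990)))
  expect_true(is.na(f3$hr_sdnn) && is.na(f3$hr_rmssd) && is.na(f3$hr_pnn50))
  expect_false(is.na(f3$hr_mean_rr))
  expect_error(hrv_minute_features(mk(c(1000, -5, 900))), "rr_ms")
  cat12 <- feature_catalogue()[source == "hr", name]
  expect_length(cat12, 12L)
  expect_setequal(setdiff(names(f1), c("participant_id", "minute")), cat12)
})

test_that("time features: weekend flag and minutes since midnight", {
  sat <- as.POSIXct("2015-01-10 00:00:00", tz = "UTC")   # Saturday
  wed <- as.POSIXct("2015-01-07 12:30:00", tz = "UTC")   # Wednesday
  eod <- as.POSIXct("2015-01-07 23:59:00", tz = "UTC")
  tf <- time_features(c(sat, wed, eod))
  expect_equal(tf$time_of_day, c(0L, 750L, 1439L))
  expect_equal(tf$weekend_flag, c(1L, 0L, 0L))
})

test_that("default catalogue has the documented group sizes", {
  cat <- feature_catalogue()
  counts <- table(cat$source)
  expect_equal(unname(counts[c("gps", "accel", "hr", "time")]),
               c(51L, 55L, 12L, 2L), ignore_attr = TRUE)
  expect_equal(nrow(cat), 120L)
  expect_false(anyDuplicated(cat$name) > 0)
  expect_identical(attr(cat, "catalogue_version"), "modesense-catalogue-v1")
})
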