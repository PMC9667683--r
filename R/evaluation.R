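## Prediction-rate definitions and cross-participant summaries.

#' Minute-level prediction rates
#'
#' Computes, in percent: the overall rate (share of minutes whose predicted
#' class equals the true class), the overall transport rate (same share
#' restricted to minutes whose TRUE class is a transport mode, exact mode
#' required), and the per-class recall (share of true-class-c minutes
#' predicted c). A supplementary binary cell, `trip_vs_place`, gives the
#' accuracy of merely distinguishing transport from activity place. Cells
#' with zero denominator are `NA`, never 0. Minutes with a missing
#' prediction (e.g. no out-of-bag tree) are excluded everywhere and counted.
#'
#' @param pred Predicted classes (character/factor; may contain `NA`).
#' @param truth True classes, same length.
#' @return An object of class `rates_report`: list with `rates` (named
#'   percent vector), `denominators`, and `n_missing_pred`.
#' @export
prediction_rates <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length", call. = FALSE)
  keep <- !is.na(pred)
  n_missing <- sum(!keep)
  pred <- pred[keep]; truth <- truth[keep]
  pct <- function(mask) {
    d <- sum(mask)
    if (d == 0L) NA_real_ else 100 * sum(pred[mask] == truth[mask]) / d
  }
  rates <- c(overall = pct(rep(TRUE, length(truth))),
             overall_transport = pct(truth %in% TRANSPORT_LEVELS))
  denoms <- c(overall = length(truth),
              overall_transport = sum(truth %in% TRANSPORT_LEVELS))
  for (cl in MODE_LEVELS) {
    rates[[cl]] <- pct(truth == cl)
    denoms[[cl]] <- sum(truth == cl)
  }
  rates[["trip_vs_place"]] <- if (length(truth) == 0L) NA_real_ else
    100 * mean((pred != "activity_place") == (truth != "activity_place"))
  denoms[["trip_vs_place"]] <- length(truth)
  structure(list(rates = rates, denominators = denoms,
                 n_missing_pred = n_missing),
            class = "rates_report")
}

#' @export
print.rates_report <- function(x, ...) {
  cat("rates_report (%):\n")
  for (nm in names(x$rates))
    cat(sprintf("  %-18s %s  (n = %d)\n", nm,
                ifelse(is.na(x$rates[[nm]]), "NA",
                       sprintf("%.1f", x$rates[[nm]])),
                x$denominators[[nm]]))
  invisible(x)
}

#' Summarize rates across participants / iterations
#'
#' Cell-wise median and 2.5th/97.5th percentiles of the prediction rates
#' over a list of reports (one per cross-validation iteration). Missing
#' cells (zero denominator in an iteration) are excluded from that cell
#' only, with the number of contributing iterations reported.
#'
#' @param reports List of `rates_report` objects.
#' @return A `data.table` with `cell`, `median`, `p2.5`, `p97.5`, `n_iter`.
#' @export
summarize_across_participants <- function(reports) {
  stopifnot(length(reports) > 0L)
  cells <- names(reports[[1L]]$rates)
  out <- data.table::rbindlist(lapply(cells, function(cl) {
    vals <- vapply(reports, function(r) r$rates[[cl]], numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L)
      return(data.table::data.table(cell = cl, median = NA_real_,
                                    p2.5 = NA_real_, p97.5 = NA_real_,
                                    n_iter = 0L))
    data.table::data.table(cell = cl, median = median(vals),
                           p2.5 = q7(vals, 0.025), p97.5 = q7(vals, 0.975),
                           n_iter = length(vals))
  }))
  out[]
}

#' Format a summary cell as "median (p2.5–p97.5)"
#'
#' @param med,lo,hi Median and percentile values (percent).
#' @return Character, e.g. `"79 (62–88)"`; `NA` cells give `"-"`.
#' @export
format_rate_cell <- function(med, lo, hi) {
  ifelse(is.na(med), "-",
         sprintf("%.0f (%.0f–%.0f)", med, lo, hi))
}

## extract per-iteration reports of one kind from a loocv_run
## kind: "test" or "oob"; weighting: "unweighted"/"weighted"
collect_reports <- function(run, feature_set, kind = "test",
                            weighting = "unweighted") {
  lapply(run$iterations, function(it) {
    slot <- if (kind == "test") it[[feature_set]]$test_rates
            else it[[feature_set]]$oob_rates
    slot[[weighting]]
  })
}

## rows of the printed tables, in order
TABLE_CELLS <- c("overall", "overall_transport", "activity_place", "bike",
                 "private_motorized", "public_transport", "walk")
TABLE_ROW_LABELS <- c("Overall", "Overall transport", "Activity place",
                      "Bike", "Private motorized", "Public transport",
                      "Walking")

format_column <- function(summary_dt) {
  s <- summary_dt[match(TABLE_CELLS, summary_dt$cell)]
  format_rate_cell(s$median, s$p2.5, s$p97.5)
}

#' Assemble the three report tables
#'
#' Builds the three standard views of a leave-one-participant-out run:
#' the split-regime comparison (naive out-of-bag rates in the training sets
#' vs rates in the held-out test sets, before and after prevalence cutoff
#' correction; without heart-rate predictors), the with/without heart rate
#' comparison (test sets; overall row unweighted, mode rows weighted), and
#' the homogenization bandwidth sweep (test sets, heart rate included).
#' Cells are formatted as `"median (p2.5–p97.5)"` across iterations.
#'
#' @param run A [loocv_run()] computed with both feature sets and
#'   `compute_oob = TRUE`.
#' @param bandwidths Bandwidths for the sweep table (default 0:5).
#' @return List with `split_comparison`, `hr_comparison`,
#'   `bandwidth_sweep` (data.frames of formatted cells) and `raw` (the
#'   underlying summary tables).
#' @export
build_report_tables <- function(run, bandwidths = 0:5) {
  stopifnot(inherits(run, "loocv_run"))
  raw <- list()

  # -- split-regime comparison (without heart rate, per the headline table)
  fs2 <- if ("without_hr" %in% run$feature_sets) "without_hr" else
    run$feature_sets[1L]
  cols2 <- list(
    oob_before = summarize_across_participants(
      collect_reports(run, fs2, "oob", "unweighted")),
    oob_after = summarize_across_participants(
      collect_reports(run, fs2, "oob", "weighted")),
    test_before = summarize_across_participants(
      collect_reports(run, fs2, "test", "unweighted")),
    test_after = summarize_across_participants(
      collect_reports(run, fs2, "test", "weighted")))
  table2 <- data.frame(rate = TABLE_ROW_LABELS,
                       lapply(cols2, format_column),
                       check.names = FALSE)
  raw$split_comparison <- cols2

  # -- with vs without heart rate (overall unweighted, mode rows weighted)
  mixed_summary <- function(fs) {
    un <- summarize_across_participants(collect_reports(run, fs, "test", "unweighted"))
    we <- summarize_across_participants(collect_reports(run, fs, "test", "weighted"))
    rbind(un[cell == "overall"], we[cell != "overall"])
  }
  fss <- intersect(c("without_hr", "with_hr"), run$feature_sets)
  cols3 <- lapply(fss, mixed_summary)
  names(cols3) <- fss
  table3 <- data.frame(rate = TABLE_ROW_LABELS,
                       lapply(cols3, format_column), check.names = FALSE)
  raw$hr_comparison <- cols3

  # -- homogenization sweep (with heart rate when available)
  fs4 <- if ("with_hr" %in% run$feature_sets) "with_hr" else run$feature_sets[1L]
  tabs <- lapply(run$iterations, function(it) it[[fs4]]$predictions)
  sweep_w <- bandwidth_sweep(tabs, "weighted_pred", bandwidths)
  sweep_u <- bandwidth_sweep(tabs, "raw_pred", bandwidths)
  cols4 <- lapply(as.character(bandwidths), function(b)
    rbind(sweep_u$summary[[b]][cell == "overall"],
          sweep_w$summary[[b]][cell != "overall"]))
  names(cols4) <- paste0("b", bandwidths)
  table4 <- data.frame(rate = TABLE_ROW_LABELS,
                       lapply(cols4, format_column), check.names = FALSE)
  raw$bandwidth_sweep <- cols4

  list(split_comparison = table2, hr_comparison = table3,
       bandwidth_sweep = table4, raw = raw)
}
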