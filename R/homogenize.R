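## A posteriori homogenization: a moving-majority output filter applied to
## each participant's minute-level predicted mode sequence, within blocks of
## contiguous minutes.

#' Contiguity blocks of a minute sequence
#'
#' A gap of more than one minute between successive minutes starts a new
#' block; the moving-majority filter never spans blocks (wear gaps and
#' participant boundaries).
#'
#' @param minute Strictly increasing integer minute indices.
#' @return Integer block id per minute.
#' @export
contiguity_blocks <- function(minute) {
  if (length(minute) == 0L) return(integer(0))
  if (is.unsorted(minute, strictly = TRUE))
    stop("minutes must be strictly increasing", call. = FALSE)
  cumsum(c(1L, as.integer(diff(minute) > 1L)))
}

## moving-majority over one contiguous block of raw labels (integer codes)
mode_filter_block <- function(codes, b, n_classes) {
  n <- length(codes)
  if (b == 0L || n == 1L) return(codes)
  out <- integer(n)
  for (t in seq_len(n)) {
    w <- codes[max(1L, t - b):min(n, t + b)]
    counts <- tabulate(w, nbins = n_classes)
    mx <- max(counts)
    winners <- which(counts == mx)
    out[t] <- if (length(winners) == 1L) winners else codes[t]
  }
  out
}

#' Moving-majority homogenization of a predicted mode sequence
#'
#' For each minute `t` the output is the mode predicted the highest number
#' of times among the raw predictions in the window `[t - b, t + b]`,
#' truncated at the edges of the minute's contiguity block. The filter is
#' non-recursive (it reads raw predictions only, so a forward and a backward
#' pass give identical results). A tie among window majorities keeps the raw
#' label of the central minute; `bandwidth = 0` is the identity.
#'
#' @param labels Character/factor raw predicted modes.
#' @param bandwidth Non-negative integer window half-width in minutes.
#' @param minute Optional minute indices (defaults to a fully contiguous
#'   sequence); used to derive contiguity blocks.
#' @param levels Label universe (defaults to [mode_levels()], extended with
#'   any labels present).
#' @return Character vector of smoothed labels, same length as `labels`.
#' @export
mode_filter <- function(labels, bandwidth, minute = seq_along(labels),
                        levels = NULL) {
  stopifnot(bandwidth >= 0, bandwidth == as.integer(bandwidth))
  labels <- as.character(labels)
  if (length(labels) != length(minute))
    stop("labels and minute must have the same length", call. = FALSE)
  if (length(labels) == 0L) return(character(0))
  if (is.null(levels)) levels <- union(MODE_LEVELS, unique(labels))
  codes <- match(labels, levels)
  if (anyNA(codes)) stop("labels outside the class set", call. = FALSE)
  blocks <- contiguity_blocks(minute)
  out <- integer(length(codes))
  for (blk in unique(blocks)) {
    idx <- which(blocks == blk)
    out[idx] <- mode_filter_block(codes[idx], as.integer(bandwidth),
                                  length(levels))
  }
  levels[out]
}

#' Smooth a prediction table over several bandwidths
#'
#' Applies [mode_filter()] per participant (blocks derived from the minute
#' indices) for each requested bandwidth, appending columns `pred_b<b>`.
#'
#' @param predictions `data.table` with `participant_id`, `minute` and a raw
#'   prediction column.
#' @param pred_col Name of the raw prediction column.
#' @param bandwidths Integer vector of bandwidths (default 0:5).
#' @return The table with one smoothed column per bandwidth appended.
#' @export
smooth_predictions <- function(predictions, pred_col = "weighted_pred",
                               bandwidths = 0:5) {
  predictions <- data.table::as.data.table(predictions)
  data.table::setorder(predictions, participant_id, minute)
  for (b in bandwidths) {
    col <- paste0("pred_b", b)
    predictions[, (col) := mode_filter(get(pred_col), b, minute),
                by = participant_id]
  }
  predictions[]
}

#' Prediction rates by homogenization bandwidth
#'
#' Smooths each iteration's predicted series at every bandwidth and computes
#' the prediction-rate report against the truth, yielding the data behind a
#' bandwidth-sensitivity table (bandwidth 0 reproduces the
#' pre-homogenization rates).
#'
#' @param prediction_tables List of per-iteration prediction tables
#'   (`participant_id`, `minute`, `truth`, and `pred_col`).
#' @param pred_col Raw prediction column to smooth.
#' @param bandwidths Integer vector of bandwidths.
#' @return A list: `reports[[as.character(b)]]` is the list of per-iteration
#'   `rates_report`s at bandwidth `b`; `summary` the cross-iteration
#'   summaries (see [summarize_across_participants()]).
#' @export
bandwidth_sweep <- function(prediction_tables, pred_col = "weighted_pred",
                            bandwidths = 0:5) {
  reports <- list()
  for (b in bandwidths) {
    reports[[as.character(b)]] <- lapply(prediction_tables, function(tab) {
      tab <- data.table::as.data.table(tab)
      data.table::setorder(tab, participant_id, minute)
      sm <- tab[, .(sm = mode_filter(get(pred_col), b, minute)),
                by = participant_id]$sm
      prediction_rates(sm, tab$truth)
    })
  }
  summary <- lapply(reports, summarize_across_participants)
  list(reports = reports, summary = summary, bandwidths = bandwidths,
       pred_col = pred_col)
}
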