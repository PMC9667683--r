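# Independent oracles used across test files.

# brute-force seven-statistic oracle (stats::quantile type 7 is the
# independent percentile implementation)
sum7_oracle <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(c(mean = NA_real_, median = NA_real_, sd = NA_real_,
             min = NA_real_, max = NA_real_, p10 = NA_real_, p90 = NA_real_))
  c(mean = mean(x), median = unname(stats::quantile(x, 0.5, type = 7)),
    sd = stats::sd(x), min = min(x), max = max(x),
    p10 = unname(stats::quantile(x, 0.10, type = 7)),
    p90 = unname(stats::quantile(x, 0.90, type = 7)))
}

# brute-force windowed-majority oracle over one contiguous sequence
windowed_mode_oracle <- function(labels, b) {
  n <- length(labels)
  out <- character(n)
  for (t in seq_len(n)) {
    w <- labels[max(1, t - b):min(n, t + b)]
    tab <- table(w)
    winners <- names(tab)[tab == max(tab)]
    out[t] <- if (length(winners) == 1L) winners else labels[t]
  }
  out
}

# expected accuracy of the bandwidth-1 filter inside a long constant-truth
# segment under i.i.d. flip noise: each minute is correct with prob q, else
# uniform over the other k-1 classes; interior minutes use a 3-window
# majority (tie keeps the raw centre), edge minutes a 2-window.
flip3_analytic <- function(q, k, L) {
  p_other <- (1 - q) / (k - 1)
  states <- seq_len(k)             # state 1 = truth
  pr <- c(q, rep(p_other, k - 1))
  interior <- 0
  for (a in states) for (b in states) for (cc in states) {
    counts <- tabulate(c(a, b, cc), nbins = k)
    mx <- max(counts)
    winners <- which(counts == mx)
    out <- if (length(winners) == 1L) winners else b   # b is the centre
    if (out == 1L) interior <- interior + pr[a] * pr[b] * pr[cc]
  }
  edge <- 0
  for (b in states) for (cc in states) {               # 2-window: always tie or 2-0
    counts <- tabulate(c(b, cc), nbins = k)
    mx <- max(counts)
    winners <- which(counts == mx)
    out <- if (length(winners) == 1L) winners else b
    if (out == 1L) edge <- edge + pr[b] * pr[cc]
  }
  (2 * edge + (L - 2) * interior) / L
}

expect_rates_equal <- function(report, cell, value) {
  expect_equal(unname(report$rates[[cell]]), value, tolerance = 1e-12)
}
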