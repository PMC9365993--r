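#' Zero-phase tremor-band filter
#'
#' Narrow band-pass (default 9--15 Hz) Butterworth applied
#' forward-backward on a plain numeric series, used before
#' cross-correlation lag estimation.
#'
#' @param x numeric series.
#' @param rate sampling rate, Hz (>= 100).
#' @param band band edges, Hz.
#' @param order Butterworth order (per pass).
#' @return Filtered series.
#' @export
bandpass_tremor <- function(x, rate, band = c(9, 15), order = 4) {
  if (rate < 100) stop("rate must be at least 100 Hz")
  filter_series(x, rate, band[1], band[2], order = order)
}

#' Lag of maximum cross-correlation between two epochs
#'
#' Pearson correlation of the overlapping samples at every integer-sample
#' lag within `+/-max_lag_ms`; returns the lag maximising `|r|`, so a
#' perfect anti-phase alignment (r = -1) counts as strongly as a perfect
#' in-phase one (r = +1).  Sign convention: a positive lag means the
#' first signal leads the second (the second is a delayed copy).  Ties in
#' `|r|` are broken toward the smallest `|lag|`.
#'
#' @param x_epoch,y_epoch equal-length (band-passed) epochs.
#' @param rate sampling rate, Hz.
#' @param max_lag_ms lag window half-width, ms.
#' @param abs_max if `FALSE`, maximise signed `r` instead of `|r|`.
#' @return List: `lag_ms`, `r` (correlation at that lag).
#' @export
max_xcorr_lag <- function(x_epoch, y_epoch, rate, max_lag_ms = 100,
                          abs_max = TRUE) {
  n <- length(x_epoch)
  if (n != length(y_epoch)) stop("epochs must have equal length")
  if (stats::sd(x_epoch) == 0 || stats::sd(y_epoch) == 0)
    stop("zero-variance epoch excluded from lag analysis")
  max_k <- as.integer(floor(max_lag_ms * rate / 1000))
  lags <- -max_k:max_k
  r <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(x_epoch[seq_len(n - k)], y_epoch[(1 + k):n])
    else stats::cor(x_epoch[(1 - k):n], y_epoch[seq_len(n + k)])
  }, 0)
  r[is.na(r)] <- 0
  score <- if (abs_max) abs(r) else r
  ord <- order(abs(lags))                      # tie-break: smallest |lag|
  best <- ord[which.max(score[ord])]
  list(lag_ms = lags[best] * 1000 / rate, r = r[best])
}

#' Histogram of maximum-correlation lags
#'
#' Lags pooled over epochs are binned over +/-100 ms in 2 ms bins (100
#' bins); probabilities are counts / number of epochs.  The peak
#' probability is the summed probability of the modal bin and its two
#' neighbours; pairs whose peak probability does not surpass the 0.1
#' threshold are excluded from network lag summaries.
#'
#' @param lags_ms numeric vector of per-epoch max-correlation lags, ms.
#' @param pair label for the channel pair.
#' @param max_lag_ms histogram half-width, ms.
#' @param bin_ms bin width, ms.
#' @param threshold inclusion threshold on the peak probability.
#' @return List of class `lag_histogram`: `bin_edges`, `bin_centres`,
#'   `prob`, `n_epochs`, `peak_lag` (modal bin centre, ms), `peak_prob`,
#'   `included`, `pair`.
#' @export
lag_histogram <- function(lags_ms, pair = "pair", max_lag_ms = 100,
                          bin_ms = 2, threshold = 0.1) {
  if (!length(lags_ms)) stop("need at least one lag")
  edges <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  # right-open bins, except the last which is closed at +max_lag
  idx <- pmin(findInterval(lags_ms, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  prob <- counts / length(lags_ms)
  modal <- which.max(prob)
  centres <- edges[-length(edges)] + bin_ms / 2
  peak <- sum(prob[max(1, modal - 1):min(length(prob), modal + 1)])
  structure(list(bin_edges = edges, bin_centres = centres, prob = prob,
                 n_epochs = length(lags_ms), peak_lag = centres[modal],
                 peak_prob = peak, included = peak > threshold,
                 pair = pair),
            class = "lag_histogram")
}

#' @export
print.lag_histogram <- function(x, ...) {
  cat(sprintf(
    "<lag_histogram> %s: n=%d, peak lag %+.0f ms, peak prob %.3f (%s)\n",
    x$pair, x$n_epochs, x$peak_lag, x$peak_prob,
    if (x$included) "included" else "below 0.1 threshold"))
  invisible(x)
}

#' Cohort summary of peak lags per pair
#'
#' Summarises per-subject lag histograms: mean and SD of the peak lags of
#' the histograms surpassing the peak-probability threshold, plus tallies
#' of positive (first channel leads) vs negative directions.
#'
#' @param histograms list of [lag_histogram()] objects (one per
#'   subject x pair).
#' @return data.frame(pair, n, mean_lag_ms, sd_lag_ms, n_positive,
#'   n_negative, n_zero); SD is `NA` for single-subject pairs.
#' @export
network_lag_summary <- function(histograms) {
  keep <- Filter(function(h) h$included, histograms)
  if (!length(keep)) stop("no histograms surpass the peak-probability threshold")
  pairs <- vapply(keep, `[[`, "", "pair")
  do.call(rbind, lapply(unique(pairs), function(p) {
    lags <- vapply(keep[pairs == p], `[[`, 0, "peak_lag")
    data.frame(pair = p, n = length(lags), mean_lag_ms = mean(lags),
               sd_lag_ms = if (length(lags) > 1) stats::sd(lags) else NA_real_,
               n_positive = sum(lags > 0), n_negative = sum(lags < 0),
               n_zero = sum(lags == 0))
  }))
}

#' Per-epoch maximum-correlation lags for a channel pair
#'
#' Band-pass filters both channels at the tremor band (on the continuous
#' series, before cutting into epochs), then finds the
#' maximum-correlation lag per selected epoch.  By default only
#' harmaline-condition `"move"` epochs clean on both channels are used,
#' mirroring the analysis restriction to moving epochs under tremor.
#'
#' @param es an epoch set (labels attached, artifacts flagged).
#' @param pair `c(first, second)` channel names; positive lags mean the
#'   first leads.
#' @param band tremor band, Hz.
#' @param states epoch labels to include.
#' @param max_lag_ms lag window half-width, ms.
#' @return data.frame(epoch, label, lag_ms, r).
#' @export
pair_lags <- function(es, pair, band = c(9, 15), states = "move",
                      max_lag_ms = 100) {
  stopifnot(inherits(es, "epoch_set"), length(pair) == 2)
  xf <- bandpass_tremor(es$samples[, pair[1]], es$rate, band)
  yf <- bandpass_tremor(es$samples[, pair[2]], es$rate, band)
  mx <- matrix(xf, nrow = es$epoch_len)
  my <- matrix(yf, nrow = es$epoch_len)
  sel <- which(es$labels %in% states & clean_epochs(es, pair))
  if (!length(sel)) stop("no eligible epochs for pair ",
                         paste(pair, collapse = "-"))
  do.call(rbind, lapply(sel, function(i) {
    l <- max_xcorr_lag(mx[, i], my[, i], es$rate, max_lag_ms)
    data.frame(epoch = i, label = es$labels[i], lag_ms = l$lag_ms, r = l$r)
  }))
}
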