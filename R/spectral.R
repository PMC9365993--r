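#' One-sided amplitude spectrum of a single epoch
#'
#' Plain FFT magnitude (rectangular window, no detrending beyond the
#' z-scoring already applied upstream).  For a 2-s epoch the frequency
#' grid has 0.5 Hz steps from 0 to the Nyquist frequency.
#'
#' @param epoch numeric vector, one epoch of samples.
#' @param rate sampling rate, Hz.
#' @return data.frame with columns `freq` (Hz) and `amp` (|FFT|).
#' @export
epoch_amplitude_spectrum <- function(epoch, rate) {
  n <- length(epoch)
  if (n < 2) stop("epoch too short")
  nh <- n %/% 2
  amp <- Mod(stats::fft(epoch))[seq_len(nh + 1)]
  data.frame(freq = (0:nh) * rate / n, amp = amp)
}

# indices of bins whose centre lies in [lo, hi] (inclusive, tolerant)
band_bins <- function(freq, lo, hi) {
  which(freq >= lo - 1e-9 & freq <= hi + 1e-9)
}

#' Tremor-band amplitude ratio
#'
#' Summed spectral amplitude over the tremor band (default 9--15 Hz,
#' inclusive bins) divided by the summed amplitude over the low-frequency
#' range (default 0--15 Hz, inclusive, DC bin included).  On the 0.5 Hz
#' grid of a 2-s epoch these are 13 and 31 bins, so the ratio of a
#' flat-spectrum signal is about 13/31.  The result lies in `[0, 1]`
#' whenever the band is a subset of the denominator range, and is
#' invariant to positive rescaling of the epoch.
#'
#' @param spec an [epoch_amplitude_spectrum()] data.frame.
#' @param band numerator band, Hz.
#' @param denom denominator band, Hz.
#' @return Ratio in `[0, 1]`, or `NA` if the denominator sum is zero
#'   (such epochs are excluded from analysis).
#' @export
amplitude_ratio <- function(spec, band = c(9, 15), denom = c(0, 15)) {
  if (max(band) > max(spec$freq) || max(denom) > max(spec$freq))
    stop("band outside the spectrum range")
  num <- sum(spec$amp[band_bins(spec$freq, band[1], band[2])])
  den <- sum(spec$amp[band_bins(spec$freq, denom[1], denom[2])])
  if (den == 0) return(NA_real_)
  num / den
}

#' Per-epoch amplitude ratios for one channel of an epoch set
#'
#' @param es an epoch set.
#' @param channel channel name.
#' @param band,denom ratio bands, Hz.
#' @return data.frame(epoch, label, artifact, ratio).
#' @export
epoch_amplitude_ratios <- function(es, channel, band = c(9, 15),
                                   denom = c(0, 15)) {
  m <- epoch_matrix(es, channel)
  ratio <- apply(m, 2, function(x)
    amplitude_ratio(epoch_amplitude_spectrum(x, es$rate), band, denom))
  data.frame(epoch = seq_len(es$n_epochs), label = es$labels,
             artifact = es$artifact[, channel], ratio = ratio)
}

#' Mean (+/- SE) amplitude spectrum over a group of epochs
#'
#' @param es an epoch set.
#' @param channel channel name.
#' @param epochs logical or integer selection of epochs (default: all
#'   epochs not artifact-flagged on `channel`).
#' @return data.frame(freq, mean, se, n).
#' @export
mean_spectrum <- function(es, channel, epochs = NULL) {
  m <- epoch_matrix(es, channel)
  if (is.null(epochs)) epochs <- !es$artifact[, channel]
  m <- m[, epochs, drop = FALSE]
  if (ncol(m) < 2) stop("need at least two epochs for a mean spectrum")
  amps <- apply(m, 2, function(x)
    epoch_amplitude_spectrum(x, es$rate)$amp)
  freq <- epoch_amplitude_spectrum(m[, 1], es$rate)$freq
  data.frame(freq = freq,
             mean = rowMeans(amps),
             se = apply(amps, 1, stats::sd) / sqrt(ncol(amps)),
             n = ncol(amps))
}
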