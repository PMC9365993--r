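#' Welch segmentation parameters
#'
#' Default segmentation of a 2000-sample epoch: segment length
#' `floor(n/4.5)`, 50% overlap, Hamming taper -- eight segments, matching
#' the default behaviour of the classical Welch magnitude-squared
#' coherence estimator.  The frequency grid follows the segment length
#' (bin spacing `rate/seg_len`).  At least two segments are required:
#' with a single segment the coherence estimate degenerates to 1
#' identically.
#'
#' @param n epoch length in samples.
#' @param seg_len segment length in samples (default `floor(n/4.5)`).
#' @param overlap fractional overlap between segments, in `[0, 1)`.
#' @param taper `"hamming"` or `"rectangular"`.
#' @return List with `seg_len`, `step`, `starts`, `window`, `n_segments`.
#' @export
welch_params <- function(n, seg_len = NULL, overlap = 0.5,
                         taper = c("hamming", "rectangular")) {
  taper <- match.arg(taper)
  if (is.null(seg_len)) seg_len <- floor(n / 4.5)
  seg_len <- as.integer(seg_len)
  if (seg_len < 4 || seg_len > n) stop("invalid segment length")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  if (length(starts) < 2)
    stop("segmentation must yield at least two segments")
  w <- if (taper == "hamming") {
    k <- seq_len(seg_len) - 1L
    0.54 - 0.46 * cos(2 * pi * k / (seg_len - 1))
  } else rep(1, seg_len)
  list(seg_len = seg_len, step = step, starts = starts, window = w,
       n_segments = length(starts))
}

# Welch auto-/cross-spectra of x against every column of Y.
# Returns list(freq, pxx (vector), pyy (matrix), pxy (complex matrix)),
# one-sided grid of length floor(seg_len/2)+1.
welch_cross <- function(x, Y, rate, params) {
  n <- length(x)
  if (nrow(Y) != n) stop("signals must have equal epoch length")
  L <- params$seg_len
  nh <- L %/% 2
  keep <- seq_len(nh + 1L)
  pxx <- numeric(nh + 1L)
  pyy <- matrix(0, nh + 1L, ncol(Y))
  pxy <- matrix(0 + 0i, nh + 1L, ncol(Y))
  for (s in params$starts) {
    idx <- s:(s + L - 1L)
    fx <- stats::fft(x[idx] * params$window)[keep]
    fy <- stats::mvfft(Y[idx, , drop = FALSE] * params$window)[keep, ,
                                                               drop = FALSE]
    pxx <- pxx + Mod(fx)^2
    pyy <- pyy + Mod(fy)^2
    pxy <- pxy + Conj(fx) * fy
  }
  list(freq = (0:nh) * rate / L, pxx = pxx, pyy = pyy, pxy = pxy)
}

#' Magnitude-squared coherence of one epoch pair
#'
#' Welch-averaged `|Pxy|^2 / (Pxx * Pyy)` per frequency bin, where `Pxy`
#' is the cross-spectrum and `Pxx`, `Pyy` the auto-spectra accumulated
#' over tapered, overlapping segments.  The estimate lies in `[0, 1]` at
#' every bin, is symmetric in its arguments, and is invariant to positive
#' rescaling of either input.
#'
#' @param x_epoch,y_epoch equal-length numeric epochs.
#' @param rate sampling rate, Hz.
#' @param params a [welch_params()] list (default: Welch defaults for the
#'   epoch length).
#' @return data.frame(freq, cxy).
#' @export
epoch_coherence <- function(x_epoch, y_epoch, rate, params = NULL) {
  if (length(x_epoch) != length(y_epoch))
    stop("signals must have equal epoch length")
  if (is.null(params)) params <- welch_params(length(x_epoch))
  w <- welch_cross(x_epoch, cbind(y_epoch), rate, params)
  denom <- w$pxx * w$pyy[, 1]
  cxy <- ifelse(denom > 0, Mod(w$pxy[, 1])^2 / denom, 0)
  data.frame(freq = w$freq, cxy = pmin(cxy, 1))
}

# coherence spectra of x against every column of Y (matrix nfreq x ncol(Y))
coherence_batch <- function(x, Y, rate, params) {
  w <- welch_cross(x, Y, rate, params)
  cxy <- Mod(w$pxy)^2 / (w$pxx * w$pyy)
  cxy[!is.finite(cxy)] <- 0
  list(freq = w$freq, cxy = pmin(cxy, 1))
}

#' Mean coherence over the tremor band
#'
#' Arithmetic mean of the coherence values at the grid bins whose centre
#' lies inside the (inclusive) band.
#'
#' @param cs an [epoch_coherence()] data.frame.
#' @param band band edges, Hz.
#' @return Scalar band-mean coherence in `[0, 1]`.
#' @export
band_mean_coherence <- function(cs, band = c(9, 15)) {
  idx <- band_bins(cs$freq, band[1], band[2])
  if (!length(idx)) stop("no coherence bins inside the band")
  mean(cs$cxy[idx])
}
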