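#' Bipolar re-referencing
#'
#' Replaces each named pair of same-role channels with their element-wise
#' difference (first minus second).  Channels not mentioned in `pairs` are
#' passed through unchanged.
#'
#' @param rec a [new_recording()].
#' @param pairs named list; each element is `c(first, second)` channel
#'   names, the element name becomes the derived channel's name.
#' @return A re-referenced recording.
#' @export
bipolar_reference <- function(rec, pairs) {
  stopifnot(inherits(rec, "tremor_recording"))
  used <- character(0)
  out <- list(); roles <- character(0)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (length(p) != 2) stop("each pair must name two channels")
    missing <- setdiff(p, colnames(rec$samples))
    if (length(missing)) stop("no such channel: ", paste(missing, collapse = ", "))
    if (rec$roles[p[1]] != rec$roles[p[2]])
      stop("bipolar pair must share a role: ", nm)
    out[[nm]] <- rec$samples[, p[1]] - rec$samples[, p[2]]
    roles[nm] <- rec$roles[p[1]]
    used <- c(used, p)
  }
  keep <- setdiff(colnames(rec$samples), used)
  for (nm in keep) {
    out[[nm]] <- rec$samples[, nm]
    roles[nm] <- rec$roles[nm]
  }
  new_recording(do.call(cbind, out), rec$rate, roles[names(out)],
                rec$condition, rec$subject)
}

# Butterworth band-pass realised as cascaded biquads (second-order
# sections).  The direct-form order-2*order polynomial recursion is badly
# conditioned for narrow low-frequency bands at high rates (rounding can
# even destabilise it); the sections are therefore designed in closed
# form -- analog prototype poles, analog band-pass transform, bilinear
# map -- so every pole is computed independently and filter linearity
# holds to ~1e-12.
butter_sos <- function(order, rate, lo, hi) {
  n <- order
  proto <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))  # LHP poles
  W1 <- 2 * rate * tan(pi * lo / rate)        # prewarped corners
  W2 <- 2 * rate * tan(pi * hi / rate)
  B <- W2 - W1; W0 <- sqrt(W1 * W2)
  # band-pass transform: each prototype pole s yields the roots of
  # p^2 - s*B*p + W0^2 = 0
  ap <- unlist(lapply(proto, function(s) {
    a <- s * B / 2
    d <- sqrt(a^2 - W0^2)
    c(a + d, a - d)
  }))
  zp <- (2 * rate + ap) / (2 * rate - ap)     # bilinear map
  # group digital poles into conjugate pairs
  used <- rep(FALSE, 2 * n); pairs <- list()
  for (i in seq_len(2 * n)) {
    if (used[i]) next
    used[i] <- TRUE
    cands <- which(!used)
    j <- cands[which.min(abs(zp[cands] - Conj(zp[i])))]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(zp[i], zp[j])
  }
  # each biquad carries one zero at z = +1 and one at z = -1; per-section
  # gain normalises |H| = 1 at the (warped) centre frequency
  zc <- exp(2i * atan(W0 / (2 * rate)))
  lapply(pairs, function(p) {
    a <- Re(c(1, -(p[1] + p[2]), p[1] * p[2]))
    g <- Mod(zc^2 + a[2] * zc + a[3]) / Mod(zc^2 - 1)
    list(b = g * c(1, 0, -1), a = a)
  })
}

sos_apply <- function(x, sos) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# Zero-phase Butterworth band-pass on a plain numeric series
# (forward-backward biquad cascade with odd-reflection edge padding).
filter_series <- function(x, rate, lo, hi, order = 4) {
  if (hi >= rate / 2) stop("upper edge must be below the Nyquist frequency")
  if (lo <= 0 || lo >= hi) stop("band edges must satisfy 0 < lo < hi")
  n <- length(x)
  sos <- butter_sos(order, rate, lo, hi)
  np <- min(n - 1L, as.integer(round(3 * rate / lo)))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  v <- sos_apply(xp, sos)
  v <- rev(sos_apply(rev(v), sos))
  v[(np + 1):(np + n)]
}

#' Band-pass filter a recording (zero-phase)
#'
#' 4th-order Butterworth applied forward and backward (`filtfilt`), so the
#' filter has zero phase/group delay and epoch timing is preserved.
#' Default corners 1--49 Hz bracket the analysis band and act as
#' anti-alias protection before down-sampling to 1 kHz.
#'
#' @param rec a [new_recording()].
#' @param lo,hi band edges, Hz.
#' @param order Butterworth order (per pass).
#' @return A filtered recording.
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 49, order = 4) {
  stopifnot(inherits(rec, "tremor_recording"))
  rec$samples <- apply(rec$samples, 2, filter_series,
                       rate = rec$rate, lo = lo, hi = hi, order = order)
  rec
}

#' Down-sample a recording by an integer factor
#'
#' Keeps every `rate/target`-th sample (band-pass filtering beforehand
#' provides the anti-alias guarantee).
#'
#' @param rec a [new_recording()].
#' @param target target rate, Hz; must divide the current rate.
#' @return Recording at `target` Hz.
#' @export
downsample <- function(rec, target = 1000) {
  stopifnot(inherits(rec, "tremor_recording"))
  factor <- rec$rate / target
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("rate must be an integer multiple of target")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  idx <- seq(1, nrow(rec$samples), by = factor)
  rec$samples <- rec$samples[idx, , drop = FALSE]
  rec$rate <- target
  rec
}

#' z-score normalisation over collated conditions
#'
#' For each channel, the mean and SD are computed over the concatenation of
#' all supplied recordings (e.g. a subject's control and harmaline
#' sessions) and the same affine transform is applied to every recording,
#' so cross-condition amplitude ratios are preserved.
#'
#' @param recs list of recordings with identical channel sets.
#' @return List of z-scored recordings in the same order.
#' @export
zscore_collated <- function(recs) {
  stopifnot(length(recs) >= 1,
            all(vapply(recs, inherits, TRUE, "tremor_recording")))
  chans <- colnames(recs[[1]]$samples)
  for (r in recs[-1])
    if (!identical(colnames(r$samples), chans))
      stop("all recordings must share the same channels")
  for (ch in chans) {
    all_x <- unlist(lapply(recs, function(r) r$samples[, ch]))
    mu <- mean(all_x); s <- stats::sd(all_x)
    if (!is.finite(s) || s == 0)
      stop("zero-variance channel cannot be z-scored: ", ch)
    for (i in seq_along(recs))
      recs[[i]]$samples[, ch] <- (recs[[i]]$samples[, ch] - mu) / s
  }
  recs
}

#' Segment a recording into non-overlapping epochs
#'
#' Epochs are contiguous from the session start; a trailing partial epoch
#' is discarded.  At the canonical 1 kHz analysis rate and 2-s epochs,
#' each epoch holds 2000 samples.
#'
#' @param rec a [new_recording()].
#' @param epoch_s epoch duration, seconds.
#' @return An object of class `epoch_set`: the trimmed sample matrix plus
#'   `epoch_len`, `n_epochs`, per-epoch `labels` (initially
#'   `"unclassified"`) and an `artifact` flag matrix (epochs x channels).
#' @export
segment_epochs <- function(rec, epoch_s = 2) {
  stopifnot(inherits(rec, "tremor_recording"))
  epoch_len <- as.integer(round(epoch_s * rec$rate))
  n_epochs <- nrow(rec$samples) %/% epoch_len
  keep <- seq_len(n_epochs * epoch_len)
  structure(list(
    samples = rec$samples[keep, , drop = FALSE],
    rate = rec$rate, roles = rec$roles,
    condition = rec$condition, subject = rec$subject,
    epoch_len = epoch_len, n_epochs = n_epochs,
    labels = rep("unclassified", n_epochs),
    artifact = matrix(FALSE, n_epochs, ncol(rec$samples),
                      dimnames = list(NULL, colnames(rec$samples)))),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d samples, %d channels @ %g Hz\n",
              x$n_epochs, x$epoch_len, ncol(x$samples), x$rate))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = " "), "\n")
  cat("  flagged epochs:", sum(apply(x$artifact, 1, any)), "\n")
  invisible(x)
}

#' One channel of an epoch set as a samples-by-epochs matrix
#'
#' @param es an [segment_epochs()] object.
#' @param channel channel name.
#' @return Numeric matrix `epoch_len x n_epochs`.
#' @export
epoch_matrix <- function(es, channel) {
  stopifnot(inherits(es, "epoch_set"))
  if (!channel %in% colnames(es$samples))
    stop("no such channel: ", channel)
  matrix(es$samples[, channel], nrow = es$epoch_len, ncol = es$n_epochs)
}

#' Flag large-amplitude artifact epochs
#'
#' Operating on z-scored data, an epoch is flagged on a channel if any
#' sample magnitude is greater than or equal to `k` standard deviations.
#' Flags are recorded per channel and the data retained; downstream
#' statistics exclude an epoch whenever any participating channel is
#' flagged.
#'
#' @param es an epoch set (z-scored data).
#' @param k rejection threshold in SD units.
#' @return The epoch set with its `artifact` matrix filled in.
#' @export
reject_artifacts <- function(es, k = 4) {
  stopifnot(inherits(es, "epoch_set"))
  for (ch in colnames(es$samples)) {
    m <- epoch_matrix(es, ch)
    es$artifact[, ch] <- apply(abs(m) >= k, 2, any)
  }
  es
}

#' Epochs clean on every listed channel
#'
#' @param es an epoch set.
#' @param channels channels participating in the statistic.
#' @return Logical vector over epochs: `TRUE` where no listed channel is
#'   artifact-flagged.
#' @export
clean_epochs <- function(es, channels) {
  stopifnot(inherits(es, "epoch_set"))
  !apply(es$artifact[, channels, drop = FALSE], 1, any)
}
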