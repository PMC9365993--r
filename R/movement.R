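#' Total acceleration magnitude
#'
#' Per-sample Euclidean norm of the three accelerometer axes,
#' `sqrt(x^2 + y^2 + z^2)`, used as a proxy of overall movement.
#'
#' @param ax,ay,az equal-length numeric series, m/s^2.
#' @return Non-negative numeric series, m/s^2.
#' @export
total_acceleration <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axes must have equal length")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Centred moving-average smoothing
#'
#' Moving mean with a centred window (default 100 samples = 100 ms at
#' 1 kHz); at the edges the window shrinks so the output has the same
#' length and no lag is introduced.
#'
#' @param a numeric series.
#' @param window window size in samples.
#' @return Smoothed series, same length as `a`.
#' @export
smooth_total_accel <- function(a, window = 100) {
  n <- length(a)
  if (n < window) stop("series shorter than the smoothing window")
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  cs <- cumsum(c(0, a))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' First principal component of tri-axial accelerometry
#'
#' Projects the centred (x, y, z) samples onto the leading eigenvector of
#' their 3x3 covariance matrix, capturing the axis of maximal variance for
#' spectral analysis.  The sign is fixed so the component correlates
#' positively with the axis of largest variance.
#'
#' @param ax,ay,az equal-length numeric series.
#' @return Numeric series (unitless after later z-scoring); attribute
#'   `"explained"` holds the share of variance explained.
#' @export
accel_pc1 <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axes must have equal length")
  m <- cbind(x = ax, y = ay, z = az)
  v <- apply(m, 2, stats::var)
  if (all(v < 1e-300)) stop("degenerate accelerometer input (constant axes)")
  mc <- sweep(m, 2, colMeans(m))
  eg <- eigen(stats::cov(mc), symmetric = TRUE)
  w <- eg$vectors[, 1]
  dom <- which.max(v)
  if (w[dom] < 0) w <- -w
  pc1 <- as.numeric(mc %*% w)
  attr(pc1, "explained") <- eg$values[1] / sum(eg$values)
  pc1
}

#' Classify epochs as resting or moving
#'
#' An epoch is `"rest"` if the smoothed total acceleration stays strictly
#' below `threshold` for the entire epoch, `"move"` if it stays strictly
#' above for the entire epoch, and `"unclassified"` otherwise (samples
#' exactly at the threshold break the entire-epoch rule).  Unclassified
#' epochs are excluded from state-contrast analyses.
#'
#' @param smoothed smoothed total-acceleration series aligned with the
#'   epoch grid (m/s^2).
#' @param epoch_len epoch length in samples.
#' @param threshold global movement threshold, m/s^2.
#' @return Character vector of labels, one per complete epoch.
#' @export
classify_epochs <- function(smoothed, epoch_len, threshold = 1.0) {
  n_epochs <- length(smoothed) %/% epoch_len
  m <- matrix(smoothed[seq_len(n_epochs * epoch_len)], nrow = epoch_len)
  below <- apply(m < threshold, 2, all)
  above <- apply(m > threshold, 2, all)
  ifelse(below, "rest", ifelse(above, "move", "unclassified"))
}

#' Movement state and kinematic series for an epoch set
#'
#' Runs the accelerometer chain on an epoch set: total acceleration,
#' 100-sample moving-average smoothing, threshold classification, and the
#' first principal component of the three axes (the kinematic partner for
#' spectral and coherence analysis).  Labels are written into the epoch
#' set and the pc1 series appended as channel `"kin"` (role
#' `"kinematic"`).
#'
#' @param es an epoch set containing `accel_x/y/z` channels.
#' @param threshold movement threshold, m/s^2.
#' @param window smoothing window, samples.
#' @return The epoch set with `labels` set, channel `kin` added, and the
#'   smoothed total-acceleration series attached as `total_accel`.
#' @export
attach_movement <- function(es, threshold = 1.0, window = 100) {
  stopifnot(inherits(es, "epoch_set"))
  need <- c("accel_x", "accel_y", "accel_z")
  if (!all(need %in% colnames(es$samples)))
    stop("epoch set lacks accel_x/accel_y/accel_z channels")
  ax <- es$samples[, "accel_x"]; ay <- es$samples[, "accel_y"]
  az <- es$samples[, "accel_z"]
  a <- smooth_total_accel(total_acceleration(ax, ay, az), window)
  es$labels <- classify_epochs(a, es$epoch_len, threshold)
  kin <- accel_pc1(ax, ay, az)
  kin <- (kin - mean(kin)) / stats::sd(kin)   # SD units, like the z-scored channels
  es$samples <- cbind(es$samples, kin = as.numeric(kin))
  es$roles <- c(es$roles, kin = "kinematic")
  es$artifact <- cbind(es$artifact, kin = rep(FALSE, es$n_epochs))
  es$total_accel <- a
  es
}
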