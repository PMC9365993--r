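#' 1/f^alpha background noise
#'
#' Spectrally shaped Gaussian noise: white noise is transformed to the
#' frequency domain, each bin scaled by `f^(-alpha/2)` (so the power
#' spectrum falls as `1/f^alpha`), transformed back and standardised to
#' zero mean and unit SD.  The DC bin is zeroed.
#'
#' @param n number of samples.
#' @param alpha spectral exponent (1 = pink noise).
#' @return Numeric vector of length `n`, mean 0, SD 1.
#' @keywords internal
pink_noise <- function(n, alpha = 1) {
  if (n < 2) return(rep(0, n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))           # avoid f = 0; DC handled below
  f <- pmin(f, n - f + 1)             # mirror for negative frequencies
  W <- W * f^(-alpha / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Channel specification for the network simulator
#'
#' @param name channel name.
#' @param role one of `"eeg"`, `"lfp"`, `"emg"`, `"accel"`.
#' @param coupling share of the shared tremor oscillator in the channel,
#'   in `[0, 1]`; the independent 1/f noise enters with weight
#'   `sqrt(1 - coupling^2)`.
#' @param lag_ms delay of the channel's copy of the oscillator relative to
#'   the oscillator itself, in milliseconds (within +/-100).
#' @param gain_rest,gain_move tremor amplitude multipliers (>= 0) applied to
#'   the oscillator component while the animal is resting / moving.
#' @return A list of class `sim_channel`.
#' @export
sim_channel <- function(name, role, coupling, lag_ms = 0,
                        gain_rest = 1, gain_move = 1) {
  if (!is.numeric(coupling) || coupling < 0 || coupling > 1)
    stop("coupling must lie in [0, 1] (channel ", name, ")")
  if (abs(lag_ms) > 100)
    stop("lag_ms must lie within +/-100 ms (channel ", name, ")")
  if (gain_rest < 0 || gain_move < 0)
    stop("tremor gains must be >= 0 (channel ", name, ")")
  structure(list(name = name, role = role, coupling = coupling,
                 lag_ms = lag_ms, gain_rest = gain_rest,
                 gain_move = gain_move),
            class = "sim_channel")
}

default_sim_channels <- function(condition) {
  # Condition scales tremor gains: harmaline drives the shared oscillator
  # hard; pre-drug control leaves only a weak rhythm.  Cerebellar coupling is
  # state-invariant; thalamic and cortical coupling strengthen with movement.
  g <- if (condition == "harmaline") 1 else 0.25
  list(
    sim_channel("lfp_cb",   "lfp", coupling = 0.8, lag_ms = 0,
                gain_rest = 1.0 * g, gain_move = 1.0 * g),
    sim_channel("lfp_thal", "lfp", coupling = 0.7, lag_ms = 5,
                gain_rest = 0.4 * g, gain_move = 1.2 * g),
    sim_channel("eeg",      "eeg", coupling = 0.5, lag_ms = 10,
                gain_rest = 0.5 * g, gain_move = 1.0 * g),
    sim_channel("emg",      "emg", coupling = 0.6, lag_ms = 15,
                gain_rest = 0.8 * g, gain_move = 1.5 * g))
}

#' Configuration for a simulated multichannel session
#'
#' Defines a shared phase-diffusing tremor oscillator (default 11 Hz with a
#' phase-locked harmonic at twice the tremor frequency), a set of recording
#' channels coupled to it with configurable strength and millisecond lags,
#' tri-axial accelerometry carrying both movement-level offsets and tremor,
#' and a rest/movement episode schedule.  Defaults emulate a harmaline
#' session: ~60% of time moving, movement acceleration ~3 m/s^2 against a
#' 0.3 m/s^2 resting baseline (classified against a 1 m/s^2 threshold), and
#' tremor gains that rise from control to harmaline.
#'
#' @param sampling_rate Hz (default 1000, the canonical analysis rate).
#' @param duration session length in seconds; the default 1200 s yields
#'   ~600 two-second epochs per condition, matching typical session sizes.
#' @param tremor_freq fundamental tremor frequency, Hz.
#' @param band tremor band, Hz (c(9, 15)).
#' @param harmonic_rel_amp amplitude of the phase-locked 2f harmonic as a
#'   fraction of the fundamental.
#' @param phase_jitter Gaussian phase-diffusion rate of the oscillator,
#'   rad/sqrt(s); broadens the tremor line so coherence < 1 is achievable
#'   without additive noise.
#' @param noise_exponent 1/f^alpha exponent of the background noise.
#' @param channels list of [sim_channel()] specs; `NULL` gives a default
#'   cerebellar-LFP / thalamic-LFP / EEG / EMG montage.
#' @param movement_schedule optional data.frame(start, end) of movement
#'   episodes in seconds; `NULL` draws a stochastic schedule covering
#'   `move_fraction` of the session.
#' @param move_fraction fraction of session time spent moving.
#' @param mean_episode_s mean movement-episode duration, s.
#' @param accel_baseline resting total acceleration, m/s^2 (< 1).
#' @param accel_move_level movement total acceleration, m/s^2 (> 1).
#' @param accel_tremor_rest,accel_tremor_move tremor amplitude on the
#'   accelerometer (m/s^2) at rest / during movement (scaled by condition
#'   like the channel gains).
#' @param accel_coupling coupling of the accelerometer tremor component.
#' @param accel_lag_ms lag of the accelerometer tremor component, ms.
#' @param accel_noise_sd SD of low-pass Gaussian sensor noise per axis.
#' @param ramp_s on/off ramp of movement episodes, s (default 0.1 = 100 ms),
#'   creating threshold-straddling samples at episode edges.
#' @param condition `"control"` or `"harmaline"`.
#' @param subject subject identifier.
#' @param seed integer RNG seed; the session is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 1000, duration = 1200,
                       tremor_freq = 11, band = c(9, 15),
                       harmonic_rel_amp = 0.3, phase_jitter = 3,
                       noise_exponent = 1, channels = NULL,
                       movement_schedule = NULL, move_fraction = 0.6,
                       mean_episode_s = 10,
                       accel_baseline = 0.3, accel_move_level = 3,
                       accel_tremor_rest = 0.3, accel_tremor_move = 0.8,
                       accel_coupling = 0.9, accel_lag_ms = 15,
                       accel_noise_sd = 0.05, ramp_s = 0.1,
                       condition = c("harmaline", "control"),
                       subject = "sim01", seed = 1L) {
  condition <- match.arg(condition)
  if (duration <= 0) stop("duration must be positive")
  if (move_fraction < 0 || move_fraction > 1)
    stop("move_fraction must lie in [0, 1]")
  if (is.null(channels)) channels <- default_sim_channels(condition)
  if (!all(vapply(channels, inherits, TRUE, "sim_channel")))
    stop("channels must be a list of sim_channel() specs")
  if (!is.null(movement_schedule)) {
    ms <- movement_schedule
    if (any(ms$start < 0) || any(ms$end > duration) || any(ms$end <= ms$start))
      stop("movement episodes must be non-overlapping within [0, duration]")
    if (nrow(ms) > 1 && any(ms$start[-1] < ms$end[-nrow(ms)]))
      stop("movement episodes must be non-overlapping within [0, duration]")
  }
  structure(list(
    sampling_rate = sampling_rate, duration = duration,
    tremor_freq = tremor_freq, band = band,
    harmonic_rel_amp = harmonic_rel_amp, phase_jitter = phase_jitter,
    noise_exponent = noise_exponent, channels = channels,
    movement_schedule = movement_schedule, move_fraction = move_fraction,
    mean_episode_s = mean_episode_s, accel_baseline = accel_baseline,
    accel_move_level = accel_move_level,
    accel_tremor_rest = accel_tremor_rest,
    accel_tremor_move = accel_tremor_move,
    accel_coupling = accel_coupling, accel_lag_ms = accel_lag_ms,
    accel_noise_sd = accel_noise_sd, ramp_s = ramp_s,
    condition = condition, subject = subject, seed = as.integer(seed)),
    class = "sim_config")
}

#' Draw a movement-episode schedule
#'
#' Movement episodes alternate with rest gaps.  Episode and gap durations
#' are drawn from exponential distributions and then rescaled so that the
#' episodes cover exactly `fraction` of the session.
#'
#' @param duration session length, s.
#' @param fraction fraction of time moving, in `[0, 1]`.
#' @param mean_episode_s mean episode duration, s.
#' @param seed optional RNG seed.
#' @return data.frame with columns `start`, `end` (seconds), possibly empty.
#' @export
make_movement_schedule <- function(duration, fraction, mean_episode_s = 10,
                                   seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (fraction == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  if (fraction == 1) return(data.frame(start = 0, end = duration))
  k <- max(1L, round(duration * fraction / mean_episode_s))
  ep <- stats::rexp(k) + 0.1          # floor avoids degenerate slivers
  ep <- ep / sum(ep) * (duration * fraction)
  gap <- stats::rexp(k + 1) + 0.1
  gap <- gap / sum(gap) * (duration * (1 - fraction))
  start <- cumsum(gap[seq_len(k)]) + c(0, cumsum(ep))[seq_len(k)]
  data.frame(start = start, end = start + ep)
}

# Smoothed 0/1 movement gate with cosine on/off ramps (length ramp_s).
movement_gate <- function(schedule, n, rate, ramp_s) {
  g <- numeric(n)
  t <- (seq_len(n) - 1) / rate
  if (nrow(schedule) == 0) return(g)
  for (i in seq_len(nrow(schedule))) {
    s <- schedule$start[i]; e <- schedule$end[i]
    idx <- t >= s & t < e
    g[idx] <- 1
    if (ramp_s > 0) {
      up <- t >= s - ramp_s & t < s
      g[up] <- pmax(g[up], 0.5 * (1 + cos(pi * (s - t[up]) / ramp_s)))
      dn <- t >= e & t < e + ramp_s
      g[dn] <- pmax(g[dn], 0.5 * (1 + cos(pi * (t[dn] - e) / ramp_s)))
    }
  }
  pmin(g, 1)
}

# Integer-sample delay with edge padding by the first/last value.
shift_series <- function(x, lag_samples) {
  n <- length(x)
  k <- as.integer(round(lag_samples))
  if (k == 0) return(x)
  if (abs(k) >= n) stop("lag exceeds series length")
  if (k > 0) c(rep(x[1], k), x[seq_len(n - k)])
  else c(x[(1 - k):n], rep(x[n], -k))
}

#' Ground-truth epoch state labels from a movement schedule
#'
#' An epoch is labelled `"move"` if it lies entirely inside one movement
#' episode (clear of the on/off ramps), `"rest"` if it lies entirely
#' outside every episode and its ramps, and `"transition"` otherwise.
#'
#' @param schedule data.frame(start, end) of movement episodes, s.
#' @param duration session length, s.
#' @param epoch_s epoch length, s.
#' @param ramp_s episode ramp length, s.
#' @return Character vector, one label per complete epoch.
#' @export
truth_epoch_labels <- function(schedule, duration, epoch_s = 2, ramp_s = 0.1) {
  n_ep <- floor(duration / epoch_s)
  starts <- (seq_len(n_ep) - 1) * epoch_s
  ends <- starts + epoch_s
  lab <- character(n_ep)
  for (i in seq_len(n_ep)) {
    inside <- nrow(schedule) > 0 &&
      any(schedule$start + ramp_s <= starts[i] &
          schedule$end - ramp_s >= ends[i])
    clear <- nrow(schedule) == 0 ||
      all(schedule$end + ramp_s <= starts[i] |
          schedule$start - ramp_s >= ends[i])
    lab[i] <- if (inside) "move" else if (clear) "rest" else "transition"
  }
  lab
}

#' Simulate a multichannel tremor-network session
#'
#' All channels share one phase-diffusing tremor oscillator (fundamental
#' plus phase-locked 2f harmonic).  LFP/EEG channels are
#' `gain(state) * coupling * oscillator(t - lag) + sqrt(1 - coupling^2) * noise`
#' with independent 1/f noise per channel.  EMG is modelled as
#' tremor-phase-gated rectified noise bursts (amplitude modulation), so its
#' tremor-band content comes from burst timing rather than a sinusoid.
#' Accelerometer axes carry the movement-level offset (ramped over
#' `ramp_s`), the tremor component, and low-pass Gaussian sensor noise.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_session` with elements `recording`
#'   (a [new_recording()]) and `truth` (list: `channels` data.frame of
#'   per-channel coupling/lag/gains, `schedule`, per-epoch `state` labels,
#'   `move_gate`, and the noiseless smoothed total-acceleration trace).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  dt <- 1 / fs
  t <- (seq_len(n) - 1) * dt

  # shared oscillator: linear phase + Gaussian phase diffusion
  phi <- 2 * pi * config$tremor_freq * t +
    cumsum(stats::rnorm(n, 0, config$phase_jitter * sqrt(dt)))
  osc <- sin(phi) + config$harmonic_rel_amp * sin(2 * phi)
  osc <- osc / stats::sd(osc)

  sched <- config$movement_schedule
  if (is.null(sched))
    sched <- make_movement_schedule(config$duration, config$move_fraction,
                                    config$mean_episode_s)
  gate <- movement_gate(sched, n, fs, config$ramp_s)

  cols <- list()
  roles <- character(0)
  for (ch in config$channels) {
    lagk <- ch$lag_ms * fs / 1000
    gain <- ch$gain_rest + (ch$gain_move - ch$gain_rest) * gate
    if (ch$role == "emg") {
      # rectified noise bursts gated at the (lagged) tremor phase
      phl <- shift_series(phi, lagk)
      m <- (0.5 * (1 + sin(phl)))^2
      burst <- m * abs(stats::rnorm(n))
      burst <- (burst - mean(burst)) / stats::sd(burst)
      sig <- burst
    } else {
      sig <- shift_series(osc, lagk)
    }
    noise <- pink_noise(n, config$noise_exponent)
    cols[[ch$name]] <- gain * ch$coupling * sig +
      sqrt(1 - ch$coupling^2) * noise
    roles[ch$name] <- ch$role
  }

  # accelerometer: movement level + tremor along a fixed body axis
  dir <- c(0.80, 0.52, 0.30); dir <- dir / sqrt(sum(dir^2))
  level <- config$accel_baseline +
    (config$accel_move_level - config$accel_baseline) * gate
  g <- if (config$condition == "harmaline") 1 else 0.25
  tg <- g * (config$accel_tremor_rest +
             (config$accel_tremor_move - config$accel_tremor_rest) * gate)
  trem <- tg * config$accel_coupling *
    shift_series(osc, config$accel_lag_ms * fs / 1000)
  for (i in 1:3) {
    nm <- c("accel_x", "accel_y", "accel_z")[i]
    sens <- if (config$accel_noise_sd > 0)
      config$accel_noise_sd * smooth_total_accel(stats::rnorm(n), 10) * sqrt(10)
    else 0
    cols[[nm]] <- dir[i] * (level + trem) + sens
    roles[nm] <- "accel"
  }

  m <- do.call(cbind, cols)
  rec <- new_recording(m, fs, roles[colnames(m)],
                       condition = config$condition, subject = config$subject)

  a_true <- smooth_total_accel(abs(level), 100)
  truth <- list(
    channels = data.frame(
      name = vapply(config$channels, `[[`, "", "name"),
      role = vapply(config$channels, `[[`, "", "role"),
      coupling = vapply(config$channels, `[[`, 0, "coupling"),
      lag_ms = vapply(config$channels, `[[`, 0, "lag_ms"),
      gain_rest = vapply(config$channels, `[[`, 0, "gain_rest"),
      gain_move = vapply(config$channels, `[[`, 0, "gain_move")),
    schedule = sched,
    state = truth_epoch_labels(sched, config$duration,
                               epoch_s = 2, ramp_s = config$ramp_s),
    move_gate = gate,
    total_accel_noiseless = a_true,
    config = config)
  structure(list(recording = rec, truth = truth), class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat("<sim_session>", x$recording$condition, "condition, seed",
      x$truth$config$seed, "\n")
  print(x$recording)
  invisible(x)
}
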