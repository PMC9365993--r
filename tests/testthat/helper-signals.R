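# shared signal fixtures, built in code

make_tone <- function(freq, n = 2000, rate = 1000, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / rate + phase)
}

# AR(1) series for surrogate fidelity checks
make_ar1 <- function(n, rho = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = rho), n))
}

# band-limited noise (zero-phase filtered white noise)
make_narrowband <- function(n, rate = 1000, band = c(9, 15), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bandpass_tremor(rnorm(n + 2000), rate, band)[1001:(1000 + n)]
}

# two-LFP-channel simulation config for coupling/lag experiments
pair_config <- function(coupling = c(1, 1), lag_ms = c(0, 0),
                        duration = 20, seed = 1, phase_jitter = 3,
                        sampling_rate = 1000, ...) {
  sim_config(
    sampling_rate = sampling_rate, duration = duration,
    phase_jitter = phase_jitter,
    channels = list(
      sim_channel("a", "lfp", coupling[1], lag_ms[1]),
      sim_channel("b", "lfp", coupling[2], lag_ms[2])),
    accel_noise_sd = 0.02, seed = seed, ...)
}
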