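# End-to-end cohort experiment: movement-modulated thalamo-kinematic
# coupling vs state-invariant cerebello-kinematic coupling.  Simulates a
# harmaline cohort, runs the preprocessing/classification/surrogate
# chain, and returns the Wald p-values of the movement effect on
# surrogate-corrected coherence for both pairs.
#
# 2-s epochs at 250 Hz keep the tremor band resolvable on the Welch grid
# (2.25 Hz bins) while holding the surrogate stage to desk scale.
run_state_cohort <- function(rep_seed, n_subjects = 6, duration = 48,
                             rate = 250, n_surr = 99) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sc <- sim_config(
      sampling_rate = rate, duration = duration, condition = "harmaline",
      move_fraction = 0.5, mean_episode_s = 8,
      channels = list(
        sim_channel("lfp_cb", "lfp", 0.8, 0, gain_rest = 1, gain_move = 1),
        sim_channel("lfp_thal", "lfp", 0.7, 5,
                    gain_rest = 0.4, gain_move = 1.2)),
      accel_tremor_rest = 0.6, accel_tremor_move = 0.6,
      subject = paste0("r", s), seed = rep_seed * 211 + s)
    ss <- simulate_session(sc)
    rec <- zscore_collated(list(bandpass_filter(ss$recording, 1, 49)))[[1]]
    es <- reject_artifacts(segment_epochs(rec))
    raw <- ss$recording
    keep <- seq_len(es$n_epochs * es$epoch_len)
    ax <- channel(raw, "accel_x")[keep]
    ay <- channel(raw, "accel_y")[keep]
    az <- channel(raw, "accel_z")[keep]
    a <- smooth_total_accel(total_acceleration(ax, ay, az), 100)
    es$labels <- classify_epochs(a, es$epoch_len, 1.0)
    kin <- accel_pc1(ax, ay, az)
    es$samples <- cbind(es$samples, kin = as.numeric(scale(kin)))
    es$roles <- c(es$roles, kin = "kinematic")
    es$artifact <- cbind(es$artifact, kin = rep(FALSE, es$n_epochs))
    for (p in list(c("lfp_cb", "kin"), c("lfp_thal", "kin"))) {
      an <- pair_surrogate_analysis(es, p, n_surr = n_surr,
                                    seed = rep_seed * 1013 + s)
      rows[[length(rows) + 1L]] <- cbind(subject = s, pair = an$pair,
                                         an$epochs)
    }
  }
  d <- do.call(rbind, rows)
  vapply(c("lfp_cb-kin", "lfp_thal-kin"), function(pr) {
    dd <- d[d$pair == pr & d$label %in% c("rest", "move"), ]
    f <- fit_two_level(
      data.frame(y = dd$C, x = as.integer(dd$label == "move"),
                 subject = dd$subject), "random_intercepts")
    wald_test(f)$p
  }, 0)
}
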