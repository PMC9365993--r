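#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis: cohort size and
#' generator settings (or paths to session CSVs), band edges, thresholds
#' (movement 1 m/s^2, artifact 4 SD, lag-histogram peak probability 0.1),
#' number of surrogates (99) and the master seed.  Can also be read from
#' a YAML file with the same field names; the full parameter set is
#' echoed into the run manifest.
#'
#' @param n_subjects number of simulated subjects.
#' @param duration session length per condition, s.
#' @param sampling_rate Hz.
#' @param band tremor band, Hz.
#' @param movement_threshold m/s^2.
#' @param artifact_sd artifact rejection threshold, SD units.
#' @param n_surr surrogates per epoch.
#' @param criterion surrogate significance rule (`"mean"` or `"rank"`).
#' @param peak_prob_threshold lag-histogram inclusion threshold.
#' @param pairs list of channel pairs for coherence/surrogate analysis;
#'   `NULL` selects each neural/EMG channel against the kinematic series
#'   plus the cerebello-thalamic and thalamo-cortical LFP pairs.
#' @param lag_pairs pairs for the cross-correlation stage (`NULL`: same
#'   as `pairs`).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @param sim_overrides named list of extra arguments passed to
#'   [sim_config()] (e.g. tweaked couplings for sensitivity runs).
#' @return List of class `run_config`.
#' @export
run_config <- function(n_subjects = 4, duration = 120, sampling_rate = 1000,
                       band = c(9, 15), movement_threshold = 1.0,
                       artifact_sd = 4, n_surr = 99,
                       criterion = "mean", peak_prob_threshold = 0.1,
                       pairs = NULL, lag_pairs = NULL, seed = 1L,
                       out_dir = NULL, sim_overrides = list()) {
  if (movement_threshold <= 0 || artifact_sd <= 0 ||
      peak_prob_threshold <= 0)
    stop("thresholds must be positive")
  if (band[1] >= band[2]) stop("band lo must be below band hi")
  if (is.null(pairs))
    pairs <- list(c("lfp_cb", "kin"), c("lfp_thal", "kin"),
                  c("eeg", "kin"), c("emg", "kin"),
                  c("lfp_cb", "lfp_thal"), c("lfp_thal", "eeg"))
  if (is.null(lag_pairs)) lag_pairs <- pairs
  structure(list(n_subjects = n_subjects, duration = duration,
                 sampling_rate = sampling_rate, band = band,
                 movement_threshold = movement_threshold,
                 artifact_sd = artifact_sd, n_surr = n_surr,
                 criterion = criterion,
                 peak_prob_threshold = peak_prob_threshold,
                 pairs = pairs, lag_pairs = lag_pairs,
                 seed = as.integer(seed), out_dir = out_dir,
                 sim_overrides = sim_overrides),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with `run_config` fields.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$pairs)) y$pairs <- lapply(y$pairs, unlist)
  if (!is.null(y$lag_pairs)) y$lag_pairs <- lapply(y$lag_pairs, unlist)
  if (!is.null(y$band)) y$band <- as.numeric(unlist(y$band))
  do.call(run_config, y)
}

# simulate -> preprocess -> classify, for one subject x condition
prepare_session <- function(cfg, subject_id, condition, seed) {
  ov <- cfg$sim_overrides
  sc <- do.call(sim_config, modifyList(list(
    sampling_rate = cfg$sampling_rate, duration = cfg$duration,
    condition = condition, subject = sprintf("rat%02d", subject_id),
    seed = seed), ov))
  simulate_session(sc)
}

process_subject <- function(cfg, subject_id) {
  sessions <- list(
    control = prepare_session(cfg, subject_id, "control",
                              derive_seed(cfg$seed, 2L * subject_id)),
    harmaline = prepare_session(cfg, subject_id, "harmaline",
                                derive_seed(cfg$seed, 2L * subject_id + 1L)))
  recs <- lapply(sessions, function(s)
    bandpass_filter(s$recording, 1, 49))
  recs <- zscore_collated(recs)
  ess <- lapply(names(recs), function(cond) {
    es <- segment_epochs(recs[[cond]], epoch_s = 2)
    es <- reject_artifacts(es, k = cfg$artifact_sd)
    # movement gating and the kinematic series use the raw (unit-bearing)
    # accelerometer axes, not the z-scored copies
    raw <- sessions[[cond]]$recording
    keep <- seq_len(es$n_epochs * es$epoch_len)
    ax <- channel(raw, "accel_x")[keep]
    ay <- channel(raw, "accel_y")[keep]
    az <- channel(raw, "accel_z")[keep]
    a <- smooth_total_accel(total_acceleration(ax, ay, az), 100)
    es$labels <- classify_epochs(a, es$epoch_len, cfg$movement_threshold)
    kin <- accel_pc1(ax, ay, az)
    kin <- (kin - mean(kin)) / stats::sd(kin)
    es$samples <- cbind(es$samples, kin = as.numeric(kin))
    es$roles <- c(es$roles, kin = "kinematic")
    es$artifact <- cbind(es$artifact,
                         kin = apply(abs(matrix(kin, es$epoch_len)) >=
                                       cfg$artifact_sd, 2, any))
    es$total_accel <- a
    es
  })
  names(ess) <- names(recs)
  list(sessions = sessions, epoch_sets = ess)
}

#' Run the full tremor-network analysis pipeline
#'
#' Simulates a cohort (two conditions per subject), then per subject:
#' band-pass filters, z-scores over collated conditions, segments into
#' 2-s epochs, flags artifacts, classifies movement state and builds the
#' kinematic series; then computes per-epoch tremor-band amplitude
#' ratios, surrogate-corrected coherence per channel pair, network
#' area-under-coherence tests, cross-correlation lag histograms
#' (harmaline moving epochs), and the two-level regression models
#' (amplitude ratio ~ condition; corrected coherence ~ movement within
#' harmaline).  All randomness derives from `config$seed`; rerunning
#' with the same config reproduces the outputs.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return List of class `pipeline_result`: `amplitude_ratios`,
#'   `amplitude_models`, `coherence_epochs`, `significant_fractions`,
#'   `auc_table`, `coherence_models`, `lag_summary`, `lag_histograms`,
#'   `epoch_accounting`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  subjects <- stage("simulate+preprocess",
    lapply(seq_len(cfg$n_subjects), function(s) process_subject(cfg, s)))

  # --- amplitude ratios per epoch (EMG / accel-pc1 / LFP channels) -------
  ratio_rows <- stage("spectra", do.call(rbind, lapply(
    seq_along(subjects), function(s) {
      do.call(rbind, lapply(names(subjects[[s]]$epoch_sets), function(cond) {
        es <- subjects[[s]]$epoch_sets[[cond]]
        chans <- intersect(c("lfp_cb", "lfp_thal", "eeg", "emg", "kin"),
                           colnames(es$samples))
        do.call(rbind, lapply(chans, function(ch) {
          r <- epoch_amplitude_ratios(es, ch, cfg$band)
          cbind(subject = s, condition = cond, channel = ch, r)
        }))
      }))
    })))

  # --- surrogate-corrected coherence per pair ----------------------------
  coh <- stage("surrogate", {
    rows <- list(); curves <- list()
    for (s in seq_along(subjects)) for (cond in c("control", "harmaline")) {
      es <- subjects[[s]]$epoch_sets[[cond]]
      for (pi in seq_along(cfg$pairs)) {
        p <- cfg$pairs[[pi]]
        an <- pair_surrogate_analysis(
          es, p, band = cfg$band, n_surr = cfg$n_surr,
          criterion = cfg$criterion,
          seed = derive_seed(cfg$seed, 1000L + 7L * s + 131L * pi +
                               911L * (cond == "harmaline")))
        rows[[length(rows) + 1L]] <-
          cbind(subject = s, condition = cond, pair = an$pair, an$epochs)
        curves[[length(curves) + 1L]] <-
          cbind(subject = s, condition = cond, pair = an$pair, an$curves)
      }
    }
    list(epochs = do.call(rbind, rows), curves = do.call(rbind, curves))
  })

  frac <- stage("surrogate", do.call(rbind, lapply(
    split(coh$epochs, list(coh$epochs$pair, coh$epochs$condition),
          drop = TRUE),
    function(d) cbind(pair = d$pair[1], condition = d$condition[1],
                      fraction_significant(d)))))
  rownames(frac) <- NULL

  auc <- stage("network_auc", {
    cur <- coh$curves[coh$curves$state != "all", ]
    if (cfg$n_subjects >= 2 && nrow(cur)) network_auc_test(cur, cfg$band)
    else NULL
  })

  # --- cross-correlation lags (harmaline, moving epochs) -----------------
  lag_res <- stage("lags", {
    hists <- list()
    for (p in cfg$lag_pairs) for (s in seq_along(subjects)) {
      es <- subjects[[s]]$epoch_sets[["harmaline"]]
      lg <- tryCatch(pair_lags(es, p, band = cfg$band, states = "move"),
                     error = function(e) NULL)
      if (is.null(lg)) next
      hists[[length(hists) + 1L]] <- lag_histogram(
        lg$lag_ms, pair = paste(p, collapse = "-"),
        threshold = cfg$peak_prob_threshold)
    }
    summ <- tryCatch(network_lag_summary(hists), error = function(e) NULL)
    list(histograms = hists, summary = summ)
  })

  # --- two-level models --------------------------------------------------
  amp_models <- stage("models", {
    lapply(stats::setNames(nm = unique(ratio_rows$channel)), function(ch) {
      d <- ratio_rows[ratio_rows$channel == ch & !ratio_rows$artifact &
                        is.finite(ratio_rows$ratio), ]
      d <- data.frame(y = d$ratio, x = as.integer(d$condition == "harmaline"),
                      subject = d$subject)
      fit_condition_contrast(d)
    })
  })

  coh_models <- stage("models", {
    lapply(stats::setNames(nm = unique(coh$epochs$pair)), function(p) {
      d <- coh$epochs[coh$epochs$pair == p &
                        coh$epochs$condition == "harmaline" &
                        coh$epochs$label %in% c("rest", "move"), ]
      if (!nrow(d)) return(NULL)
      d <- data.frame(y = d$C, x = as.integer(d$label == "move"),
                      subject = d$subject)
      fit_condition_contrast(d)
    })
  })

  accounting <- do.call(rbind, lapply(seq_along(subjects), function(s) {
    do.call(rbind, lapply(names(subjects[[s]]$epoch_sets), function(cond) {
      es <- subjects[[s]]$epoch_sets[[cond]]
      flagged <- apply(es$artifact, 1, any)
      data.frame(subject = s, condition = cond, n_total = es$n_epochs,
                 n_flagged = sum(flagged), n_kept = sum(!flagged),
                 n_rest = sum(es$labels == "rest"),
                 n_move = sum(es$labels == "move"),
                 n_unclassified = sum(es$labels == "unclassified"))
    }))
  }))

  manifest <- list(
    package = "tremornet",
    version = as.character(utils::packageVersion("tremornet")),
    seed = cfg$seed, timestamp = format(Sys.time(), tz = "UTC"),
    parameters = cfg[setdiff(names(cfg), c("pairs", "lag_pairs"))],
    pairs = vapply(cfg$pairs, paste, "", collapse = "-"))

  out <- structure(list(
    amplitude_ratios = ratio_rows, amplitude_models = amp_models,
    coherence_epochs = coh$epochs, coherence_curves = coh$curves,
    significant_fractions = frac, auc_table = auc,
    coherence_models = coh_models, lag_summary = lag_res$summary,
    lag_histograms = lag_res$histograms,
    epoch_accounting = accounting, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

# Gaussian chain with Poisson fallback on the level-1 residual diagnostic;
# returns the fit, the Wald test, and the null/RI/RS model comparison.
fit_condition_contrast <- function(d) {
  null <- fit_two_level(d, "null")
  ri <- fit_two_level(d, "random_intercepts")
  cmp_ri <- compare_models(null, ri)
  rs <- tryCatch(fit_two_level(d, "random_slopes"), error = function(e) NULL)
  cmp_rs <- if (!is.null(rs) && cmp_ri$preferred == "random_intercepts") NULL
            else if (!is.null(rs)) compare_models(ri, rs) else NULL
  chosen <- if (!is.null(cmp_rs) && cmp_rs$preferred == "random_slopes") rs
            else ri
  diag <- residual_normality(chosen)
  final <- chosen
  if (!diag$normal && all(d$y >= 0) && any(d$y > 0))
    final <- fit_two_level(d, "poisson_ri")
  list(fit = final, wald = wald_test(final),
       compare_null_ri = cmp_ri, compare_ri_rs = cmp_rs,
       residual_diag = diag,
       effects = report_fixed_effects(final))
}

#' Write pipeline result tables to CSV/JSON
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(result$amplitude_ratios, "amplitude_ratios.csv")
  w(result$coherence_epochs, "coherence_epochs.csv")
  w(result$significant_fractions, "significant_fractions.csv")
  w(result$auc_table, "network_auc.csv")
  w(result$lag_summary, "lag_summary.csv")
  w(result$epoch_accounting, "epoch_accounting.csv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed", x$manifest$seed, "\n")
  cat("  epochs analysed:", sum(x$epoch_accounting$n_total),
      sprintf("(%d flagged)\n", sum(x$epoch_accounting$n_flagged)))
  cat("  pairs:", paste(unique(x$coherence_epochs$pair), collapse = ", "),
      "\n")
  invisible(x)
}
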