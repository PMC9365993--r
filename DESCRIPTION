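Package: tremornet
Title: Tremor-Band Oscillation and Coherence Analysis Across Neural Recording Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for tremor-band (9-15 Hz) oscillations in
    multichannel electrophysiological recordings (EEG, local field
    potentials, EMG and tri-axial accelerometry), as used to study
    harmaline-induced tremor in rodents. Provides movement-state epoch
    classification from accelerometry, per-epoch amplitude spectra and
    tremor-band amplitude ratios, Welch magnitude-squared coherence with an
    iterative amplitude-adjusted Fourier transform (IAAFFT) surrogate null
    and surrogate-corrected coherence, band-limited cross-correlation lag
    histograms, network-level area-under-coherence testing with
    Holm-Bonferroni correction, and two-level (epochs within subjects)
    random-intercept and random-slope regression models.  A synthetic
    multichannel session generator with known ground-truth coupling, lags
    and movement schedules supports end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    glmmTMB,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
SystemRequirements: fftw3
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
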