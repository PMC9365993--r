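#' IAAFFT surrogate series
#'
#' Iterative amplitude-adjusted Fourier transform surrogates.  Starting
#' from a random permutation of the input, each iteration (i) imposes the
#' original Fourier amplitude spectrum on the current phases, then (ii)
#' rank-remaps the result onto the original value multiset.  Iteration
#' stops when the relative spectral mismatch changes by less than `tol`
#' or after `max_iter` iterations; the final step is always the rank
#' remap, so every surrogate's sorted values equal the original's
#' exactly, while the amplitude spectrum matches within the convergence
#' tolerance and phase relationships are randomised.
#'
#' @param x finite numeric series, length >= 4, non-constant.
#' @param n_surr number of surrogates to generate (columns).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the change in relative spectral
#'   mismatch (L2 norm of the |FFT| difference over the L2 norm of the
#'   original |FFT|).
#' @param seed optional RNG seed.
#' @param trace if `TRUE`, attach the per-iteration mismatch history as
#'   attribute `"mismatch"` (iterations x surrogates).
#' @return Numeric matrix `length(x) x n_surr` of surrogate series.
#' @export
iaafft <- function(x, n_surr = 1, max_iter = 100, tol = 1e-4, seed = NULL,
                   trace = FALSE) {
  n <- length(x)
  if (n < 4) stop("series too short for surrogate generation")
  if (!all(is.finite(x))) stop("series must be finite")
  sx <- sort(x)
  if (sx[1] == sx[n]) stop("constant series has undefined Fourier phases")
  if (!is.null(seed)) set.seed(seed)
  res <- iaafft_engine(x, as.integer(n_surr), as.integer(max_iter),
                       tol, isTRUE(trace))
  y <- res$y
  if (trace) attr(y, "mismatch") <- res$mismatch
  y
}

#' Surrogate-corrected band coherence (Eq.-style correction)
#'
#' `C = S * (P - P_surr) / (1 - P_surr)`, where `P` is the observed
#' tremor-band mean coherence, `P_surr` the surrogate-ensemble mean, and
#' `S` the 0/1 significance gate.  `S = 0` forces `C = 0`; with `S = 1`
#' and `P > P_surr`, `C` lies in `(0, 1]`.
#'
#' @param P observed band-mean coherence, in `[0, 1]`.
#' @param P_surr_mean surrogate-ensemble band-mean coherence, in `[0, 1)`.
#' @param S significance indicator, 0 or 1.
#' @return Corrected coherence value.
#' @export
corrected_coherence <- function(P, P_surr_mean, S) {
  if (any(P < 0 | P > 1) || any(P_surr_mean < 0 | P_surr_mean > 1))
    stop("coherence values must lie in [0, 1]")
  if (any(P_surr_mean == 1))
    stop("surrogate mean coherence of 1 leaves the correction undefined")
  if (!all(S %in% c(0, 1))) stop("S must be 0 or 1")
  S * (P - P_surr_mean) / (1 - P_surr_mean)
}

#' Surrogate significance test for one epoch pair
#'
#' Generates `n_surr` IAAFFT surrogates of the second signal (the first
#' held fixed), computes the tremor-band mean coherence of the real pair
#' (`P`) and of each real-vs-surrogate pair, and gates significance:
#' * `criterion = "mean"` (the literal rule): `S = 1` iff
#'   `P > mean(P_surr)`;
#' * `criterion = "rank"` (calibrated): `S = 1` iff the rank-based
#'   p-value `(1 + #\{P_surr >= P\}) / (n_surr + 1)` is at most `alpha`
#'   (with 99 surrogates and `alpha = 0.05`, `P` must exceed all but at
#'   most four surrogates).
#'
#' @param x_epoch,y_epoch equal-length clean epochs; `y_epoch` is the
#'   surrogated channel.
#' @param rate sampling rate, Hz.
#' @param band tremor band, Hz.
#' @param n_surr number of surrogates (default 99).
#' @param criterion significance rule (both p-value styles are reported
#'   regardless; the choice controls `S` and hence `C`).
#' @param alpha level for the rank criterion.
#' @param params Welch parameters ([welch_params()]).
#' @param max_iter,tol IAAFFT controls.
#' @param seed RNG seed for the surrogate draw.
#' @return One-row data.frame: `P`, `P_surr_mean`, `S`, `C`, `p_rank`.
#' @export
epoch_surrogate_test <- function(x_epoch, y_epoch, rate, band = c(9, 15),
                                 n_surr = 99,
                                 criterion = c("mean", "rank"),
                                 alpha = 0.05, params = NULL,
                                 max_iter = 100, tol = 1e-4, seed = NULL) {
  criterion <- match.arg(criterion)
  if (length(x_epoch) != length(y_epoch))
    stop("signals must have equal epoch length")
  if (is.null(params)) params <- welch_params(length(x_epoch))
  P <- band_mean_coherence(epoch_coherence(x_epoch, y_epoch, rate, params),
                           band)
  Ys <- iaafft(y_epoch, n_surr = n_surr, max_iter = max_iter, tol = tol,
               seed = seed)
  cb <- coherence_batch(x_epoch, Ys, rate, params)
  idx <- band_bins(cb$freq, band[1], band[2])
  P_surr <- colMeans(cb$cxy[idx, , drop = FALSE])
  P_surr_mean <- mean(P_surr)
  p_rank <- (1 + sum(P_surr >= P)) / (n_surr + 1)
  S <- if (criterion == "mean") as.integer(P > P_surr_mean)
       else as.integer(p_rank <= alpha)
  data.frame(P = P, P_surr_mean = P_surr_mean, S = S,
             C = corrected_coherence(P, P_surr_mean, S), p_rank = p_rank)
}

# reproducible per-epoch surrogate seed derived from a master seed
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 65521) * 32749 + index * 7919) %% 2147483629L
}

#' Surrogate coherence analysis of a channel pair over an epoch set
#'
#' Applies [epoch_surrogate_test()] to every epoch that is clean
#' (artifact-free) on both channels and non-constant, with fresh
#' per-epoch surrogate seeds derived from `seed` via a counter (so the
#' analysis is reproducible and order-independent).  Also accumulates the
#' mean real and mean surrogate coherence curves per behavioural state
#' for network-level area-under-coherence testing.
#'
#' @param es an epoch set (labels attached, artifacts flagged).
#' @param pair `c(x_channel, y_channel)`; the second channel is
#'   surrogated.
#' @param band tremor band, Hz.
#' @param n_surr surrogates per epoch.
#' @param criterion significance rule, see [epoch_surrogate_test()].
#' @param params Welch parameters.
#' @param seed master seed.
#' @param max_iter,tol IAAFFT controls.
#' @return List: `epochs` (per-epoch data.frame with `epoch`, `label`,
#'   `P`, `P_surr_mean`, `S`, `C`, `p_rank`), `curves`
#'   (data.frame `state`, `freq`, `real`, `surr` with states `"all"`,
#'   `"rest"`, `"move"`), `pair`, `n_clean`.
#' @export
pair_surrogate_analysis <- function(es, pair, band = c(9, 15), n_surr = 99,
                                    criterion = c("mean", "rank"),
                                    params = NULL, seed = 1L,
                                    max_iter = 100, tol = 1e-4) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(es, "epoch_set"), length(pair) == 2)
  if (is.null(params)) params <- welch_params(es$epoch_len)
  mx <- epoch_matrix(es, pair[1])
  my <- epoch_matrix(es, pair[2])
  clean <- clean_epochs(es, pair)
  rows <- list(); curves <- list()
  for (i in seq_len(es$n_epochs)) {
    if (!clean[i]) next
    x <- mx[, i]; y <- my[, i]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # constant: excluded
    P <- band_mean_coherence(epoch_coherence(x, y, es$rate, params), band)
    Ys <- iaafft(y, n_surr = n_surr, max_iter = max_iter, tol = tol,
                 seed = derive_seed(seed, i))
    cb <- coherence_batch(x, Ys, es$rate, params)
    idx <- band_bins(cb$freq, band[1], band[2])
    P_surr <- colMeans(cb$cxy[idx, , drop = FALSE])
    p_rank <- (1 + sum(P_surr >= P)) / (n_surr + 1)
    S <- if (criterion == "mean") as.integer(P > mean(P_surr))
         else as.integer(p_rank <= 0.05)
    rows[[length(rows) + 1L]] <- data.frame(
      epoch = i, label = es$labels[i], P = P, P_surr_mean = mean(P_surr),
      S = S, C = corrected_coherence(P, mean(P_surr), S), p_rank = p_rank)
    curves[[length(curves) + 1L]] <- list(
      label = es$labels[i],
      real = epoch_coherence(x, y, es$rate, params)$cxy,
      surr = rowMeans(cb$cxy))
  }
  if (!length(rows)) stop("no clean epochs for pair ",
                          paste(pair, collapse = "-"))
  freq <- welch_cross(mx[, 1], cbind(my[, 1]), es$rate, params)$freq
  mk_curve <- function(sel, state) {
    if (!any(sel)) return(NULL)
    data.frame(state = state, freq = freq,
               real = rowMeans(vapply(curves[sel], `[[`,
                                      numeric(length(freq)), "real")),
               surr = rowMeans(vapply(curves[sel], `[[`,
                                      numeric(length(freq)), "surr")))
  }
  labs <- vapply(curves, `[[`, "", "label")
  curve_df <- do.call(rbind, c(
    list(mk_curve(rep(TRUE, length(labs)), "all")),
    lapply(c("rest", "move"), function(s) mk_curve(labs == s, s))))
  list(epochs = do.call(rbind, rows), curves = curve_df,
       pair = paste(pair, collapse = "-"), n_clean = length(rows))
}

#' Fraction of epochs with significant coherence
#'
#' @param epochs per-epoch results from [pair_surrogate_analysis()].
#' @return data.frame(group, n, n_sig, fraction) with an `"all"` row and
#'   one row per behavioural state present.
#' @export
fraction_significant <- function(epochs) {
  if (!nrow(epochs)) stop("no epochs supplied")
  groups <- c("all", intersect(c("rest", "move", "unclassified"),
                               unique(epochs$label)))
  do.call(rbind, lapply(groups, function(g) {
    sel <- if (g == "all") rep(TRUE, nrow(epochs)) else epochs$label == g
    data.frame(group = g, n = sum(sel), n_sig = sum(epochs$S[sel]),
               fraction = mean(epochs$S[sel]))
  }))
}

# trapezoidal area under y(freq) restricted to the band
auc_band <- function(freq, y, band = c(9, 15)) {
  idx <- band_bins(freq, band[1], band[2])
  if (length(idx) < 2) stop("need at least two bins inside the band for AUC")
  f <- freq[idx]; v <- y[idx]
  sum(diff(f) * (head(v, -1) + tail(v, -1)) / 2)
}

#' Network-level area-under-coherence test
#'
#' For every pair x condition x state cell, computes per subject the
#' trapezoidal area under the mean real and mean surrogate coherence
#' curves over the tremor band, then a one-tailed paired t-test
#' (real > surrogate) across subjects.  Holm-Bonferroni adjustment is
#' applied within each condition x state family of pair comparisons.
#'
#' @param curves data.frame with columns `subject`, `pair`, `condition`,
#'   `state`, `freq`, `real`, `surr` (per-subject mean coherence curves,
#'   e.g. stacked from [pair_surrogate_analysis()] runs).
#' @param band tremor band, Hz.
#' @return data.frame(pair, condition, state, n, t, p_raw, p_adj).
#' @export
network_auc_test <- function(curves, band = c(9, 15)) {
  need <- c("subject", "pair", "condition", "state", "freq", "real", "surr")
  if (!all(need %in% names(curves))) stop("curves lacks required columns")
  cells <- unique(curves[, c("pair", "condition", "state")])
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- merge(curves, cells[i, , drop = FALSE])
    subjects <- unique(sub$subject)
    if (length(subjects) < 2)
      stop("paired t-test needs at least two subjects")
    d <- vapply(subjects, function(s) {
      ss <- sub[sub$subject == s, ]
      ss <- ss[order(ss$freq), ]
      auc_band(ss$freq, ss$real, band) - auc_band(ss$freq, ss$surr, band)
    }, 0)
    if (stats::sd(d) == 0) {
      # degenerate paired differences: identical curves give t = 0, p = 0.5
      tt <- if (all(d == 0)) list(statistic = 0, p.value = 0.5)
            else list(statistic = sign(mean(d)) * Inf,
                      p.value = if (mean(d) > 0) 0 else 1)
    } else {
      tt <- stats::t.test(d, alternative = "greater")
    }
    data.frame(pair = cells$pair[i], condition = cells$condition[i],
               state = cells$state[i], n = length(subjects),
               t = unname(tt$statistic), p_raw = tt$p.value)
  }))
  res$p_adj <- NA_real_
  for (cond in unique(res$condition)) for (st in unique(res$state)) {
    fam <- res$condition == cond & res$state == st
    res$p_adj[fam] <- stats::p.adjust(res$p_raw[fam], method = "holm")
  }
  res
}
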