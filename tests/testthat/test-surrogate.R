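test_that("surrogates preserve the value multiset exactly", {
  x <- make_ar1(600, seed = 1)
  s <- iaafft(x, n_surr = 5, seed = 2)
  for (j in 1:5) {
    expect_identical(sort(s[, j]), sort(x))
    expect_false(identical(s[, j], x))
  }
  expect_error(iaafft(rep(1, 100)), "constant")
  expect_error(iaafft(c(1, 2)), "short")
  expect_error(iaafft(c(1, NA, 3, 4)), "finite")
})

test_that("spectral mismatch is non-increasing across iterations", {
  x <- make_ar1(1000, seed = 3)
  s <- iaafft(x, n_surr = 4, seed = 4, max_iter = 60, tol = 1e-12,
              trace = TRUE)
  mm <- attr(s, "mismatch")
  expect_gt(nrow(mm), 3)
  # after the first amplitude-adjustment pass the mismatch only improves
  for (j in seq_len(ncol(mm)))
    expect_true(all(diff(mm[-1, j]) <= 1e-9))
})

test_that("surrogates preserve AR(1) autocorrelation within 10%", {
  x <- make_ar1(2000, rho = 0.95, seed = 5)
  s <- iaafft(x, n_surr = 20, seed = 6, max_iter = 100, tol = 1e-9)
  ac_x <- stats::acf(x, 50, plot = FALSE)$acf[-1]
  ac_s <- rowMeans(vapply(1:20, function(j)
    stats::acf(s[, j], 50, plot = FALSE)$acf[-1], numeric(50)))
  # 10% relative agreement where the autocorrelation is meaningfully
  # nonzero; a small absolute band where it has decayed to ~0
  meaningful <- abs(ac_x) >= 0.1
  expect_true(any(meaningful))
  expect_lt(max(abs(ac_s - ac_x)[meaningful] / abs(ac_x)[meaningful]), 0.10)
  expect_lt(max(abs(ac_s - ac_x)), 0.02)
})

test_that("the surrogate correction follows its defining algebra", {
  expect_equal(corrected_coherence(0.5, 0.5, S = 0), 0)
  expect_equal(corrected_coherence(0.8, 0.2, S = 1), 0.75)
  expect_equal(corrected_coherence(1, 0.2, S = 1), 1)
  expect_equal(corrected_coherence(0.1, 0.3, S = 0), 0)   # null retained
  expect_error(corrected_coherence(1.2, 0.5, 1), "\\[0, 1\\]")
  expect_error(corrected_coherence(0.5, 1, 1), "undefined")
  expect_error(corrected_coherence(0.5, 0.4, 2), "S must")
  # range property over random valid inputs with the mean criterion
  set.seed(7)
  for (i in 1:200) {
    P <- runif(1); Ps <- runif(1, 0, 0.99)
    S <- as.integer(P > Ps)
    C <- corrected_coherence(P, Ps, S)
    expect_true(C >= 0 && C <= 1)
  }
})

test_that("the per-epoch surrogate test is seeded and detects coupling", {
  ss <- simulate_session(pair_config(coupling = c(0.9, 0.9), duration = 6,
                                     seed = 8))
  es <- segment_epochs(ss$recording)
  x <- epoch_matrix(es, "a")[, 2]; y <- epoch_matrix(es, "b")[, 2]
  r1 <- epoch_surrogate_test(x, y, 1000, seed = 11)
  r2 <- epoch_surrogate_test(x, y, 1000, seed = 11)
  expect_identical(r1, r2)                     # bit-for-bit reproducible
  expect_equal(r1$S, 1)
  expect_gt(r1$C, 0.2)
  expect_lte(r1$p_rank, 0.05)
  expect_error(epoch_surrogate_test(rnorm(500), rep(1, 500), 250), "constant")
})

test_that("significant fractions rise with coupling", {
  frac <- vapply(c(0, 0.8), function(cpl) {
    ss <- simulate_session(pair_config(coupling = c(0.9, cpl), duration = 40,
                                       seed = 9, sampling_rate = 250))
    es <- segment_epochs(ss$recording)
    es$labels <- rep("move", es$n_epochs)
    an <- pair_surrogate_analysis(es, c("a", "b"), criterion = "rank",
                                  seed = 10)
    fraction_significant(an$epochs)$fraction[1]
  }, 0)
  expect_gt(frac[2], frac[1])
  expect_gt(frac[2], 0.5)
  expect_lt(frac[1], 0.3)
})

test_that("fraction_significant splits totals by state", {
  df <- data.frame(label = c("rest", "rest", "move", "move"),
                   S = c(1, 1, 1, 1))
  f <- fraction_significant(df)
  expect_equal(f$fraction[f$group == "all"], 1)
  df$S <- 0
  expect_equal(fraction_significant(df)$fraction, c(0, 0, 0))
  df$S <- c(1, 0, 0, 0)
  f2 <- fraction_significant(df)
  expect_equal(f2$fraction[f2$group == "rest"], 0.5)
  expect_equal(f2$fraction[f2$group == "move"], 0)
})

test_that("Holm adjustment matches a step-down oracle", {
  p <- c(0.001, 0.011, 0.02, 0.04, 0.3, 0.9)
  # independent step-down implementation
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  expect_equal(stats::p.adjust(p, "holm"), adj)
})

test_that("network AUC test recovers hand-computed paired statistics", {
  freq <- seq(0, 20, 0.5)
  flat <- function(level) rep(level, length(freq))
  mk <- function(subj, d)
    data.frame(subject = subj, pair = "cb-kin", condition = "harmaline",
               state = "move", freq = freq, real = flat(0.3 + d / 6),
               surr = flat(0.3))
  # differences of band AUC across subjects: 1, 2, 3
  curves <- rbind(mk("r1", 1), mk("r2", 2), mk("r3", 3))
  res <- network_auc_test(curves)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$p_raw, stats::pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical real and surrogate curves: t = 0, one-tailed p = 0.5
  curves0 <- curves; curves0$real <- curves0$surr
  res0 <- network_auc_test(curves0)
  expect_equal(res0$t, 0)
  expect_equal(res0$p_raw, 0.5)
  # Holm within a condition x state family
  fam <- do.call(rbind, lapply(c("a-kin", "b-kin", "c-kin"), function(pr) {
    cc <- rbind(mk("r1", 1), mk("r2", 1.5 + runif(1, 0, 0.2)), mk("r3", 3))
    cc$pair <- pr
    cc
  }))
  resf <- network_auc_test(fam)
  expect_equal(resf$p_adj, stats::p.adjust(resf$p_raw, "holm"))
  expect_error(network_auc_test(mk("r1", 1)), "two subjects")
})
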