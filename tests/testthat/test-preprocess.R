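make_rec <- function(m, rate = 1000, roles = NULL) {
  if (is.null(roles)) roles <- rep("lfp", ncol(m))
  new_recording(m, rate, roles)
}

test_that("bipolar referencing subtracts the second channel of each pair", {
  set.seed(1)
  m <- cbind(a = rnorm(500), b = rnorm(500), z = rep(0, 500))
  rec <- make_rec(m)
  out <- bipolar_reference(rec, list(d = c("a", "b")))
  # independent per-sample loop oracle
  oracle <- numeric(500)
  for (i in 1:500) oracle[i] <- m[i, "a"] - m[i, "b"]
  expect_equal(unname(channel(out, "d")), oracle)
  same <- bipolar_reference(rec, list(d = c("a", "a")))
  expect_true(all(channel(same, "d") == 0))
  vs0 <- bipolar_reference(rec, list(d = c("a", "z")))
  expect_equal(unname(channel(vs0, "d")), unname(m[, "a"]))
  expect_error(bipolar_reference(rec, list(d = c("a", "missing"))),
               "no such channel")
})

test_that("band-pass filter passes 11 Hz, rejects 100 Hz, is zero-phase", {
  rec <- make_rec(cbind(t11 = make_tone(11, 4000), t100 = make_tone(100, 4000),
                        zero = rep(0, 4000)))
  out <- bandpass_filter(rec, 1, 49)
  gain <- function(ch, f) {
    sp <- epoch_amplitude_spectrum(channel(out, ch)[1001:3000], 1000)
    sp$amp[which.min(abs(sp$freq - f))] /
      epoch_amplitude_spectrum(channel(rec, ch)[1001:3000], 1000)$amp[
        which.min(abs(sp$freq - f))]
  }
  expect_gt(gain("t11", 11), 0.95)                   # within 5%
  expect_lt(gain("t100", 100), 10^(-20 / 20))        # >= 20 dB down
  expect_true(all(channel(out, "zero") == 0))
  # zero-phase: filtered 11 Hz tone stays aligned with the original
  lag <- max_xcorr_lag(channel(rec, "t11")[1001:3000],
                       channel(out, "t11")[1001:3000], 1000, max_lag_ms = 20)
  expect_equal(lag$lag_ms, 0)
  expect_error(bandpass_filter(rec, 1, 600), "Nyquist")
})

test_that("filtering is linear on 2000-sample inputs", {
  set.seed(2)
  x <- rnorm(2000); y <- rnorm(2000)
  f <- function(v) bandpass_tremor(v, 1000, c(1, 49))
  expect_equal(f(3 * x - 2 * y), 3 * f(x) - 2 * f(y), tolerance = 1e-8)
})

test_that("downsampling keeps every k-th sample and preserves spectra", {
  x <- make_tone(11, 4000, rate = 2000)
  rec <- make_rec(cbind(x = x), rate = 2000)
  out <- downsample(rec, 1000)
  expect_equal(unname(channel(out, "x")), x[seq(1, 4000, by = 2)])
  sp <- epoch_amplitude_spectrum(channel(out, "x"), 1000)
  expect_equal(sp$freq[which.max(sp$amp)], 11)
  expect_identical(downsample(rec, 2000)$samples, rec$samples)  # factor 1
  r30 <- make_rec(cbind(x = make_tone(11, 60000, rate = 30000)), rate = 30000)
  d30 <- downsample(r30, 1000)                       # factor 30
  expect_equal(nrow(d30$samples), 2000)
  expect_equal(d30$rate, 1000)
  expect_error(downsample(make_rec(cbind(x = rnorm(100)), rate = 1500), 1000),
               "integer multiple")
})

test_that("bandpass + downsample is stable under re-application", {
  # analysis-band content sits in the flat passband interior, so a second
  # pass of the identical chain leaves it essentially untouched
  x <- make_narrowband(8000, rate = 2000, band = c(9, 15), seed = 3)
  rec <- make_rec(cbind(x = x), rate = 2000)
  once <- downsample(bandpass_filter(rec, 1, 49), 1000)
  twice <- downsample(bandpass_filter(once, 1, 49), 1000)
  d <- channel(twice, "x") - channel(once, "x")
  expect_lt(sqrt(mean(d^2)), 0.1 * sd(channel(once, "x")))
  expect_gt(cor(channel(twice, "x"), channel(once, "x")), 0.99)
})

test_that("z-scoring is computed over collated conditions", {
  set.seed(4)
  base <- rnorm(3000)
  r1 <- make_rec(cbind(x = base))
  r2 <- make_rec(cbind(x = 2 * rnorm(3000)))        # 2:1 amplitude
  out <- zscore_collated(list(r1, r2))
  collated <- c(channel(out[[1]], "x"), channel(out[[2]], "x"))
  expect_lt(abs(mean(collated)), 1e-10)
  expect_equal(sd(collated), 1, tolerance = 1e-10)
  ratio <- sd(channel(out[[2]], "x")) / sd(channel(out[[1]], "x"))
  expect_equal(ratio, sd(channel(r2, "x")) / sd(channel(r1, "x")),
               tolerance = 1e-12)
  # already-standardised input passes through (same affine map applied)
  z <- (base - mean(base)) / sd(base)
  out2 <- zscore_collated(list(make_rec(cbind(x = z))))
  expect_equal(unname(channel(out2[[1]], "x")), z, tolerance = 1e-10)
  expect_error(zscore_collated(list(make_rec(cbind(x = rep(1, 100))))),
               "zero-variance")
})

test_that("epoch segmentation discards the trailing remainder", {
  mk <- function(sec) make_rec(cbind(x = rnorm(sec * 1000)))
  expect_equal(segment_epochs(mk(10))$n_epochs, 5)
  expect_equal(segment_epochs(mk(10))$epoch_len, 2000)
  expect_equal(segment_epochs(mk(2.9))$n_epochs, 1)
  expect_equal(segment_epochs(mk(0.5))$n_epochs, 0)
})

test_that("artifact flags follow the >= 4 SD rule and keep accounting", {
  set.seed(5)
  x <- rnorm(20000) * 0.5                            # everything within (-4, 4)
  x[x >= 4 | x <= -4] <- 0
  spiked <- c(3, 7)                                  # inject epochs 3 and 7
  x[(spiked[1] - 1) * 2000 + 10] <- 6
  x[(spiked[2] - 1) * 2000 + 500] <- -5
  es <- reject_artifacts(segment_epochs(make_rec(cbind(x = x))))
  expect_equal(which(es$artifact[, "x"]), spiked)
  # boundary: a sample exactly at 4 SD is flagged ("larger than or equal")
  y <- rnorm(2000) * 0.1; y[100] <- 4.0
  es2 <- reject_artifacts(segment_epochs(make_rec(cbind(y = y))))
  expect_true(es2$artifact[1, "y"])
  # epoch accounting: kept + flagged = total
  flagged <- apply(es$artifact, 1, any)
  expect_equal(sum(flagged) + sum(!flagged), es$n_epochs)
  expect_equal(sum(clean_epochs(es, "x")) + sum(flagged), es$n_epochs)
})
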