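# simulate a two-level dataset with known parameters
sim_two_level <- function(n_subj = 12, n_epoch = 500, beta0 = 0.2,
                          beta1 = 0.1, var_u0 = 0.01, var_u1 = 0,
                          var_e = 0.04, seed = 1) {
  set.seed(seed)
  subj <- rep(seq_len(n_subj), each = n_epoch)
  x <- rep(rep(0:1, each = n_epoch / 2), n_subj)
  u0 <- rnorm(n_subj, 0, sqrt(var_u0))[subj]
  u1 <- rnorm(n_subj, 0, sqrt(var_u1))[subj]
  y <- beta0 + u0 + (beta1 + u1) * x + rnorm(length(x), 0, sqrt(var_e))
  data.frame(y = y, x = x, subject = subj)
}

test_that("the balanced null model estimates the grand mean exactly", {
  d <- sim_two_level(n_subj = 6, n_epoch = 40, seed = 2)
  f <- fit_two_level(d, "null")
  expect_equal(f$beta0, mean(d$y), tolerance = 1e-8)
  expect_true(is.na(f$beta1))
  expect_true(f$var_u0 >= 0 && f$var_e >= 0)
})

test_that("with no subject variance the fit collapses onto OLS", {
  d <- sim_two_level(n_subj = 8, n_epoch = 100, var_u0 = 0, seed = 3)
  f <- fit_two_level(d, "random_intercepts")
  ols <- coef(lm(y ~ x, data = d))
  expect_equal(f$beta0, unname(ols[1]), tolerance = 1e-6)
  expect_equal(f$beta1, unname(ols[2]), tolerance = 1e-6)
})

test_that("input contracts are enforced", {
  d <- sim_two_level(n_subj = 4, n_epoch = 20, seed = 4)
  expect_error(fit_two_level(d[d$subject == 1, ], "null"), "two subjects")
  d2 <- d; d2$x <- 2
  expect_error(fit_two_level(d2, "random_intercepts"), "dichotomous")
  d3 <- d; d3$x <- 0
  expect_error(fit_two_level(d3, "random_intercepts"), "singular")
  expect_error(fit_two_level(d[, c("y", "subject")], "random_intercepts"),
               "indicator")
})

test_that("random-intercepts parameters are recovered from simulation", {
  d <- sim_two_level(seed = 5)                  # 12 subjects x 500 epochs
  f <- fit_two_level(d, "random_intercepts")
  expect_lt(abs(f$beta0 - 0.2), 3 * sqrt(0.01 / 12 + 0.04 / 6000))
  expect_lt(abs(f$beta1 - 0.1), 3 * f$se_beta1)
  expect_lt(abs(f$var_e - 0.04), 3 * 0.04 * sqrt(2 / 6000))
  expect_lt(abs(f$var_u0 - 0.01), 3 * 0.01 * sqrt(2 / 11))
  expect_true(f$converged)
})

test_that("slope heterogeneity is recovered and models stay ordered", {
  d <- sim_two_level(var_u1 = 0.02, seed = 6)
  f0 <- fit_two_level(d, "null")
  f1 <- fit_two_level(d, "random_intercepts")
  f2 <- fit_two_level(d, "random_slopes")
  expect_lte(f0$loglik, f1$loglik + 1e-6)       # likelihood monotonicity
  expect_lte(f1$loglik, f2$loglik + 1e-6)
  expect_lt(abs(f2$var_u1 - 0.02), 3 * 0.02 * sqrt(2 / 11) + 0.005)
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$preferred, "random_slopes")
  # covariance matrix of the random effects is positive semi-definite
  expect_gte(f2$var_u0 * f2$var_u1 - f2$cov_u01^2, -1e-10)
})

test_that("Wald statistics follow their closed form", {
  fake <- structure(list(beta1 = 0.2, se_beta1 = 0.1),
                    class = "two_level_fit")
  w <- wald_test(fake)
  expect_equal(w$chi2, 4)
  expect_equal(w$p, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(w$p, 0.0455, tolerance = 1e-3)
  zero <- structure(list(beta1 = 0, se_beta1 = 0.3),
                    class = "two_level_fit")
  expect_equal(wald_test(zero)$chi2, 0)
  expect_equal(wald_test(zero)$p, 1)
  expect_error(wald_test(structure(list(beta1 = 1, se_beta1 = NA),
                                   class = "two_level_fit")), "standard error")
})

test_that("model comparison applies the boundary-corrected reference", {
  a <- structure(list(model_kind = "random_intercepts", loglik = -100,
                      n_obs = 50), class = "two_level_fit")
  b <- structure(list(model_kind = "random_slopes", loglik = -100,
                      n_obs = 50), class = "two_level_fit")
  cmp <- compare_models(a, b)
  expect_equal(cmp$lr, 0)
  expect_equal(cmp$p, 1)                        # both mixture components
  expect_equal(cmp$preferred, "random_intercepts")
  b$loglik <- -97                               # LR = 6
  cmp2 <- compare_models(a, b)
  expect_equal(cmp2$p, 0.5 * pchisq(6, 1, lower.tail = FALSE) +
                 0.5 * pchisq(6, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(compare_models(b, a), "nested")
  nullf <- structure(list(model_kind = "null", loglik = -120, n_obs = 50),
                     class = "two_level_fit")
  expect_equal(compare_models(nullf, a)$p,
               pchisq(40, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("fixed-effect reports give symmetric CIs and log-scale backtransform", {
  d <- sim_two_level(n_subj = 6, n_epoch = 60, seed = 7)
  f <- fit_two_level(d, "random_intercepts")
  eff <- report_fixed_effects(f)
  expect_equal(eff$ci_hi - eff$estimate, eff$estimate - eff$ci_lo,
               tolerance = 1e-10)                        # symmetric CI
  se1 <- (eff$ci_hi[2] - eff$ci_lo[2]) / (2 * 1.96)
  expect_equal(se1, f$se_beta1, tolerance = 1e-10)       # width = 2 * 1.96 SE
  expect_equal(eff$estimate[1], f$beta0)
  # Poisson variant: response-scale columns are exponentiated
  set.seed(8)
  dp <- data.frame(subject = rep(1:6, each = 80),
                   x = rep(rep(0:1, each = 40), 6))
  mu <- exp(-1.93 + 0.3 * dp$x + rnorm(6, 0, 0.2)[dp$subject])
  dp$y <- rpois(nrow(dp), mu)
  fp <- fit_two_level(dp, "poisson_ri")
  ep <- report_fixed_effects(fp)
  expect_equal(ep$resp_estimate, exp(ep$estimate), tolerance = 1e-12)
  expect_equal(ep$estimate[1], -1.93, tolerance = 3 * 0.25)
  expect_equal(ep$resp_ci_lo, exp(ep$ci_lo), tolerance = 1e-12)
  wp <- wald_test(fp)
  expect_true(wp$chi2 > 0 && wp$p < 1)
})

test_that("the Poisson fallback accepts a continuous coherence response", {
  set.seed(9)
  d <- data.frame(subject = rep(1:6, each = 60),
                  x = rep(rep(0:1, each = 30), 6))
  d$y <- exp(-2 + 0.5 * d$x + rnorm(6, 0, 0.3)[d$subject]) *
    exp(rnorm(nrow(d), 0, 0.5))
  expect_no_warning(f <- fit_two_level(d, "poisson_ri"))
  expect_equal(f$model_kind, "poisson_ri")
  expect_gt(f$beta1, 0)
  expect_true(is.finite(f$loglik))
})

test_that("residual diagnostics flag clearly non-Gaussian responses", {
  set.seed(10)
  d <- sim_two_level(n_subj = 6, n_epoch = 100, seed = 10)
  f <- fit_two_level(d, "random_intercepts")
  expect_true(residual_normality(f)$normal)
  dskew <- d
  dskew$y <- exp(3 * d$y)                       # strongly skewed
  fskew <- fit_two_level(dskew, "random_intercepts")
  expect_false(residual_normality(fskew)$normal)
})
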