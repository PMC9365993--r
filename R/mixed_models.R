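#' Fit a two-level regression model
#'
#' Epoch-level responses (level 1) nested in subjects (level 2), fitted by
#' full maximum likelihood (`REML = FALSE`) so nested models can be
#' compared by deviance:
#' * `"null"`: `y ~ 1 + (1 | subject)` -- grand mean plus subject and
#'   epoch variability;
#' * `"random_intercepts"`: adds the dichotomous indicator `x` (e.g.
#'   harmaline vs baseline, or movement vs resting) as a fixed effect;
#' * `"random_slopes"`: additionally lets the indicator's effect vary
#'   across subjects (`y ~ x + (1 + x | subject)`);
#' * `"poisson_ri"`: generalised random-intercepts variant with a log
#'   link and (approximate) Poisson response, used when level-1
#'   residual diagnostics reject normality.
#'
#' @param data data.frame with columns `y` (response), `x` (0/1
#'   indicator; not used by the null model), `subject`.
#' @param model_kind one of `"null"`, `"random_intercepts"`,
#'   `"random_slopes"`, `"poisson_ri"`.
#' @return An object of class `two_level_fit`: extracted fixed effects
#'   (`beta0`, `beta1`, `se_beta1`), variance components (`var_u0`,
#'   `var_u1`, `cov_u01`, `var_e`), `loglik`, `model_kind`, `n_obs`,
#'   `n_subjects`, `converged`, and the underlying fit object.
#' @export
fit_two_level <- function(data, model_kind = c("null", "random_intercepts",
                                               "random_slopes",
                                               "poisson_ri")) {
  model_kind <- match.arg(model_kind)
  if (!all(c("y", "subject") %in% names(data)))
    stop("data must contain columns y and subject")
  data$subject <- factor(data$subject)
  if (nlevels(data$subject) < 2) stop("need at least two subjects")
  if (min(table(data$subject)) < 2) stop("need >= 2 epochs per subject")
  if (model_kind != "null") {
    if (!"x" %in% names(data)) stop("data must contain indicator column x")
    if (!all(data$x %in% c(0, 1))) stop("x must be dichotomous {0, 1}")
    if (length(unique(data$x)) < 2) stop("singular design: x is constant")
  }

  fit <- switch(model_kind,
    null = lme4::lmer(y ~ 1 + (1 | subject), data = data, REML = FALSE),
    random_intercepts =
      lme4::lmer(y ~ x + (1 | subject), data = data, REML = FALSE),
    random_slopes =
      lme4::lmer(y ~ x + (1 + x | subject), data = data, REML = FALSE),
    poisson_ri = withCallingHandlers(
      glmmTMB::glmmTMB(y ~ x + (1 | subject), data = data,
                       family = stats::poisson()),
      warning = function(w) {
        # continuous response under a log link: TMB's Poisson density is the
        # gamma-function extension (a quasi-likelihood), so the non-integer
        # count warning is expected and benign here
        if (grepl("non-integer", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }))

  if (model_kind == "poisson_ri") {
    fe <- glmmTMB::fixef(fit)$cond
    vc <- glmmTMB::VarCorr(fit)$cond$subject
    se <- sqrt(diag(as.matrix(stats::vcov(fit)$cond)))
    var_u0 <- vc[1, 1]; var_u1 <- NA_real_; cov_u01 <- NA_real_
    var_e <- NA_real_
    conv <- fit$fit$convergence == 0
  } else {
    fe <- lme4::fixef(fit)
    vc <- lme4::VarCorr(fit)$subject
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    var_u0 <- vc[1, 1]
    var_u1 <- if (nrow(vc) > 1) vc[2, 2] else NA_real_
    cov_u01 <- if (nrow(vc) > 1) vc[1, 2] else NA_real_
    var_e <- attr(lme4::VarCorr(fit), "sc")^2
    conv <- length(fit@optinfo$conv$lme4) == 0
  }
  structure(list(
    beta0 = unname(fe[1]),
    beta1 = if (length(fe) > 1) unname(fe[2]) else NA_real_,
    se_beta1 = if (length(se) > 1) unname(se[2]) else NA_real_,
    var_u0 = var_u0, var_u1 = var_u1, cov_u01 = cov_u01, var_e = var_e,
    loglik = as.numeric(stats::logLik(fit)),
    model_kind = model_kind, n_obs = nrow(data),
    n_subjects = nlevels(data$subject), converged = conv, fit = fit),
    class = "two_level_fit")
}

#' @export
print.two_level_fit <- function(x, ...) {
  cat(sprintf("<two_level_fit:%s> n=%d epochs, %d subjects, logLik=%.2f%s\n",
              x$model_kind, x$n_obs, x$n_subjects, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  beta0=%.4f", x$beta0))
  if (!is.na(x$beta1))
    cat(sprintf("  beta1=%.4f (SE %.4f)", x$beta1, x$se_beta1))
  cat(sprintf("\n  var_u0=%.5f", x$var_u0))
  if (!is.na(x$var_u1))
    cat(sprintf("  var_u1=%.5f  cov_u01=%.5f", x$var_u1, x$cov_u01))
  if (!is.na(x$var_e)) cat(sprintf("  var_e=%.5f", x$var_e))
  cat("\n")
  invisible(x)
}

#' Wald chi-squared test of the indicator effect
#'
#' `chi2 = (beta1 / SE)^2` referred to a chi-squared distribution with
#' one degree of freedom, testing whether the coefficient for the
#' explanatory indicator differs from the reference level.
#'
#' @param fit a [fit_two_level()] result with an indicator effect.
#' @return List: `chi2`, `df` (= 1), `p`.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "two_level_fit"))
  if (is.na(fit$beta1) || is.na(fit$se_beta1))
    stop("fit has no indicator effect / standard error")
  chi2 <- (fit$beta1 / fit$se_beta1)^2
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Likelihood-ratio comparison of nested two-level models
#'
#' `LR = 2 * (logLik(larger) - logLik(smaller))`.  Comparing the null to
#' the random-intercepts model adds one fixed effect (chi-squared, 1 df).
#' Comparing random intercepts to random slopes adds a variance and a
#' covariance whose null value lies on the boundary of the parameter
#' space, so the reference is the 50:50 mixture of chi-squared(1) and
#' chi-squared(2).
#'
#' @param fit_small,fit_large nested fits on identical data.
#' @param alpha decision level.
#' @return List: `lr`, `p`, `preferred` (model kind), `reference`.
#' @export
compare_models <- function(fit_small, fit_large, alpha = 0.05) {
  stopifnot(inherits(fit_small, "two_level_fit"),
            inherits(fit_large, "two_level_fit"))
  order_kinds <- c(null = 1, random_intercepts = 2, random_slopes = 3)
  ks <- order_kinds[fit_small$model_kind]
  kl <- order_kinds[fit_large$model_kind]
  if (is.na(ks) || is.na(kl) || kl != ks + 1)
    stop("models are not an adjacent nested Gaussian pair")
  if (fit_small$n_obs != fit_large$n_obs)
    stop("models were not fitted to identical data")
  lr <- 2 * (fit_large$loglik - fit_small$loglik)
  lr <- max(lr, 0)
  if (fit_large$model_kind == "random_slopes") {
    p <- 0.5 * stats::pchisq(lr, 1, lower.tail = FALSE) +
         0.5 * stats::pchisq(lr, 2, lower.tail = FALSE)
    ref <- "0.5*chisq(1) + 0.5*chisq(2) (boundary)"
  } else {
    p <- stats::pchisq(lr, 1, lower.tail = FALSE)
    ref <- "chisq(1)"
  }
  list(lr = lr, p = p,
       preferred = if (p < alpha) fit_large$model_kind
                   else fit_small$model_kind,
       reference = ref)
}

#' Fixed-effect estimates with 95% confidence intervals
#'
#' `estimate +/- 1.96 * SE`; for the log-link (Poisson) variant the
#' estimates and interval bounds are also exponentiated onto the
#' response scale.
#'
#' @param fit a converged [fit_two_level()] result.
#' @return data.frame(term, estimate, ci_lo, ci_hi, and for log-link
#'   models resp_estimate, resp_ci_lo, resp_ci_hi).
#' @export
report_fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "two_level_fit"))
  is_pois <- fit$model_kind == "poisson_ri"
  if (is_pois) {
    fe <- glmmTMB::fixef(fit$fit)$cond
    se <- sqrt(diag(as.matrix(stats::vcov(fit$fit)$cond)))
  } else {
    fe <- lme4::fixef(fit$fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit$fit))))
  }
  out <- data.frame(term = names(fe), estimate = unname(fe),
                    ci_lo = unname(fe - 1.96 * se),
                    ci_hi = unname(fe + 1.96 * se))
  if (is_pois) {
    out$resp_estimate <- exp(out$estimate)
    out$resp_ci_lo <- exp(out$ci_lo)
    out$resp_ci_hi <- exp(out$ci_hi)
  }
  out
}

#' Level-1 residual normality diagnostic
#'
#' Shapiro-Wilk check on (a subsample of) the level-1 residuals at
#' `alpha = 0.01`; a rejection triggers the Poisson fallback in the
#' pipeline.
#'
#' @param fit a Gaussian [fit_two_level()] result.
#' @param alpha diagnostic level.
#' @param max_n subsample cap for the Shapiro-Wilk statistic.
#' @return List: `normal` (logical), `p`.
#' @export
residual_normality <- function(fit, alpha = 0.01, max_n = 4000) {
  stopifnot(inherits(fit, "two_level_fit"))
  if (fit$model_kind == "poisson_ri")
    stop("diagnostic applies to Gaussian fits")
  r <- stats::residuals(fit$fit)
  if (length(r) > max_n) {
    set.seed(length(r))  # deterministic subsample
    r <- sample(r, max_n)
  }
  p <- stats::shapiro.test(r)$p.value
  list(normal = p >= alpha, p = p)
}
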