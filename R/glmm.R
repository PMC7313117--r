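# Mixed models of tactic choice and trip descriptors.
#
# Binomial GLMMs (logit link, individual random intercept, optionally one
# random slope) model the probability of a dynamic-foraging trip against
# standardized weather and individual covariates. On top of the fits this
# module computes the quantities of interest for individual repeatability:
# adjusted repeatability with the delta-method observation-level variance,
# Nakagawa marginal/conditional R2, semi-partial effect sizes, conditional
# modes of the individual intercepts with simulation SDs, boundary
# likelihood-ratio tests for variance components, and the single-step
# removal of weak sex-by-weather interactions.

has_random_slope <- function(formula) {
  bars <- lme4::findbars(formula)
  any(vapply(bars, function(b) !identical(deparse(b[[2]]), "1"), logical(1)))
}

#' Fit a binomial mixed model of tactic choice
#'
#' Maximum-likelihood fit through [lme4::glmer()] with a logit link. Random
#' intercept models use adaptive Gauss-Hermite quadrature with `nagq` nodes;
#' models with a random slope fall back to the Laplace approximation (the
#' one-node special case), which is what adaptive quadrature software
#' supports for vector-valued random effects.
#'
#' @param formula A `lme4`-style formula, e.g.
#'   `tactic_df ~ solar + cwc + stage + (1 | individual_id)`.
#' @param data Data frame with the response coded 0/1 and standardized
#'   covariates.
#' @param nagq Number of quadrature nodes for random-intercept models.
#' @param ... Passed to [lme4::glmer()].
#' @return An object of class `forage_glmm`: the underlying fit plus a
#'   coefficient table with Wald 95% CIs, the random-intercept variance
#'   `sigma2_id`, `loglik`, fitted probabilities, the overdispersion ratio
#'   `phi` (Pearson chi-square over residual df) and a `converged` flag.
#' @export
fit_glmm_binomial <- function(formula, data, nagq = 15, ...) {
  id_var <- vapply(lme4::findbars(formula), function(b) deparse(b[[3]]), character(1))
  tab <- table(data[[id_var[1]]])
  if (length(tab) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (has_random_slope(formula)) nagq <- 1
  fit <- lme4::glmer(formula, data = data, family = stats::binomial(),
                     nAGQ = nagq, ...)
  summ <- summary(fit)$coefficients
  beta <- data.frame(term = rownames(summ),
                     estimate = summ[, "Estimate"],
                     se = summ[, "Std. Error"],
                     z = summ[, "z value"],
                     ci_lo = summ[, "Estimate"] - stats::qnorm(0.975) * summ[, "Std. Error"],
                     ci_hi = summ[, "Estimate"] + stats::qnorm(0.975) * summ[, "Std. Error"],
                     row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_id <- vc$vcov[vc$grp == id_var[1] & vc$var1 == "(Intercept)" &
                         is.na(vc$var2)][1]
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  phi <- pearson / stats::df.residual(fit)
  conv <- length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  structure(list(model = fit, formula = formula, beta = beta,
                 sigma2_id = sigma2_id, loglik = as.numeric(stats::logLik(fit)),
                 fitted_p = stats::fitted(fit), phi = phi,
                 id_var = id_var[1], family = "binomial",
                 converged = conv, n_obs = nrow(stats::model.frame(fit))),
            class = "forage_glmm")
}

#' @export
print.forage_glmm <- function(x, ...) {
  cat(sprintf("Binomial GLMM (logit), %d obs, %d individuals\n", x$n_obs,
              length(unique(stats::model.frame(x$model)[[x$id_var]]))))
  cat(sprintf("  sigma2_id = %.3f, logLik = %.2f, phi = %.2f%s\n",
              x$sigma2_id, x$loglik, x$phi,
              if (x$converged) "" else " [convergence flagged]"))
  tab <- x$beta
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fit a Gaussian mixed model of a trip descriptor
#'
#' REML fit through [lmerTest::lmer()]; fixed effects are tested with F tests
#' using Satterthwaite denominator degrees of freedom, and marginal and
#' conditional R2 are computed by variance partitioning.
#'
#' @param formula A `lme4`-style formula with a Gaussian response.
#' @param data Data frame.
#' @param ... Passed to [lmerTest::lmer()].
#' @return A list of class `forage_lmm`: the fit, a coefficient table with
#'   Wald CIs, the ANOVA table, variance components and `r2`
#'   (marginal/conditional).
#' @export
fit_lmm <- function(formula, data, ...) {
  fit <- suppressMessages(lmerTest::lmer(formula, data = data, ...))
  summ <- stats::coef(summary(fit))
  beta <- data.frame(term = rownames(summ),
                     estimate = summ[, "Estimate"],
                     se = summ[, "Std. Error"],
                     ci_lo = summ[, "Estimate"] - stats::qnorm(0.975) * summ[, "Std. Error"],
                     ci_hi = summ[, "Estimate"] + stats::qnorm(0.975) * summ[, "Std. Error"],
                     row.names = NULL)
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_id <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  sigma2_res <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(fit)
  sigma2_f <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
  denom <- sigma2_f + sigma2_id + sigma2_res
  structure(list(model = fit, beta = beta, anova = an,
                 sigma2_id = sigma2_id, sigma2_res = sigma2_res,
                 sigma2_fixed = sigma2_f,
                 r2 = c(marginal = sigma2_f / denom,
                        conditional = (sigma2_f + sigma2_id) / denom),
                 family = "gaussian"),
            class = "forage_lmm")
}

#' Single-step removal of weak sex-by-weather interactions
#'
#' Fits the initial model containing all two-way interactions between sex and
#' each weather variable, removes in a single step every interaction whose
#' Wald 95% CI includes zero, and refits.
#'
#' @param response Name of the 0/1 response column.
#' @param weather_vars Names of the (standardized) weather covariates.
#' @param controls Names of the remaining fixed-effect terms.
#' @param sex_var Name of the standardized sex covariate.
#' @param id_var Name of the individual identifier.
#' @param data Data frame.
#' @param nagq Quadrature nodes for both fits.
#' @return A list with the `initial` and `final` [fit_glmm_binomial()] fits
#'   and the character vector of `dropped` interaction terms.
#' @export
backward_prune_interactions <- function(response, weather_vars, controls,
                                        sex_var, id_var, data, nagq = 15) {
  inter <- paste(sex_var, weather_vars, sep = ":")
  f_init <- stats::reformulate(c(controls, weather_vars, inter,
                                 sprintf("(1 | %s)", id_var)),
                               response = response)
  init <- fit_glmm_binomial(f_init, data, nagq = nagq)
  bt <- init$beta
  is_weak <- function(term) {
    row <- bt[bt$term %in% c(term, sub("(.*):(.*)", "\\2:\\1", term)), ]
    nrow(row) == 1 && row$ci_lo <= 0 && row$ci_hi >= 0
  }
  dropped <- inter[vapply(inter, is_weak, logical(1))]
  kept <- setdiff(inter, dropped)
  f_final <- stats::reformulate(c(controls, weather_vars, kept,
                                  sprintf("(1 | %s)", id_var)),
                                response = response)
  final <- if (length(dropped)) fit_glmm_binomial(f_final, data, nagq = nagq) else init
  list(initial = init, final = final, dropped = dropped)
}

#' Likelihood-ratio test for a random-effect term
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` (clamped at zero for boundary
#' fits), compared to a chi-square with `df` degrees of freedom: 1 when
#' testing a random intercept, 2 when testing a random slope plus its
#' covariance with the intercept. At the boundary of the parameter space this
#' reference distribution is conservative.
#'
#' @param loglik_full,loglik_reduced Log-likelihoods of the nested fits.
#' @param df Difference in the number of variance-covariance parameters.
#' @return A list with `chi2`, `df` and `p`.
#' @export
lrt_random_effect <- function(loglik_full, loglik_reduced, df = 1) {
  chi2 <- 2 * (loglik_full - loglik_reduced)
  if (chi2 < -1e-4) warning("full model has lower log-likelihood than reduced; refit advised")
  chi2 <- max(0, chi2)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Adjusted repeatability of tactic choice
#'
#' The proportion of variance attributable to individual identity after
#' accounting for the fixed effects, on the observation (latent logit) scale:
#' `R_adj = sigma2_id / (sigma2_id + sigma2_dist)`, where the
#' observation-level variance `sigma2_dist = 1 / (p (1 - p))` is obtained by
#' the delta method, evaluated by default at the mean fitted probability.
#' Significance of the individual effect is assessed by a likelihood-ratio
#' test against the fixed-effects-only logistic regression.
#'
#' @param fit A [fit_glmm_binomial()] random-intercept fit.
#' @param p_mode How to evaluate the delta-method probability:
#'   `"fitted_mean"` (mean of the fitted probabilities) or `"intercept"`
#'   (inverse-logit of the intercept).
#' @param lrt Set `FALSE` to skip the likelihood-ratio test (the LRT slots
#'   are then `NA`).
#' @return A list of class `repeatability_estimate`: `r_adj`, `sigma2_id`,
#'   `sigma2_dist`, and the LRT (`lrt_chi2`, `lrt_df`, `p`).
#' @export
adjusted_repeatability <- function(fit, p_mode = c("fitted_mean", "intercept"),
                                   lrt = TRUE) {
  p_mode <- match.arg(p_mode)
  stopifnot(inherits(fit, "forage_glmm"))
  pbar <- switch(p_mode,
                 fitted_mean = mean(fit$fitted_p),
                 intercept = stats::plogis(fit$beta$estimate[fit$beta$term == "(Intercept)"]))
  if (pbar <= 0 || pbar >= 1) stop("mean fitted probability at 0 or 1: R_adj undefined", call. = FALSE)
  sigma2_dist <- 1 / (pbar * (1 - pbar))
  r_adj <- fit$sigma2_id / (fit$sigma2_id + sigma2_dist)
  lr <- list(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
  if (lrt) {
    mf <- stats::model.frame(fit$model)
    form_fixed <- lme4::nobars(fit$formula)
    glm_fit <- stats::glm(form_fixed, data = mf, family = stats::binomial())
    lr <- lrt_random_effect(fit$loglik, as.numeric(stats::logLik(glm_fit)), df = 1)
  }
  structure(list(r_adj = r_adj, sigma2_id = fit$sigma2_id,
                 sigma2_dist = sigma2_dist, pbar = pbar,
                 lrt_chi2 = lr$chi2, lrt_df = lr$df, p = lr$p),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Adjusted repeatability R_adj = %.3f (sigma2_id = %.3f, sigma2_dist = %.3f)\n",
              x$r_adj, x$sigma2_id, x$sigma2_dist))
  cat(sprintf("  LRT: chi2 = %.2f, df = %d, p = %.3g\n", x$lrt_chi2, x$lrt_df, x$p))
  invisible(x)
}

#' Marginal and conditional R2 by variance partitioning
#'
#' `R2_marginal = sigma2_f / (sigma2_f + sigma2_id + sigma2_resid)` and
#' `R2_conditional = (sigma2_f + sigma2_id) / (same denominator)`, with
#' `sigma2_f` the variance of the fixed-effect linear predictor. For binomial
#' fits the residual slot is the delta-method observation-level variance.
#'
#' @param fit A [fit_glmm_binomial()] or [fit_lmm()] fit.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
r2_nakagawa <- function(fit) {
  if (inherits(fit, "forage_lmm")) return(fit$r2)
  stopifnot(inherits(fit, "forage_glmm"))
  X <- stats::model.matrix(fit$model)
  sigma2_f <- stats::var(as.numeric(X %*% lme4::fixef(fit$model)))
  pbar <- mean(fit$fitted_p)
  sigma2_dist <- 1 / (pbar * (1 - pbar))
  denom <- sigma2_f + fit$sigma2_id + sigma2_dist
  c(marginal = sigma2_f / denom,
    conditional = (sigma2_f + fit$sigma2_id) / denom)
}

#' Semi-partial effect size of a covariate
#'
#' Absolute Pearson-r analogue obtained from the variance partition:
#' `r = sqrt(beta_j^2 var(x_j) / (sigma2_f + sigma2_id + sigma2_dist))`. For
#' a single standardized covariate this reduces to the square root of the
#' marginal R2.
#'
#' @param fit A [fit_glmm_binomial()] fit.
#' @param term Name of the fixed-effect term.
#' @return Non-negative effect size `r`.
#' @export
effect_size_r <- function(fit, term) {
  stopifnot(inherits(fit, "forage_glmm"))
  X <- stats::model.matrix(fit$model)
  if (!term %in% colnames(X)) stop("term not in the model: ", term, call. = FALSE)
  beta <- lme4::fixef(fit$model)
  sigma2_f <- stats::var(as.numeric(X %*% beta))
  pbar <- mean(fit$fitted_p)
  sigma2_dist <- 1 / (pbar * (1 - pbar))
  sqrt(beta[term]^2 * stats::var(X[, term]) /
         (sigma2_f + fit$sigma2_id + sigma2_dist))[[1]]
}

#' Conditional modes of the individual intercepts with simulation SDs
#'
#' The conditional mode of each individual's latent deviation evaluated at
#' the parameter estimates (the GLMM analogue of the BLUP) is the
#' individual's tendency to perform dynamic-foraging trips. Uncertainty is
#' expressed as the SD of `n_sim` draws from the Gaussian approximation to
#' each conditional distribution at its mode.
#'
#' @param fit A [fit_glmm_binomial()] random-intercept fit.
#' @param n_sim Number of simulation draws per individual.
#' @param seed Integer seed for the draws.
#' @return Data frame with `individual`, `mode` (logit scale) and `sd`.
#' @export
conditional_modes <- function(fit, n_sim = 10000, seed = 1) {
  stopifnot(inherits(fit, "forage_glmm"))
  re <- lme4::ranef(fit$model, condVar = TRUE)[[fit$id_var]]
  modes <- re[["(Intercept)"]]
  pv <- attr(re, "postVar")
  sds <- sqrt(pv[1, 1, ])
  if (fit$sigma2_id <= 1e-12) {
    modes <- rep(0, length(modes))
    sds <- rep(0, length(sds))
  }
  sim_sd <- with_rng(seed, vapply(seq_along(modes), function(i) {
    if (sds[i] == 0) return(0)
    stats::sd(stats::rnorm(n_sim, modes[i], sds[i]))
  }, numeric(1)))
  data.frame(individual = rownames(re), mode = modes, sd = sim_sd,
             row.names = NULL)
}

#' Behavioural reaction norm test for one weather variable
#'
#' Fits a binomial GLMM with an individual-level random slope for a single
#' weather variable (plus the random intercept and their covariance) and
#' tests the slope by a 2-df likelihood-ratio test against the
#' random-intercept-only model. One weather variable at a time keeps the
#' random-effects structure identifiable.
#'
#' @param response Name of the 0/1 response column.
#' @param weather_var Name of the weather covariate receiving the slope.
#' @param controls Names of the other fixed-effect terms.
#' @param id_var Name of the individual identifier.
#' @param data Data frame.
#' @return A list with the `full` and `reduced` fits, `sigma2_slope` and the
#'   `lrt` result.
#' @export
random_slope_model <- function(response, weather_var, controls, id_var, data) {
  f_full <- stats::reformulate(c(controls, weather_var,
                                 sprintf("(1 + %s | %s)", weather_var, id_var)),
                               response = response)
  f_red <- stats::reformulate(c(controls, weather_var,
                                sprintf("(1 | %s)", id_var)),
                              response = response)
  full <- fit_glmm_binomial(f_full, data, nagq = 1)
  reduced <- fit_glmm_binomial(f_red, data, nagq = 1)
  vc <- as.data.frame(lme4::VarCorr(full$model))
  sigma2_slope <- vc$vcov[vc$var1 == weather_var & is.na(vc$var2)][1]
  lrt <- lrt_random_effect(full$loglik, reduced$loglik, df = 2)
  list(full = full, reduced = reduced, sigma2_slope = sigma2_slope, lrt = lrt)
}
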