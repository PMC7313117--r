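# statistical layer: binomial GLMMs of tactic choice, repeatability and the
# quantities derived from the fits

sim_glmm_data <- function(n_id = 25, n_per = 20, beta = c(x1 = 0.8, x2 = -0.4),
                          beta0 = 0.2, sigma_id = 0.7, seed = 1) {
  simulate_tactic_data(n_individuals = n_id, trips_per_individual = n_per,
                       beta = beta, beta0 = beta0, sigma_id = sigma_id,
                       stage_var = "", seed = seed)
}

test_that("with no individual variance the GLMM collapses onto the GLM", {
  d <- sim_glmm_data(n_id = 20, n_per = 25, sigma_id = 0, seed = 3)
  fit <- fit_glmm_binomial(tactic_df ~ x1 + x2 + (1 | individual_id), d,
                           nagq = 15)
  glm_fit <- stats::glm(tactic_df ~ x1 + x2, data = d, family = binomial())
  expect_lt(fit$sigma2_id, 1e-4)
  expect_equal(fit$beta$estimate, unname(coef(glm_fit)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(glm_fit)), tolerance = 1e-6)
})

test_that("overdispersion ratio is near one for well-specified data", {
  d <- sim_glmm_data(seed = 5)
  fit <- fit_glmm_binomial(tactic_df ~ x1 + x2 + (1 | individual_id), d)
  expect_gt(fit$phi, 0.8)
  expect_lt(fit$phi, 1.2)
  expect_true(fit$converged)
  expect_error(fit_glmm_binomial(tactic_df ~ x1 + (1 | individual_id),
                                 d[d$individual_id == "id001", ]),
               "at least 2 individuals")
})

test_that("Gaussian LMM reduces to OLS without individual variance and to the
           ANOVA estimator under balance", {
  withr::with_seed(7, {
    n_id <- 12; n_per <- 8
    id <- rep(sprintf("i%02d", 1:n_id), each = n_per)
    x <- rnorm(n_id * n_per)
    y0 <- 1 + 0.5 * x + rnorm(n_id * n_per)
    d0 <- data.frame(individual_id = id, x = x, y = y0)
  })
  f0 <- suppressMessages(fit_lmm(y ~ x + (1 | individual_id), d0))
  ols <- lm(y ~ x, data = d0)
  if (f0$sigma2_id < 1e-8) {
    expect_equal(f0$beta$estimate, unname(coef(ols)), tolerance = 1e-6)
  }
  # balanced one-way design: REML variance equals the method-of-moments one
  withr::with_seed(8, {
    b <- rnorm(12, 0, 1.5)
    d1 <- data.frame(individual_id = rep(sprintf("i%02d", 1:12), each = 8),
                     y = rep(b, each = 8) + rnorm(96))
  })
  f1 <- fit_lmm(y ~ 1 + (1 | individual_id), d1)
  an <- anova(lm(y ~ individual_id, data = d1))
  msb <- an[["Mean Sq"]][1]; msw <- an[["Mean Sq"]][2]
  expect_equal(f1$sigma2_id, (msb - msw) / 8, tolerance = 1e-6)
  expect_equal(f1$sigma2_res, msw, tolerance = 1e-6)
  expect_equal(unname(f1$r2["conditional"] >= f1$r2["marginal"]), TRUE)
})

test_that("orthogonal covariates leave the other estimates unchanged", {
  withr::with_seed(9, {
    n <- 120
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    x2 <- residuals(lm(x2 ~ x1))          # exactly orthogonal, mean 0
    d <- data.frame(individual_id = rep(sprintf("i%02d", 1:12), each = 10),
                    x1 = x1, x2 = x2,
                    y = 2 + 0.7 * x1 + rnorm(n, 0, 0.5))
  })
  fa <- fit_lmm(y ~ x1 + (1 | individual_id), d)
  fb <- fit_lmm(y ~ x1 + x2 + (1 | individual_id), d)
  est <- function(f, term) f$beta$estimate[f$beta$term == term]
  expect_equal(est(fb, "x1"), est(fa, "x1"), tolerance = 1e-2)
})

test_that("likelihood-ratio helper handles identical and boundary fits", {
  l <- lrt_random_effect(-100, -100, df = 1)
  expect_equal(l$chi2, 0)
  expect_equal(l$p, 1)
  expect_warning(lrt_random_effect(-100.1, -100, df = 1), "lower log-likelihood")
  l2 <- lrt_random_effect(-95, -100, df = 2)
  expect_equal(l2$chi2, 10)
  expect_equal(l2$p, pchisq(10, 2, lower.tail = FALSE))
})

test_that("adjusted repeatability follows the delta-method formula", {
  d <- sim_glmm_data(n_id = 30, n_per = 20, sigma_id = 0.8, seed = 11)
  fit <- fit_glmm_binomial(tactic_df ~ x1 + x2 + (1 | individual_id), d)
  rpt <- adjusted_repeatability(fit)
  pbar <- mean(fit$fitted_p)
  expect_equal(rpt$sigma2_dist, 1 / (pbar * (1 - pbar)))
  expect_equal(rpt$r_adj,
               fit$sigma2_id / (fit$sigma2_id + rpt$sigma2_dist))
  expect_gt(rpt$lrt_chi2, 0)
  expect_lt(rpt$p, 0.05)
  # no individual variance: repeatability zero
  d0 <- sim_glmm_data(n_id = 20, n_per = 25, sigma_id = 0, seed = 3)
  fit0 <- fit_glmm_binomial(tactic_df ~ x1 + x2 + (1 | individual_id), d0)
  rpt0 <- adjusted_repeatability(fit0, lrt = FALSE)
  expect_lt(rpt0$r_adj, 0.01)
  # direct substitution: sigma2 = pi^2/3 at pbar = 0.5
  fake <- structure(list(sigma2_id = pi^2 / 3, fitted_p = 0.5,
                         beta = data.frame(term = "(Intercept)", estimate = 0),
                         loglik = NA, model = NULL, formula = NULL),
                    class = "forage_glmm")
  rf <- adjusted_repeatability(fake, lrt = FALSE)
  expect_equal(rf$r_adj, (pi^2 / 3) / (pi^2 / 3 + 4), tolerance = 1e-12)
  expect_equal(rf$r_adj, 0.451, tolerance = 1e-3)
})

test_that("variance-partition R2 and effect sizes behave algebraically", {
  d <- sim_glmm_data(n_id = 30, n_per = 20, beta = c(x1 = 0.9, x2 = 0),
                     sigma_id = 0.6, seed = 13)
  fit <- fit_glmm_binomial(tactic_df ~ x1 + x2 + (1 | individual_id), d)
  r2 <- r2_nakagawa(fit)
  expect_gt(r2["conditional"], r2["marginal"])
  expect_true(all(r2 >= 0 & r2 <= 1))
  # single-covariate model: effect size equals sqrt of marginal R2
  fit1 <- fit_glmm_binomial(tactic_df ~ x1 + (1 | individual_id), d)
  r1 <- effect_size_r(fit1, "x1")
  expect_equal(r1, sqrt(unname(r2_nakagawa(fit1)["marginal"])),
               tolerance = 1e-9)
  # effect size orders with the coefficient magnitude
  expect_gt(effect_size_r(fit, "x1"), effect_size_r(fit, "x2"))
  expect_error(effect_size_r(fit, "nope"), "not in the model")
})

test_that("conditional modes match a direct optimizer and shrink correctly", {
  d <- sim_glmm_data(n_id = 12, n_per = 15, beta = c(x1 = 0.5),
                     sigma_id = 0.9, seed = 15)
  fit <- fit_glmm_binomial(tactic_df ~ x1 + (1 | individual_id), d, nagq = 15)
  cm <- conditional_modes(fit, n_sim = 2000, seed = 2)
  expect_equal(nrow(cm), 12)
  # oracle: maximize each individual's conditional log-density directly
  beta <- lme4::fixef(fit$model)
  s2 <- fit$sigma2_id
  for (i in c(1, 5, 12)) {
    idi <- sprintf("id%03d", i)
    di <- d[d$individual_id == idi, ]
    eta0 <- beta[1] + beta[2] * di$x1
    obj <- function(b) {
      sum(stats::dbinom(di$tactic_df, 1, stats::plogis(eta0 + b), log = TRUE)) +
        stats::dnorm(b, 0, sqrt(s2), log = TRUE)
    }
    opt <- stats::optimize(obj, c(-4, 4), maximum = TRUE)$maximum
    expect_equal(cm$mode[cm$individual == idi], opt, tolerance = 1e-3)
  }
  # individuals doing more DF than predicted sit above zero
  pred <- tapply(stats::plogis(beta[1] + beta[2] * d$x1), d$individual_id, mean)
  obs <- tapply(d$tactic_df, d$individual_id, mean)
  excess <- (obs - pred)[cm$individual]
  expect_true(all(sign(cm$mode[abs(excess) > 0.1]) ==
                    sign(excess[abs(excess) > 0.1])))
  expect_true(all(cm$sd > 0))
  # boundary fit: all modes and SDs collapse to zero
  d0 <- sim_glmm_data(n_id = 20, n_per = 25, sigma_id = 0, seed = 3)
  fit0 <- fit_glmm_binomial(tactic_df ~ x1 + x2 + (1 | individual_id), d0)
  cm0 <- conditional_modes(fit0, n_sim = 100, seed = 1)
  expect_true(all(cm0$mode == 0))
})

test_that("single-step pruning removes exactly the weak interactions", {
  # null interactions: all four dropped
  withr::with_seed(17, {
    n_id <- 30; n_per <- 20; n <- n_id * n_per
    d <- data.frame(individual_id = rep(sprintf("id%03d", 1:n_id), each = n_per),
                    solar = rnorm(n), rain = rnorm(n), twc = rnorm(n),
                    cwc = rnorm(n), sex = zscore(rbinom(n, 1, 0.4)))
    b <- rep(rnorm(n_id, 0, 0.5), each = n_per)
    d$tactic_df <- rbinom(n, 1, plogis(0.3 + 0.6 * d$solar + b))
  })
  pr <- backward_prune_interactions(
    response = "tactic_df", weather_vars = c("solar", "rain", "twc", "cwc"),
    controls = character(0), sex_var = "sex", id_var = "individual_id",
    data = d, nagq = 1)
  expect_length(pr$dropped, 4)
  expect_false(any(grepl(":", pr$final$beta$term)))

  # a strong true interaction survives the single step
  withr::with_seed(18, {
    d2 <- d
    d2$tactic_df <- rbinom(nrow(d2), 1,
                           plogis(0.3 + 0.6 * d2$solar + 1.2 * d2$sex * d2$solar +
                                    rep(rnorm(n_id, 0, 0.5), each = n_per)))
  })
  pr2 <- backward_prune_interactions(
    response = "tactic_df", weather_vars = c("solar", "rain", "twc", "cwc"),
    controls = character(0), sex_var = "sex", id_var = "individual_id",
    data = d2, nagq = 1)
  expect_true(any(grepl("solar", pr2$dropped) == FALSE) &&
                !("sex:solar" %in% pr2$dropped))
  expect_true(any(grepl(":", pr2$final$beta$term)))
})

test_that("random-slope reaction-norm test runs and is bounded", {
  d <- sim_glmm_data(n_id = 20, n_per = 15, beta = c(x1 = 0.5),
                     sigma_id = 0.6, seed = 19)
  rs <- suppressWarnings(random_slope_model("tactic_df", "x1", character(0),
                                            "individual_id", d))
  expect_gte(rs$lrt$chi2, 0)
  expect_equal(rs$lrt$df, 2)
  expect_true(rs$lrt$p >= 0 && rs$lrt$p <= 1)
})
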