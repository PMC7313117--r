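test_that("scaled mass index corrects mass by the SMA allometry", {
  # equal keels: condition is mass itself
  expect_equal(as.numeric(scaled_mass_index(c(110, 120, 130), rep(32, 3))),
               c(110, 120, 130))
  # exact power law: every bird has identical condition
  keel <- c(29, 31, 32, 33.5, 35)
  mass <- 0.004 * keel^3
  smi <- scaled_mass_index(mass, keel)
  expect_equal(diff(range(smi)), 0, tolerance = 1e-9)
  expect_equal(attr(smi, "b"), 3, tolerance = 1e-9)
  # independent SMA oracle: slope = sign(r) * sd(ln M) / sd(ln L)
  withr::with_seed(21, {
    keel2 <- rnorm(5, 32, 1.5)
    mass2 <- 0.004 * keel2^2.6 * exp(rnorm(5, 0, 0.05))
  })
  b_oracle <- sign(cor(log(mass2), log(keel2))) * sd(log(mass2)) / sd(log(keel2))
  smi2 <- scaled_mass_index(mass2, keel2)
  expect_equal(attr(smi2, "b"), b_oracle, tolerance = 1e-9)
  expect_equal(as.numeric(smi2), mass2 * (mean(keel2) / keel2)^b_oracle,
               tolerance = 1e-9)
  expect_error(scaled_mass_index(c(1, 2), c(3, 4)), "length >= 3")
  expect_error(scaled_mass_index(c(-1, 2, 3), c(3, 4, 5)), "positive")
})

test_that("daily body mass increase matches the hand-worked broods", {
  # two nestlings each doubling over 7 days
  expect_equal(dbmi(c(30, 40), c(60, 80), 7), 1 / 7)
  # single nestling 40 -> 44 g over 8 days
  expect_equal(dbmi(40, 44, 8), 0.0125)
  # one death before the second measurement: average over the 2 survivors
  m1 <- c(35, 40, 45); m2 <- c(42, NA, 49.5)
  by_hand <- mean(c((42 - 35) / 35, (49.5 - 45) / 45) / 7)
  expect_equal(dbmi(m1, m2, 7), by_hand)
  # no survivors: undefined
  expect_true(is.na(dbmi(c(30, 35), c(NA, NA), 7)))
  # scale invariance
  expect_equal(dbmi(m1 * 3.2, m2 * 3.2, 7), dbmi(m1, m2, 7), tolerance = 1e-12)
})

test_that("residualizing strips nuisance structure exactly", {
  withr::with_seed(22, {
    x <- rnorm(40)
    z <- factor(sample(c("a", "b", "c"), 40, replace = TRUE))
    y <- 2 + 0.5 * x + as.numeric(z) + rnorm(40)
  })
  r <- residualize(y, data.frame(x = x, z = z))
  expect_equal(mean(r), 0, tolerance = 1e-10)
  expect_lt(abs(cor(r, x)), 1e-10)
  # already centred and orthogonal response passes through
  y2 <- residuals(lm(y ~ x + z))
  expect_equal(residualize(y2, data.frame(x = x, z = z)), unname(y2),
               tolerance = 1e-10)
  expect_error(residualize(y, data.frame(x = x, x2 = 2 * x)), "rank-deficient")
})

test_that("feeding frequency counts trips per device-on hour", {
  expect_equal(feeding_frequency(12, 16, rep("nestling_rearing", 12)), 0.75)
  expect_true(is.na(feeding_frequency(12, 16, rep("incubation", 12))))
  expect_equal(feeding_frequency(24, 32, c("incubation", "nestling_rearing")),
               feeding_frequency(12, 16, "nestling_rearing"))
  expect_error(feeding_frequency(3, 0, "nestling_rearing"), "positive")
})

test_that("weighted correlation generalizes Pearson", {
  withr::with_seed(23, {
    x <- rnorm(25); y <- 0.6 * x + rnorm(25)
  })
  expect_equal(weighted_corr(x, y, rep(2.5, 25)), cor(x, y), tolerance = 1e-12)
  expect_equal(weighted_corr(x, 2 * x + 1, runif(25, 0.5, 3)), 1,
               tolerance = 1e-12)
  # 4-point direct-formula oracle
  x4 <- c(1, 2, 4, 7); y4 <- c(2, 1, 5, 9); w4 <- c(1, 2, 0.5, 3)
  xm <- sum(w4 * x4) / sum(w4); ym <- sum(w4 * y4) / sum(w4)
  r_oracle <- sum(w4 * (x4 - xm) * (y4 - ym)) /
    sqrt(sum(w4 * (x4 - xm)^2) * sum(w4 * (y4 - ym)^2))
  expect_equal(weighted_corr(x4, y4, w4), r_oracle, tolerance = 1e-12)
  expect_error(weighted_corr(x4, y4, c(1, -1, 1, 1)), "positive")
  expect_warning(weighted_corr(rep(1, 4), y4, w4), "zero weighted variance")
})

test_that("randomization test enumerates exactly for small n", {
  x <- c(0.3, -1.2, 0.5, 2.1, -0.4)
  w <- c(1, 2, 1.5, 0.7, 1.1)
  rt <- randomization_test(x, x, w)
  expect_equal(rt$method, "exhaustive")
  # independent enumeration oracle over all 120 permutations
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  r_obs <- weighted_corr(x, x, w)
  rs <- apply(perms, 1, function(p) weighted_corr(x, x[p], w))
  expect_equal(rt$p, mean(abs(rs) >= abs(r_obs) - 1e-12))
  expect_gt(rt$p, 0)
  expect_lte(rt$p, 1)
  # Monte-Carlo mode is deterministic given the seed and add-one smoothed
  withr::with_seed(24, { xx <- rnorm(12); yy <- rnorm(12) })
  m1 <- randomization_test(xx, yy, B = 499, seed = 9)
  m2 <- randomization_test(xx, yy, B = 499, seed = 9)
  expect_equal(m1$p, m2$p)
  expect_equal(m1$method, "monte_carlo")
  expect_gt(m1$p, 0)
})

test_that("tendency correlates recover generator couplings", {
  make_adults <- function(coupling, seed) {
    withr::with_seed(seed, {
      n <- 24
      tendency <- rnorm(n, 0, 0.8)
      data.frame(individual_id = sprintf("a%02d", 1:n),
                 tendency = tendency,
                 tendency_sd = runif(n, 0.3, 0.6),
                 sex = rbinom(n, 1, 0.4),
                 year = sample(2016:2018, n, replace = TRUE),
                 smi = rnorm(n, 120, 6),
                 breeding_success = rbinom(n, 1, 0.8),
                 dbmi = 0.014 + coupling * tendency + rnorm(n, 0, 0.004),
                 brood_size = sample(1:4, n, replace = TRUE),
                 feeding_freq = runif(n, 0.3, 1),
                 device_load = runif(n, 0.038, 0.055))
    })
  }
  pos <- vapply(1:10, function(s) {
    tab <- correlate_tendency(make_adults(0.006, s), B = 199, seed = s)
    tab$r_w[tab$target == "residual_dbmi"]
  }, numeric(1))
  expect_gte(mean(pos > 0), 0.9)
  # equal weights: identical to the unweighted Pearson on the residuals
  ad <- make_adults(0, 3)
  ad$tendency_sd <- 1
  tab <- correlate_tendency(ad, B = 199, seed = 1)
  res <- residualize(ad$dbmi, data.frame(year = factor(ad$year),
                                         brood_size = ad$brood_size))
  expect_equal(tab$r_w[tab$target == "residual_dbmi"], cor(ad$tendency, res),
               tolerance = 1e-12)
})
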