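# Condition and fitness proxies and their association with the individual
# tendency to perform dynamic-foraging trips: scaled mass index (SMI), daily
# body mass increase of nestlings (DBMI), feeding frequency, and weighted
# correlations with randomization tests.

#' Scaled mass index of body condition
#'
#' `SMI_i = M_i * (Lbar / L_i)^b`, where `b` is the standardized major axis
#' (SMA) slope of `ln M` on `ln L` (the OLS slope divided by the Pearson
#' correlation) and `Lbar` is the mean skeletal measure, here keel length.
#'
#' @param mass Body masses (g), length at least 3.
#' @param keel Keel lengths (mm), same length.
#' @return Numeric vector of SMI values (g), with the SMA slope `b` as an
#'   attribute.
#' @export
scaled_mass_index <- function(mass, keel) {
  if (length(mass) < 3 || length(mass) != length(keel)) {
    stop("scaled_mass_index() needs matched vectors of length >= 3", call. = FALSE)
  }
  if (any(mass <= 0) || any(keel <= 0)) stop("mass and keel must be positive", call. = FALSE)
  if (stats::sd(keel) == 0) {
    # no skeletal variation: condition is mass itself
    return(structure(mass, b = NA_real_))
  }
  lm_ <- log(mass); ll <- log(keel)
  r <- stats::cor(lm_, ll)
  if (abs(r) < .Machine$double.eps^0.5) {
    stop("mass and keel are uncorrelated: SMA slope undefined", call. = FALSE)
  }
  b_ols <- stats::cov(lm_, ll) / stats::var(ll)
  b_sma <- b_ols / r
  structure(mass * (mean(keel) / keel)^b_sma, b = b_sma)
}

#' Daily body mass increase of a brood
#'
#' Mean over the brood's surviving nestlings of the daily relative body-mass
#' gain between the two measurement days:
#' `DBMI_k = (1/m) * sum_j (1/i_j) * (BM_j,day(n+i) - BM_j,day(n)) / BM_j,day(n)`.
#' Nestlings without a second measurement (dead before day `n+i`) are
#' excluded, and `m` is the number of survivors.
#'
#' @param mass_first First body-mass measurements (g), one per nestling.
#' @param mass_second Second measurements (g); `NA` for nestlings that died.
#' @param days_elapsed Days between the two measurements (scalar or
#'   per-nestling).
#' @return The brood DBMI (per day), or `NA` when no nestling survived.
#' @export
dbmi <- function(mass_first, mass_second, days_elapsed) {
  stopifnot(length(mass_first) == length(mass_second))
  days_elapsed <- rep_len(days_elapsed, length(mass_first))
  ok <- !is.na(mass_second)
  if (!any(ok)) return(NA_real_)
  if (any(mass_first[ok] <= 0)) stop("first body masses must be positive", call. = FALSE)
  if (any(days_elapsed[ok] < 1)) stop("days elapsed must be at least 1", call. = FALSE)
  gains <- (mass_second[ok] - mass_first[ok]) / mass_first[ok] / days_elapsed[ok]
  mean(gains)
}

#' Residualize a variable on nuisance predictors
#'
#' OLS residuals of `y` on the given predictors (with intercept), used to
#' strip sex, year or brood-size heterogeneity from condition and fitness
#' proxies before correlating them with individual tendency.
#'
#' @param y Response vector.
#' @param predictors Data frame of predictors (factors allowed).
#' @return Numeric vector of residuals (mean zero, orthogonal to the
#'   predictor columns).
#' @export
residualize <- function(y, predictors) {
  df <- droplevels(data.frame(.y = y, predictors))
  fit <- stats::lm(.y ~ ., data = df)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    stop("rank-deficient design in residualize()", call. = FALSE)
  }
  unname(stats::residuals(fit))
}

#' Feeding frequency during the tracking period
#'
#' Number of foraging trips per device-on hour, defined only for birds
#' tracked during the nestling-rearing stage.
#'
#' @param n_trips Number of foraging trips.
#' @param tracked_hours Device-on hours over the tracking period.
#' @param stage Breeding stage of the bird's trips (a bird qualifies when any
#'   of its trips is `nestling_rearing`).
#' @return Trips per hour, or `NA` for birds never tracked while rearing
#'   nestlings.
#' @export
feeding_frequency <- function(n_trips, tracked_hours, stage) {
  if (!any(stage == "nestling_rearing")) return(NA_real_)
  if (tracked_hours <= 0) stop("tracked_hours must be positive", call. = FALSE)
  n_trips / tracked_hours
}

#' Weighted Pearson correlation
#'
#' `r_w = sum w (x - xbar_w)(y - ybar_w) / sqrt(sum w (x - xbar_w)^2 * sum w
#' (y - ybar_w)^2)` with weighted means; equal weights reduce it to the
#' ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param w Positive weights.
#' @return The weighted correlation coefficient.
#' @export
weighted_corr <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (n < 3 || length(y) != n || length(w) != n) {
    stop("x, y, w must have equal length >= 3", call. = FALSE)
  }
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sxy <- sum(w * (x - xm) * (y - ym))
  sxx <- sum(w * (x - xm)^2)
  syy <- sum(w * (y - ym)^2)
  if (sxx == 0 || syy == 0) {
    warning("zero weighted variance: correlation undefined")
    return(NA_real_)
  }
  sxy / sqrt(sxx * syy)
}

#' Randomization test for a weighted correlation
#'
#' Two-sided permutation test of `r_w`: `y` is shuffled (weights stay paired
#' with `x`) and the p-value is the probability of a permuted `|r_w*|` at
#' least as extreme as the observed one. For `n <= 7` all `n!` permutations
#' are enumerated exactly; otherwise `B` random shuffles are drawn and the
#' add-one-smoothed estimate `p = (1 + #extreme) / (B + 1)` is returned.
#'
#' @inheritParams weighted_corr
#' @param B Number of random shuffles in Monte-Carlo mode.
#' @param seed Integer seed for the shuffles.
#' @return A list with `r_obs`, `p` and `method` (`"exhaustive"` or
#'   `"monte_carlo"`).
#' @export
randomization_test <- function(x, y, w = rep(1, length(x)), B = 9999, seed = 1) {
  r_obs <- weighted_corr(x, y, w)
  n <- length(x)
  if (n <= 7) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(p) weighted_corr(x, y[p], w))
    p_val <- mean(abs(rs) >= abs(r_obs) - 1e-12)
    return(list(r_obs = r_obs, p = p_val, method = "exhaustive"))
  }
  rs <- with_rng(seed, vapply(seq_len(B), function(b) {
    weighted_corr(x, y[sample.int(n)], w)
  }, numeric(1)))
  p_val <- (1 + sum(abs(rs) >= abs(r_obs) - 1e-12)) / (B + 1)
  list(r_obs = r_obs, p = p_val, method = "monte_carlo")
}

#' Correlates of the individual tendency to forage dynamically
#'
#' Weighted correlations (weights = inverse SD of the conditional modes)
#' between the individual tendency to perform dynamic-foraging trips and
#' condition/fitness proxies: residual SMI (sex removed), breeding success,
#' residual nestling DBMI (year and brood size removed), residual feeding
#' frequency (year, sex and brood size removed) and, separately per sex, the
#' relative device load. Significance by [randomization_test()].
#'
#' @param adults Data frame with one row per individual: `tendency`,
#'   `tendency_sd`, `sex` (0/1), `year`, `smi`, `breeding_success` (0/1),
#'   `dbmi`, `brood_size`, `feeding_freq`, `device_load`. `NA` entries drop
#'   the individual from the relevant target only.
#' @param B,seed Passed to [randomization_test()].
#' @return Data frame with one row per target: `target`, `n`, `r_w`,
#'   `p_rand`. Targets with fewer than 3 usable individuals are skipped with
#'   a warning.
#' @export
correlate_tendency <- function(adults, B = 9999, seed = 1) {
  stopifnot(all(c("tendency", "tendency_sd") %in% names(adults)))
  w_all <- 1 / adults$tendency_sd
  out <- list()
  run_target <- function(name, y, keep, salt, resid_on = NULL) {
    keep <- keep & !is.na(y) & is.finite(w_all) & w_all > 0
    if (sum(keep) < 3) {
      warning("skipping target '", name, "': fewer than 3 individuals")
      return(NULL)
    }
    yy <- y[keep]
    if (!is.null(resid_on)) {
      pred <- resid_on[keep, , drop = FALSE]
      # nuisance terms constant within the usable subset carry no information
      informative <- vapply(pred, function(col) length(unique(col)) > 1, logical(1))
      pred <- pred[, informative, drop = FALSE]
      if (ncol(pred) > 0) {
        yy <- tryCatch(residualize(yy, pred), error = function(e) NULL)
        if (is.null(yy)) {
          warning("skipping target '", name, "': ", "degenerate nuisance design")
          return(NULL)
        }
      }
    }
    rt <- randomization_test(adults$tendency[keep], yy, w_all[keep],
                             B = B, seed = sub_seed(seed, salt))
    data.frame(target = name, n = sum(keep), r_w = rt$r_obs, p_rand = rt$p)
  }
  out$smi <- run_target("residual_smi", adults$smi, !is.na(adults$smi), 1,
                        resid_on = data.frame(sex = adults$sex))
  out$success <- run_target("breeding_success", adults$breeding_success,
                            !is.na(adults$breeding_success), 2)
  out$dbmi <- run_target("residual_dbmi", adults$dbmi,
                         !is.na(adults$dbmi) & !is.na(adults$brood_size), 3,
                         resid_on = data.frame(year = factor(adults$year),
                                               brood_size = adults$brood_size))
  out$feed <- run_target("residual_feeding_freq", adults$feeding_freq,
                         !is.na(adults$feeding_freq) & !is.na(adults$brood_size), 4,
                         resid_on = data.frame(year = factor(adults$year),
                                               sex = adults$sex,
                                               brood_size = adults$brood_size))
  for (s in sort(unique(adults$sex))) {
    nm <- paste0("device_load_sex", s)
    out[[nm]] <- run_target(nm, adults$device_load, adults$sex == s, 5 + s)
  }
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
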