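# Behavioural-mode annotation: EM clustering of fixes in (speed, |turn|)
# space into four modes delimited by low/high splits on each axis, plus a
# margin-gated majority smoother for temporally coherent label sequences.

BEHAVIOUR_MODES <- c("perch", "intensive_search", "relocation", "extensive_search")

# binary low/high pattern of each mode on (speed, turn): TRUE = low
MODE_PATTERN <- matrix(c(TRUE,  TRUE,    # perch: low speed, low turn
                         TRUE,  FALSE,   # intensive search: low speed, high turn
                         FALSE, TRUE,    # relocation: high speed, low turn
                         FALSE, FALSE),  # extensive search: high speed, high turn
                       ncol = 2, byrow = TRUE,
                       dimnames = list(BEHAVIOUR_MODES, c("speed", "turn")))

# log density of a bivariate normal, manual 2x2 algebra
ldmvnorm2 <- function(x, mu, S) {
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2, 2) / det_s
  d1 <- x[, 1] - mu[1]
  d2 <- x[, 2] - mu[2]
  q <- inv[1, 1] * d1^2 + 2 * inv[1, 2] * d1 * d2 + inv[2, 2] * d2^2
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

cov_floor <- function(S, floor = 1e-8) {
  diag(S) <- pmax(diag(S), floor)
  # cap the correlation so the covariance stays comfortably positive-definite
  rho <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  if (!is.finite(rho)) rho <- 0
  if (abs(rho) > 0.99) {
    S[1, 2] <- S[2, 1] <- sign(rho) * 0.99 * sqrt(S[1, 1] * S[2, 2])
  }
  S
}

weighted_cov2 <- function(x, w, mu) {
  sw <- sum(w)
  d1 <- x[, 1] - mu[1]
  d2 <- x[, 2] - mu[2]
  S <- matrix(c(sum(w * d1^2), sum(w * d1 * d2),
                sum(w * d1 * d2), sum(w * d2^2)), 2, 2) / sw
  cov_floor(S)
}

#' Fit a four-mode behavioural clustering in speed-by-turn space
#'
#' Expectation-maximization on a four-component bivariate Gaussian mixture
#' over (speed, absolute turning angle), initialized from the four quadrants
#' delimited by the per-axis medians. After convergence, per-axis low/high
#' delimiters are placed midway between the mean projection of the two low
#' components and that of the two high components, and each component is
#' mapped to the behavioural mode matching its quadrant: low speed/low turn =
#' perching, low/high = intensive search, high/low = relocation, high/high =
#' extensive search.
#'
#' @param speed Numeric vector of per-fix speeds (m/s).
#' @param turn Numeric vector of per-fix absolute turning angles (radians,
#'   `[0, pi]`), same length as `speed`.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the change in log-likelihood.
#' @param seed Integer seed for the k-means-seeded second start.
#' @return An object of class `embc_model`: component means, covariances and
#'   weights, the component-to-mode map, per-axis `delimiters`, the
#'   log-likelihood trace, `n_iter` and a `converged` flag.
#' @export
embc_fit <- function(speed, turn, max_iter = 200, tol = 1e-6, seed = 1) {
  x <- cbind(speed = speed, turn = turn)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 50) stop("embc_fit() needs at least 50 complete points", call. = FALSE)
  stopifnot_finite(x, "speed/turn")
  if (stats::sd(x[, 1]) == 0 || stats::sd(x[, 2]) == 0) {
    stop("degenerate input: zero variance on an axis", call. = FALSE)
  }
  n <- nrow(x)
  K <- 4

  # primary start: the four quadrants around the per-axis medians
  med <- apply(x, 2, stats::median)
  quad <- 1L + (x[, 1] > med[1]) * 2L + (x[, 2] > med[2]) * 1L
  # second start: k-means on z-scored axes, robust when mode mixes are skewed
  km_cl <- with_rng(seed, tryCatch(
    stats::kmeans(scale(x), K, nstart = 5, iter.max = 50)$cluster,
    error = function(e) NULL))
  init_from <- function(cl) {
    mu <- vector("list", K); S <- vector("list", K); w <- numeric(K)
    for (k in 1:K) {
      pts <- x[cl == k, , drop = FALSE]
      if (nrow(pts) < 2) pts <- x      # empty group: fall back to global
      mu[[k]] <- colMeans(pts)
      S[[k]] <- cov_floor(stats::cov(pts))
      w[k] <- max(1, nrow(pts)) / n
    }
    list(mu = mu, S = S, w = w / sum(w))
  }
  fits <- lapply(Filter(Negate(is.null), list(quad, km_cl)), function(cl) {
    embc_em(x, init_from(cl), max_iter, tol)
  })
  best <- fits[[which.max(vapply(fits, function(f) {
    f$ll_trace[length(f$ll_trace)]
  }, numeric(1)))]]
  mu <- best$mu; S <- best$S; w <- best$w
  ll_trace <- best$ll_trace; converged <- best$converged
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")

  ll <- ll_trace[length(ll_trace)]

  mu_mat <- do.call(rbind, mu)
  delim <- vapply(1:2, function(ax) {
    ord <- order(mu_mat[, ax])
    (mean(mu_mat[ord[1:2], ax]) + mean(mu_mat[ord[3:4], ax])) / 2
  }, numeric(1))
  names(delim) <- c("speed", "turn")

  # component -> mode by the quadrant of the component mean relative to the
  # delimiters; the map need not be a bijection (a rare mode may end up with
  # no component, its points falling to the neighbouring quadrant's modes)
  pat <- cbind(mu_mat[, 1] < delim["speed"], mu_mat[, 2] < delim["turn"])
  idx <- apply(pat, 1, function(p) {
    which(MODE_PATTERN[, 1] == p[1] & MODE_PATTERN[, 2] == p[2])
  })
  mode_of_component <- BEHAVIOUR_MODES[idx]

  structure(list(means = mu_mat, covariances = S, weights = w,
                 mode_of_component = mode_of_component,
                 delimiters = delim, loglik = ll_trace,
                 n_iter = length(ll_trace), converged = converged),
            class = "embc_model")
}

#' @export
print.embc_model <- function(x, ...) {
  cat("Four-mode behavioural clustering (EM, bivariate Gaussian mixture)\n")
  cat(sprintf("  iterations: %d (%s), log-likelihood: %.2f\n", x$n_iter,
              if (x$converged) "converged" else "not converged",
              x$loglik[length(x$loglik)]))
  cat(sprintf("  delimiters: speed %.3f m/s, turn %.3f rad\n",
              x$delimiters["speed"], x$delimiters["turn"]))
  tab <- data.frame(mode = x$mode_of_component,
                    speed = round(x$means[, 1], 3),
                    turn = round(x$means[, 2], 3),
                    weight = round(x$weights, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Label fixes with behavioural modes under a fitted model
#'
#' Assigns each (speed, turn) point the mode of the mixture component with
#' the highest posterior probability.
#'
#' @param model An [embc_fit()] model.
#' @param speed,turn Numeric vectors of the points to label.
#' @return A list with `mode` (character vector) and `posterior` (matrix with
#'   one column per behavioural mode, rows summing to 1). Points with missing
#'   speed or turn get `NA` labels.
#' @export
embc_label <- function(model, speed, turn) {
  x <- cbind(speed, turn)
  ok <- stats::complete.cases(x)
  if (any(!is.finite(x[ok, ]))) stop("points must be finite", call. = FALSE)
  n <- length(speed)
  post <- matrix(NA_real_, n, 4, dimnames = list(NULL, BEHAVIOUR_MODES))
  mode <- rep(NA_character_, n)
  if (any(ok)) {
    xo <- x[ok, , drop = FALSE]
    lp <- vapply(1:4, function(k) {
      log(model$weights[k]) + ldmvnorm2(xo, model$means[k, ], model$covariances[[k]])
    }, numeric(sum(ok)))
    if (sum(ok) == 1) lp <- matrix(lp, nrow = 1)
    m <- pmax(lp[, 1], lp[, 2], lp[, 3], lp[, 4])
    p <- exp(lp - m)
    p <- p / rowSums(p)
    # mode posterior = sum of its components' posteriors
    pm <- vapply(BEHAVIOUR_MODES, function(md) {
      cols <- which(model$mode_of_component == md)
      if (length(cols) == 0) rep(0, nrow(p)) else rowSums(p[, cols, drop = FALSE])
    }, numeric(nrow(p)))
    if (nrow(p) == 1) pm <- matrix(pm, nrow = 1, dimnames = list(NULL, BEHAVIOUR_MODES))
    post[ok, ] <- pm
    mode[ok] <- BEHAVIOUR_MODES[max.col(pm, ties.method = "first")]
  }
  list(mode = mode, posterior = post)
}

#' Temporal smoothing of behavioural labels
#'
#' Single-pass majority smoother: a fix's label is replaced by the majority
#' label of the centred window when (a) a strict majority exists, (b) it
#' differs from the fix's own label, and (c) the fix's posterior margin (top
#' minus second-best probability) is below `margin`. Windows shrink at the
#' sequence edges; ties leave the label unchanged.
#'
#' @param mode Character vector of labels, time-ordered within one trajectory.
#' @param posterior Posterior matrix as returned by [embc_label()].
#' @param window Odd window width (fixes), at least 3.
#' @param margin Posterior-margin gate below which a label may be replaced.
#' @return Character vector of smoothed labels.
#' @export
smooth_labels <- function(mode, posterior, window = 5, margin = 0.5) {
  if (window < 3 || window %% 2 == 0) {
    stop("window must be odd and at least 3", call. = FALSE)
  }
  n <- length(mode)
  if (n == 0) return(mode)
  marg <- apply(posterior, 1, function(p) {
    if (all(is.na(p))) return(Inf)
    s <- sort(p, decreasing = TRUE)
    s[1] - s[2]
  })
  h <- (window - 1) / 2
  out <- mode
  for (i in seq_len(n)) {
    if (is.na(mode[i]) || marg[i] >= margin) next
    win <- mode[max(1, i - h):min(n, i + h)]
    win <- win[!is.na(win)]
    if (length(win) == 0) next
    tab <- table(win)
    top <- tab[tab == max(tab)]
    if (length(top) > 1) next                       # tie: unchanged
    if (max(tab) <= length(win) / 2) next           # no strict majority
    if (names(top) != mode[i]) out[i] <- names(top)
  }
  out
}

# core EM loop for the 4-component bivariate mixture
embc_em <- function(x, init, max_iter, tol) {
  n <- nrow(x); K <- length(init$mu)
  mu <- init$mu; S <- init$S; w <- init$w
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lp <- vapply(1:K, function(k) log(w[k]) + ldmvnorm2(x, mu[[k]], S[[k]]),
                 numeric(n))
    m <- pmax(lp[, 1], lp[, 2], lp[, 3], lp[, 4])
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lp - lse)
    if (!is.finite(ll)) break
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    nk <- colSums(resp)
    for (k in 1:K) {
      if (nk[k] < 1e-3) next                 # dying component: freeze it
      w[k] <- nk[k] / n
      mu[[k]] <- colSums(resp[, k] * x) / nk[k]
      S[[k]] <- weighted_cov2(x, resp[, k], mu[[k]])
    }
    w <- w / sum(w)
  }
  list(mu = mu, S = S, w = w, ll_trace = ll_trace, converged = converged)
}

# all permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}
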