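# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

wrap_deg <- function(x) ((x %% 360) + 360) %% 360

# signed angular difference a - b mapped to [-180, 180)
angle_diff_deg <- function(a, b) ((a - b + 180) %% 360) - 180

circular_mean_deg <- function(x) {
  r <- deg2rad(x)
  wrap_deg(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

# deterministic child seed; result stays below 2^31 - 1
sub_seed <- function(seed, salt = 0) {
  as.integer((as.double(seed) * 48271 + as.double(salt) * 8191) %% 2147483629)
}

# evaluate `code` under a fixed RNG state, restoring the caller's stream
with_rng <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), mode = "integer", inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# inverse-CDF truncated normal draw (deterministic given RNG state)
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# z-score that tolerates zero-variance columns
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
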