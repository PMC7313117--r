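# fixtures built in code: planar fix tracks, quadrant clouds and Markov
# behaviour sequences used across the test files

t0_utc <- as.POSIXct("2017-06-05 06:00:00", tz = "UTC")

# metres per degree of latitude on the package's reference sphere
m_per_deg <- 6371000 * pi / 180

# fixes along a bearing at constant speed (planar, metres)
line_fixes <- function(n, spacing_m = 600, bearing_deg = 90,
                       lat0 = 40.666, lon0 = 16.604, dt_s = 60) {
  step_lat <- spacing_m * cos(pi * bearing_deg / 180) / m_per_deg
  step_lon <- spacing_m * sin(pi * bearing_deg / 180) /
    (m_per_deg * cos(pi * lat0 / 180))
  data.frame(t = t0_utc + (0:(n - 1)) * dt_s,
             lat = lat0 + (0:(n - 1)) * step_lat,
             lon = lon0 + (0:(n - 1)) * step_lon)
}

offset_fix <- function(nest, north_m, east_m) {
  c(lat = unname(nest["lat"] + north_m / m_per_deg),
    lon = unname(nest["lon"] + east_m / (m_per_deg * cos(pi * nest["lat"] / 180))))
}

# four well-separated Gaussian clouds, one per behavioural quadrant
quadrant_points <- function(n = 2000, seed = 1,
                            centers = list(perch = c(0.3, 0.3),
                                           intensive_search = c(0.5, 2.3),
                                           relocation = c(9, 0.3),
                                           extensive_search = c(8, 2.3)),
                            sds = c(0.15, 0.25)) {
  withr::with_seed(seed, {
    lab <- sample(names(centers), n, replace = TRUE)
    speed <- vapply(lab, function(l) {
      max(0.01, rnorm(1, centers[[l]][1], sds[1] * max(1, centers[[l]][1] / 2)))
    }, numeric(1))
    turn <- vapply(lab, function(l) {
      min(pi, max(0, rnorm(1, centers[[l]][2], sds[2])))
    }, numeric(1))
    data.frame(label = unname(lab), speed = unname(speed), turn = unname(turn))
  })
}

# first-order Markov behaviour sequence with mixing rate a around mix pi
markov_modes <- function(n, mix, a = 0.12, seed = 1) {
  withr::with_seed(seed, {
    out <- character(n)
    out[1] <- sample(names(mix), 1, prob = mix)
    for (i in 2:n) {
      out[i] <- if (runif(1) < a) sample(names(mix), 1, prob = mix) else out[i - 1]
    }
    out
  })
}

# emit (speed, turn) observations for a mode sequence
emit_metrics <- function(modes, seed = 1, params = NULL) {
  if (is.null(params)) params <- default_behaviour_params()
  withr::with_seed(seed, {
    bp <- params[modes, ]
    data.frame(
      speed = pmax(0, rnorm(length(modes), bp$speed_mean, bp$speed_sd)),
      turn = pmin(pi, pmax(0, rnorm(length(modes), bp$turn_mean, bp$turn_sd))))
  })
}

# small config for study-level tests
small_config <- function(seed = 1, n_individuals = 6, trip_count_mu = 8, ...) {
  sim_config(n_individuals = n_individuals, trip_count_mu = trip_count_mu,
             seed = seed, ...)
}
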