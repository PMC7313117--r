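# Synthetic biologging study generator.
#
# Emulates a colony of central-place foragers tracked with combined GPS
# (1 fix/min, 05:00-21:00 local) and tri-axial accelerometer (25 Hz)
# loggers: per-individual foraging trips whose static/dynamic tactic is
# drawn from a logistic model with weather covariates and individual random
# intercepts, trajectories built from tactic-conditional behaviour
# sequences, hourly weather, nest timelines, adult morphometrics and
# nestling masses. Every generated quantity carries ground truth so that
# downstream recovery can be tested.

default_behaviour_params <- function() {
  data.frame(
    mode = c("perch", "intensive_search", "extensive_search", "relocation"),
    speed_mean = c(0.15, 2.0, 6.5, 9.0),   # m/s
    speed_sd   = c(0.10, 0.8, 1.5, 2.0),
    turn_mean  = c(0.30, 2.1, 2.0, 0.30),  # rad, absolute
    turn_sd    = c(0.25, 0.5, 0.5, 0.25),
    acc_sd     = c(0.04, 0.14, 0.22, 0.18),  # dynamic acceleration SD, g
    row.names = c("perch", "intensive_search", "extensive_search", "relocation")
  )
}

#' Configuration of a synthetic biologging study
#'
#' Collects every tunable of the generator: study design (individuals, trip
#' counts, fix cadence, accelerometer rate), the per-mode movement and
#' acceleration distributions, the true tactic-choice model (logit
#' coefficients on covariates standardized against the `ref_moments`,
#' individual intercept SD, year effects), the tactic-conditional behaviour
#' mixes, weather ranges, nest location and fitness couplings.
#'
#' @param n_individuals Number of tracked birds.
#' @param trips_per_individual Length-2 integer range to which drawn trip
#'   counts are clamped.
#' @param trip_count_mu,trip_count_size Negative-binomial mean and size for
#'   the per-individual trip count (right-skewed, as deployments are).
#' @param fix_interval GPS fix interval, seconds.
#' @param acc_rate Accelerometer sampling rate, Hz.
#' @param behaviour_params Data frame of per-mode speed/turn/acceleration
#'   distributions (see `default_behaviour_params()`).
#' @param sigma_id SD of the individual logit intercepts.
#' @param beta Named true coefficients (standardized scale) for intercept,
#'   solar, rain, twc, cwc, stage and sex.
#' @param year_effects Named additive year effects on the logit (treatment
#'   scale, first year = 0).
#' @param ref_moments Reference means/SDs used to standardize the raw
#'   covariates inside the generator.
#' @param tactic_profiles Behaviour mixes of the foraging (non-commuting)
#'   phase for SF and DF trips.
#' @param tactic_mixing Markov mixing rate per tactic (probability of
#'   redrawing the mode from the mix at each fix; smaller = longer runs).
#' @param duration_pars Lognormal duration parameters per tactic plus bounds
#'   (hours).
#' @param commute_frac Per-tactic range of the share of a trip spent
#'   commuting; the target foraging distance is derived from it and the
#'   drawn duration.
#' @param maxdist_pars Bounds (`min`, `max`, km) on the target foraging
#'   distance.
#' @param weather_ranges Hourly weather generator settings.
#' @param nest_coords Colony location, `c(lat = , lon = )`.
#' @param buffer_m Nest-buffer radius used by the segmentation.
#' @param day_start,day_end Device-on window, local hours.
#' @param tz_offset_h Local-time offset from UTC, hours.
#' @param dbmi_pars Nestling growth: mean total relative gain, coupling to
#'   the parent's intercept, brood and nestling noise SDs.
#' @param success_pars Breeding-success logit intercept and coupling.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 36,
                       trips_per_individual = c(1L, 45L),
                       trip_count_mu = 12.6, trip_count_size = 2,
                       fix_interval = 60, acc_rate = 25,
                       behaviour_params = default_behaviour_params(),
                       sigma_id = 0.81,
                       beta = c(intercept = -0.18, solar = 0.70, rain = -0.12,
                                twc = -0.16, cwc = 0.32, stage = 0.53,
                                sex = 0.04),
                       year_effects = c("2016" = 0, "2017" = 1.38, "2018" = 1.14),
                       ref_moments = list(solar = c(450, 250),
                                          rain = c(0.14, 0.35),
                                          twc = c(0, 2.8),
                                          cwc = c(2.5, 1.7),
                                          stage = c(0.55, 0.5),
                                          sex = c(0.36, 0.48)),
                       tactic_profiles = list(
                         SF = c(perch = 0.68, intensive_search = 0.19,
                                extensive_search = 0.05, relocation = 0.08),
                         DF = c(perch = 0.12, intensive_search = 0.44,
                                extensive_search = 0.12, relocation = 0.32)),
                       tactic_mixing = c(SF = 0.25, DF = 0.30),
                       duration_pars = list(SF = c(meanlog = log(2.0), sdlog = 0.6),
                                            DF = c(meanlog = log(0.9), sdlog = 0.55),
                                            min_h = 0.3, max_h = 6),
                       commute_frac = list(SF = c(0.10, 0.22),
                                           DF = c(0.30, 0.55)),
                       maxdist_pars = c(min = 1.2, max = 18),
                       weather_ranges = list(solar_max = 850, wind_mean = 4,
                                             wind_sd = 1.8, rain_day_p = 0.3,
                                             rain_hour_p = 0.5, rain_mm_mean = 1.5),
                       nest_coords = c(lat = 40.666, lon = 16.604),
                       buffer_m = 50, day_start = 5, day_end = 21,
                       tz_offset_h = 2,
                       dbmi_pars = c(mean = 0.114, coupling = 0.055,
                                     sd_brood = 0.04, sd_nestling = 0.015),
                       success_pars = c(intercept = 1.5, coupling = 0.25),
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              trips_per_individual = as.integer(trips_per_individual),
              trip_count_mu = trip_count_mu, trip_count_size = trip_count_size,
              fix_interval = fix_interval, acc_rate = acc_rate,
              behaviour_params = behaviour_params, sigma_id = sigma_id,
              beta = beta, year_effects = year_effects,
              ref_moments = ref_moments, tactic_profiles = tactic_profiles,
              tactic_mixing = tactic_mixing, duration_pars = duration_pars,
              commute_frac = commute_frac,
              maxdist_pars = maxdist_pars, weather_ranges = weather_ranges,
              nest_coords = nest_coords, buffer_m = buffer_m,
              day_start = day_start, day_end = day_end,
              tz_offset_h = tz_offset_h, dbmi_pars = dbmi_pars,
              success_pars = success_pars, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bp <- cfg$behaviour_params
  if (cfg$n_individuals <= 0 || any(cfg$trips_per_individual <= 0)) {
    stop("configuration error: counts must be positive", call. = FALSE)
  }
  if (cfg$fix_interval <= 0) stop("configuration error: fix_interval must be > 0", call. = FALSE)
  if (cfg$acc_rate <= 0) stop("configuration error: acc_rate must be > 0", call. = FALSE)
  if (any(c(bp$speed_sd, bp$turn_sd, bp$acc_sd) < 0) || cfg$sigma_id < 0) {
    stop("configuration error: SDs must be non-negative", call. = FALSE)
  }
  srch <- bp[c("intensive_search", "extensive_search"), "speed_mean"]
  if (!(bp["perch", "speed_mean"] < min(srch) &&
        max(srch) < bp["relocation", "speed_mean"])) {
    stop("configuration error: speed means must be ordered perch < search modes < relocation",
         call. = FALSE)
  }
  invisible(cfg)
}

# ---- weather ---------------------------------------------------------------

# hourly weather table for one year's tracking window (UTC timestamps,
# wind_dir_deg in the meteorological FROM convention)
simulate_weather_year <- function(year, days, cfg) {
  wr <- cfg$weather_ranges
  dates <- as.Date(sprintf("%d-06-%02d", year, days))
  rows <- list()
  for (d in seq_along(dates)) {
    rainy <- stats::runif(1) < wr$rain_day_p
    cloud <- if (rainy) stats::runif(1, 0.3, 0.7) else stats::runif(1, 0.6, 1.0)
    wmean <- max(0.5, stats::rnorm(1, wr$wind_mean, wr$wind_sd))
    wbase <- stats::runif(1, 0, 360)
    hours <- 0:23
    solar <- wr$solar_max * cloud * pmax(0, sin(pi * (hours - 5) / 16))
    solar[hours < 5 | hours > 21] <- 0
    rain <- ifelse(rainy & stats::runif(24) < wr$rain_hour_p,
                   stats::rexp(24, 1 / wr$rain_mm_mean), 0)
    wspeed <- pmax(0.2, wmean * exp(stats::rnorm(24, 0, 0.15)))
    wdir <- wrap_deg(wbase + cumsum(stats::rnorm(24, 0, 15)))
    rows[[d]] <- data.frame(
      t = as.POSIXct(paste(dates[d]), tz = "UTC") + hours * 3600 -
        cfg$tz_offset_h * 3600,
      solar_wm2 = solar, rain_mm = rain, wind_speed_ms = wspeed,
      wind_dir_deg = wdir)
  }
  do.call(rbind, rows)
}

# ---- habitat ---------------------------------------------------------------

# deterministic synthetic land-cover lookup: a 400-m grid of habitat classes
# (arable-dominated farmland) with an urban disc around the colony
habitat_lookup <- function(lat, lon, cfg) {
  centre <- cfg$nest_coords
  y <- (lat - centre["lat"]) * 111320
  x <- (lon - centre["lon"]) * 111320 * cos(deg2rad(centre["lat"]))
  urban <- sqrt(x^2 + y^2) <= 500
  ix <- floor(x / 400); iy <- floor(y / 400)
  probs <- c(artificial = 0.02, arable = 0.56, permanent_crop = 0.07,
             grassland = 0.20, heterogeneous_agri = 0.10, wooded = 0.05)
  cum <- cumsum(probs) / sum(probs)
  # hash each cell to a reproducible uniform deviate
  h <- (ix * 73856093 + iy * 19349663 + as.double(cfg$seed) * 83492791) %% 1e9
  u <- ((h * 2654435761) %% 1e9) / 1e9
  cls <- names(probs)[findInterval(u, cum) + 1]
  cls[urban] <- "artificial"
  cls
}

# ---- trajectories ----------------------------------------------------------

sample_mode_steps <- function(modes, cfg) {
  bp <- cfg$behaviour_params[modes, ]
  list(speed = rtruncnorm(length(modes), bp$speed_mean, bp$speed_sd, lower = 0),
       turn = rtruncnorm(length(modes), bp$turn_mean, bp$turn_sd,
                         lower = 0, upper = pi))
}

# one foraging trip in a local planar frame around the nest (metres).
# Commuting legs are relocation; the foraging phase draws modes from the
# tactic's mix with Markov persistence. Returns behaviours and positions;
# the trip ends when the bird re-enters the nest buffer (or max_fixes).
sim_trip_track <- function(n_fix_target, dist_target_m, td_deg, tactic, cfg,
                           max_fixes) {
  dt <- cfg$fix_interval
  mix <- cfg$tactic_profiles[[tactic]]
  a <- cfg$tactic_mixing[[tactic]]
  v_home <- cfg$behaviour_params["relocation", "speed_mean"]
  goal <- c(dist_target_m * sin(deg2rad(td_deg)),
            dist_target_m * cos(deg2rad(td_deg)))
  x <- numeric(max_fixes); y <- numeric(max_fixes)
  modes <- character(max_fixes)
  pos <- c(0, 0)
  heading <- td_deg
  phase <- "out"
  mode <- "relocation"
  n <- 0L
  repeat {
    if (n >= max_fixes) break
    d_nest <- sqrt(sum(pos^2))
    d_goal <- sqrt(sum((pos - goal)^2))
    if (phase == "out" && d_goal < max(250, 1.2 * v_home * dt)) phase <- "forage"
    if (phase != "return") {
      fixes_home <- d_nest / (v_home * dt) * 1.2 + 2
      if (n + fixes_home >= n_fix_target) phase <- "return"
    }
    if (phase == "forage") {
      if (stats::runif(1) < a) {
        mode <- sample(names(mix), 1, prob = mix)
      }
    } else {
      mode <- "relocation"
    }
    st <- sample_mode_steps(mode, cfg)
    target_bearing <- if (phase == "out") {
      wrap_deg(rad2deg(atan2(goal[1] - pos[1], goal[2] - pos[2])))
    } else if (phase == "return") {
      wrap_deg(rad2deg(atan2(-pos[1], -pos[2])))
    } else if (d_goal > 1500) {
      # foraging stays within the goal patch: drift back when straying
      wrap_deg(rad2deg(atan2(goal[1] - pos[1], goal[2] - pos[2])))
    } else NA_real_
    if (is.na(target_bearing)) {
      heading <- wrap_deg(heading + sample(c(-1, 1), 1) * rad2deg(st$turn))
    } else {
      cand <- wrap_deg(heading + c(-1, 1) * rad2deg(st$turn))
      heading <- cand[which.min(abs(angle_diff_deg(cand, target_bearing)))]
    }
    step_len <- st$speed * dt
    if (phase == "return") {
      # decelerate into the buffer: never overshoot the nest
      if (d_nest < 2 * step_len) heading <- target_bearing
      step_len <- min(step_len, max(0, d_nest - 15))
    }
    pos <- pos + step_len * c(sin(deg2rad(heading)), cos(deg2rad(heading)))
    n <- n + 1L
    x[n] <- pos[1]; y[n] <- pos[2]; modes[n] <- mode
    if (phase == "return" && sqrt(sum(pos^2)) <= cfg$buffer_m * 0.4) break
  }
  list(x = x[seq_len(n)], y = y[seq_len(n)], modes = modes[seq_len(n)], n = n)
}

local_to_latlon <- function(x, y, nest) {
  lat <- nest["lat"] + y / 111320
  lon <- nest["lon"] + x / (111320 * cos(deg2rad(nest["lat"])))
  cbind(lat = unname(lat), lon = unname(lon))
}

# ---- study -----------------------------------------------------------------

#' Generate a complete synthetic biologging study
#'
#' Produces GPS fix tables, hourly weather, nest timelines, adult
#' morphometrics and nestling body masses for a colony study, together with
#' the full ground truth (per-fix behaviour, per-trip tactic and covariates,
#' per-individual intercepts, true parameters). Tri-axial acceleration is
#' generated on demand per trip by [simulate_acc_stream()] (streams at 25 Hz
#' are bulky, so they are not materialized for the whole study). Output is
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `forage_study`: `fixes` (with `fix_id`,
#'   `individual_id`, `t` UTC, `lat`, `lon`, `habitat`), `weather`, `nests`
#'   (daily egg/nestling counts), `nest_coords` (per individual), `adults`,
#'   `nestlings`, `tracking` (per-individual tracked days/hours), `truth` and
#'   the `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  with_rng(cfg$seed, simulate_study_impl(cfg))
}

simulate_study_impl <- function(cfg) {
  years <- as.integer(names(cfg$year_effects))
  nid <- cfg$n_individuals
  ids <- sprintf("LK%02d", seq_len(nid))

  # individuals: sex (~13F/23M), year, latent intercept, morphometrics
  sex <- stats::rbinom(nid, 1, 0.36)                 # 1 = female
  year <- years[((seq_len(nid) - 1) %% length(years)) + 1]
  b_id <- stats::rnorm(nid, 0, cfg$sigma_id)
  keel <- stats::rnorm(nid, 32, 1.2)
  base_mass <- ifelse(sex == 1, 132, 115)
  mass <- base_mass * (keel / 32)^2 * exp(stats::rnorm(nid, 0, 0.04))
  device_mass <- stats::runif(nid, 5.9, 7.2)

  n_trips <- pmin(pmax(stats::rnbinom(nid, mu = cfg$trip_count_mu,
                                      size = cfg$trip_count_size),
                       cfg$trips_per_individual[1]),
                  cfg$trips_per_individual[2])
  n_days <- pmin(pmax(ceiling(n_trips / 8), 2), 5)
  start_day <- vapply(n_days, function(d) sample.int(20 - d, 1), integer(1))
  hatch_day <- start_day + sample(-6:6, nid, replace = TRUE)

  # nest positions: colony buildings, jitter within the urban core
  ang <- stats::runif(nid, 0, 2 * pi)
  rad <- stats::runif(nid, 0, 180)
  nest_coords <- data.frame(
    individual_id = ids,
    lat = cfg$nest_coords["lat"] + rad * cos(ang) / 111320,
    lon = cfg$nest_coords["lon"] +
      rad * sin(ang) / (111320 * cos(deg2rad(cfg$nest_coords["lat"]))),
    row.names = NULL)

  weather <- do.call(rbind, lapply(years, function(yr) {
    simulate_weather_year(yr, 1:20, cfg)
  }))
  weather <- weather[order(weather$t), ]

  rm <- cfg$ref_moments
  zref <- function(x, nm) (x - rm[[nm]][1]) / rm[[nm]][2]

  fix_list <- list()
  trip_list <- list()
  trip_counter <- 0L
  dt <- cfg$fix_interval
  fph <- 3600 / dt                                   # fixes per hour

  for (i in seq_len(nid)) {
    nest <- c(lat = nest_coords$lat[i], lon = nest_coords$lon[i])
    trips_left <- n_trips[i]
    ind_fixes <- list()
    for (day in start_day[i]:(start_day[i] + n_days[i] - 1)) {
      date <- as.Date(sprintf("%d-06-%02d", year[i], day))
      day0 <- as.POSIXct(paste(date), tz = "UTC") - cfg$tz_offset_h * 3600
      t_cur <- cfg$day_start                          # local hours
      day_rows <- list()
      # per-day trip quota keeps heavy trackers from exhausting early days
      quota <- ceiling(trips_left / max(1, start_day[i] + n_days[i] - day))
      done_today <- 0L
      while (trips_left > 0 && done_today < quota) {
        gap_h <- 0.05 + stats::rexp(1, 1 / 0.45)
        dep_h <- t_cur + gap_h
        if (dep_h > cfg$day_end - 0.5) break
        dep_t <- day0 + dep_h * 3600
        # covariates at departure (truth model)
        wi <- match_weather(dep_t, weather, max_gap_h = 3)
        solar <- weather$solar_wm2[wi]
        ws <- weather$wind_speed_ms[wi]
        wd_toward <- wrap_deg(weather$wind_dir_deg[wi] + 180)
        td <- stats::runif(1, 0, 360)
        delta <- deg2rad(td - wd_toward)
        twc <- ws * cos(delta)
        cwc <- abs(ws * sin(delta))
        rain_dep <- as.integer(weather$rain_mm[wi] > 0)
        stage01 <- as.integer(day >= hatch_day[i])
        lin <- cfg$beta[["intercept"]] + cfg$year_effects[[as.character(year[i])]] +
          cfg$beta[["solar"]] * zref(solar, "solar") +
          cfg$beta[["rain"]] * zref(rain_dep, "rain") +
          cfg$beta[["twc"]] * zref(twc, "twc") +
          cfg$beta[["cwc"]] * zref(cwc, "cwc") +
          cfg$beta[["stage"]] * zref(stage01, "stage") +
          cfg$beta[["sex"]] * zref(sex[i], "sex") +
          b_id[i]
        tactic <- if (stats::runif(1) < stats::plogis(lin)) "DF" else "SF"
        dp <- cfg$duration_pars
        dur <- min(max(stats::rlnorm(1, dp[[tactic]]["meanlog"],
                                     dp[[tactic]]["sdlog"]),
                       dp$min_h), dp$max_h, cfg$day_end - dep_h - 0.1)
        n_fix_target <- max(10, round(dur * fph))
        md <- cfg$maxdist_pars
        # distance scales with duration so the commute occupies a stable,
        # tactic-specific share of the trip
        cf <- stats::runif(1, cfg$commute_frac[[tactic]][1],
                           cfg$commute_frac[[tactic]][2])
        v_home_kmh <- cfg$behaviour_params["relocation", "speed_mean"] * 3.6
        dist_km <- min(max(cf * v_home_kmh * dur / 2, md["min"]), md["max"])
        max_fixes <- min(round((cfg$day_end - dep_h) * fph) - 1,
                         n_fix_target * 3)
        if (max_fixes < 10) break
        trk <- sim_trip_track(n_fix_target, dist_km * 1000, td, tactic, cfg,
                              max_fixes)
        ll <- local_to_latlon(trk$x, trk$y, nest)
        # at-nest fixes covering [t_cur, dep_h)
        n_gap <- max(0, round((dep_h - t_cur) * fph) - 1)
        if (n_gap > 0) {
          jit <- stats::runif(n_gap, 0, 10)
          jang <- stats::runif(n_gap, 0, 2 * pi)
          gpos <- local_to_latlon(jit * sin(jang), jit * cos(jang), nest)
          day_rows[[length(day_rows) + 1]] <- data.frame(
            individual_id = ids[i],
            t = day0 + (t_cur * 3600) + (seq_len(n_gap) - 1) * dt,
            lat = gpos[, "lat"], lon = gpos[, "lon"],
            behaviour = "perch", trip_id = NA_character_)
        }
        trip_counter <- trip_counter + 1L
        trip_id <- sprintf("%s_T%03d", ids[i], trip_counter)
        ret_t <- dep_t + (trk$n - 1) * dt
        day_rows[[length(day_rows) + 1]] <- data.frame(
          individual_id = ids[i],
          t = dep_t + (seq_len(trk$n) - 1) * dt,
          lat = ll[, "lat"], lon = ll[, "lon"],
          behaviour = trk$modes, trip_id = trip_id)
        trip_list[[trip_counter]] <- data.frame(
          trip_id = trip_id, individual_id = ids[i], year = year[i],
          date = date, tactic = tactic, dep_t = dep_t, ret_t = ret_t,
          td_deg = td, solar = solar, rain = rain_dep, twc = twc, cwc = cwc,
          stage = stage01, sex = sex[i], n_fixes = trk$n,
          linpred = lin)
        trips_left <- trips_left - 1L
        done_today <- done_today + 1L
        t_cur <- dep_h + trk$n / fph
      }
      # fill the rest of the day at the nest
      n_rest <- max(0, round((cfg$day_end - t_cur) * fph))
      if (n_rest > 0) {
        jit <- stats::runif(n_rest, 0, 10)
        jang <- stats::runif(n_rest, 0, 2 * pi)
        gpos <- local_to_latlon(jit * sin(jang), jit * cos(jang), nest)
        day_rows[[length(day_rows) + 1]] <- data.frame(
          individual_id = ids[i],
          t = day0 + (t_cur * 3600) + seq_len(n_rest) * dt,
          lat = gpos[, "lat"], lon = gpos[, "lon"],
          behaviour = "perch", trip_id = NA_character_)
      }
      ind_fixes[[length(ind_fixes) + 1]] <- do.call(rbind, day_rows)
    }
    fix_list[[i]] <- do.call(rbind, ind_fixes)
  }

  fixes_full <- do.call(rbind, fix_list)
  fixes_full$fix_id <- seq_len(nrow(fixes_full))
  fixes_full$habitat <- habitat_lookup(fixes_full$lat, fixes_full$lon, cfg)
  trips <- do.call(rbind, trip_list)
  realized <- table(factor(trips$individual_id, levels = ids))

  # nest timelines: clutch of eggs until the day before hatching, nestlings
  # afterwards; brood losses happen after the tracking window
  clutch <- sample(3:5, nid, replace = TRUE)
  success <- stats::rbinom(nid, 1, stats::plogis(cfg$success_pars["intercept"] +
                                                   cfg$success_pars["coupling"] * b_id))
  brood0 <- pmax(1, clutch - stats::rbinom(nid, 1, 0.3))
  brood14 <- ifelse(success == 1, pmax(1, brood0 - stats::rbinom(nid, 1, 0.25)), 0)
  nests <- list(); nestlings <- list()
  for (i in seq_len(nid)) {
    span <- (start_day[i] - 2):(start_day[i] + n_days[i] + 2)
    span <- span[span >= 1]
    dts <- as.Date(sprintf("%d-06-%02d", year[i], pmin(span, 30)))
    hatch_date <- as.Date(sprintf("%d-06-%02d", year[i],
                                  min(max(hatch_day[i], 1), 30)))
    nests[[i]] <- data.frame(
      individual_id = ids[i], date = dts,
      n_eggs = ifelse(dts < hatch_date, clutch[i], 0L),
      n_nestlings = ifelse(dts < hatch_date, 0L, brood0[i]))
    d1 <- sample(5:9, 1); d2 <- sample(13:17, 1)
    m1 <- stats::rnorm(brood0[i], 38, 5)
    gain_b <- cfg$dbmi_pars["mean"] + cfg$dbmi_pars["coupling"] * b_id[i] +
      stats::rnorm(1, 0, cfg$dbmi_pars["sd_brood"])
    gain_j <- pmax(0.02, gain_b + stats::rnorm(brood0[i], 0,
                                               cfg$dbmi_pars["sd_nestling"]))
    alive <- rep(FALSE, brood0[i])
    if (brood14[i] > 0) alive[seq_len(brood14[i])] <- TRUE
    m2 <- ifelse(alive, m1 * (1 + gain_j), NA_real_)
    nestlings[[i]] <- data.frame(
      brood_id = ids[i], nestling_id = sprintf("%s_N%d", ids[i], seq_len(brood0[i])),
      day_first = d1, day_second = d2, days_elapsed = d2 - d1,
      mass_first = m1, mass_second = m2)
  }

  adults <- data.frame(
    individual_id = ids, sex = sex, year = year, body_mass = mass,
    keel = keel, device_mass = device_mass,
    device_load = device_mass / mass,
    breeding_success = success, brood_size = brood14,
    n_trips_drawn = n_trips, n_trips = as.integer(realized),
    tracked_hours = n_days * (cfg$day_end - cfg$day_start),
    row.names = NULL)

  truth <- list(
    fix_behaviour = fixes_full$behaviour,
    fix_trip = fixes_full$trip_id,
    trips = trips,
    individual = data.frame(individual_id = ids, intercept = b_id,
                            sex = sex, year = year, hatch_day = hatch_day,
                            row.names = NULL),
    true_params = list(beta = cfg$beta, year_effects = cfg$year_effects,
                       sigma_id = cfg$sigma_id))

  fixes <- fixes_full[, c("fix_id", "individual_id", "t", "lat", "lon", "habitat")]
  structure(list(fixes = fixes, weather = weather,
                 nests = do.call(rbind, nests),
                 nest_coords = nest_coords,
                 adults = adults, nestlings = do.call(rbind, nestlings),
                 truth = truth, config = cfg),
            class = "forage_study")
}

#' @export
print.forage_study <- function(x, ...) {
  cat(sprintf("Synthetic biologging study: %d individuals, %d trips, %d fixes\n",
              nrow(x$adults), nrow(x$truth$trips), nrow(x$fixes)))
  cat(sprintf("  tactics: %d SF / %d DF; years %s\n",
              sum(x$truth$trips$tactic == "SF"),
              sum(x$truth$trips$tactic == "DF"),
              paste(sort(unique(x$adults$year)), collapse = "/")))
  invisible(x)
}

#' Simulate a tri-axial acceleration stream for a fix sequence
#'
#' For each GPS fix interval, `fix_interval * acc_rate` samples are drawn:
#' the static component approximates the gravity vector (0, 0, 1 g) and the
#' dynamic component is zero-mean Gaussian noise with the per-behaviour SD of
#' the configuration, so flight modes carry strictly more dynamic
#' acceleration than perching.
#'
#' @param behaviours Character vector of per-fix behavioural modes.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A data frame with `t_offset` (seconds from the first fix), `ax`,
#'   `ay`, `az` (g), of `length(behaviours) * fix_interval * acc_rate` rows.
#' @export
simulate_acc_stream <- function(behaviours, config = sim_config(), seed = 1) {
  if (length(behaviours) == 0) stop("behaviours must be nonempty", call. = FALSE)
  bad <- setdiff(unique(behaviours), rownames(config$behaviour_params))
  if (length(bad)) stop("unknown behaviour label: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  per_fix <- round(config$fix_interval * config$acc_rate)
  sds <- rep(config$behaviour_params[behaviours, "acc_sd"], each = per_fix)
  n <- length(sds)
  with_rng(seed, data.frame(
    t_offset = (seq_len(n) - 1) / config$acc_rate,
    ax = stats::rnorm(n, 0, sds),
    ay = stats::rnorm(n, 0, sds),
    az = 1 + stats::rnorm(n, 0, sds)))
}

#' Simulate tactic-choice data at the model level
#'
#' Draws binary tactic outcomes directly from the logistic mixed model
#' (standardized covariates, individual random intercepts) without building
#' trajectories — the generator used for coefficient- and
#' repeatability-recovery experiments where only the statistical layer is
#' exercised.
#'
#' @param n_individuals Number of individuals.
#' @param trips_per_individual Trips per individual.
#' @param beta Named coefficients for the standardized covariates; names
#'   become column names.
#' @param beta0 Intercept on the logit scale.
#' @param sigma_id SD of the individual intercepts.
#' @param stage_var Name (if any) of a covariate to draw as a standardized
#'   0/1 indicator rather than a standard normal.
#' @param seed Integer seed.
#' @return A data frame with `individual_id`, one column per covariate, and
#'   `tactic_df` (0/1); the individual intercepts and parameters are attached
#'   as the `truth` attribute.
#' @export
simulate_tactic_data <- function(n_individuals = 40, trips_per_individual = 30,
                                 beta = c(solar = 0.70, cwc = 0.32, stage = 0.53),
                                 beta0 = 0.62, sigma_id = 0.81,
                                 stage_var = "stage", seed = 1) {
  with_rng(seed, {
    n <- n_individuals * trips_per_individual
    id <- rep(sprintf("id%03d", seq_len(n_individuals)),
              each = trips_per_individual)
    b <- stats::rnorm(n_individuals, 0, sigma_id)
    X <- vapply(names(beta), function(nm) {
      if (identical(nm, stage_var)) zscore(stats::rbinom(n, 1, 0.55))
      else stats::rnorm(n)
    }, numeric(n))
    lin <- beta0 + as.numeric(X %*% beta) + rep(b, each = trips_per_individual)
    y <- stats::rbinom(n, 1, stats::plogis(lin))
    out <- data.frame(individual_id = id, X, tactic_df = y)
    attr(out, "truth") <- list(beta = beta, beta0 = beta0, sigma_id = sigma_id,
                               intercepts = b)
    out
  })
}

#' Write the study tables to CSV
#'
#' Writes `fixes.csv`, `weather.csv`, `nests.csv`, `adults.csv`,
#' `nestlings.csv` and (when `jsonlite` is installed) `truth.json` into
#' `dir`. Acceleration streams are regenerated on demand and are not written.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  fx <- study$fixes
  fx$t <- format(fx$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  wr(fx, "fixes.csv")
  wt <- study$weather
  wt$t <- format(wt$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  wr(wt, "weather.csv")
  wr(study$nests, "nests.csv")
  wr(study$adults, "adults.csv")
  wr(study$nestlings, "nestlings.csv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(individual = study$truth$individual,
           trips = study$truth$trips[, c("trip_id", "individual_id", "tactic")],
           true_params = study$truth$true_params),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      POSIXt = "ISO8601")
  }
  invisible(dir)
}
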