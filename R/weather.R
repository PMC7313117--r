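# Weather annotation of trips: nearest-in-time matching of hourly records,
# trip direction, and decomposition of wind into tailwind (TWC) and
# crosswind (CWC) components relative to the trip direction:
#
#   TWC = WS * cos(TD - WD),   CWC = |WS * sin(TD - WD)|
#
# with WS/WD the mean wind speed and (circular-mean) direction at departure
# and return, and TD the bearing from the nest to the trip's farthest point.
# The equations require WD in the direction the wind blows TOWARD (TD = WD
# means pure tailwind); station files usually report the FROM convention,
# controlled by `wind_dir_from`.

#' Match timestamps to the nearest hourly weather record
#'
#' @param t Vector of timestamps (`POSIXct`).
#' @param weather Data frame of hourly records with a `t` column, sorted in
#'   time.
#' @param max_gap_h Records farther than this many hours give `NA` (flagged
#'   missing).
#' @return Integer vector of row indices into `weather` (ties go to the
#'   earlier record), `NA` where no record is close enough.
#' @export
match_weather <- function(t, weather, max_gap_h = 3) {
  if (nrow(weather) == 0) stop("weather records are empty", call. = FALSE)
  wt <- as.numeric(weather$t)
  tt <- as.numeric(t)
  pos <- findInterval(tt, wt)
  lo <- pmax(pos, 1)
  hi <- pmin(pos + 1, length(wt))
  d_lo <- abs(tt - wt[lo])
  d_hi <- abs(tt - wt[hi])
  idx <- ifelse(d_lo <= d_hi, lo, hi)   # tie -> earlier record
  gap <- pmin(d_lo, d_hi)
  idx[gap > max_gap_h * 3600] <- NA_integer_
  idx
}

#' Trip direction
#'
#' The direction of a foraging trip is the initial great-circle bearing from
#' the nest to the trip's farthest fix, taken to reflect the direction of the
#' goal foraging area.
#'
#' @param trip Data frame of trip fixes (`lat`, `lon`).
#' @param nest Named numeric vector `c(lat = , lon = )`.
#' @return Bearing in degrees from north, `[0, 360)`; `NA` with a warning
#'   when the farthest fix coincides with the nest.
#' @export
trip_direction <- function(trip, nest) {
  d <- haversine_distance(trip$lat, trip$lon, nest["lat"], nest["lon"])
  if (max(d) == 0) {
    warning("farthest fix coincides with the nest: trip direction undefined")
    return(NA_real_)
  }
  far <- which.max(d)
  unname(initial_bearing(nest["lat"], nest["lon"], trip$lat[far], trip$lon[far]))
}

#' Tailwind/crosswind decomposition and weather covariates of a trip
#'
#' Computes the wind components from the mean of the departure- and
#' return-matched wind records (arithmetic mean for speed, circular mean for
#' direction), the solar radiation at departure, and the presence of rain in
#' any hourly record spanning the trip.
#'
#' @param dep_t,ret_t Departure and return timestamps (`POSIXct`).
#' @param td Trip direction, degrees from north.
#' @param weather Hourly weather data frame with columns `t`, `solar_wm2`,
#'   `rain_mm`, `wind_speed_ms`, `wind_dir_deg`.
#' @param wind_dir_from `TRUE` when `wind_dir_deg` uses the meteorological
#'   FROM convention (converted internally to the TOWARD convention the
#'   decomposition requires).
#' @param max_gap_h Matching tolerance passed to [match_weather()].
#' @return Named list with `twc_ms` (signed), `cwc_ms` (non-negative),
#'   `ws_ms`, `wd_deg` (toward), `solar_wm2` at departure and `rain_present`
#'   (0/1). All-`NA` when departure or return weather is missing.
#' @export
wind_components <- function(dep_t, ret_t, td, weather, wind_dir_from = TRUE,
                            max_gap_h = 3) {
  i_dep <- match_weather(dep_t, weather, max_gap_h)
  i_ret <- match_weather(ret_t, weather, max_gap_h)
  if (is.na(i_dep) || is.na(i_ret) || is.na(td)) {
    return(list(twc_ms = NA_real_, cwc_ms = NA_real_, ws_ms = NA_real_,
                wd_deg = NA_real_, solar_wm2 = NA_real_,
                rain_present = NA_integer_))
  }
  wd_raw <- c(weather$wind_dir_deg[i_dep], weather$wind_dir_deg[i_ret])
  if (wind_dir_from) wd_raw <- wrap_deg(wd_raw + 180)
  ws <- mean(c(weather$wind_speed_ms[i_dep], weather$wind_speed_ms[i_ret]))
  wd <- circular_mean_deg(wd_raw)
  delta <- deg2rad(td - wd)
  # records that would be nearest-matched by some fix of the trip
  span <- weather$t >= (dep_t - 1800) & weather$t <= (ret_t + 1800)
  rain <- as.integer(any(weather$rain_mm[span & !is.na(weather$rain_mm)] > 0))
  list(twc_ms = ws * cos(delta),
       cwc_ms = abs(ws * sin(delta)),
       ws_ms = ws, wd_deg = wd,
       solar_wm2 = weather$solar_wm2[i_dep],
       rain_present = rain)
}
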