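# Trip segmentation and spatio-temporal descriptors for central-place foragers.
#
# All distances are great-circle (haversine) on a sphere of radius 6,371 km;
# headings are initial great-circle bearings, degrees clockwise from north.

EARTH_RADIUS_M <- 6371000

HABITAT_CLASSES <- c("artificial", "arable", "permanent_crop", "grassland",
                     "heterogeneous_agri", "wooded")

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 180)) {
    stop("invalid coordinates: lat must be in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Great-circle distance between positions
#'
#' Haversine distance on a spherical Earth of radius 6,371,000 m, the distance
#' kernel used for step lengths, nest buffers and trip descriptors.
#'
#' @param lat1,lon1 Coordinates of the first position (decimal degrees, WGS84).
#' @param lat2,lon2 Coordinates of the second position. All arguments are
#'   recycled to a common length.
#' @return Numeric vector of distances in metres.
#' @examples
#' haversine_distance(0, 0, 0, 1)  # ~111 km along the equator
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing between positions
#'
#' @inheritParams haversine_distance
#' @return Bearing in degrees clockwise from north, in `[0, 360)`.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  wrap_deg(rad2deg(atan2(y, x)))
}

#' Per-fix movement metrics along a trajectory
#'
#' Computes, for an ordered sequence of GPS fixes, the step length and
#' instantaneous speed of the step leaving each fix, the heading of that step,
#' and the absolute turning angle at each interior fix (the unsigned change in
#' heading, wrapped to `[0, pi]` radians). Speed and heading are `NA` at the
#' last fix; the turning angle is additionally `NA` at the first fix.
#'
#' @param fixes A data frame with columns `t` (`POSIXct`, strictly increasing),
#'   `lat` and `lon`.
#' @return A data frame with one row per fix and columns `step_length` (m),
#'   `speed` (m/s), `heading` (degrees from north) and `turn` (radians).
#' @export
step_metrics <- function(fixes) {
  if (nrow(fixes) < 3) stop("step_metrics() needs at least 3 fixes", call. = FALSE)
  dt <- diff(as.numeric(fixes$t))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  n <- nrow(fixes)
  i <- seq_len(n - 1)
  d <- haversine_distance(fixes$lat[i], fixes$lon[i],
                          fixes$lat[i + 1], fixes$lon[i + 1])
  hd <- initial_bearing(fixes$lat[i], fixes$lon[i],
                        fixes$lat[i + 1], fixes$lon[i + 1])
  step_length <- c(d, NA_real_)
  speed <- c(d / dt, NA_real_)
  heading <- c(hd, NA_real_)
  turn <- rep(NA_real_, n)
  if (n >= 3) {
    j <- 2:(n - 1)
    turn[j] <- abs(deg2rad(angle_diff_deg(hd[j], hd[j - 1])))
  }
  data.frame(step_length = step_length, speed = speed,
             heading = heading, turn = turn)
}

#' Segment a fix series into foraging trips
#'
#' A foraging trip is a maximal run of consecutive fixes outside the 50-m
#' buffer around the nest (and any supplied roost sites), bounded by
#' inside-buffer fixes or by the start/end of the tracking day. The first
#' excursion of a day that lacks a preceding inside-buffer fix is discarded
#' when its first fix lies more than `first_fix_discard_km` from the nest
#' (the bird was already in the countryside when the device switched on).
#' Excursions whose fixes all fall in `artificial` habitat are dropped, as are
#' runs shorter than `min_fixes`. A trip cut off by the end of the tracking
#' day (no closing inside-buffer fix) is kept but flagged `incomplete`.
#'
#' @param fixes Data frame for a single individual with columns `t`
#'   (`POSIXct`, time-ordered), `lat`, `lon`, and optionally `habitat`.
#' @param nest Named numeric vector `c(lat = , lon = )`.
#' @param roosts Optional data frame of roost coordinates (`lat`, `lon`);
#'   their buffers also open/close trips.
#' @param buffer_m Buffer radius around nest/roosts, metres.
#' @param first_fix_discard_km Distance threshold for the first-of-day rule.
#' @param min_fixes Minimum run length retained as a trip.
#' @param tz_offset_h Offset added to UTC timestamps to obtain local time
#'   (used only to delimit tracking days).
#' @param include_bounds When `TRUE`, the bounding inside-buffer fixes are
#'   attached to each trip so that trips start and end at the nest (the trip
#'   definition used for descriptors such as tortuosity); the segmentation
#'   rules themselves always operate on the outside-buffer run.
#' @return A list of trips; each element is the corresponding subset of
#'   `fixes` with attributes `trip_seq` (integer), `incomplete` (logical) and
#'   `fix_rows` (row indices into `fixes`). The list carries a `discarded`
#'   attribute counting runs removed by each rule.
#' @export
segment_trips <- function(fixes, nest, roosts = NULL, buffer_m = 50,
                          first_fix_discard_km = 2, min_fixes = 3,
                          tz_offset_h = 0, include_bounds = FALSE) {
  if (is.null(nest) || any(!is.finite(nest[c("lat", "lon")]))) {
    stop("nest coordinates are required", call. = FALSE)
  }
  if (nrow(fixes) == 0) return(structure(list(), discarded = integer(0)))
  if (is.unsorted(as.numeric(fixes$t), strictly = FALSE)) {
    stop("fixes must be time-ordered", call. = FALSE)
  }
  dist_nest <- haversine_distance(fixes$lat, fixes$lon, nest["lat"], nest["lon"])
  inside <- dist_nest <= buffer_m
  if (!is.null(roosts) && nrow(roosts) > 0) {
    for (r in seq_len(nrow(roosts))) {
      inside <- inside | haversine_distance(fixes$lat, fixes$lon,
                                            roosts$lat[r], roosts$lon[r]) <= buffer_m
    }
  }
  local_day <- as.Date(fixes$t + tz_offset_h * 3600, tz = "UTC")
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  discarded <- c(first_fix_rule = 0L, urban_only = 0L, too_short = 0L)
  trips <- list()
  seq_id <- 0L
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next                     # inside-buffer run
    i1 <- starts[k]; i2 <- ends[k]
    open_ok <- i1 > 1 && local_day[i1 - 1] == local_day[i1]
    if (!open_ok && dist_nest[i1] > first_fix_discard_km * 1000) {
      discarded["first_fix_rule"] <- discarded["first_fix_rule"] + 1L
      next
    }
    if (i2 - i1 + 1 < min_fixes) {
      discarded["too_short"] <- discarded["too_short"] + 1L
      next
    }
    if (!is.null(fixes$habitat) && all(fixes$habitat[i1:i2] == "artificial")) {
      discarded["urban_only"] <- discarded["urban_only"] + 1L
      next
    }
    incomplete <- !(i2 < nrow(fixes) && local_day[i2 + 1] == local_day[i2])
    seq_id <- seq_id + 1L
    j1 <- i1; j2 <- i2
    if (include_bounds) {
      if (open_ok) j1 <- i1 - 1L
      if (!incomplete) j2 <- i2 + 1L
    }
    trip <- fixes[j1:j2, , drop = FALSE]
    rownames(trip) <- NULL
    attr(trip, "trip_seq") <- seq_id
    attr(trip, "incomplete") <- incomplete
    attr(trip, "fix_rows") <- j1:j2
    trips[[seq_id]] <- trip
  }
  structure(trips, discarded = discarded)
}

#' Spatio-temporal descriptors of a foraging trip
#'
#' Duration (h), total path length (km), maximum distance from the nest (km)
#' and tortuosity, the ratio of length to maximum distance. For trips that
#' start and end at the nest buffer the tortuosity is bounded below by 2
#' (out-and-back along the same line).
#'
#' @param trip Data frame of trip fixes (`t`, `lat`, `lon`).
#' @param nest Named numeric vector `c(lat = , lon = )`.
#' @return Named list with `duration_h`, `length_km`, `max_distance_km`,
#'   `tortuosity` (`NA` with a warning when the maximum distance is zero) and
#'   `n_fixes`.
#' @export
trip_descriptors <- function(trip, nest) {
  if (nrow(trip) < 2) stop("trip_descriptors() needs at least 2 fixes", call. = FALSE)
  dur <- as.numeric(difftime(trip$t[nrow(trip)], trip$t[1], units = "hours"))
  i <- seq_len(nrow(trip) - 1)
  len <- sum(haversine_distance(trip$lat[i], trip$lon[i],
                                trip$lat[i + 1], trip$lon[i + 1])) / 1000
  dmax <- max(haversine_distance(trip$lat, trip$lon, nest["lat"], nest["lon"])) / 1000
  tort <- if (dmax > 0) len / dmax else { warning("trip never left the nest: tortuosity undefined"); NA_real_ }
  list(duration_h = dur, length_km = len, max_distance_km = dmax,
       tortuosity = tort, n_fixes = nrow(trip))
}

#' Breeding stage on given dates from a nest-record timeline
#'
#' A date is classified as `incubation` when the nest held only eggs, and as
#' `nestling_rearing` when at least one nestling was present. The most recent
#' record on or before each date is used.
#'
#' @param dates `Date` vector (trip dates).
#' @param nest_records Data frame with columns `date`, `n_eggs`,
#'   `n_nestlings` for one nest.
#' @return Character vector of stages.
#' @export
assign_stage <- function(dates, nest_records) {
  nest_records <- nest_records[order(nest_records$date), , drop = FALSE]
  vapply(dates, function(d) {
    idx <- which(nest_records$date <= d)
    if (length(idx) == 0) stop("no nest record on or before ", d, call. = FALSE)
    rec <- nest_records[max(idx), ]
    if (rec$n_nestlings >= 1) return("nestling_rearing")
    if (rec$n_eggs >= 1) return("incubation")
    stop("nest record for ", d, " has neither eggs nor nestlings", call. = FALSE)
  }, character(1))
}

#' Time spent per habitat class during a trip
#'
#' Proportion of fixes in each of the six habitat classes, computed over
#' non-relocation fixes only (commuting positions do not reflect habitat use).
#'
#' @param habitat Character vector of per-fix habitat codes.
#' @param behaviour Character vector of per-fix behavioural modes.
#' @return Named numeric vector over [HABITAT_CLASSES] summing to 1, or all
#'   `NA` (with a warning) when every fix is relocation.
#' @export
habitat_time <- function(habitat, behaviour) {
  stopifnot(length(habitat) == length(behaviour))
  keep <- behaviour != "relocation"
  out <- stats::setNames(rep(NA_real_, length(HABITAT_CLASSES)), HABITAT_CLASSES)
  if (!any(keep)) {
    warning("all fixes are relocation: habitat proportions undefined")
    return(out)
  }
  tab <- table(factor(habitat[keep], levels = HABITAT_CLASSES))
  out[] <- as.numeric(tab) / sum(tab)
  out
}
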