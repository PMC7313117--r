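nest <- c(lat = 40.666, lon = 16.604)

test_that("haversine distance matches closed forms and is symmetric", {
  expect_equal(haversine_distance(40, 16, 40, 16), 0)
  # one degree of longitude along the equator: R * pi/180
  expect_equal(haversine_distance(0, 0, 0, 1), 6371000 * pi / 180,
               tolerance = 1e-9)
  withr::with_seed(4, {
    a <- cbind(runif(20, -60, 60), runif(20, -180, 180))
    b <- cbind(runif(20, -60, 60), runif(20, -180, 180))
    d_ab <- haversine_distance(a[, 1], a[, 2], b[, 1], b[, 2])
    d_ba <- haversine_distance(b[, 1], b[, 2], a[, 1], a[, 2])
    expect_equal(d_ab, d_ba, tolerance = 1e-12)
    skip_if_not_installed("geosphere")
    d_ref <- geosphere::distHaversine(cbind(a[, 2], a[, 1]),
                                      cbind(b[, 2], b[, 1]), r = 6371000)
    expect_equal(d_ab, d_ref, tolerance = 1e-9)
  })
  expect_error(haversine_distance(91, 0, 0, 0), "invalid coordinates")
})

test_that("step metrics recover speed, heading and turning angle", {
  fx <- line_fixes(6, spacing_m = 600, bearing_deg = 90)
  sm <- step_metrics(fx)
  expect_equal(sm$speed[1:5], rep(10, 5), tolerance = 1e-6)
  expect_equal(sm$turn[2:5], rep(0, 4), tolerance = 1e-6)
  expect_true(all(abs(sm$heading[1:5] - 90) < 0.01))
  # out-and-back: reversal point turns by pi
  out <- line_fixes(4, spacing_m = 500, bearing_deg = 0)
  back <- out[c(3, 2, 1), ]
  back$t <- max(out$t) + (1:3) * 60
  sm2 <- step_metrics(rbind(out, back))
  expect_equal(sm2$turn[4], pi, tolerance = 1e-6)
  dup <- fx; dup$t[3] <- dup$t[2]
  expect_error(step_metrics(dup), "strictly increasing")
  expect_error(step_metrics(fx[1:2, ]), "at least 3")
})

test_that("trip segmentation applies buffer, first-fix and urban rules", {
  at_nest <- function(n, t_start) {
    data.frame(t = t_start + (0:(n - 1)) * 60,
               lat = rep(nest["lat"], n), lon = rep(nest["lon"], n))
  }
  away <- function(n, t_start, dist0 = 500) {
    p <- t(vapply(seq_len(n), function(i) offset_fix(nest, dist0 + i * 300, 0),
                  numeric(2)))
    data.frame(t = t_start + (0:(n - 1)) * 60, lat = p[, 1], lon = p[, 2])
  }
  # all fixes inside the buffer: no trips
  expect_length(segment_trips(at_nest(10, t0_utc), nest), 0)

  # inside, 10 outside, inside: exactly one 10-fix trip
  fx <- rbind(at_nest(1, t0_utc), away(10, t0_utc + 60),
              at_nest(1, t0_utc + 11 * 60))
  trips <- segment_trips(fx, nest)
  expect_length(trips, 1)
  expect_equal(nrow(trips[[1]]), 10)
  expect_false(attr(trips[[1]], "incomplete"))
  # with bounds attached the trip starts and ends at the nest
  trips_b <- segment_trips(fx, nest, include_bounds = TRUE)
  expect_equal(nrow(trips_b[[1]]), 12)

  # first fix of the day 3 km out with no prior inside fix: run discarded
  fx_far <- rbind(away(8, t0_utc, dist0 = 3000), at_nest(2, t0_utc + 8 * 60))
  segs <- segment_trips(fx_far, nest)
  expect_length(segs, 0)
  expect_equal(unname(attr(segs, "discarded")["first_fix_rule"]), 1L)
  # but kept when the first fix is within 2 km
  fx_near <- rbind(away(8, t0_utc, dist0 = 500), at_nest(2, t0_utc + 8 * 60))
  expect_length(segment_trips(fx_near, nest), 1)

  # urban-only excursions are dropped
  fx_urb <- rbind(at_nest(1, t0_utc), away(5, t0_utc + 60),
                  at_nest(1, t0_utc + 6 * 60))
  fx_urb$habitat <- c("artificial", rep("artificial", 5), "artificial")
  segs_u <- segment_trips(fx_urb, nest)
  expect_length(segs_u, 0)
  expect_equal(unname(attr(segs_u, "discarded")["urban_only"]), 1L)

  expect_error(segment_trips(fx, NULL), "nest coordinates")
})

test_that("segmentation is idempotent on its own output", {
  at_nest <- function(n, t_start) {
    data.frame(t = t_start + (0:(n - 1)) * 60,
               lat = rep(nest["lat"], n), lon = rep(nest["lon"], n))
  }
  away <- function(n, t_start) {
    p <- t(vapply(seq_len(n), function(i) offset_fix(nest, 400 + i * 250, i * 100),
                  numeric(2)))
    data.frame(t = t_start + (0:(n - 1)) * 60, lat = p[, 1], lon = p[, 2])
  }
  fx <- rbind(at_nest(2, t0_utc), away(6, t0_utc + 2 * 60),
              at_nest(3, t0_utc + 8 * 60), away(4, t0_utc + 11 * 60),
              at_nest(2, t0_utc + 15 * 60))
  first <- segment_trips(fx, nest, include_bounds = TRUE)
  rebuilt <- do.call(rbind, lapply(first, as.data.frame))
  rebuilt <- rebuilt[order(rebuilt$t), ]
  rebuilt <- rebuilt[!duplicated(rebuilt$t), ]
  second <- segment_trips(rebuilt, nest, include_bounds = TRUE)
  expect_length(second, length(first))
  for (k in seq_along(first)) {
    expect_equal(second[[k]]$t, first[[k]]$t)
  }
})

test_that("trip descriptors give duration, length, range and tortuosity", {
  # straight out 5 km and back along the same line
  out <- t(vapply(1:10, function(i) offset_fix(nest, i * 500, 0), numeric(2)))
  path <- rbind(c(nest["lat"], nest["lon"]), out, out[9:1, ],
                c(nest["lat"], nest["lon"]))
  trip <- data.frame(t = t0_utc + (0:(nrow(path) - 1)) * 180,
                     lat = path[, 1], lon = path[, 2])
  d <- trip_descriptors(trip, nest)
  expect_equal(d$length_km, 10, tolerance = 1e-6)
  expect_equal(d$max_distance_km, 5, tolerance = 1e-6)
  expect_equal(d$tortuosity, 2, tolerance = 1e-6)
  expect_equal(d$duration_h, (nrow(path) - 1) * 180 / 3600, tolerance = 1e-12)

  # nest-cornered unit-km square loop: length 4, range sqrt(2), tort 2*sqrt(2)
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000), c(0, 0))
  pts <- t(apply(sq, 1, function(p) offset_fix(nest, p[2], p[1])))
  trip2 <- data.frame(t = t0_utc + (0:4) * 300, lat = pts[, 1], lon = pts[, 2])
  d2 <- trip_descriptors(trip2, nest)
  expect_equal(d2$length_km, 4, tolerance = 5e-4)
  expect_equal(d2$max_distance_km, sqrt(2), tolerance = 5e-4)
  expect_equal(d2$tortuosity, 2 * sqrt(2), tolerance = 5e-4)

  still <- data.frame(t = t0_utc + (0:3) * 60,
                      lat = rep(nest["lat"], 4), lon = rep(nest["lon"], 4))
  expect_warning(d3 <- trip_descriptors(still, nest), "tortuosity undefined")
  expect_true(is.na(d3$tortuosity))
})

test_that("breeding stage follows the egg/nestling timeline", {
  recs <- data.frame(date = as.Date("2017-06-01") + 0:9,
                     n_eggs = c(rep(4, 5), rep(0, 5)),
                     n_nestlings = c(rep(0, 5), rep(3, 5)))
  expect_equal(assign_stage(as.Date("2017-06-03"), recs), "incubation")
  expect_equal(assign_stage(as.Date("2017-06-08"), recs), "nestling_rearing")
  # mixed content counts as rearing as soon as one nestling is present
  recs2 <- data.frame(date = as.Date("2017-06-01"), n_eggs = 1, n_nestlings = 2)
  expect_equal(assign_stage(as.Date("2017-06-01"), recs2), "nestling_rearing")
  recs3 <- data.frame(date = as.Date("2017-06-01"), n_eggs = 0, n_nestlings = 0)
  expect_error(assign_stage(as.Date("2017-06-01"), recs3), "neither eggs nor")
  expect_error(assign_stage(as.Date("2017-05-01"), recs), "no nest record")
})

test_that("habitat time ignores relocation fixes and sums to one", {
  hab <- c("arable", "arable", "arable", "grassland", "wooded", "wooded")
  beh <- c(rep("perch", 4), "relocation", "relocation")
  p <- habitat_time(hab, beh)
  expect_equal(unname(p["arable"]), 0.75)
  expect_equal(unname(p["grassland"]), 0.25)
  expect_equal(sum(p), 1)
  # adding relocation fixes leaves the proportions unchanged
  p2 <- habitat_time(c(hab, rep("permanent_crop", 10)),
                     c(beh, rep("relocation", 10)))
  expect_equal(p2, p)
  expect_warning(p3 <- habitat_time("arable", "relocation"), "undefined")
  expect_true(all(is.na(p3)))
})
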