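# fixes moving east at the given per-fix speeds (km/h), 10 s cadence
speed_track <- function(speeds, dt = 10) {
  n <- length(speeds)
  x <- cumsum(speeds / 3.6 * dt)
  ll <- unproject_aeqd(x, rep(0, n), c(5.47, 51.44))
  tibble::tibble(
    time = naive_time(as.Date("2021-06-01"), 9 * 3600 + (seq_len(n) - 1) * dt),
    lat = ll[, 2], lon = ll[, 1], ele = 20, speed_kmph = speeds)
}

test_that("still streams produce no trips and short movement is filtered", {
  none <- segment_trips(speed_track(rep(0, 100)))
  expect_equal(nrow(none$trips), 0)
  expect_true(all(none$fixes$trip_role == "stationary"))

  # two moving fixes never open a trip
  short <- segment_trips(speed_track(c(0, 0, 5, 5, 0, 0, 0, 0, 0, 0)))
  expect_equal(nrow(short$trips), 0)
})

test_that("a sustained walk forms one trip with the expected duration", {
  ts <- segment_trips(speed_track(rep(4, 60)))
  expect_equal(nrow(ts$trips), 1)
  expect_equal(ts$trips$duration_s, 590) # first to last fix
  expect_equal(ts$trips$n_fixes, 60L)
  expect_equal(ts$trips$mode, "pedestrian")
  expect_equal(ts$trips$distance_m, 59 * 4 / 3.6 * 10, tolerance = 1e-6)
})

test_that("pauses up to 2 min stay inside a trip; longer spells split it", {
  walk5 <- rep(4, 30)
  one_trip <- segment_trips(speed_track(c(walk5, rep(0, 9), walk5)))
  expect_equal(nrow(one_trip$trips), 1)
  expect_equal(one_trip$trips$n_pauses, 1L)
  expect_equal(nrow(one_trip$pauses), 1)
  expect_equal(one_trip$pauses$duration_s, 80) # span of the 9 still fixes

  two_trips <- segment_trips(speed_track(c(walk5, rep(0, 15), walk5)))
  expect_equal(nrow(two_trips$trips), 2)
  expect_equal(two_trips$trips$n_pauses, c(0L, 0L))
})

test_that("mode classification follows the p90 thresholds", {
  expect_equal(classify_mode(rep(4, 10))$mode, "pedestrian")
  expect_equal(classify_mode(rep(20, 10))$mode, "bicycle")
  expect_equal(classify_mode(rep(40, 10))$mode, "vehicle")
  expect_equal(classify_mode(rep(0.5, 10))$mode, "unclassified")

  cl <- classify_mode(c(rep(5, 8), 40, 40))
  expect_equal(cl$p90_speed_kmph, 40) # type-7 p90 of {5 x8, 40 x2}
  expect_equal(cl$mode, "vehicle")

  expect_error(classify_mode(numeric(0)), "no member speeds")

  # boundary conventions: bounds are lower-inclusive
  expect_equal(classify_mode(rep(10, 5))$mode, "bicycle")
  expect_equal(classify_mode(rep(35, 5))$mode, "vehicle")
  expect_equal(classify_mode(rep(1, 5))$mode, "pedestrian")
})

test_that("the 30 s gap rule discards the whole trip", {
  f <- speed_track(rep(4, 60))
  f$time[31:60] <- f$time[31:60] + 40 # open a 50 s hole mid-trip
  ts <- segment_trips(f)
  expect_equal(nrow(ts$trips), 0)
  expect_equal(unname(ts$dropped[["gap"]]), 1L)
})

test_that("pause fixes are excluded from the p90 speed", {
  # walk at 4 with a pause of zeros: p90 must come from the moving fixes only
  ts <- segment_trips(speed_track(c(rep(4, 30), rep(0, 9), rep(4, 30))))
  expect_equal(ts$trips$p90_speed_kmph, 4)
})

test_that("scaling all speeds up never demotes the mode", {
  withr::with_seed(23, {
    for (i in 1:20) {
      sp <- pmax(0, rnorm(40, runif(1, 2, 30), 3))
      base <- classify_mode(sp)
      rank0 <- match(base$mode, c("unclassified", "pedestrian", "bicycle", "vehicle"))
      for (c_mult in c(1.5, 3, 8)) {
        rank1 <- match(classify_mode(sp * c_mult)$mode,
                       c("unclassified", "pedestrian", "bicycle", "vehicle"))
        expect_gte(rank1, rank0)
      }
    }
  })
})

test_that("segmentation agrees with the brute-force oracle on random streams", {
  withr::with_seed(1234, {
    for (i in 1:150) {
      expect_trips_equal_oracle(rand_gps_stream())
    }
  })
})

test_that("every cleaned fix is either in exactly one trip or stationary", {
  withr::with_seed(55, {
    f <- rand_gps_stream()
    ts <- segment_trips(f)
    in_trip <- !is.na(ts$fixes$trip_id)
    expect_equal(sum(in_trip) + sum(ts$fixes$trip_role == "stationary"), nrow(f))
    if (nrow(ts$trips) > 0) {
      expect_equal(sort(unique(ts$fixes$trip_id[in_trip])), ts$trips$trip_id)
    }
  })
})

test_that("truncating a surviving trip never creates an earlier trip", {
  withr::with_seed(77, {
    for (i in 1:25) {
      f <- rand_gps_stream()
      ts <- segment_trips(f)
      if (nrow(ts$trips) == 0) next
      cut <- nrow(f) - sample(1:10, 1)
      if (cut < 5) next
      ts2 <- segment_trips(f[1:cut, ])
      if (nrow(ts2$trips) > 0) {
        expect_gte(min(as.numeric(ts2$trips$start_time)),
                   min(as.numeric(ts$trips$start_time)))
      }
    }
  })
})
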