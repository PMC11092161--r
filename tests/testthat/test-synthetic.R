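test_that("a generated day tiles 06:00-22:00 with contiguous segments", {
  coh <- generate_cohort(1, 1, seed = 7, config = noiseless_config())
  expect_equal(nrow(coh$profiles), 1)
  expect_equal(nrow(coh$days), 1)
  truth <- coh$days$truth[[1]]
  expect_equal(sum(truth$segments$n_epochs), 16 * 360)
  expect_equal(nrow(truth$epochs), 16 * 360)
  # segments are contiguous, ordered, non-overlapping
  expect_equal(truth$segments$start_time[-1],
               truth$segments$end_time[-nrow(truth$segments)])
  expect_equal(truth$segments$start_time[1],
               naive_time(coh$days$date[1], 6 * 3600))
  # home and school are distinct
  p <- coh$profiles
  expect_gt(haversine_m(p$home_lon, p$home_lat, p$school_lon, p$school_lat), 100)
})

test_that("generation and emission are deterministic given the seed", {
  a <- generate_cohort(2, 2, seed = 7)
  b <- generate_cohort(2, 2, seed = 7)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$days$truth[[3]]$epochs, b$days$truth[[3]]$epochs)
  c <- generate_cohort(2, 2, seed = 8)
  expect_false(identical(a$profiles$home_lon, c$profiles$home_lon))

  s1 <- emit_sensors(a$days$truth[[1]], seed = 5)
  s2 <- emit_sensors(a$days$truth[[1]], seed = 5)
  expect_identical(s1, s2)
  s3 <- emit_sensors(a$days$truth[[1]], seed = 6)
  expect_false(identical(s1$fixes$lat, s3$fixes$lat))
})

test_that("day types follow the calendar and a week has 2/7 weekend days", {
  coh <- generate_cohort(20, 7, seed = 1, config = noiseless_config())
  expect_equal(nrow(coh$days), 140)
  expect_equal(mean(coh$days$day_type == "weekend"), 2 / 7)
  iso <- lubridate::wday(coh$days$date, week_start = 1)
  expect_identical(as.character(coh$days$day_type),
                   ifelse(iso >= 6, "weekend", "weekday"))
})

test_that("invalid generator arguments are rejected", {
  expect_error(generate_cohort(0, 1), "positive integer")
  expect_error(generate_cohort(1, 0), "positive integer")
  expect_error(sim_config(gps_dropout_p = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(mode_probs = c(pedestrian = 0.5, bicycle = 0.2, vehicle = 0.1)),
               "sum to 1")
  expect_error(emit_sensors(list(segments = NULL)), "no segments")
})

test_that("expected minutes conserve simulated weartime exactly", {
  coh <- small_noisy_cohort()
  for (row in c(1, 4, 8)) {
    truth <- coh$days$truth[[row]]
    gt <- ground_truth_summary(truth, true_anchors(coh, coh$days$child_id[row]),
                               coh$public_spaces, coh$schedule)
    worn_min <- sum(truth$epochs$worn) * 10 / 60
    expect_equal(gt$weartime_min[gt$dimension == "total"], worn_min)
    expect_equal(sum(gt$weartime_min[gt$dimension == "context"]), worn_min)
    expect_equal(sum(gt$weartime_min[gt$dimension == "trip"]), worn_min)
  }
})

test_that("zero-noise emission reproduces the itinerary exactly", {
  coh <- small_noiseless_cohort()
  truth <- coh$days$truth[[1]]
  sens <- emit_sensors(truth, seed = 3, config = coh$config)
  # fixes lie exactly on the itinerary path
  expect_equal(sens$fixes$lon, truth$epochs$lon, tolerance = 1e-9)
  expect_equal(sens$fixes$lat, truth$epochs$lat, tolerance = 1e-9)
  expect_equal(sens$fixes$speed_kmph, truth$epochs$speed_kmph)
  # derived haversine speeds match the logged target within discretization
  moving <- truth$epochs$state == "trip"
  d <- haversine_m(sens$fixes$lon[-1], sens$fixes$lat[-1],
                   sens$fixes$lon[-nrow(sens$fixes)], sens$fixes$lat[-nrow(sens$fixes)])
  derived <- d / 10 * 3.6
  expect_equal(derived[moving[-1]], truth$epochs$speed_kmph[-1][moving[-1]],
               tolerance = 1e-6)
  # counts are exactly invertible to the simulated intensity
  cls <- classify_intensity(
    dplyr::mutate(sens$epochs, wear = truth$epochs$worn),
    scale_cutpoints(cutpoint_set(), 10), epoch_len_s = 10)
  expect_identical(as.character(cls$intensity), as.character(truth$epochs$intensity))
})

test_that("non-wear episodes emit zero counts and low-variability summaries", {
  cfg <- noiseless_config(nonwear_episode_p = 1, nonwear_dur_min = c(75, 75))
  coh <- generate_cohort(1, 1, seed = 21, config = cfg) # a Tuesday
  truth <- coh$days$truth[[1]]
  nw <- !truth$epochs$worn
  expect_equal(sum(nw) * 10 / 60, 75) # the configured episode length
  sens <- emit_sensors(truth, seed = 2, config = cfg)
  expect_true(all(sens$epochs$counts[nw] == 0))
  expect_true(all(sens$epochs$raw_sd_mg[nw] < 13))
  expect_true(all(sens$epochs$raw_range_mg[nw] < 50))
  # the detector flags the episode interior and never a worn epoch
  det <- detect_nonwear(sens$epochs)
  expect_gt(sum(!det$wear), 0)
  expect_true(all(nw[!det$wear]))
})

test_that("a noisy 600 m pedestrian trip keeps its path length", {
  # Monte-Carlo over 100 seeds with AR(1) position noise (sd 5 m): the summed
  # haversine path length stays within [570, 630] m of the 600 m ground truth
  # (empirical range of this simulation: 575-609 m)
  cfg <- sim_config(gps_noise_sd_m = 5, gps_dropout_p = 0, speed_noise_sd_kmph = 0)
  n_ep <- 54
  x <- (1:n_ep) / n_ep * 600
  ll <- unproject_aeqd(x, rep(0, n_ep), c(5.47, 51.44))
  truth <- list(
    epochs = tibble::tibble(
      time = naive_time(as.Date("2021-06-01"), 9 * 3600 + (0:(n_ep - 1)) * 10),
      state = "trip", trip_mode = "pedestrian", speed_kmph = 4,
      lon = ll[, 1], lat = ll[, 2], worn = TRUE,
      intensity = factor("LPA", levels = intensity_levels())),
    segments = tibble::tibble(state = "trip", n_epochs = n_ep))
  sums <- sapply(1:100, function(s) {
    fx <- emit_sensors(truth, seed = s, config = cfg)$fixes
    sum(haversine_m(fx$lon[-nrow(fx)], fx$lat[-nrow(fx)], fx$lon[-1], fx$lat[-1]))
  })
  expect_true(all(sums >= 570 & sums <= 630))
  expect_equal(mean(sums), 600, tolerance = 0.05)
})

test_that("the ground-truth oracle puts a stay-at-home day entirely at home", {
  coh <- small_noiseless_cohort()
  prof <- coh$profiles[1, ]
  n <- 16 * 360
  truth <- list(
    epochs = tibble::tibble(
      time = naive_time(as.Date("2021-06-01"), 6 * 3600 + (0:(n - 1)) * 10),
      state = "home_indoor", trip_mode = NA_character_, speed_kmph = 0,
      lon = prof$home_lon, lat = prof$home_lat, worn = TRUE,
      intensity = factor("SB", levels = intensity_levels())),
    segments = tibble::tibble(state = "home_indoor", n_epochs = n))
  gt <- ground_truth_summary(truth, true_anchors(coh, prof$child_id))
  ctx <- gt[gt$dimension == "context", ]
  expect_equal(ctx$weartime_min[ctx$level == "at_home"], 960)
  expect_equal(sum(ctx$weartime_min[ctx$level != "at_home"]), 0)
  expect_equal(gt$mvpa_min[gt$dimension == "total"], 0)
})

test_that("expected trips satisfy the survivable-trip invariants", {
  coh <- small_noiseless_cohort()
  trips <- dplyr::bind_rows(lapply(coh$days$truth, function(t) t$trips))
  expect_gt(nrow(trips), 0)
  expect_true(all(trips$distance_m >= 100))
  expect_true(all(trips$duration_s >= 60))
  v <- trips$distance_m / trips$duration_s * 3.6
  expect_true(all(v[trips$mode == "pedestrian"] < 10 & v[trips$mode == "pedestrian"] >= 1))
  expect_true(all(v[trips$mode == "bicycle"] >= 10 & v[trips$mode == "bicycle"] < 25))
  expect_true(all(v[trips$mode == "vehicle"] > 25))
})
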