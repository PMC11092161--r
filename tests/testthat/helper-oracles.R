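# Independent brute-force oracles. These re-implement the published rules in
# a deliberately different style from the package internals (per-fix state
# machines and per-block loops instead of run-length algebra and interval
# search), so agreement is evidence about the rules, not shared code.

# --- trip segmentation oracle ------------------------------------------------

oracle_segment_trips <- function(fixes, start_speed = 1, start_run = 3,
                                 pause_max = 120, gap_max = 30,
                                 min_dist = 100, min_dur = 60,
                                 bounds = mode_bounds()) {
  n <- nrow(fixes)
  t <- as.numeric(fixes$time)
  v <- fixes$speed_kmph
  moving <- !is.na(v) & v >= start_speed

  # walk fix by fix, collecting candidate trips as index ranges
  candidates <- list()
  i <- 1L
  while (i <= n - start_run + 1L) {
    if (!all(moving[i:(i + start_run - 1L)])) { i <- i + 1L; next }
    s <- i                       # trip opens here
    last_move <- i
    j <- i + 1L
    repeat {
      if (j > n) break
      if (moving[j]) { last_move <- j; j <- j + 1L; next }
      # still spell: find where movement resumes
      m <- j
      while (m <= n && !moving[m]) m <- m + 1L
      if (m > n) break                       # recording ends during the spell
      spell <- t[m - 1L] - t[j]              # span of the still fixes
      if (spell > pause_max) break           # trip ends before this spell
      j <- m                                 # pause absorbed, trip continues
    }
    candidates[[length(candidates) + 1L]] <- c(s, last_move)
    i <- if (j > n) n + 1L else j            # resume scanning after the spell
  }

  hav <- function(k1, k2) haversine_m(fixes$lon[k1], fixes$lat[k1],
                                      fixes$lon[k2], fixes$lat[k2])
  trips <- list()
  trip_id <- rep(NA_integer_, n)
  role <- rep("stationary", n)
  dropped <- c(distance = 0L, duration = 0L, gap = 0L)
  id <- 0L
  for (cand in candidates) {
    idx <- cand[1]:cand[2]
    dist <- sum(hav(idx[-length(idx)], idx[-1]))
    dur <- t[cand[2]] - t[cand[1]]
    if (dist < min_dist) { dropped[["distance"]] <- dropped[["distance"]] + 1L; next }
    if (dur < min_dur) { dropped[["duration"]] <- dropped[["duration"]] + 1L; next }
    if (any(diff(t[idx]) > gap_max)) { dropped[["gap"]] <- dropped[["gap"]] + 1L; next }
    id <- id + 1L
    trip_id[idx] <- id
    role[idx] <- ifelse(moving[idx], "moving", "pause")
    p90 <- unname(quantile(v[idx][moving[idx]], 0.9, type = 7))
    mode <- if (p90 < bounds$walk_min) "unclassified"
            else if (p90 < bounds$bike_min) "pedestrian"
            else if (p90 < bounds$vehicle_min) "bicycle"
            else "vehicle"
    still_in <- rle(moving[idx])
    trips[[id]] <- data.frame(
      trip_id = id, start = fixes$time[cand[1]], end = fixes$time[cand[2]],
      n_fixes = length(idx), distance_m = dist, duration_s = dur,
      p90_speed_kmph = p90, mode = mode,
      n_pauses = sum(!still_in$values))
  }
  list(trips = if (id > 0) do.call(rbind, trips) else NULL,
       trip_id = trip_id, role = role, dropped = dropped)
}

expect_trips_equal_oracle <- function(fixes, ...) {
  got <- segment_trips(fixes, ...)
  exp <- oracle_segment_trips(fixes)
  expect_identical(got$fixes$trip_id, exp$trip_id)
  expect_identical(got$fixes$trip_role, exp$role)
  expect_identical(unname(got$dropped), unname(exp$dropped))
  expect_equal(nrow(got$trips), if (is.null(exp$trips)) 0L else nrow(exp$trips))
  if (!is.null(exp$trips)) {
    expect_equal(got$trips$distance_m, exp$trips$distance_m)
    expect_equal(got$trips$duration_s, exp$trips$duration_s)
    expect_equal(got$trips$p90_speed_kmph, exp$trips$p90_speed_kmph)
    expect_identical(got$trips$mode, exp$trips$mode)
    expect_identical(got$trips$n_pauses, exp$trips$n_pauses)
  }
  invisible(identical(got$fixes$trip_id, exp$trip_id) &&
              identical(got$fixes$trip_role, exp$role))
}

# random GPS stream with mixed regimes, gaps and still spells
rand_gps_stream <- function(n_max = 200) {
  n <- sample(10:n_max, 1)
  dt <- ifelse(runif(n) < 0.12, sample(c(15, 25, 35, 60, 150), n, replace = TRUE), 10)
  t0 <- as.POSIXct("2021-06-01 08:00:00", tz = "UTC")
  time <- t0 + cumsum(dt)
  regimes <- list(c(0, 0.4), c(4, 1.2), c(15, 4), c(45, 10))
  v <- numeric(0)
  while (length(v) < n) {
    r <- regimes[[sample(4, 1, prob = c(0.4, 0.3, 0.2, 0.1))]]
    len <- sample(1:12, 1)
    v <- c(v, pmax(0, rnorm(len, r[1], r[2])))
  }
  v <- v[1:n]
  pos_scale <- sample(c(1, 0.05), 1, prob = c(0.8, 0.2)) # sometimes going nowhere
  x <- cumsum(v / 3.6 * dt) * pos_scale
  ll <- unproject_aeqd(x, rep(0, n), c(5.47, 51.44))
  tibble::tibble(time = time, lat = ll[, 2], lon = ll[, 1],
                 ele = 20, speed_kmph = v)
}

# --- non-wear oracle ---------------------------------------------------------

oracle_nonwear <- function(epochs, block_min = 15, window_min = 60,
                           sd_thresh = 13, range_thresh = 50,
                           min_window_min = 30, epoch_len_s = 10) {
  t <- as.numeric(epochs$time)
  wear <- rep(TRUE, nrow(epochs))
  for (b in unique(floor(t / (block_min * 60)))) {
    center <- b * block_min * 60 + block_min * 30
    in_win <- t >= center - window_min * 30 & t < center + window_min * 30
    if (sum(in_win) * epoch_len_s < min_window_min * 60) next
    win_sd <- sqrt(mean(epochs$raw_sd_mg[in_win]^2))
    win_range <- max(epochs$raw_range_mg[in_win])
    if (win_sd < sd_thresh && win_range < range_thresh) {
      wear[floor(t / (block_min * 60)) == b] <- FALSE
    }
  }
  wear
}

# random day signal alternating worn / unworn / borderline variability
rand_day_signal <- function(date = as.Date("2021-06-01"), hours = 16) {
  n <- hours * 360
  time <- naive_time(date, 6 * 3600 + (seq_len(n) - 1) * 10)
  sd_v <- numeric(0); rng_v <- numeric(0)
  specs <- list(worn = c(20, 120, 60, 350), still = c(0, 5, 0, 12),
                border = c(5, 20, 30, 70))
  while (length(sd_v) < n) {
    s <- specs[[sample(3, 1, prob = c(0.5, 0.3, 0.2))]]
    len <- sample(30:720, 1)
    sd_v <- c(sd_v, runif(len, s[1], s[2]))
    rng_v <- c(rng_v, runif(len, s[3], s[4]))
  }
  tibble::tibble(time = time, counts = 0L,
                 raw_sd_mg = sd_v[1:n], raw_range_mg = rng_v[1:n])
}

naive_time <- actispace:::naive_time
hm_to_secs <- actispace:::hm_to_secs
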