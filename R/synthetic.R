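#' Settings for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline targets: suburban Dutch
#' school catchments, six measurement days containing a weekend, 10 s epochs
#' recorded 06:00-22:00, escorted school trips, short sporadic MVPA bursts,
#' autocorrelated GPS noise with sporadic dropout, delayed weekend wear and
#' occasional water-activity non-wear episodes. All knobs are exposed so the
#' noiseless limits used in validation are reachable by configuration.
#'
#' @param center_lon,center_lat study-area centre (degrees WGS84)
#' @param n_schools,school_spacing_m number and spacing of schools
#' @param start_date first measurement day (a Tuesday by default, so six
#'   consecutive days contain both weekend days)
#' @param home_school_min_m,home_school_max_m home distance range from school
#' @param postal_offset_max_m postal-code centroid offset from the true home
#'   (distance uniform on 0..max)
#' @param gps_noise_sd_m stationary sd of GPS position noise per axis
#' @param gps_noise_rho lag-one autocorrelation of the position noise (GPS
#'   error drifts rather than jitters white)
#' @param gps_dropout_p i.i.d. per-fix dropout probability
#' @param speed_noise_sd_kmph sd of logged-speed noise
#' @param mode_probs trip-mode probabilities (renormalized over modes
#'   feasible for the trip distance)
#' @param mode_speeds_kmph cruise speed per mode
#' @param mode_min_dist_m minimum trip distance for a mode to be considered
#'   (keeps every simulated trip above the distance/duration trip filters)
#' @param burst_rate_per_h MVPA-burst arrival rate per state
#' @param burst_mean_s mean burst duration
#' @param burst_profile,base_profiles,trip_profiles per-epoch intensity
#'   distributions inside bursts, outside bursts per state, and during trips
#'   per mode
#' @param nonwear_episode_p probability of a weekday evening non-wear episode
#'   (e.g. swimming lesson, device left at home)
#' @param nonwear_dur_min episode duration range, minutes
#' @param weekend_delayed_wear,weekend_wake delayed weartime on weekend
#'   mornings (device not worn before `weekend_wake`)
#' @param p_weekday_outing probability of an after-school public-space visit
#' @param weekend_outing_other_p probability the weekend outing targets a
#'   non-public-space location instead of a park/playground/sports terrain
#' @param weekend_second_outing_p probability of a second weekend outing in
#'   the afternoon
#' @param school_start,school_bell,wednesday_bell,friday_bell school schedule
#' @param epoch_len_s epoch and GPS logging cadence, seconds
#' @param sed_max,mod_min,vig_min,reference_epoch_s intensity cut-points used
#'   to emit counts (counts are drawn uniformly within the class interval, so
#'   classification is exactly invertible under zero noise)
#' @param worn_raw_sd_mg,worn_raw_range_mg,nonworn_raw_sd_mg,nonworn_raw_range_mg
#'   uniform ranges for per-epoch raw-signal summaries
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(center_lon = 5.47, center_lat = 51.44,
                       n_schools = 2, school_spacing_m = 2500,
                       start_date = "2021-06-01",
                       home_school_min_m = 150, home_school_max_m = 1200,
                       postal_offset_max_m = 100,
                       gps_noise_sd_m = 10, gps_noise_rho = 0.95,
                       gps_dropout_p = 0.02, speed_noise_sd_kmph = 0.3,
                       mode_probs = c(pedestrian = 0.7, bicycle = 0.2, vehicle = 0.1),
                       mode_speeds_kmph = c(pedestrian = 4, bicycle = 15, vehicle = 40),
                       mode_min_dist_m = c(pedestrian = 0, bicycle = 300, vehicle = 800),
                       burst_rate_per_h = c(home_indoor = 1, home_yard = 8, school = 8,
                                            public_space = 10, other_location = 5),
                       burst_mean_s = 45,
                       burst_profile = c(SB = 0, LPA = 0, MPA = 0.7, VPA = 0.3),
                       base_profiles = list(
                         home_indoor = c(SB = 0.75, LPA = 0.25, MPA = 0, VPA = 0),
                         home_yard = c(SB = 0.35, LPA = 0.65, MPA = 0, VPA = 0),
                         school = c(SB = 0.55, LPA = 0.45, MPA = 0, VPA = 0),
                         public_space = c(SB = 0.30, LPA = 0.70, MPA = 0, VPA = 0),
                         other_location = c(SB = 0.60, LPA = 0.40, MPA = 0, VPA = 0)),
                       trip_profiles = list(
                         pedestrian = c(SB = 0.20, LPA = 0.55, MPA = 0.20, VPA = 0.05),
                         bicycle = c(SB = 0.30, LPA = 0.55, MPA = 0.13, VPA = 0.02),
                         vehicle = c(SB = 0.85, LPA = 0.15, MPA = 0, VPA = 0)),
                       nonwear_episode_p = 0.25, nonwear_dur_min = c(45, 75),
                       weekend_delayed_wear = TRUE, weekend_wake = "08:30",
                       p_weekday_outing = 0.5, weekend_outing_other_p = 0.5,
                       weekend_second_outing_p = 0.6,
                       school_start = "08:30", school_bell = "14:30",
                       wednesday_bell = "12:15", friday_bell = NULL,
                       epoch_len_s = 10,
                       sed_max = 25, mod_min = 574, vig_min = 1003,
                       reference_epoch_s = 15,
                       worn_raw_sd_mg = c(25, 120), worn_raw_range_mg = c(80, 350),
                       nonworn_raw_sd_mg = c(0.2, 3), nonworn_raw_range_mg = c(0.5, 8)) {
  cfg <- as.list(environment())
  probs <- c(cfg$mode_probs, cfg$gps_dropout_p, cfg$nonwear_episode_p,
             cfg$p_weekday_outing, cfg$weekend_outing_other_p,
             cfg$weekend_second_outing_p, cfg$burst_profile,
             unlist(cfg$base_profiles), unlist(cfg$trip_profiles), cfg$gps_noise_rho)
  if (any(probs < 0 | probs > 1)) {
    abort("sim_config: all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$mode_probs) - 1) > 1e-9) abort("mode_probs must sum to 1")
  if (cfg$gps_noise_sd_m < 0 || cfg$speed_noise_sd_kmph < 0) {
    abort("noise standard deviations must be nonnegative")
  }
  structure(cfg, class = "sim_config")
}

sim_schedule <- function(config) {
  school_schedule(config$school_start, config$school_bell,
                  config$wednesday_bell, config$friday_bell)
}

rand_point_around <- function(center, min_m, max_m) {
  d <- runif(1, min_m, max_m)
  b <- runif(1, 0, 360)
  p <- dest_point(center[1], center[2], b, d)
  c(p[1, 1], p[1, 2])
}

sample_intensity <- function(n, profile) {
  if (n == 0) return(character(0))
  sample(names(profile), n, replace = TRUE, prob = profile)
}

# Poisson-arrival MVPA bursts with geometric durations, realized per segment
burst_mask <- function(n, rate_per_h, mean_s, epoch_len_s) {
  if (n == 0 || rate_per_h == 0) return(logical(n))
  p_start <- rate_per_h * epoch_len_s / 3600
  starts <- which(runif(n) < p_start)
  mask <- logical(n)
  if (length(starts)) {
    lens <- 1L + rgeom(length(starts), pmin(1, epoch_len_s / mean_s))
    for (k in seq_along(starts)) {
      mask[starts[k]:min(n, starts[k] + lens[k] - 1L)] <- TRUE
    }
  }
  mask
}

seg_stationary <- function(state, n_ep, point, worn = TRUE) {
  list(state = state, n_ep = as.integer(n_ep), mode = NA_character_,
       speed_kmph = 0, from = point, to = point, worn = worn)
}

seg_trip <- function(from, to, config, mode = NULL) {
  d <- haversine_m(from[1], from[2], to[1], to[2])
  feas <- names(config$mode_probs)[d >= config$mode_min_dist_m[names(config$mode_probs)]]
  if (is.null(mode)) {
    pr <- config$mode_probs[feas]
    mode <- sample(feas, 1, prob = pr / sum(pr))
  }
  v_mps <- config$mode_speeds_kmph[[mode]] / 3.6
  n_ep <- max(3L, as.integer(ceiling(d / v_mps / config$epoch_len_s)))
  list(state = "trip", n_ep = n_ep, mode = mode,
       speed_kmph = d / (n_ep * config$epoch_len_s) * 3.6,
       from = from, to = to, worn = TRUE)
}

# Build the ground-truth epoch grid for one child-day. Segments tile
# 06:00-22:00 exactly; every duration is a whole number of epochs.
build_truth_day <- function(profile, date, day_type, config, destinations) {
  len <- config$epoch_len_s
  day_start <- 6 * 3600
  n_total <- as.integer((22 - 6) * 3600 / len)
  home <- c(profile$home_lon, profile$home_lat)
  yard <- c(profile$yard_lon, profile$yard_lat)
  school <- c(profile$school_lon, profile$school_lat)
  other <- c(profile$other_lon, profile$other_lat)
  segs <- list()
  used <- 0L
  add <- function(seg) {
    if (seg$n_ep > 0) segs[[length(segs) + 1L]] <<- seg
    used <<- used + max(0L, seg$n_ep)
  }
  ep_of <- function(secs) as.integer((secs - day_start) / len)
  rmin <- function(lo, hi) as.integer(round(runif(1, lo, hi))) # whole minutes

  outing <- function(at_point) {
    # choose an outing destination and return a list of segments, or NULL
    pub_ok <- destinations[
      haversine_m(destinations$lon, destinations$lat, home[1], home[2]) >= 200, ,
      drop = FALSE]
    use_other <- runif(1) < config$weekend_outing_other_p || nrow(pub_ok) == 0
    if (day_type == "weekday") use_other <- FALSE
    if (use_other) {
      dest <- other; state <- "other_location"
    } else {
      if (nrow(pub_ok) == 0) return(NULL)
      i <- sample.int(nrow(pub_ok), 1)
      dest <- c(pub_ok$lon[i], pub_ok$lat[i]); state <- "public_space"
    }
    stay_ep <- rmin(if (day_type == "weekday") 45 else 60,
                    if (day_type == "weekday") 75 else 120) * 60 / len
    t1 <- seg_trip(at_point, dest, config)
    t2 <- seg_trip(dest, at_point, config)
    list(t1, seg_stationary(state, stay_ep, dest), t2)
  }

  if (day_type == "weekday") {
    sched <- sim_schedule(config)
    wd <- lubridate::wday(date, week_start = 1)
    start_s <- sched$start_s[sched$weekday == wd]
    bell_s <- sched$bell_s[sched$weekday == wd]
    mode_day <- {
      d <- haversine_m(home[1], home[2], school[1], school[2])
      feas <- names(config$mode_probs)[d >= config$mode_min_dist_m[names(config$mode_probs)]]
      pr <- config$mode_probs[feas]
      sample(feas, 1, prob = pr / sum(pr))
    }
    trip1 <- seg_trip(home, school, config, mode = mode_day)
    arrive_ep <- ep_of(start_s - 300)
    dep_ep <- arrive_ep - trip1$n_ep
    add(seg_stationary("home_indoor", dep_ep, home))
    add(trip1)
    add(seg_stationary("school", ep_of(bell_s) - arrive_ep, school))
    trip2 <- seg_trip(school, home, config, mode = mode_day)
    add(trip2)
    add(seg_stationary("home_indoor", rmin(15, 45) * 60 / len, home))
    if (runif(1) < config$p_weekday_outing) {
      out <- outing(home)
      if (!is.null(out)) for (s in out) add(s)
    } else {
      add(seg_stationary("home_yard", rmin(30, 60) * 60 / len, yard))
    }
    # evening at home, with an optional non-wear episode ending by 21:30
    if (runif(1) < config$nonwear_episode_p) {
      dur_ep <- rmin(config$nonwear_dur_min[1], config$nonwear_dur_min[2]) * 60 / len
      nw_end <- ep_of(21.5 * 3600)
      nw_start <- max(used, nw_end - dur_ep)
      add(seg_stationary("home_indoor", nw_start - used, home))
      add(seg_stationary("home_indoor", nw_end - nw_start, home, worn = FALSE))
    }
    add(seg_stationary("home_indoor", n_total - used, home))
  } else {
    if (config$weekend_delayed_wear) {
      add(seg_stationary("home_indoor", ep_of(hm_to_secs(config$weekend_wake)), home,
                         worn = FALSE))
    }
    dep_ep <- ep_of(10 * 3600) + rmin(0, 60) * 60 / len
    add(seg_stationary("home_indoor", dep_ep - used, home))
    out <- outing(home)
    if (!is.null(out)) for (s in out) add(s)
    add(seg_stationary("home_indoor", rmin(15, 45) * 60 / len, home))
    add(seg_stationary("home_yard", rmin(60, 120) * 60 / len, yard))
    if (runif(1) < config$weekend_second_outing_p) {
      out2 <- outing(home)
      if (!is.null(out2)) for (s in out2) add(s)
    }
    add(seg_stationary("home_indoor", n_total - used, home))
  }

  # realize the epoch grid
  time <- naive_time(date, day_start + (seq_len(n_total) - 1L) * len)
  state <- character(n_total); worn <- logical(n_total)
  mode <- rep(NA_character_, n_total); speed <- numeric(n_total)
  lon <- numeric(n_total); lat <- numeric(n_total)
  intensity <- rep(NA_character_, n_total)
  pos <- 0L
  seg_rows <- list()
  trip_rows <- list()
  for (seg in segs) {
    idx <- pos + seq_len(seg$n_ep)
    pos <- pos + seg$n_ep
    state[idx] <- seg$state
    worn[idx] <- seg$worn
    if (seg$state == "trip") {
      mode[idx] <- seg$mode
      speed[idx] <- seg$speed_kmph
      path <- gc_path_points(seg$from, seg$to, seg$n_ep)
      lon[idx] <- path[, 1]; lat[idx] <- path[, 2]
      intensity[idx] <- sample_intensity(seg$n_ep, config$trip_profiles[[seg$mode]])
      trip_rows[[length(trip_rows) + 1L]] <- tibble(
        mode = seg$mode,
        distance_m = haversine_m(seg$from[1], seg$from[2], seg$to[1], seg$to[2]),
        duration_s = seg$n_ep * len,
        start_time = time[idx[1]], end_time = time[idx[length(idx)]])
    } else {
      lon[idx] <- seg$from[1]; lat[idx] <- seg$from[2]
      if (seg$worn) {
        mask <- burst_mask(seg$n_ep, config$burst_rate_per_h[[seg$state]],
                           config$burst_mean_s, len)
        intensity[idx[mask]] <- sample_intensity(sum(mask), config$burst_profile)
        intensity[idx[!mask]] <- sample_intensity(sum(!mask),
                                                  config$base_profiles[[seg$state]])
      }
    }
    seg_rows[[length(seg_rows) + 1L]] <- tibble(
      state = seg$state, trip_mode = seg$mode, n_epochs = seg$n_ep,
      start_time = time[idx[1]], end_time = time[idx[length(idx)]] + len,
      worn = seg$worn)
  }
  stopifnot(pos == n_total)
  list(
    epochs = tibble(time = time, state = state, trip_mode = mode,
                    speed_kmph = speed, lon = lon, lat = lat, worn = worn,
                    intensity = factor(intensity, levels = intensity_levels())),
    segments = list_rbind(seg_rows),
    trips = if (length(trip_rows)) list_rbind(trip_rows) else
      tibble(mode = character(), distance_m = numeric(), duration_s = numeric(),
             start_time = as.POSIXct(character(), tz = "UTC"),
             end_time = as.POSIXct(character(), tz = "UTC")))
}

#' Generate a ground-truth-labelled synthetic cohort
#'
#' Lays out schools with parcel polygons and nearby public spaces, places
#' children's homes 150-1200 m from their school with a postal-code centroid
#' offset, and simulates per-day itineraries (escorted school trips on
#' weekdays, outings, yard play, MVPA bursts, delayed weekend wear and
#' non-wear episodes) as ground-truth epoch grids. Deterministic given
#' `(seed, config)`.
#'
#' @param n_children,n_days cohort size; days are consecutive calendar days
#'   from `config$start_date`
#' @param seed integer RNG seed
#' @param config a [sim_config()]
#' @return a `synthetic_cohort`: list with `profiles`, `schools`,
#'   `public_spaces` (a [polygon_set()]), `schedule`, `days` (one row per
#'   child-day with a `truth` list column), `config`, `seed`
#' @export
generate_cohort <- function(n_children, n_days = 6, seed = 1, config = sim_config()) {
  if (!is.numeric(n_children) || n_children < 1 || n_children != round(n_children)) {
    abort("n_children must be a positive integer")
  }
  if (!is.numeric(n_days) || n_days < 1 || n_days != round(n_days)) {
    abort("n_days must be a positive integer")
  }
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), {
    center <- c(config$center_lon, config$center_lat)
    schools <- map(seq_len(config$n_schools), function(s) {
      pt <- if (s == 1) center else {
        p <- dest_point(center[1], center[2], 360 * (s - 1) / config$n_schools,
                        config$school_spacing_m)
        c(p[1, 1], p[1, 2])
      }
      tibble(school_id = sprintf("s%02d", s), lon = pt[1], lat = pt[2],
             polygon = list(list(rect_polygon(pt, 60))))
    }) |> list_rbind()

    pub_rows <- map(seq_len(nrow(schools)), function(s) {
      pt <- c(schools$lon[s], schools$lat[s])
      specs <- list(park = c(250, 500, 80), playground = c(200, 400, 30),
                    sports_terrain = c(300, 600, 60))
      map(names(specs), function(lab) {
        ctr <- rand_point_around(pt, specs[[lab]][1], specs[[lab]][2])
        tibble(label = lab, school_id = schools$school_id[s],
               lon = ctr[1], lat = ctr[2],
               rings = list(list(rect_polygon(ctr, specs[[lab]][3]))))
      }) |> list_rbind()
    }) |> list_rbind()

    profiles <- map(seq_len(n_children), function(i) {
      s <- ((i - 1) %% config$n_schools) + 1
      sp <- c(schools$lon[s], schools$lat[s])
      home <- rand_point_around(sp, config$home_school_min_m, config$home_school_max_m)
      yard <- rand_point_around(home, 25, 35)
      postal <- rand_point_around(home, 0, config$postal_offset_max_m)
      other <- rand_point_around(home, 900, 2000)
      tibble(child_id = sprintf("c%03d", i), school_id = schools$school_id[s],
             home_lon = home[1], home_lat = home[2],
             yard_lon = yard[1], yard_lat = yard[2],
             postal_lon = postal[1], postal_lat = postal[2],
             other_lon = other[1], other_lat = other[2],
             school_lon = sp[1], school_lat = sp[2])
    }) |> list_rbind()

    dates <- as.Date(config$start_date) + seq_len(n_days) - 1
    days <- map(seq_len(n_children), function(i) {
      prof <- profiles[i, ]
      dests <- pub_rows[pub_rows$school_id == prof$school_id,
                        c("label", "lon", "lat")]
      map(seq_along(dates), function(d) {
        dt <- day_type_of(dates[d])
        tibble(child_id = prof$child_id, date = dates[d], day_type = dt,
               truth = list(build_truth_day(prof, dates[d], as.character(dt),
                                            config, dests)))
      }) |> list_rbind()
    }) |> list_rbind()

    structure(list(
      profiles = profiles, schools = schools,
      public_spaces = polygon_set(pub_rows$label, pub_rows$rings,
                                  feature_id = paste0(pub_rows$school_id, "_", pub_rows$label)),
      schedule = sim_schedule(config), days = days,
      config = config, seed = as.integer(seed)
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d children x %d days (seed %d)\n",
              nrow(x$profiles), length(unique(x$days$date)), x$seed))
  invisible(x)
}

#' Anchor geometry of a synthetic child, as the pipeline would know it
#'
#' Uses the true home point for both day types, the school point and parcel
#' polygon, and the postal centroid; intended for ground-truth oracles and
#' for tests that bypass anchor inference.
#'
#' @param cohort a `synthetic_cohort`
#' @param child_id child identifier
#' @return an [anchor_set()]
#' @export
true_anchors <- function(cohort, child_id) {
  p <- cohort$profiles[cohort$profiles$child_id == child_id, ]
  if (nrow(p) != 1) abort(sprintf("unknown child_id '%s'", child_id))
  s <- cohort$schools[cohort$schools$school_id == p$school_id, ]
  anchor_set(home_weekday = c(p$home_lon, p$home_lat),
             school_point = c(s$lon, s$lat),
             school_polygon = s$polygon[[1]],
             postal_centroid = c(p$postal_lon, p$postal_lat))
}

#' Expected day summary from the ground truth, bypassing the sensor model
#'
#' Labels every ground-truth epoch directly from the itinerary: the context
#' category from the true (noise-free) position and true anchors with
#' straight-line distances, the trip state from the itinerary's trip mode,
#' public-space membership from the true position, and temporal bins from the
#' clock. Worn epochs are the expected weartime; no GPS noise, dropout,
#' matching or segmentation is involved, so this is the recovery oracle for
#' the full pipeline.
#'
#' @param truth a `truth` entry of a `synthetic_cohort` day row
#' @param anchors an [anchor_set()] (normally [true_anchors()])
#' @param polygons optional [polygon_set()] of public spaces
#' @param schedule optional [school_schedule()]
#' @param child_id identifier stamped on the output
#' @param epoch_len_s epoch length in seconds
#' @return a day cell table shaped like [summarize_day()]'s output
#' @export
ground_truth_summary <- function(truth, anchors, polygons = NULL, schedule = NULL,
                                 child_id = NA_character_, epoch_len_s = 10) {
  ep <- truth$epochs
  dt <- as.character(day_type_of(date_of(ep$time[1])))
  df <- tibble(time = ep$time, lon = ep$lon, lat = ep$lat)
  df <- assign_category(df, anchors, dist_provider("euclidean"), day_type = dt)
  if (!is.null(polygons)) df <- assign_public_space(df, polygons)
  df$wear <- ep$worn
  df$gps_present <- TRUE
  df$intensity <- ep$intensity
  is_trip <- ep$state == "trip"
  df$trip_id <- ifelse(is_trip, cumsum(is_trip & !c(FALSE, is_trip[-length(is_trip)])), NA)
  df$trip_mode <- ep$trip_mode
  summarize_day(df, child_id = child_id, schedule = schedule,
                epoch_len_s = epoch_len_s)
}

#' Emit sensor streams for one ground-truth day
#'
#' Turns a ground-truth epoch grid into what the devices would record: counts
#' drawn uniformly within the intensity class's count interval (so
#' classification is exactly invertible), per-epoch raw-signal summaries (low
#' variability during non-wear), and GPS fixes at the epoch cadence with
#' AR(1) position noise, logged-speed noise and i.i.d. dropout. During
#' non-wear the accelerometer shows the near-constant signal of an unworn
#' device while the logger keeps recording at the place the device was left.
#' With all noise at zero and no dropout the emitted streams reproduce the
#' itinerary exactly. Deterministic given `(truth, seed, config)`.
#'
#' @param truth a `truth` entry of a `synthetic_cohort` day row
#' @param seed integer RNG seed
#' @param config the [sim_config()] the cohort was generated with
#' @return list with `epochs` (time, counts, raw_sd_mg, raw_range_mg) and
#'   `fixes` (time, lat, lon, ele, speed_kmph)
#' @export
emit_sensors <- function(truth, seed = 1, config = sim_config()) {
  if (is.null(truth$segments) || nrow(truth$segments) == 0) {
    abort("cannot emit sensors for a day with no segments")
  }
  ep <- truth$epochs
  n <- nrow(ep)
  len <- config$epoch_len_s
  withr::with_seed(as.integer(seed), {
    cp <- scale_cutpoints(
      cutpoint_set(config$sed_max, config$mod_min, config$vig_min,
                   config$reference_epoch_s), len)
    lo <- c(SB = 0, LPA = floor(cp$sed_max) + 1,
            MPA = ceiling(cp$mod_min), VPA = ceiling(cp$vig_min))
    hi <- c(SB = floor(cp$sed_max), LPA = ceiling(cp$mod_min) - 1,
            MPA = ceiling(cp$vig_min) - 1, VPA = ceiling(cp$vig_min) + 1200)
    cls <- as.character(ep$intensity)
    counts <- integer(n)
    worn <- ep$worn
    counts[worn] <- as.integer(floor(runif(sum(worn), lo[cls[worn]], hi[cls[worn]] + 1)))
    raw_sd <- ifelse(worn,
                     runif(n, config$worn_raw_sd_mg[1], config$worn_raw_sd_mg[2]),
                     runif(n, config$nonworn_raw_sd_mg[1], config$nonworn_raw_sd_mg[2]))
    raw_range <- ifelse(worn,
                        runif(n, config$worn_raw_range_mg[1], config$worn_raw_range_mg[2]),
                        runif(n, config$nonworn_raw_range_mg[1], config$nonworn_raw_range_mg[2]))
    epochs <- tibble(time = ep$time, counts = counts,
                     raw_sd_mg = raw_sd, raw_range_mg = raw_range)

    # AR(1) position noise in a local frame centred on the day's first position
    center <- c(ep$lon[1], ep$lat[1])
    xy <- project_aeqd(ep$lon, ep$lat, center)
    noise_xy <- matrix(0, n, 2)
    if (config$gps_noise_sd_m > 0) {
      rho <- config$gps_noise_rho
      innov_sd <- config$gps_noise_sd_m * sqrt(1 - rho^2)
      for (j in 1:2) {
        e <- numeric(n)
        e[1] <- rnorm(1, 0, config$gps_noise_sd_m)
        innov <- rnorm(n - 1, 0, innov_sd)
        for (i in 2:n) e[i] <- rho * e[i - 1] + innov[i - 1]
        noise_xy[, j] <- e
      }
    }
    ll <- unproject_aeqd(xy[, 1] + noise_xy[, 1], xy[, 2] + noise_xy[, 2], center)
    speed <- ep$speed_kmph
    if (config$speed_noise_sd_kmph > 0) {
      speed <- pmax(0, speed + rnorm(n, 0, config$speed_noise_sd_kmph))
    }
    keep <- if (config$gps_dropout_p > 0) runif(n) >= config$gps_dropout_p else rep(TRUE, n)
    fixes <- tibble(time = ep$time, lat = ll[, 2], lon = ll[, 1],
                    ele = 20, speed_kmph = speed)[keep, ]
    list(epochs = epochs, fixes = fixes)
  })
}
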