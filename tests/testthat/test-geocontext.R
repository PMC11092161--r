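HOME <- c(5.4700, 51.4400)
SCHOOL <- c(5.4850, 51.4400) # about 1 km east of home

mk_anchors <- function(polygon = TRUE) {
  anchor_set(home_weekday = HOME, school_point = SCHOOL,
             school_polygon = if (polygon) list(rect_polygon(SCHOOL, 60)),
             postal_centroid = HOME)
}

fix_at <- function(point) {
  tibble::tibble(time = naive_time(as.Date("2021-06-01"), 10 * 3600),
                 lat = point[2], lon = point[1])
}

test_that("home anchor inference averages morning fixes in metric space", {
  d <- as.Date("2021-06-01")
  t_morning <- naive_time(d, 6.5 * 3600 + 0:9 * 10)
  same <- tibble::tibble(time = t_morning, lat = HOME[2], lon = HOME[1])
  a <- infer_home_anchor(same, day_type = "weekday")
  expect_equal(c(a$lon, a$lat), HOME, tolerance = 1e-9)
  expect_equal(a$n_fixes, 10L)

  # two fixes symmetric about home average back to home
  e <- dest_point(HOME[1], HOME[2], 90, 40)
  w <- dest_point(HOME[1], HOME[2], 270, 40)
  sym <- tibble::tibble(time = t_morning[1:2],
                        lat = c(e[1, 2], w[1, 2]), lon = c(e[1, 1], w[1, 1]))
  a2 <- infer_home_anchor(sym, day_type = "weekday")
  expect_lt(haversine_m(a2$lon, a2$lat, HOME[1], HOME[2]), 0.01)

  # fixes outside the window or on the wrong day type are ignored
  off <- tibble::tibble(time = naive_time(d, 9 * 3600), lat = 0, lon = 0)
  expect_error(infer_home_anchor(off, day_type = "weekday"), "postal")
  expect_error(infer_home_anchor(same, day_type = "weekend"), "postal")
})

test_that("noisy morning fixes recover the true home within metres", {
  withr::with_seed(321, {
    errs <- sapply(1:10, function(i) {
      n <- 6 * 720 # six days of 6-8 AM fixes
      xy <- matrix(rnorm(2 * n, 0, 10), ncol = 2)
      ll <- unproject_aeqd(xy[, 1], xy[, 2], HOME)
      days <- rep(as.Date("2021-05-31") + 0:5, each = 720)[1:n] # Mon-Sat
      f <- tibble::tibble(
        time = naive_time(days, 6 * 3600 + rep(0:719 * 10, 6)[1:n]),
        lat = ll[, 2], lon = ll[, 1])
      a <- infer_home_anchor(f, day_type = "weekday")
      haversine_m(a$lon, a$lat, HOME[1], HOME[2])
    })
    expect_lt(max(errs), 5)
  })
})

test_that("postal validation distance is plain great-circle geodesy", {
  expect_equal(validate_home(HOME, HOME), 0)
  # one arc-second of latitude is about 30.9 m
  sec <- c(HOME[1], HOME[2] + 1 / 3600)
  expect_equal(validate_home(HOME, sec), 30.9, tolerance = 0.01)
})

test_that("the category decision table matches the hand-derived grid", {
  d <- c(5, 50, 250, 600, 900)
  grid <- expand.grid(d_home = d, d_school = d)
  got <- as.character(category_from_distances(grid$d_home, grid$d_school))
  want <- matrix(c(
    # ds:  5            50                250                          600             900            (dh rows)
    "at_home",     "at_home",        "at_home",                   "at_home",      "at_home",
    "at_school",   "close_to_home",  "close_to_home",             "close_to_home", "close_to_home",
    "at_school",   "close_to_school", "overlap_home_school_nb",   "unclassified", "home_nb_outside_school_nb",
    "at_school",   "close_to_school", "unclassified",             "unclassified", "unclassified",
    "at_school",   "close_to_school", "school_nb_outside_home_nb", "unclassified", "outside_both"),
    nrow = 5, byrow = TRUE)
  for (k in seq_len(nrow(grid))) {
    i <- match(grid$d_home[k], d); j <- match(grid$d_school[k], d)
    expect_identical(got[k], want[i, j],
                     label = sprintf("d_home=%g d_school=%g -> %s", grid$d_home[k],
                                     grid$d_school[k], got[k]))
  }
})

test_that("every fix receives exactly one category", {
  withr::with_seed(404, {
    dh <- runif(500, 0, 1500); ds <- runif(500, 0, 1500)
    cats <- category_from_distances(dh, ds)
    expect_true(all(!is.na(cats)))
    expect_true(all(as.character(cats) %in% context_levels()))
  })
})

test_that("assign_category uses geometry, polygon membership and precedence", {
  anch <- mk_anchors()
  # 5 m from home: at home
  p <- dest_point(HOME[1], HOME[2], 45, 5)
  expect_equal(as.character(assign_category(fix_at(p[1, ]), anch)$category), "at_home")
  # inside the school parcel but 25 m from the school point: still at school
  corner <- dest_point(SCHOOL[1], SCHOOL[2], 45, 25)
  expect_equal(as.character(assign_category(fix_at(corner[1, ]), anch)$category),
               "at_school")
  # 250 m from home is about 750 m from school here: no listed combination
  mid <- dest_point(HOME[1], HOME[2], 90, 250)
  expect_equal(as.character(assign_category(fix_at(mid[1, ]), anch)$category),
               "unclassified")
  # 250 m on the far side of home: school is then > 800 m away
  far <- dest_point(HOME[1], HOME[2], 270, 250)
  expect_equal(as.character(assign_category(fix_at(far[1, ]), anch)$category),
               "home_nb_outside_school_nb")
  expect_error(assign_category(fix_at(HOME), list()), "anchor_set")
})

test_that("distance providers are sane and detours only lengthen", {
  p <- dest_point(HOME[1], HOME[2], 30, 350)[1, ]
  eu <- dist_provider("euclidean")
  de <- dist_provider("detour", detour_factor = 1.4)
  expect_equal(provider_distance(eu, HOME[1], HOME[2], HOME), 0)
  expect_equal(provider_distance(eu, p[1], p[2], HOME),
               provider_distance(eu, HOME[1], HOME[2], c(p[1], p[2])))
  expect_gte(provider_distance(de, p[1], p[2], HOME),
             provider_distance(eu, p[1], p[2], HOME))
  expect_error(dist_provider("detour", detour_factor = 0.5), ">= 1")
  expect_error(dist_provider("network"), "network_fun")

  # a detour provider can move a fix to a wider band
  q <- dest_point(HOME[1], HOME[2], 90, 350)[1, ]
  f <- fix_at(c(q[1], q[2]))
  anch <- mk_anchors(polygon = FALSE)
  eu_cat <- assign_category(f, anch, eu)$category
  de_cat <- assign_category(f, anch, dist_provider("detour", 1.5))$category
  expect_equal(as.character(eu_cat), "unclassified") # 350 home / ~650 school
  expect_equal(as.character(de_cat), "unclassified") # 525 home: 400-800 band
})

test_that("public-space buffers are honoured and labels are non-exclusive", {
  park_ctr <- dest_point(HOME[1], HOME[2], 180, 500)[1, ]
  park <- rect_polygon(c(park_ctr[1], park_ctr[2]), 80)
  play_ctr <- dest_point(park_ctr[1], park_ctr[2], 90, 45)[1, ] # overlapping buffers
  play <- rect_polygon(c(play_ctr[1], play_ctr[2]), 30)
  ps <- polygon_set(c("park", "playground"), list(list(park), list(play)))

  inside <- assign_public_space(fix_at(c(park_ctr[1], park_ctr[2])), ps)
  expect_true(inside$ps_park); expect_false(inside$ps_playground)

  near <- dest_point(park_ctr[1], park_ctr[2], 0, 49)[1, ] # 9 m outside the edge
  out9 <- assign_public_space(fix_at(c(near[1], near[2])), ps)
  expect_true(out9$ps_park)

  far <- dest_point(park_ctr[1], park_ctr[2], 0, 51)[1, ] # 11 m outside
  out11 <- assign_public_space(fix_at(c(far[1], far[2])), ps)
  expect_false(out11$ps_park)

  between <- dest_point(park_ctr[1], park_ctr[2], 90, 42)[1, ]
  both <- assign_public_space(fix_at(c(between[1], between[2])), ps)
  expect_true(both$ps_park && both$ps_playground)
})

test_that("invalid polygon geometry is rejected with the feature id", {
  bowtie <- cbind(lon = c(0, 1, 1, 0, 0) * 0.001 + 5.47,
                  lat = c(0, 1, 0, 1, 0) * 0.001 + 51.44)
  expect_error(polygon_set("park", list(list(bowtie)), feature_id = "p7"),
               "p7")
  open_ring <- rect_polygon(HOME, 50)[1:4, ]
  expect_error(polygon_set("park", list(list(open_ring))), "closed")
})
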