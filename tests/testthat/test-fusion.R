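mk_day_fused <- function(retained_epochs, date = as.Date("2021-06-02"),
                         total = 5760, intensity = "SB") {
  # a fused weekday stream with exactly `retained_epochs` worn+matched epochs
  tibble::tibble(
    time = naive_time(date, 6 * 3600 + (seq_len(total) - 1) * 10),
    wear = seq_len(total) <= retained_epochs,
    gps_present = TRUE,
    intensity = factor(intensity, levels = intensity_levels()))
}

test_that("epochs match the nearest fix within tolerance, ties to earlier", {
  d <- as.Date("2021-06-02")
  ep <- tibble::tibble(time = naive_time(d, 8 * 3600 + 0:5 * 10))
  # aligned fixes: every epoch matches its own timestamp
  fx <- tibble::tibble(time = ep$time, lat = 51.44, lon = 5.47, mark = 1:6)
  m <- match_epochs(ep, fx)
  expect_true(all(m$gps_present))
  expect_equal(m$mark, 1:6)

  # a 5-minute hole leaves those epochs unmatched
  ep2 <- tibble::tibble(time = naive_time(d, 8 * 3600 + 0:59 * 10))
  fx2 <- tibble::tibble(time = ep2$time, lat = 51.44, lon = 5.47)[-(20:49), ]
  m2 <- match_epochs(ep2, fx2)
  expect_equal(sum(!m2$gps_present), 28) # interior epochs > 10 s from any fix
  expect_true(all(!m2$gps_present[22:47]))

  # +4 s beats +6 s; equidistant -4/+4 goes to the earlier fix
  ep3 <- tibble::tibble(time = naive_time(d, 9 * 3600))
  fx3 <- tibble::tibble(time = naive_time(d, 9 * 3600 + c(4, 6)), mark = c("a", "b"))
  expect_equal(match_epochs(ep3, fx3)$mark, "a")
  fx4 <- tibble::tibble(time = naive_time(d, 9 * 3600 + c(-4, 4)), mark = c("a", "b"))
  expect_equal(match_epochs(ep3, fx4)$mark, "a")
})

test_that("valid-day thresholds are strict and day-type specific", {
  # 2021-06-02 is a Wednesday; 2021-06-05 a Saturday
  wk_exact <- apply_valid_day(mk_day_fused(8 * 360))
  expect_true(wk_exact$valid)
  expect_equal(wk_exact$weartime_min, 480)

  wk_short <- apply_valid_day(mk_day_fused(8 * 360 - 1)) # 7 h 59 m 50 s
  expect_false(wk_short$valid)

  we_exact <- apply_valid_day(mk_day_fused(6 * 360, date = as.Date("2021-06-05")))
  expect_true(we_exact$valid)
  expect_equal(as.character(we_exact$day_type), "weekend")

  we_short <- apply_valid_day(mk_day_fused(6 * 360 - 1, date = as.Date("2021-06-05")))
  expect_false(we_short$valid)

  # a zero threshold validates everything
  expect_true(apply_valid_day(mk_day_fused(10, date = as.Date("2021-06-05")),
                              weekend_min_h = 0)$valid)
})

test_that("day cells partition weartime and percentages are cell-relative", {
  coh <- small_noiseless_cohort()
  r <- run_truth_day(coh, 1)
  cells <- r$res$cells
  total <- cells[cells$dimension == "total", ]
  for (dim in c("context", "trip", "hour")) {
    sub <- cells[cells$dimension == dim, ]
    expect_equal(sum(sub$weartime_min), total$weartime_min, tolerance = 1e-9)
    expect_equal(sum(sub$lpa_min), total$lpa_min, tolerance = 1e-9)
    expect_equal(sum(sub$mvpa_min), total$mvpa_min, tolerance = 1e-9)
  }
  sched <- cells[cells$dimension == "schedule", ]
  expect_equal(sum(sched$weartime_min), total$weartime_min, tolerance = 1e-9)
  nz <- cells[cells$weartime_min > 0, ]
  expect_equal(nz$mvpa_pct, 100 * nz$mvpa_min / nz$weartime_min)
})

test_that("school-time assignment is half-open [start, bell)", {
  d <- as.Date("2021-06-02") # Wednesday: shortened bell 12:15
  sched <- school_schedule()
  fused <- tibble::tibble(
    time = naive_time(d, hm_to_secs(c("08:25", "08:30", "12:10", "12:15", "15:00"))),
    wear = TRUE, gps_present = TRUE,
    intensity = factor("MPA", levels = intensity_levels()))
  cells <- summarize_temporal(fused, sched, epoch_len_s = 10)
  sc <- cells[cells$dimension == "schedule", ]
  expect_equal(sc$weartime_min[sc$level == "before_school"], 1 / 6)
  expect_equal(sc$weartime_min[sc$level == "school"], 2 / 6) # 08:30 and 12:10
  expect_equal(sc$weartime_min[sc$level == "after_school"], 2 / 6) # bell epoch is after school
  # without a schedule, weekday epochs are schedule-unknown
  cells2 <- summarize_temporal(fused, NULL, epoch_len_s = 10)
  sc2 <- cells2[cells2$dimension == "schedule", ]
  expect_equal(sc2$weartime_min[sc2$level == "schedule_unknown"], 5 / 6)
})

test_that("cohort aggregation reports day-level mean and sample SD", {
  mk_cells <- function(mvpa, date) {
    tibble::tibble(child_id = "c", date = date, day_type = day_type_of(date),
                   dimension = "total", level = "all", weartime_min = 600,
                   sb_min = 0, lpa_min = 100, mvpa_min = mvpa,
                   lpa_pct = NA, mvpa_pct = NA)
  }
  two <- dplyr::bind_rows(mk_cells(10, as.Date("2021-06-02")),
                          mk_cells(20, as.Date("2021-06-03")))
  agg <- aggregate_cohort(two)
  expect_equal(agg$mvpa_min, 15)
  expect_equal(agg$mvpa_sd, sd(c(10, 20)))
  expect_equal(round(agg$mvpa_sd, 2), 7.07)
  expect_equal(agg$n_days, 2L)
  expect_false(agg$single_day)
  # percentage is the aggregate ratio
  expect_equal(agg$mvpa_pct, 100 * 15 / 600)

  one <- aggregate_cohort(mk_cells(10, as.Date("2021-06-02")))
  expect_equal(one$mvpa_sd, 0)
  expect_true(one$single_day)

  same <- aggregate_cohort(dplyr::bind_rows(mk_cells(12, as.Date("2021-06-02")),
                                            mk_cells(12, as.Date("2021-06-03")),
                                            mk_cells(12, as.Date("2021-06-04"))))
  expect_equal(same$mvpa_sd, 0)

  expect_warning(empty <- aggregate_cohort(tibble::tibble()), "no valid days")
  expect_equal(nrow(empty), 0)
})

test_that("tidy and glance methods expose the cohort table", {
  coh <- small_noiseless_cohort()
  r1 <- run_truth_day(coh, 1); r2 <- run_truth_day(coh, 2)
  agg <- aggregate_cohort(dplyr::bind_rows(r1$res$cells, r2$res$cells))
  expect_s3_class(agg, "cohort_summary")
  td <- generics::tidy(agg)
  expect_false(inherits(td, "cohort_summary"))
  gl <- generics::glance(agg)
  expect_equal(gl$n_weekdays + gl$n_weekend_days, 2)
  expect_s3_class(ggplot2::autoplot(agg), "ggplot")
})
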