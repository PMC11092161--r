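# Shared synthetic fixtures, built once per test run.

noiseless_config <- function(...) {
  args <- list(gps_noise_sd_m = 0, gps_dropout_p = 0, speed_noise_sd_kmph = 0,
               nonwear_episode_p = 0, weekend_delayed_wear = FALSE)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

small_noiseless_cohort <- function() {
  cached("small_noiseless", generate_cohort(3, 7, seed = 11, config = noiseless_config()))
}

small_noisy_cohort <- function() {
  cached("small_noisy", generate_cohort(3, 4, seed = 12, config = sim_config()))
}

# run one synthetic child-day through the full pipeline against true anchors
run_truth_day <- function(cohort, row, config = pipeline_config(),
                          emit_seed = 1000 + row, sim_cfg = cohort$config) {
  truth <- cohort$days$truth[[row]]
  child <- cohort$days$child_id[row]
  sens <- emit_sensors(truth, seed = emit_seed, config = sim_cfg)
  anch <- true_anchors(cohort, child)
  res <- process_day(sens$epochs, sens$fixes, anch, cohort$public_spaces,
                     cohort$schedule, config, child_id = child)
  gt <- ground_truth_summary(truth, anch, cohort$public_spaces, cohort$schedule,
                             child_id = child)
  list(res = res, gt = gt, truth = truth)
}

compare_cells <- function(got, want) {
  dplyr::inner_join(got, want, by = c("dimension", "level"),
                    suffix = c("_got", "_want"))
}
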