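# Shared fixture cohorts, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small but fully featured cohort + labelled minute dataset
tiny_cohort <- function() memo("tiny_cohort", {
  cfg <- sim_config(n_participants = 4, n_days = 1, seed = 42)
  generate_cohort(cfg)
})

tiny_minutes <- function() memo("tiny_minutes", {
  suppressWarnings(build_minute_dataset(tiny_cohort()))
})

# a single-participant effects row with neutral random effects
neutral_effects <- function(id = "P001") {
  data.table::data.table(
    participant_id = id, resting_hr = 62, walk_speed_shift = 0,
    accel_mult = 1, body_weight_kg = 75, base_lat = 48.85, base_lon = 2.35,
    elev_base = 60)
}

make_episode <- function(mode, start_minute = 0L, end_minute = 10L) {
  list(start_minute = start_minute, end_minute = end_minute, mode = mode)
}

# The split-bias experiment: 20 participants x 2 days, leave-one-out with
# per-iteration naive OOB rates, with and without participant heterogeneity,
# over three pre-registered seeds. Built once and shared by the acceptance
# tests of the split-bias and weighting phenomena.
bias_experiment <- function() memo("bias_experiment", {
  one <- function(seed, het) {
    hetl <- if (het) sim_config()$participant_heterogeneity
            else list(resting_hr_sd = 0, walk_speed_sd = 0, accel_log_sd = 0)
    cfg <- sim_config(n_participants = 20, n_days = 2, seed = seed,
                      participant_heterogeneity = hetl)
    m <- suppressWarnings(build_minute_dataset(generate_cohort(cfg)))
    run <- loocv_run(m, feature_sets = "without_hr", n_trees = 100,
                     seed = seed)
    cell <- function(kind, w) vapply(run$iterations, function(it)
      it$without_hr[[paste0(kind, "_rates")]][[w]]$rates[["overall_transport"]],
      numeric(1))
    list(oob_tr = cell("oob", "unweighted"),
         test_tr = cell("test", "unweighted"),
         preds = data.table::rbindlist(lapply(run$iterations, function(it)
           it$without_hr$predictions[, .(truth, raw_pred, weighted_pred)])))
  }
  seeds <- c(101L, 202L, 303L)
  list(het = lapply(seeds, one, het = TRUE),
       none = lapply(seeds, one, het = FALSE))
})
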