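test_that("weighted classification moves cutoffs to class prevalence", {
  votes <- matrix(c(0.5, 0.3, 0.2), 1,
                  dimnames = list(NULL, c("activity_place", "bike", "walk")))
  prev <- c(activity_place = 0.8, bike = 0.05, walk = 0.15)
  # ratios 0.625, 6.0, 1.33 -> bike wins under correction
  expect_equal(as.character(weighted_classify(votes, prev)), "bike")
  expect_equal(as.character(weighted_classify(votes)), "activity_place")
  expect_error(weighted_classify(votes, c(activity_place = 0, bike = 0.5,
                                          walk = 0.5)), "prevalence")
})

test_that("uniform prevalence is equivalent to the unweighted arg-max", {
  set.seed(7)
  classes <- mode_levels()
  for (i in 1:30) {
    v <- matrix(runif(5 * 5), 5, dimnames = list(NULL, classes))
    v[1, ] <- c(0.2, 0.2, 0.2, 0.2, 0.2)   # full tie -> first class
    v <- v / rowSums(v)
    uni <- stats::setNames(rep(0.2, 5), classes)
    expect_identical(weighted_classify(v, uni), weighted_classify(v, NULL))
  }
  tie <- matrix(0.2, 1, 5, dimnames = list(NULL, classes))
  expect_equal(as.character(weighted_classify(tie)), classes[1L])
})

test_that("forests are deterministic, mask features, and expose sane votes", {
  m <- tiny_minutes()
  fit <- train_forest(m, "without_hr", n_trees = 50, seed = 3)
  expect_false(any(grepl("^hr_", fit$features)))
  expect_equal(sum(fit$prevalence), 1, tolerance = 1e-12)
  fit2 <- train_forest(m, "without_hr", n_trees = 50, seed = 3)
  v1 <- tree_vote_shares(fit, m)
  v2 <- tree_vote_shares(fit2, m)
  expect_identical(v1, v2)
  expect_equal(rowSums(v1), rep(1, nrow(m)), tolerance = 1e-12)
  # arg-max of vote shares reproduces the library's aggregated prediction
  agg <- predict(fit$fit, data = as.data.frame(m[, fit$features, with = FALSE]),
                 num.threads = 1)$predictions
  expect_equal(as.character(weighted_classify(v1)), as.character(agg))
  # single-class input refuses to train
  expect_error(train_forest(m[label == "activity_place"], "with_hr"),
               "2 classes")
})

test_that("perfectly separated classes give near-zero OOB error", {
  m <- data.table::copy(tiny_minutes())[label %in% c("activity_place", "walk")]
  fit <- train_forest(m, "without_hr", n_trees = 50, seed = 5)
  votes <- oob_vote_shares(fit)
  pred <- weighted_classify(votes)
  rep <- prediction_rates(as.character(pred), as.character(fit$train_y))
  expect_gt(rep$rates[["overall"]], 99)
})

test_that("a one-tree forest leaves in-bag rows without an OOB vote", {
  m <- tiny_minutes()[1:400]
  fit <- train_forest(m, "without_hr", n_trees = 1, seed = 2)
  votes <- oob_vote_shares(fit)
  expect_gt(attr(votes, "n_no_oob"), 0)
  pred <- weighted_classify(votes)
  rep <- prediction_rates(as.character(pred), as.character(fit$train_y))
  expect_equal(rep$n_missing_pred, attr(votes, "n_no_oob"))
  # OOB predictions differ from resubstitution predictions on noisy data:
  # in-bag trees memorize shuffled labels that OOB trees cannot reproduce
  noisy <- data.table::copy(tiny_minutes())
  set.seed(8)
  flip <- sample(nrow(noisy), nrow(noisy) %/% 3)
  noisy[flip, label := sample(mode_levels(), length(flip), replace = TRUE)]
  big <- train_forest(noisy, "without_hr", n_trees = 50, seed = 2)
  resub <- weighted_classify(tree_vote_shares(big, noisy))
  oob <- weighted_classify(oob_vote_shares(big))
  expect_gt(sum(as.character(resub) != as.character(oob), na.rm = TRUE), 0)
  # and resubstitution tracks the (noisy) training labels more closely
  expect_gt(mean(as.character(resub) == as.character(big$train_y)),
            mean(as.character(oob) == as.character(big$train_y), na.rm = TRUE))
})

test_that("leave-one-participant-out partitions participants exactly", {
  m <- tiny_minutes()
  ids <- sort(unique(m$participant_id))[1:3]
  run <- loocv_run(m[participant_id %in% ids], feature_sets = "without_hr",
                   n_trees = 25, seed = 1)
  expect_length(run$iterations, 3L)
  test_ids <- vapply(run$iterations, `[[`, character(1), "participant_id")
  expect_setequal(test_ids, ids)
  for (it in run$iterations) {
    preds <- it$without_hr$predictions
    # test predictions cover exactly the held-out participant's minutes
    expect_setequal(unique(preds$participant_id), it$participant_id)
    expect_equal(nrow(preds), sum(m$participant_id == it$participant_id))
  }
  expect_error(loocv_run(m[participant_id == ids[1]]), "2 participants")
})

test_that("bootstrap inclusion fractions behave as expected", {
  expect_equal(bootstrap_inclusion_fraction(1, reps = 10, seed = 1),
               c(inbag = 1, oob = 0))
  fr <- bootstrap_inclusion_fraction(5000, reps = 60, seed = 4)
  expect_equal(unname(fr["inbag"]), 1 - exp(-1), tolerance = 0.01)
  expect_equal(unname(fr["oob"]), exp(-1), tolerance = 0.02)
})

test_that("variable importance ranks signal above noise", {
  m <- data.table::copy(tiny_minutes())
  fit <- train_forest(m, "with_hr", n_trees = 50, seed = 9)
  imp <- variable_importance(fit)
  expect_equal(nrow(imp), length(fit$features))
  expect_true(all(imp$mean_decrease_gini >= 0))
  # a speed-dispersion statistic sits in the top decile of accuracy importance
  rk <- match(c("speed_sd", "speed_max", "speed_p90"), imp$feature)
  expect_lte(min(rk), ceiling(nrow(imp) / 10))
  # weekend_flag (constant in a one-day cohort) cannot outrank speed signal
  expect_gt(imp[feature == "speed_mean", mean_decrease_accuracy],
            imp[feature == "weekend_flag", mean_decrease_accuracy])
})

test_that("heart rate predictors help bike recall on HR-elevated cohorts", {
  cfg <- sim_config(n_participants = 10, n_days = 1, seed = 77)
  m <- suppressWarnings(build_minute_dataset(generate_cohort(cfg)))
  run <- loocv_run(m, feature_sets = c("without_hr", "with_hr"),
                   n_trees = 100, seed = 7, compute_oob = FALSE)
  pool <- function(fs) {
    p <- data.table::rbindlist(lapply(run$iterations,
                                      function(it) it[[fs]]$predictions))
    100 * mean((p$weighted_pred == p$truth)[p$truth == "bike"])
  }
  expect_gte(pool("with_hr"), pool("without_hr"))
})
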