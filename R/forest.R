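## Random-forest training and evaluation regimes.
##
## Forests are 100-tree bagged classification forests with library-default
## feature subsetting (mtry = floor(sqrt(p))) and Gini splitting, grown
## single-threaded for determinism. Per-tree votes are exposed so that the
## class-prevalence cutoff correction can be applied at the aggregation
## step, and so that out-of-bag predictions (each observation predicted only
## by trees whose bootstrap excluded it) can be computed exactly.

feature_set_columns <- function(feature_set = c("with_hr", "without_hr"),
                                catalogue = feature_catalogue()) {
  feature_set <- match.arg(feature_set)
  if (feature_set == "without_hr") catalogue[source != "hr", name]
  else catalogue$name
}

#' Train a transport-mode random forest
#'
#' Fits a 100-tree classification forest (bootstrap samples of the training
#' rows per tree, random feature subsetting at nodes, Gini criterion,
#' library defaults otherwise). Rows with any missing feature are excluded
#' and counted. Deterministic under a fixed seed.
#'
#' @param records Labelled minute dataset from [build_minute_dataset()].
#' @param feature_set `"with_hr"` (all predictors) or `"without_hr"`
#'   (heart-rate predictors masked out).
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @param catalogue Feature catalogue defining the predictor set.
#' @return An object of class `mode_forest`: the fitted forest, the feature
#'   names used, the class levels present in training (in the fixed class
#'   order), their prevalence in the training data, and the training frame
#'   (kept for out-of-bag evaluation and importance).
#' @export
train_forest <- function(records, feature_set = c("with_hr", "without_hr"),
                         n_trees = 100L, seed = 1L,
                         catalogue = feature_catalogue()) {
  feature_set <- match.arg(feature_set)
  records <- data.table::as.data.table(records)
  feats <- feature_set_columns(feature_set, catalogue)
  x <- records[, feats, with = FALSE]
  cc <- stats::complete.cases(x)
  n_dropped <- sum(!cc)
  x <- as.data.frame(x[cc])
  labs <- as.character(records$label)[cc]
  classes <- MODE_LEVELS[MODE_LEVELS %in% unique(labs)]
  if (length(classes) < 2L)
    stop("training data must contain at least 2 classes", call. = FALSE)
  y <- factor(labs, levels = classes)
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        keep.inbag = TRUE, seed = seed, num.threads = 1L)
  prevalence <- as.numeric(table(y)) / length(y)
  names(prevalence) <- classes
  structure(list(fit = fit, features = feats, feature_set = feature_set,
                 classes = classes, prevalence = prevalence,
                 n_trees = n_trees, n_dropped = n_dropped, seed = seed,
                 train_x = x, train_y = y),
            class = "mode_forest")
}

#' @export
print.mode_forest <- function(x, ...) {
  cat(sprintf("mode_forest: %d trees, %d features (%s), %d training rows\n",
              x$n_trees, length(x$features), x$feature_set, nrow(x$train_x)))
  cat("  prevalence:", paste(sprintf("%s=%.3f", names(x$prevalence),
                                     x$prevalence), collapse = ", "), "\n")
  invisible(x)
}

## per-tree predicted class labels, n x n_trees character matrix
per_tree_predictions <- function(model, newdata) {
  pr <- predict(model$fit, data = newdata, predict.all = TRUE,
                num.threads = 1L)$predictions
  # per-tree predictions index directly into forest$levels
  matrix(model$fit$forest$levels[pr], nrow = nrow(pr))
}

#' Per-class tree vote shares
#'
#' For each row, the fraction of trees voting for each class. Rows sum to 1;
#' the unweighted forest prediction is the arg-max (first class in the fixed
#' class order on ties).
#'
#' @param model A [train_forest()] model.
#' @param records New data containing the model's feature columns (rows with
#'   missing features yield `NA` shares).
#' @return Numeric matrix, one column per model class.
#' @export
tree_vote_shares <- function(model, records) {
  records <- data.table::as.data.table(records)
  x <- as.data.frame(records[, model$features, with = FALSE])
  cc <- stats::complete.cases(x)
  out <- matrix(NA_real_, nrow(x), length(model$classes),
                dimnames = list(NULL, model$classes))
  if (any(cc)) {
    pt <- per_tree_predictions(model, x[cc, , drop = FALSE])
    for (j in seq_along(model$classes))
      out[cc, j] <- rowMeans(pt == model$classes[j])
  }
  out
}

#' Out-of-bag vote shares on the training data
#'
#' Each training row is predicted only by the trees whose bootstrap sample
#' excluded it. Rows that are in-bag for every tree have no out-of-bag vote
#' and get `NA` shares.
#'
#' @param model A [train_forest()] model.
#' @return Numeric matrix as in [tree_vote_shares()], with an attribute
#'   `n_no_oob` counting rows without any out-of-bag tree.
#' @export
oob_vote_shares <- function(model) {
  pt <- per_tree_predictions(model, model$train_x)
  inbag <- matrix(unlist(model$fit$inbag.counts), nrow = nrow(model$train_x))
  oob <- inbag == 0L
  denom <- rowSums(oob)
  out <- matrix(NA_real_, nrow(pt), length(model$classes),
                dimnames = list(NULL, model$classes))
  ok <- denom > 0L
  for (j in seq_along(model$classes))
    out[ok, j] <- rowSums((pt == model$classes[j]) & oob)[ok] / denom[ok]
  attr(out, "n_no_oob") <- sum(!ok)
  out
}

#' Classify from vote shares with prevalence cutoff correction
#'
#' The predicted class maximizes `votes_c / prevalence_c`, i.e. the vote
#' cutoffs are moved to the observed class proportions so that a rarer
#' class is predicted once its vote share exceeds its (low) prevalence
#' relative to the other classes. With uniform prevalence this is the
#' ordinary unweighted arg-max. Ties go to the first class in the fixed
#' class order; rows with `NA` votes give `NA`.
#'
#' @param votes Vote-share matrix (columns named by class).
#' @param prevalence Named per-class prevalence; all entries must be > 0.
#'   `NULL` (default) means uniform, i.e. no correction.
#' @return Factor of predicted classes with the matrix's class levels.
#' @export
weighted_classify <- function(votes, prevalence = NULL) {
  classes <- colnames(votes)
  if (is.null(prevalence)) prevalence <- stats::setNames(rep(1, length(classes)), classes)
  if (!all(classes %in% names(prevalence)))
    stop("prevalence must be named for every class", call. = FALSE)
  prevalence <- prevalence[classes]
  if (any(prevalence <= 0))
    stop("all class prevalences must be > 0", call. = FALSE)
  ratio <- sweep(votes, 2L, prevalence, "/")
  ok <- !apply(ratio, 1L, anyNA)
  pred <- rep(NA_integer_, nrow(votes))
  if (any(ok))
    pred[ok] <- max.col(ratio[ok, , drop = FALSE], ties.method = "first")
  factor(classes[pred], levels = classes)
}

#' Naive out-of-bag prediction rates within a training set
#'
#' Trains a forest on `records` and evaluates it on the same records using
#' only out-of-bag trees per row — the "naive" regime in which minutes from
#' the same participants appear on both sides of each tree's split, which
#' upwardly biases the apparent transport prediction rates when
#' participant-level heterogeneity is present.
#'
#' @inheritParams train_forest
#' @param weighting `"unweighted"` or `"weighted"` (prevalence cutoff
#'   correction at aggregation).
#' @return A `rates_report` (see [prediction_rates()]); rows without
#'   out-of-bag votes are excluded and counted in `n_missing_pred`.
#' @export
naive_oob_rates <- function(records, feature_set = c("with_hr", "without_hr"),
                            weighting = c("unweighted", "weighted"),
                            n_trees = 100L, seed = 1L,
                            catalogue = feature_catalogue()) {
  weighting <- match.arg(weighting)
  model <- train_forest(records, feature_set, n_trees, seed, catalogue)
  votes <- oob_vote_shares(model)
  prev <- if (weighting == "weighted") model$prevalence else NULL
  pred <- weighted_classify(votes, prev)
  truth <- as.character(model$train_y)
  prediction_rates(as.character(pred), truth)
}

#' Mean bootstrap inclusion fractions
#'
#' Draws `reps` bootstrap resamples of size `n` with replacement from
#' `1..n` and returns the mean fraction of distinct original indices
#' included (the in-bag fraction, converging to 1 - 1/e as n grows) and its
#' complement (the out-of-bag fraction, converging to 1/e).
#'
#' @param n Sample size.
#' @param reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Named numeric vector `c(inbag = , oob = )`.
#' @export
bootstrap_inclusion_fraction <- function(n, reps = 200L, seed = 1L) {
  stopifnot(n >= 1L, reps >= 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fr <- vapply(seq_len(reps), function(i)
    length(unique(sample.int(n, n, replace = TRUE))) / n, numeric(1))
  c(inbag = mean(fr), oob = 1 - mean(fr))
}

#' Variable importance
#'
#' Permutation-based mean decrease in accuracy (computed on each tree's
#' out-of-bag data) and mean decrease in Gini impurity, one score per
#' feature. The stored training frame is refitted once per metric with the
#' model's own seed.
#'
#' @param model A [train_forest()] model.
#' @return A `data.table` with `feature`, `mean_decrease_accuracy`,
#'   `mean_decrease_gini`, sorted by decreasing accuracy importance.
#' @export
variable_importance <- function(model) {
  ref <- function(imp) ranger::ranger(
    x = model$train_x, y = model$train_y, num.trees = model$n_trees,
    importance = imp, seed = model$seed, num.threads = 1L)
  acc <- ref("permutation")$variable.importance
  gini <- ref("impurity")$variable.importance
  out <- data.table::data.table(
    feature = names(acc),
    mean_decrease_accuracy = as.numeric(acc),
    mean_decrease_gini = as.numeric(gini[names(acc)]))
  data.table::setorder(out, -mean_decrease_accuracy)
  out[]
}

#' Leave-one-participant-out cross-validation
#'
#' Repeats the participant-level split once per participant: the held-out
#' participant's minutes form the test set and a forest is grown on everyone
#' else. Per iteration and feature set, test-set vote shares, raw and
#' prevalence-corrected predictions, test-set rates (both weightings) and
#' the training set's naive out-of-bag rates (both weightings) are
#' returned. Participants with zero usable minutes are skipped with a
#' warning.
#'
#' @param minutes Labelled minute dataset.
#' @param feature_sets Character vector, subset of
#'   `c("without_hr", "with_hr")`.
#' @param n_trees Trees per forest.
#' @param seed Master seed; iteration i trains with seed `seed + i`.
#' @param compute_oob Set `FALSE` to skip the per-iteration naive
#'   out-of-bag evaluation.
#' @param catalogue Feature catalogue.
#' @param verbose Print per-iteration progress.
#' @return An object of class `loocv_run`: list with `iterations` (one
#'   element per test participant) and the run settings.
#' @export
loocv_run <- function(minutes, feature_sets = c("without_hr", "with_hr"),
                      n_trees = 100L, seed = 1L, compute_oob = TRUE,
                      catalogue = feature_catalogue(), verbose = FALSE) {
  minutes <- data.table::as.data.table(minutes)
  ids <- sort(unique(minutes$participant_id))
  if (length(ids) < 2L)
    stop("leave-one-out needs at least 2 participants", call. = FALSE)
  iterations <- list()
  for (i in seq_along(ids)) {
    pid <- ids[i]
    test <- minutes[participant_id == pid]
    train <- minutes[participant_id != pid]
    if (nrow(test) == 0L) {
      warning(sprintf("participant %s has no minutes; iteration skipped", pid))
      next
    }
    iter <- list(participant_id = pid, index = i)
    for (fs in feature_sets) {
      model <- train_forest(train, fs, n_trees, seed + i, catalogue)
      votes <- tree_vote_shares(model, test)
      raw_pred <- weighted_classify(votes, NULL)
      w_pred <- weighted_classify(votes, model$prevalence)
      preds <- data.table::data.table(
        participant_id = test$participant_id, minute = test$minute,
        timestamp = test$timestamp, truth = as.character(test$label),
        raw_pred = as.character(raw_pred),
        weighted_pred = as.character(w_pred))
      preds <- cbind(preds, data.table::as.data.table(votes))
      res <- list(
        predictions = preds,
        prevalence = model$prevalence,
        test_rates = list(
          unweighted = prediction_rates(preds$raw_pred, preds$truth),
          weighted = prediction_rates(preds$weighted_pred, preds$truth)))
      if (compute_oob) {
        oob_votes <- oob_vote_shares(model)
        truth_tr <- as.character(model$train_y)
        res$oob_rates <- list(
          unweighted = prediction_rates(
            as.character(weighted_classify(oob_votes, NULL)), truth_tr),
          weighted = prediction_rates(
            as.character(weighted_classify(oob_votes, model$prevalence)),
            truth_tr))
      }
      iter[[fs]] <- res
    }
    iterations[[length(iterations) + 1L]] <- iter
    if (verbose)
      message(sprintf("loocv iteration %d/%d (test participant %s) done",
                      i, length(ids), pid))
  }
  structure(list(iterations = iterations, feature_sets = feature_sets,
                 n_trees = n_trees, seed = seed),
            class = "loocv_run")
}

#' @export
print.loocv_run <- function(x, ...) {
  cat(sprintf("loocv_run: %d iterations, feature sets: %s, %d trees\n",
              length(x$iterations), paste(x$feature_sets, collapse = ", "),
              x$n_trees))
  invisible(x)
}
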