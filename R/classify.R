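# Random-forest behaviour classifiers.
#
# Protocol: a 60/20/20 train/validation/test row split; forests grown two
# trees at a time with validation overall accuracy monitored after every
# increment, stopping when the two-evaluation moving average improves on the
# previous two-evaluation average by less than 0.1 percentage points
# (stopping-rounds = 2); depth refined over a grid by retained validation
# accuracy; five-fold cross-validation reported as mean +/- sd. Class votes
# are accumulated across increments, so probabilities are ordinary vote
# fractions and predictions are deterministic (ties go to the first class
# level).

#' Train/validation/test split specification
#'
#' @param train,valid,test Fractions; must sum to 1. Defaults 0.6/0.2/0.2.
#' @param seed Integer seed for the row permutation.
#' @return A `split_spec` object.
#' @export
split_spec <- function(train = 0.6, valid = 0.2, test = 0.2, seed = 1L) {
  if (abs(train + valid + test - 1) > 1e-9) abort("fractions must sum to 1")
  if (min(train, valid, test) <= 0) abort("all three fractions must be positive")
  structure(list(train = train, valid = valid, test = test,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a labelled dataset into train / validation / test
#'
#' Uniform random disjoint row partition: the training part receives
#' `floor(train * n)` rows, validation `floor(valid * n)`, and the test part
#' the remainder. Identical seeds give identical partitions.
#'
#' @param data Labelled dataset (a data frame).
#' @param spec A [split_spec()].
#' @return Named list `train`, `valid`, `test` of data frames.
#' @export
#' @examples
#' parts <- split_dataset(data.frame(x = 1:100), split_spec(seed = 7))
#' sapply(parts, nrow)  # 60 20 20
split_dataset <- function(data, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(data)
  if (n < 5) abort("need at least 5 rows to split")
  perm <- withr::with_seed(spec$seed, sample.int(n))
  n_train <- floor(spec$train * n)
  n_valid <- floor(spec$valid * n)
  list(train = data[perm[seq_len(n_train)], , drop = FALSE],
       valid = data[perm[n_train + seq_len(n_valid)], , drop = FALSE],
       test = data[perm[(n_train + n_valid + 1):n], , drop = FALSE])
}

#' Random-forest model configuration
#'
#' @param n_trees Upper bound on the forest size; early stopping usually
#'   halts well below it.
#' @param depth_grid Integer vector of candidate maximum tree depths for
#'   [tune_depth()] (depth d caps trees at 2^d terminal nodes).
#' @param stopping_rounds Number of accuracy evaluations averaged on each
#'   side of the early-stopping comparison.
#' @param stopping_tolerance Minimum improvement in validation accuracy (on
#'   the 0-1 scale) that keeps the forest growing.
#' @param cv_folds Folds for [cross_validate()].
#' @param eval_every Trees added between accuracy evaluations.
#' @param mtry Predictors sampled per split; default `floor(sqrt(p))`.
#' @param seed Integer seed for tree growing.
#' @return A `model_config` object.
#' @export
model_config <- function(n_trees = 500, depth_grid = c(6, 12, 24),
                         stopping_rounds = 2, stopping_tolerance = 0.001,
                         cv_folds = 5, eval_every = 2, mtry = NULL,
                         seed = 1L) {
  if (length(depth_grid) == 0) abort("`depth_grid` must be non-empty")
  if (stopping_tolerance <= 0 || stopping_tolerance >= 1) {
    abort("`stopping_tolerance` must be in (0, 1)")
  }
  structure(list(n_trees = n_trees, depth_grid = sort(unique(depth_grid)),
                 stopping_rounds = stopping_rounds,
                 stopping_tolerance = stopping_tolerance,
                 cv_folds = cv_folds, eval_every = eval_every, mtry = mtry,
                 seed = as.integer(seed)),
            class = "model_config")
}

# accuracy / MSE / RMSE / r2 from a vote-fraction matrix and true labels.
# MSE is the mean squared probability shortfall on the true class,
# (1 - p_truth)^2; r2 relates it to the variance of the numeric class codes.
prob_metrics <- function(prob, truth, levels) {
  pred <- levels[max.col(prob, ties.method = "first")]
  idx <- match(truth, levels)
  p_true <- ifelse(is.na(idx), 0, prob[cbind(seq_along(truth), ifelse(is.na(idx), 1L, idx))])
  mse <- mean((1 - p_true)^2)
  code_var <- var(as.numeric(factor(truth, levels = levels)))
  tibble(accuracy = mean(pred == truth), mse = mse, rmse = sqrt(mse),
         r2 = if (isTRUE(code_var > 0)) 1 - mse / code_var else NA_real_)
}

# vote counts (not fractions) of a chunk forest on new data
chunk_votes <- function(chunk, newdata, levels) {
  v <- predict(chunk, newdata, type = "vote", norm.votes = FALSE)
  out <- matrix(0, nrow(newdata), length(levels),
                dimnames = list(NULL, levels))
  out[, colnames(v)] <- v
  out
}

#' Train a random forest with validation-based early stopping
#'
#' Grows a forest `eval_every` trees at a time, evaluating overall accuracy
#' on the validation rows after each increment, and stops when the moving
#' average of the last `stopping_rounds` evaluations improves on the
#' previous `stopping_rounds` average by less than `stopping_tolerance`
#' (or when `n_trees` is reached). Training and validation metrics, the
#' validation confusion matrix, and the impurity importance table are
#' recorded; test metrics are computed separately (and exactly once) by
#' [evaluate_test()].
#'
#' @param train,valid Labelled feature frames (14 predictor columns plus
#'   `behaviour`).
#' @param config A [model_config()].
#' @param depth Optional maximum tree depth (caps trees at `2^depth`
#'   terminal nodes); `NULL` grows unrestricted trees.
#' @return An `rf_fit` object.
#' @export
train_rf <- function(train, valid, config = model_config(), depth = NULL) {
  preds <- rf_predictors()
  missing_cols <- setdiff(c(preds, "behaviour"), names(train))
  if (length(missing_cols) > 0) {
    abort(paste0("training data lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  levels <- sort(unique(c(train$behaviour, valid$behaviour)))
  y <- factor(train$behaviour, levels = levels)
  if (length(unique(train$behaviour)) < 2) {
    abort("training data must contain at least 2 behaviour classes")
  }
  xtr <- as.data.frame(train[, preds])
  xval <- as.data.frame(valid[, preds])
  mtry <- config$mtry %||% max(1, floor(sqrt(length(preds))))
  maxnodes <- if (is.null(depth)) NULL else
    max(2L, min(as.integer(2^min(depth, 25)), nrow(xtr)))

  state <- withr::with_seed(config$seed, {
    votes_val <- matrix(0, nrow(xval), length(levels), dimnames = list(NULL, levels))
    votes_tr <- matrix(0, nrow(xtr), length(levels), dimnames = list(NULL, levels))
    imp <- stats::setNames(numeric(length(preds)), preds)
    acc_hist <- numeric(0)
    trees <- 0L
    while (trees < config$n_trees) {
      k <- min(config$eval_every, config$n_trees - trees)
      chunk <- randomForest::randomForest(
        x = xtr, y = y, ntree = k, mtry = mtry, maxnodes = maxnodes,
        keep.forest = TRUE)
      trees <- trees + k
      votes_val <- votes_val + chunk_votes(chunk, xval, levels)
      votes_tr <- votes_tr + chunk_votes(chunk, xtr, levels)
      imp <- imp + chunk$importance[preds, "MeanDecreaseGini"] * k
      pred_val <- levels[max.col(votes_val, ties.method = "first")]
      acc_hist <- c(acc_hist, mean(pred_val == valid$behaviour))
      r <- config$stopping_rounds
      if (length(acc_hist) >= 2 * r) {
        recent <- mean(tail(acc_hist, r))
        previous <- mean(tail(acc_hist, 2 * r)[seq_len(r)])
        if (recent - previous < config$stopping_tolerance) break
      }
    }
    list(votes_val = votes_val, votes_tr = votes_tr, imp = imp / trees,
         acc_hist = acc_hist, trees = trees)
  })

  prob_val <- state$votes_val / state$trees
  prob_tr <- state$votes_tr / state$trees
  metrics <- bind_rows(
    mutate(prob_metrics(prob_tr, train$behaviour, levels), dataset = "train"),
    mutate(prob_metrics(prob_val, valid$behaviour, levels), dataset = "valid")
  ) |> select("dataset", "accuracy", "mse", "rmse", "r2")
  pred_val <- levels[max.col(prob_val, ties.method = "first")]
  structure(
    list(levels = levels, config = config, depth = depth, trees = state$trees,
         metrics = metrics,
         confusion_valid = confusion_matrix(valid$behaviour, pred_val, levels),
         valid_predictions = tibble(behaviour = valid$behaviour,
                                    predicted = pred_val),
         importance_raw = state$imp,
         accuracy_history = state$acc_hist,
         train = train, valid = valid),
    class = "rf_fit"
  )
}

#' @export
print.rf_fit <- function(x, ...) {
  va <- x$metrics$accuracy[x$metrics$dataset == "valid"]
  cat(sprintf("<rf_fit> %d classes, %d trees%s, validation accuracy %.3f\n",
              length(x$levels), x$trees,
              if (is.null(x$depth)) "" else sprintf(" (depth %d)", x$depth), va))
  invisible(x)
}

#' Refine tree depth by validation accuracy
#'
#' Fits one early-stopped forest per depth in the config's `depth_grid` and
#' retains the model with the highest validation overall accuracy; ties go
#' to the smallest depth.
#'
#' @inheritParams train_rf
#' @return The retained `rf_fit`, with the full grid's accuracies in
#'   `$depth_search`.
#' @export
tune_depth <- function(train, valid, config = model_config()) {
  fits <- purrr::map(config$depth_grid, function(d) train_rf(train, valid, config, depth = d))
  accs <- purrr::map_dbl(fits, function(f) f$metrics$accuracy[f$metrics$dataset == "valid"])
  best <- which.max(accs)  # first maximum = smallest depth on ties
  fit <- fits[[best]]
  fit$depth_search <- tibble(depth = config$depth_grid, valid_accuracy = accs)
  fit
}

#' Evaluate the held-out test partition (once)
#'
#' Applies the fitted forest to the test rows, appending test metrics and
#' the test confusion matrix to the fit. The test data are used exactly
#' once: calling this on a fit that already has test metrics is an error.
#'
#' @param fit An `rf_fit`.
#' @param test Labelled feature frame.
#' @return The fit with `metrics` gaining a `"test"` row and
#'   `confusion_test` added.
#' @export
evaluate_test <- function(fit, test) {
  stopifnot(inherits(fit, "rf_fit"))
  if ("test" %in% fit$metrics$dataset) {
    abort("test metrics were already computed for this fit")
  }
  prob <- predict_prob(fit, test)
  pred <- fit$levels[max.col(prob, ties.method = "first")]
  fit$metrics <- bind_rows(
    fit$metrics,
    mutate(prob_metrics(prob, test$behaviour, fit$levels), dataset = "test") |>
      select("dataset", "accuracy", "mse", "rmse", "r2"))
  fit$confusion_test <- confusion_matrix(test$behaviour, pred, fit$levels)
  fit
}

# Vote-fraction probabilities of a fit on new rows. The fit's forest is not
# retained tree-by-tree (votes were accumulated incrementally), so new data
# are scored by refitting? No: we retain the training data and rebuild a
# deterministic forest of the same size and seed. Cheaper and exact: the
# incremental protocol is replayed without the validation bookkeeping.
predict_prob <- function(fit, newdata) {
  preds <- rf_predictors()
  xtr <- as.data.frame(fit$train[, preds])
  y <- factor(fit$train$behaviour, levels = fit$levels)
  xnew <- as.data.frame(newdata[, preds])
  mtry <- fit$config$mtry %||% max(1, floor(sqrt(length(preds))))
  maxnodes <- if (is.null(fit$depth)) NULL else
    max(2L, min(as.integer(2^min(fit$depth, 25)), nrow(xtr)))
  withr::with_seed(fit$config$seed, {
    votes <- matrix(0, nrow(xnew), length(fit$levels),
                    dimnames = list(NULL, fit$levels))
    trees <- 0L
    while (trees < fit$trees) {
      k <- min(fit$config$eval_every, fit$trees - trees)
      chunk <- randomForest::randomForest(
        x = xtr, y = y, ntree = k, mtry = mtry, maxnodes = maxnodes,
        keep.forest = TRUE)
      trees <- trees + k
      votes <- votes + chunk_votes(chunk, xnew, fit$levels)
    }
    votes / trees
  })
}

#' Predict behaviour labels for new samples
#'
#' @param object An `rf_fit`.
#' @param newdata Feature frame with the 14 predictor columns.
#' @param type `"class"` for labels, `"prob"` for vote fractions.
#' @param ... Unused.
#' @return A character vector of labels or a probability matrix.
#' @export
predict.rf_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  prob <- predict_prob(object, newdata)
  if (type == "prob") return(prob)
  object$levels[max.col(prob, ties.method = "first")]
}

#' Five-fold cross-validation
#'
#' Seeded k-fold partition (fold sizes differing by at most one); each fold
#' is held out in turn and scored with the same early-stopping protocol,
#' using the held-out fold for both stopping and metrics. Reports per-fold
#' metrics and their mean and standard deviation.
#'
#' @param data Labelled feature frame.
#' @param config A [model_config()]; `cv_folds` sets k.
#' @param depth Optional maximum tree depth passed to [train_rf()].
#' @return An `rf_cv` object with `$folds` (per-fold metrics) and
#'   `$summary` (mean and sd per metric).
#' @export
cross_validate <- function(data, config = model_config(), depth = NULL) {
  k <- config$cv_folds
  if (k < 2) abort("`cv_folds` must be at least 2")
  n <- nrow(data)
  if (n < k) abort("fewer rows than folds")
  fold <- withr::with_seed(config$seed + 211L, sample(rep(seq_len(k), length.out = n)))
  per_fold <- purrr::map(seq_len(k), function(i) {
    fit <- train_rf(data[fold != i, , drop = FALSE],
                    data[fold == i, , drop = FALSE], config, depth = depth)
    mutate(filter(fit$metrics, .data$dataset == "valid"), fold = i) |>
      select("fold", "accuracy", "mse", "rmse", "r2")
  }) |> purrr::list_rbind()
  summary <- per_fold |>
    tidyr::pivot_longer(-"fold", names_to = "metric") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value)) |>
    ungroup()
  structure(list(folds = per_fold, summary = summary, k = k, config = config),
            class = "rf_cv")
}

#' @export
print.rf_cv <- function(x, ...) {
  acc <- filter(x$summary, .data$metric == "accuracy")
  cat(sprintf("<rf_cv> %d folds, accuracy %.3f (sd %.3f)\n",
              x$k, acc$mean, acc$sd))
  invisible(x)
}

#' Variable importance table
#'
#' Raw impurity-improvement importances with the two normalisations used
#' for reporting: scaled importance (% of the largest importance, so the top
#' predictor is exactly 100) and explanatory power (% of the importance
#' total, summing to 100 over all predictors).
#'
#' @param fit An `rf_fit`.
#' @return Tibble `predictor`, `importance`, `scaled_importance`,
#'   `explanatory_power`, sorted by decreasing importance.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "rf_fit"))
  raw <- fit$importance_raw
  total <- sum(raw)
  tibble(predictor = names(raw), importance = as.numeric(raw)) |>
    mutate(scaled_importance = if (max(.data$importance) > 0)
             100 * .data$importance / max(.data$importance) else 0,
           explanatory_power = if (total > 0)
             100 * .data$importance / total else 0) |>
    arrange(dplyr::desc(.data$importance))
}

#' @rdname variable_importance
#' @param x An `rf_fit`.
#' @param ... Unused.
#' @method tidy rf_fit
#' @export
tidy.rf_fit <- function(x, ...) variable_importance(x)

#' One-row metric summary of a fit
#'
#' @param x An `rf_fit`.
#' @param ... Unused.
#' @return A one-row tibble with train/validation (and, if computed, test)
#'   accuracy, MSE, RMSE, and r2.
#' @method glance rf_fit
#' @export
glance.rf_fit <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_wider(names_from = "dataset",
                       values_from = c("accuracy", "mse", "rmse", "r2")) |>
    mutate(trees = x$trees, classes = length(x$levels))
}

#' @rdname cross_validate
#' @param x An `rf_cv`.
#' @param ... Unused.
#' @method tidy rf_cv
#' @export
tidy.rf_cv <- function(x, ...) x$folds

#' @rdname cross_validate
#' @method glance rf_cv
#' @export
glance.rf_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"))
}
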