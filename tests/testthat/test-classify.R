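test_that("the 60/20/20 split has exact sizes and is a seeded partition", {
  d <- data.frame(id = 1:100)
  parts <- split_dataset(d, split_spec(seed = 5))
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 60L, valid = 20L, test = 20L))
  again <- split_dataset(d, split_spec(seed = 5))
  expect_identical(parts, again)
  # union of parts is the original set, intersections empty
  ids <- c(parts$train$id, parts$valid$id, parts$test$id)
  expect_setequal(ids, d$id)
  expect_equal(anyDuplicated(ids), 0L)
  # general n: sizes floor(0.6n), floor(0.2n), remainder
  d2 <- data.frame(id = 1:103)
  p2 <- split_dataset(d2, split_spec(seed = 2))
  expect_equal(vapply(p2, nrow, integer(1)),
               c(train = 61L, valid = 20L, test = 22L))
  expect_error(split_dataset(data.frame(id = 1:4)), "at least 5")
})

test_that("well-separated classes are learned nearly perfectly", {
  ds <- coarse_dataset()
  two <- ds[ds$behaviour %in% c("active", "inactive"), ]
  parts <- split_dataset(two, split_spec(seed = 6))
  fit <- train_rf(parts$train, parts$valid, model_config(seed = 7))
  acc <- fit$metrics$accuracy[fit$metrics$dataset == "valid"]
  expect_gte(acc, 0.99)
  expect_lte(fit$trees, 500)
})

test_that("permuted labels score at chance level", {
  ds <- coarse_dataset()
  # balance the four classes so chance level is 1/4
  n_per <- min(table(ds$behaviour))
  bal <- do.call(rbind, lapply(split(ds, ds$behaviour), function(g) g[seq_len(n_per), ]))
  bal$behaviour <- withr::with_seed(8, sample(bal$behaviour))
  parts <- split_dataset(bal, split_spec(seed = 9))
  fit <- train_rf(parts$train, parts$valid, model_config(seed = 10))
  acc <- fit$metrics$accuracy[fit$metrics$dataset == "valid"]
  k <- 4
  se <- sqrt((1 / k) * (1 - 1 / k) / nrow(parts$valid))
  expect_lt(abs(acc - 1 / k), 3 * se + 0.02)
})

test_that("metric identities hold", {
  ds <- coarse_dataset()
  parts <- split_dataset(ds, split_spec(seed = 11))
  fit <- train_rf(parts$train, parts$valid, model_config(seed = 12))
  m <- fit$metrics
  expect_equal(m$rmse^2, m$mse, tolerance = 1e-12)
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 1))
  expect_true(all(m$r2 <= 1))
})

test_that("single-class training data is refused", {
  ds <- coarse_dataset()
  one <- ds[ds$behaviour == "active", ]
  expect_error(train_rf(one, one, model_config()), "2 behaviour classes")
})

test_that("depth tuning retains the best validation accuracy, ties to smaller depth", {
  ds <- coarse_dataset()
  parts <- split_dataset(ds, split_spec(seed = 13))
  cfg <- model_config(depth_grid = c(2, 20), seed = 14)
  tuned <- tune_depth(parts$train, parts$valid, cfg)
  accs <- tuned$depth_search$valid_accuracy
  best_acc <- tuned$metrics$accuracy[tuned$metrics$dataset == "valid"]
  expect_equal(best_acc, max(accs))
  # the retained depth is the smallest depth achieving the maximum
  expect_equal(tuned$depth,
               tuned$depth_search$depth[which.max(accs)])
  # a one-point grid reduces to plain training at that depth
  cfg1 <- model_config(depth_grid = 12, seed = 15)
  t1 <- tune_depth(parts$train, parts$valid, cfg1)
  f1 <- train_rf(parts$train, parts$valid, cfg1, depth = 12)
  expect_equal(t1$metrics, f1$metrics)
  expect_equal(unclass(t1$confusion_valid), unclass(f1$confusion_valid))
})

test_that("cross-validation partitions evenly and reports mean and sd over 5 folds", {
  ds <- coarse_dataset()[1:1200, ]
  cv <- cross_validate(ds, model_config(seed = 16), depth = 12)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(c("mean", "sd") %in% names(cv$summary)))
  # no-overfitting check on separable data: cv accuracy near training accuracy
  parts <- split_dataset(ds, split_spec(seed = 17))
  fit <- train_rf(parts$train, parts$valid, model_config(seed = 16), depth = 12)
  tr_acc <- fit$metrics$accuracy[fit$metrics$dataset == "train"]
  cv_acc <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_lt(abs(cv_acc - tr_acc), 0.05)
  expect_error(cross_validate(ds, model_config(cv_folds = 1)), "at least 2")
})

test_that("cross-validation fold sizes differ by at most one", {
  n <- 103; k <- 5
  fold <- withr::with_seed(accelcat::model_config(seed = 1)$seed + 211L,
                           sample(rep(seq_len(k), length.out = n)))
  expect_lte(diff(range(table(fold))), 1)
})

test_that("importance normalisations are exact and planted signals rank first", {
  ds <- planted_dataset()
  parts <- split_dataset(ds, split_spec(seed = 18))
  fit <- train_rf(parts$train, parts$valid, model_config(seed = 19))
  imp <- variable_importance(fit)
  expect_equal(max(imp$scaled_importance), 100)
  expect_equal(sum(imp$explanatory_power), 100, tolerance = 1e-6)
  expect_equal(imp$predictor[1], "static_heave")
  expect_equal(tidy(fit), imp)
})

test_that("identical data and config give identical confusion matrices", {
  ds <- coarse_dataset()[1:1500, ]
  parts <- split_dataset(ds, split_spec(seed = 20))
  f1 <- train_rf(parts$train, parts$valid, model_config(seed = 21))
  f2 <- train_rf(parts$train, parts$valid, model_config(seed = 21))
  expect_identical(unclass(f1$confusion_valid), unclass(f2$confusion_valid))
  expect_equal(f1$metrics, f2$metrics)
})

test_that("the test partition is scored once and only once", {
  ds <- coarse_dataset()[1:1000, ]
  parts <- split_dataset(ds, split_spec(seed = 22))
  fit <- train_rf(parts$train, parts$valid, model_config(seed = 23), depth = 10)
  fit <- evaluate_test(fit, parts$test)
  expect_true("test" %in% fit$metrics$dataset)
  expect_error(evaluate_test(fit, parts$test), "already computed")
})

test_that("glance lays metrics out wide", {
  ds <- coarse_dataset()[1:1000, ]
  parts <- split_dataset(ds, split_spec(seed = 24))
  fit <- train_rf(parts$train, parts$valid, model_config(seed = 25), depth = 10)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(all(c("accuracy_train", "accuracy_valid", "trees") %in% names(g)))
})
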