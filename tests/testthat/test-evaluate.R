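test_that("confusion matrices tally exactly", {
  cm <- confusion_matrix(c("a", "a", "a", "a", "b", "b"),
                         c("a", "a", "a", "b", "b", "b"))
  expect_equal(unclass(cm),
               matrix(c(3L, 0L, 1L, 2L), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))
  ident <- confusion_matrix(c("x", "y"), c("x", "y"))
  expect_equal(sum(ident) - sum(diag(unclass(ident))), 0L)
  expect_error(confusion_matrix("a", c("a", "b")), "lengths differ")
})

test_that("random label pairs match a double-loop counting oracle", {
  withr::with_seed(51, {
    lv <- letters[1:5]
    truth <- sample(lv, 1200, replace = TRUE)
    pred <- sample(lv, 1200, replace = TRUE)
    cm <- confusion_matrix(truth, pred, levels = lv)
    for (i in lv) for (j in lv) {
      expect_equal(unclass(cm)[i, j], sum(truth == i & pred == j))
    }
  })
})

test_that("per-class accuracy is row-normalised recall", {
  cm <- confusion_matrix(c(rep("A", 4), rep("B", 2)),
                         c("A", "A", "A", "B", "B", "B"))
  pca <- per_class_accuracy(cm)
  expect_equal(pca$accuracy[pca$behaviour == "A"], 75)
  expect_equal(pca$accuracy[pca$behaviour == "B"], 100)
  # weighted by support, per-class accuracies reproduce plain accuracy
  plain <- overall_accuracy(cm, disregard = character())
  expect_equal(sum(pca$accuracy * pca$support) / sum(pca$support), plain)
})

test_that("overall accuracy disregards rag-bag rows from both sides", {
  truth <- c(rep("walk", 8), rep("other", 4))
  pred <- c(rep("walk", 8), rep("walk", 4))   # only "other" rows are wrong
  cm <- confusion_matrix(truth, pred)
  expect_equal(overall_accuracy(cm, disregard = character()), 100 * 8 / 12)
  expect_equal(overall_accuracy(cm, disregard = "other"), 100)
  ident <- confusion_matrix(c("a", "b"), c("a", "b"))
  expect_equal(overall_accuracy(ident, disregard = "a"), 100)
  expect_error(overall_accuracy(cm[0, 0]), "empty")
})

test_that("random confusion matrices match the row-filtered trace oracle", {
  withr::with_seed(52, {
    lv <- c(letters[1:6], "other")
    truth <- sample(lv, 1500, replace = TRUE)
    pred <- sample(lv, 1500, replace = TRUE)
    cm <- confusion_matrix(truth, pred, levels = lv)
    keep <- truth != "other"
    expect_equal(overall_accuracy(cm, disregard = "other"),
                 100 * sum(truth[keep] == pred[keep]) / sum(keep))
    expect_equal(overall_accuracy(cm, disregard = character()),
                 100 * mean(truth == pred))
  })
})

test_that("misclassification shares use the stated denominators", {
  truth <- c(rep("A", 10), rep("B", 3))
  pred <- c(rep("A", 2), rep("B", 6), rep("C", 2), rep("B", 3))
  cm <- confusion_matrix(truth, pred, levels = c("A", "B", "C"))
  sh <- misclassification_shares(cm, "A")
  expect_equal(sh$share[sh$confused_with == "B"], 60)
  expect_equal(sh$share[sh$confused_with == "C"], 20)
  sh_err <- misclassification_shares(cm, "A", denominator = "errors")
  expect_equal(sh_err$share[sh_err$confused_with == "B"], 75)
  # all-correct rows give an empty table
  expect_equal(nrow(misclassification_shares(cm, "B")), 0)
  expect_error(misclassification_shares(cm, "Z"), "not in the confusion matrix")
})

test_that("random rows match the share oracle", {
  withr::with_seed(53, {
    lv <- letters[1:6]
    truth <- sample(lv, 1000, replace = TRUE)
    pred <- sample(lv, 1000, replace = TRUE)
    cm <- confusion_matrix(truth, pred, levels = lv)
    for (b in lv) {
      sh <- misclassification_shares(cm, b)
      row_n <- sum(truth == b)
      for (k in seq_len(nrow(sh))) {
        expect_equal(sh$share[k],
                     100 * sum(truth == b & pred == sh$confused_with[k]) / row_n)
      }
    }
  })
})

test_that("device comparison reproduces the closed-form chi-squared", {
  row <- compare_devices("trot", correct_a = 30, n_a = 100,
                         correct_b = 50, n_b = 100)
  expect_equal(row$statistic, chisq_2x2_oracle(30, 70, 50, 50), tolerance = 1e-9)
  expect_equal(row$statistic, 8.333, tolerance = 1e-3)
  expect_equal(row$df, 1)
  expect_equal(row$percent_difference, -20)
  expect_equal(row$verdict, "GCDC")
  # equal proportions: statistic 0, no difference
  null_row <- compare_devices("walk", 30, 100, 30, 100)
  expect_equal(null_row$statistic, 0, tolerance = 1e-12)
  expect_equal(null_row$verdict, "n.d.")
})

test_that("published stand accuracies give a +2.6 point difference", {
  acc <- cheetah_reported_accuracy()
  stand <- acc[acc$model == "fine" & acc$behaviour == "stand", ]
  expect_equal(round(stand$cefas - stand$gcdc, 1), 2.6)
})

test_that("small expected counts fall back to Fisher's exact test", {
  row <- compare_devices("sitting stalk", correct_a = 26, n_a = 27,
                         correct_b = 40, n_b = 40)
  expect_equal(row$test, "fisher")
  expect_true(is.na(row$statistic))
  expect_false(is.na(row$odds_ratio))
  # odds ratio (conditional MLE) is 1 exactly when ad = bc
  bal <- compare_devices("x", 2, 4, 3, 6, small_count_threshold = 10)
  expect_equal(bal$test, "fisher")
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-9)
})

test_that("swapping devices negates differences and keeps the statistic", {
  withr::with_seed(54, {
    for (i in 1:20) {
      n1 <- sample(50:300, 1); n2 <- sample(50:300, 1)
      c1 <- sample(seq_len(n1 - 1), 1); c2 <- sample(seq_len(n2 - 1), 1)
      ab <- compare_devices("b", c1, n1, c2, n2)
      ba <- compare_devices("b", c2, n2, c1, n1, devices = c("GCDC", "CEFAS"))
      expect_equal(ba$percent_difference, -ab$percent_difference)
      if (ab$test == "chisq" && ba$test == "chisq") {
        expect_equal(ba$statistic, ab$statistic, tolerance = 1e-9)
        # statistic vanishes iff the correct proportions coincide
        expect_equal(ab$statistic < 1e-12, abs(c1 / n1 - c2 / n2) < 1e-12)
      }
    }
  })
})

test_that("degenerate 2x2 tables are refused", {
  expect_error(compare_devices("x", 10, 10, 10, 10), "zero margin")
  expect_error(compare_devices("x", 0, 10, 0, 10), "zero margin")
})

test_that("mean difference averages behaviours, excluding the rag-bag", {
  rows <- tibble::tibble(behaviour = c("walk", "trot", "other"),
                         percent_difference = c(-2, -4, 50))
  expect_equal(mean_difference(rows), -3)
  expect_equal(mean_difference(rows[1, ]), -2)
  expect_error(mean_difference(rows[rows$behaviour == "other", ]), "no behaviours")
})
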