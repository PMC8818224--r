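# Evaluation surfaces: confusion matrices, per-behaviour categorisation
# accuracy (per-class recall), overall accuracy with the rag-bag "other"
# class optionally disregarded, misclassification shares, and the
# two-device chi-squared / Fisher comparison table.

#' Confusion matrix
#'
#' Exact cross-tabulation of true against predicted labels; rows are truth,
#' columns are prediction.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param levels Label ordering; defaults to the sorted union.
#' @return A `conf_mat`: an integer matrix with class attribute.
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` lengths differ")
  }
  levels <- levels %||% sort(unique(c(truth, predicted)))
  m <- table(factor(truth, levels = levels), factor(predicted, levels = levels))
  out <- matrix(as.integer(m), nrow(m), ncol(m),
                dimnames = list(levels, levels))
  class(out) <- c("conf_mat", class(out))
  out
}

#' @rdname confusion_matrix
#' @param x A `conf_mat`.
#' @param ... Unused.
#' @method tidy conf_mat
#' @export
tidy.conf_mat <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "n")) |>
    rename(truth = "Var1", predicted = "Var2") |>
    mutate(truth = as.character(.data$truth),
           predicted = as.character(.data$predicted))
}

#' Per-behaviour categorisation accuracy
#'
#' Recall per class: the diagonal count divided by the row (truth) total,
#' as a percentage. Classes with zero support are omitted.
#'
#' @param cm A `conf_mat`.
#' @return Tibble `behaviour`, `support`, `accuracy` (%).
#' @export
per_class_accuracy <- function(cm) {
  support <- rowSums(cm)
  keep <- support > 0
  tibble(behaviour = rownames(cm)[keep],
         support = unname(as.integer(support[keep])),
         accuracy = unname(100 * diag(unclass(cm))[keep] / support[keep]))
}

#' Overall accuracy, optionally disregarding a rag-bag class
#'
#' Correctly categorised events divided by total events, as a percentage.
#' With a non-empty `disregard` set, rows whose TRUE label is in the set are
#' excluded from both numerator and denominator — the convention for the
#' uninformative "other" class, which stays in the model but is left out of
#' headline accuracy.
#'
#' @param cm A `conf_mat`.
#' @param disregard Character vector of true labels to exclude; use
#'   `character()` for plain accuracy.
#' @return A single percentage.
#' @export
overall_accuracy <- function(cm, disregard = "other") {
  if (sum(cm) == 0) abort("empty confusion matrix")
  keep <- !(rownames(cm) %in% disregard)
  m <- unclass(cm)[keep, , drop = FALSE]
  if (sum(m) == 0) abort("no events left after disregarding")
  100 * sum(diag(m[, rownames(cm)[keep], drop = FALSE])) / sum(m)
}

#' Where a behaviour's events go when misclassified
#'
#' For one true behaviour, the off-diagonal counts of its confusion-matrix
#' row as percentages. The default denominator is the behaviour's total
#' event count (so the shares plus the behaviour's accuracy sum to 100%);
#' `denominator = "errors"` uses only the misclassified events instead.
#'
#' @param cm A `conf_mat`.
#' @param behaviour True behaviour of interest.
#' @param denominator `"row_total"` (default) or `"errors"`.
#' @return Tibble `confused_with`, `n`, `share` (%), sorted by share;
#'   empty when nothing was misclassified.
#' @export
misclassification_shares <- function(cm, behaviour,
                                     denominator = c("row_total", "errors")) {
  denominator <- match.arg(denominator)
  if (!behaviour %in% rownames(cm)) {
    abort(sprintf("behaviour '%s' not in the confusion matrix", behaviour))
  }
  row <- unclass(cm)[behaviour, ]
  errors <- row[names(row) != behaviour]
  errors <- errors[errors > 0]
  if (length(errors) == 0) {
    return(tibble(confused_with = character(), n = integer(), share = numeric()))
  }
  den <- if (denominator == "row_total") sum(row) else sum(errors)
  tibble(confused_with = names(errors), n = as.integer(errors),
         share = 100 * as.numeric(errors) / den) |>
    arrange(dplyr::desc(.data$share))
}

#' Compare two devices on one behaviour
#'
#' Builds the 2x2 table (device by correct/incorrect) for one behaviour and
#' tests whether the two loggers' correct-categorisation proportions differ:
#' a Pearson chi-squared test with df = 1 and no continuity correction, or
#' Fisher's exact test (reporting the odds ratio in lieu of the statistic)
#' when any expected cell count falls below `small_count_threshold`. The
#' percent difference is `accuracy_a - accuracy_b` in percentage points, and
#' the verdict names the more accurate device when p < 0.05, else `"n.d."`.
#'
#' @param behaviour Behaviour label for the output row.
#' @param correct_a,n_a Correctly categorised and total events on device a.
#' @param correct_b,n_b The same for device b.
#' @param devices Length-2 character: the device names, a first.
#' @param small_count_threshold Expected-count threshold below which the
#'   Fisher branch is used (default 5).
#' @return A one-row tibble: `behaviour`, `accuracy_a`, `accuracy_b`,
#'   `percent_difference`, `test`, `statistic`, `df`, `odds_ratio`,
#'   `p_value`, `verdict`.
#' @export
#' @examples
#' compare_devices("trot", correct_a = 30, n_a = 100, correct_b = 50, n_b = 100)
compare_devices <- function(behaviour, correct_a, n_a, correct_b, n_b,
                            devices = c("CEFAS", "GCDC"),
                            small_count_threshold = 5) {
  if (n_a < 1 || n_b < 1) abort("both devices need at least one event")
  if (correct_a > n_a || correct_b > n_b) abort("correct counts exceed totals")
  tab <- matrix(c(correct_a, n_a - correct_a, correct_b, n_b - correct_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(devices, c("correct", "incorrect")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate 2x2 table: a zero margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  acc_a <- 100 * correct_a / n_a
  acc_b <- 100 * correct_b / n_b
  if (any(expected < small_count_threshold)) {
    ft <- fisher.test(tab)
    test <- "fisher"; statistic <- NA_real_; df <- NA_real_
    odds_ratio <- unname(ft$estimate); p <- ft$p.value
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    test <- "chisq"; statistic <- unname(ct$statistic); df <- unname(ct$parameter)
    odds_ratio <- NA_real_; p <- ct$p.value
  }
  tibble(behaviour = behaviour, accuracy_a = acc_a, accuracy_b = acc_b,
         percent_difference = acc_a - acc_b,
         test = test, statistic = statistic, df = df,
         odds_ratio = odds_ratio, p_value = p,
         verdict = if (p < 0.05) devices[which.max(c(acc_a, acc_b))] else "n.d.")
}

#' Device comparison table from two confusion matrices
#'
#' Runs [compare_devices()] for every behaviour present in both devices'
#' validation confusion matrices and returns the per-behaviour rows
#' (degenerate tables yield an untested row with `verdict = "n.d."`).
#'
#' @param cm_a,cm_b `conf_mat`s for the two devices (same label vocabulary).
#' @param devices Length-2 device names.
#' @param small_count_threshold Passed to [compare_devices()].
#' @return Tibble of comparison rows.
#' @export
device_comparison <- function(cm_a, cm_b, devices = c("CEFAS", "GCDC"),
                              small_count_threshold = 5) {
  shared <- intersect(rownames(cm_a)[rowSums(cm_a) > 0],
                      rownames(cm_b)[rowSums(cm_b) > 0])
  purrr::map(shared, function(b) {
    row_a <- unclass(cm_a)[b, ]; row_b <- unclass(cm_b)[b, ]
    tryCatch(
      compare_devices(b, correct_a = row_a[b], n_a = sum(row_a),
                      correct_b = row_b[b], n_b = sum(row_b),
                      devices = devices,
                      small_count_threshold = small_count_threshold),
      error = function(e) tibble(
        behaviour = b,
        accuracy_a = 100 * row_a[b] / sum(row_a),
        accuracy_b = 100 * row_b[b] / sum(row_b),
        percent_difference = 100 * row_a[b] / sum(row_a) - 100 * row_b[b] / sum(row_b),
        test = "none", statistic = NA_real_, df = NA_real_,
        odds_ratio = NA_real_, p_value = NA_real_, verdict = "n.d."))
  }) |> purrr::list_rbind()
}

#' Mean accuracy difference across behaviours
#'
#' Arithmetic mean of the per-behaviour percent differences, excluding the
#' rag-bag `"other"` row; the summary statistic of a device-comparison
#' table.
#'
#' @param rows A device-comparison tibble with columns `behaviour` and
#'   `percent_difference`.
#' @return A single value in percentage points.
#' @export
mean_difference <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("behaviour", "percent_difference") %in% names(rows)))
  rows <- filter(rows, .data$behaviour != "other")
  if (nrow(rows) == 0) abort("no behaviours to average over")
  mean(rows$percent_difference)
}
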