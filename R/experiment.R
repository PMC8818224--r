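# End-to-end experiment: simulate one ground-truth session, record it
# through each device profile, calibrate, derive features, label, train one
# forest per device x resolution (six models by default), evaluate, and
# compare the devices per behaviour.

#' Experiment configuration
#'
#' One master seed fans out deterministically: the session uses `seed`, the
#' row split `seed + 1`, and tree growing `seed + 2`, so stages are
#' independently re-runnable.
#'
#' @param plan A [session_plan()]; defaults to the full exercise-bout plan.
#'   Its seed is overridden by the master seed.
#' @param devices Named list of [device_profile()]s (at least one).
#' @param resolutions Model resolutions to run, subset of
#'   `c("fine", "medium", "coarse")`.
#' @param split A [split_spec()]; its seed is overridden.
#' @param model A [model_config()]; its seed is overridden.
#' @param cv Also run k-fold cross-validation per model (slower).
#' @param ideal_rate Sampling rate of the simulated ground truth, samples/s.
#' @param output_dir Optional directory; when given the report artefacts are
#'   written there as plain-text files.
#' @param seed Master seed.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(plan = cheetah_session_plan("full", seed = seed),
                              devices = cheetah_devices(),
                              resolutions = c("fine", "medium", "coarse"),
                              split = split_spec(),
                              model = model_config(),
                              cv = FALSE,
                              ideal_rate = 100,
                              output_dir = NULL,
                              seed = 1L) {
  resolutions <- match.arg(resolutions, several.ok = TRUE)
  if (length(devices) == 0) abort("need at least one device")
  plan$seed <- as.integer(seed)
  split$seed <- as.integer(seed + 1L)
  model$seed <- as.integer(seed + 2L)
  structure(list(plan = plan, devices = devices, resolutions = resolutions,
                 split = split, model = model, cv = cv,
                 ideal_rate = ideal_rate, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full behaviour-categorisation experiment
#'
#' Simulates the planned session once at the ideal rate, records it through
#' every configured device, calibrates each recording against the rail
#' window, derives the 14 predictor channels, aligns and cleans the labels,
#' trains one depth-tuned early-stopped forest per device and resolution
#' (2 devices x 3 resolutions = 6 models by default), evaluates validation
#' and test partitions, and compares the devices per behaviour on the
#' validation confusion matrices. Identical configs and seeds give
#' identical reports.
#'
#' @param config An [experiment_config()].
#' @return An `experiment_report` with elements `models` (per device x
#'   resolution `rf_fit`s), `metrics`, `accuracy_table` (per-behaviour
#'   validation accuracy by device and resolution), `comparisons` (one
#'   comparison tibble per resolution), `mean_differences`,
#'   `collapse_check` (fine-collapsed-to-coarse versus fine accuracy), and
#'   `provenance`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  ses <- with_stage("simulate", compose_session(config$plan, rate = config$ideal_rate))
  ref <- calibration_reference(c(0, config$plan$rail_window))

  datasets <- purrr::map(config$devices, function(dev) {
    rec <- with_stage("record", apply_device(ses$trace, dev))
    corr <- with_stage("calibrate", estimate_correction(rec, ref))
    cal <- apply_correction(rec, corr)
    feats <- with_stage("features", derive_features(cal))
    labs <- with_stage("label", align_labels(cal, ses$intervals))
    ds <- with_stage("label", suppressMessages(
      drop_unassignable(label_features(feats, labs, dev$name))))
    list(data = ds, correction = corr)
  })

  models <- purrr::map(datasets, function(d) {
    purrr::map(
      stats::setNames(config$resolutions, config$resolutions),
      function(res) {
        with_stage(paste0("train-", res), {
          data <- d$data
          data$behaviour <- collapse_labels(data$behaviour, to = res)
          parts <- split_dataset(data, config$split)
          fit <- if (length(config$model$depth_grid) > 1) {
            tune_depth(parts$train, parts$valid, config$model)
          } else {
            train_rf(parts$train, parts$valid, config$model,
                     depth = config$model$depth_grid[1])
          }
          fit <- evaluate_test(fit, parts$test)
          if (config$cv) fit$cv <- cross_validate(data, config$model, depth = fit$depth)
          fit
        })
      })
  })

  metrics <- purrr::imap(models, function(fits, dev) {
    purrr::imap(fits, function(fit, res) {
      mutate(glance(fit), device = dev, resolution = res)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind() |>
    select("device", "resolution", dplyr::everything())

  accuracy_table <- purrr::imap(models, function(fits, dev) {
    purrr::imap(fits, function(fit, res) {
      mutate(per_class_accuracy(fit$confusion_valid), device = dev, resolution = res)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  comparisons <- NULL
  mean_differences <- NULL
  if (length(config$devices) >= 2) {
    dn <- names(config$devices)[1:2]
    dev_names <- purrr::map_chr(config$devices[dn], "name")
    comparisons <- purrr::map(
      stats::setNames(config$resolutions, config$resolutions),
      function(res) {
        with_stage("compare", device_comparison(
          models[[dn[1]]][[res]]$confusion_valid,
          models[[dn[2]]][[res]]$confusion_valid,
          devices = dev_names))
      })
    mean_differences <- purrr::imap(comparisons, function(tb, res) {
      tibble(resolution = res, mean_difference = mean_difference(tb))
    }) |> purrr::list_rbind()
  }

  # structural check: collapsing fine predictions with the coarse map can
  # only turn errors into hits, never the reverse
  collapse_check <- NULL
  if ("fine" %in% config$resolutions) {
    collapse_check <- purrr::imap(models, function(fits, dev) {
      vp <- fits[["fine"]]$valid_predictions
      fine_acc <- mean(vp$predicted == vp$behaviour)
      coarse_acc <- mean(collapse_labels(vp$predicted, "coarse") ==
                           collapse_labels(vp$behaviour, "coarse"))
      tibble(device = dev, fine_accuracy = fine_acc,
             coarse_by_collapsing = coarse_acc)
    }) |> purrr::list_rbind()
    stopifnot(all(collapse_check$coarse_by_collapsing >=
                    collapse_check$fine_accuracy))
  }

  report <- structure(
    list(models = models, metrics = metrics, accuracy_table = accuracy_table,
         comparisons = comparisons, mean_differences = mean_differences,
         collapse_check = collapse_check,
         calibrations = purrr::map(datasets, "correction"),
         provenance = list(seed = config$seed,
                           resolutions = config$resolutions,
                           devices = purrr::map_chr(config$devices, "name"),
                           package_version = as.character(utils::packageVersion("accelcat")))),
    class = "experiment_report")
  if (!is.null(config$output_dir)) write_experiment_report(report, config$output_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d models (%s x %s), seed %d\n",
              sum(lengths(x$models)),
              paste(x$provenance$devices, collapse = "/"),
              paste(x$provenance$resolutions, collapse = "/"),
              x$provenance$seed))
  print(select(x$metrics, "device", "resolution", "accuracy_valid",
               "rmse_valid", "trees"))
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @method tidy experiment_report
#' @export
tidy.experiment_report <- function(x, ...) x$metrics

#' @rdname run_experiment
#' @method glance experiment_report
#' @export
glance.experiment_report <- function(x, ...) {
  tibble(models = sum(lengths(x$models)),
         devices = length(x$models),
         resolutions = length(x$provenance$resolutions),
         seed = x$provenance$seed)
}

#' Persist an experiment report as plain-text artefacts
#'
#' Writes `metrics.csv`, the per-model confusion matrices
#' (`confusion_<device>_<resolution>.csv`, labelled rows = truth, columns =
#' prediction), the per-behaviour `accuracy_table.csv`, the per-resolution
#' comparison tables, and a `provenance.yaml`.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(report$accuracy_table, file.path(dir, "accuracy_table.csv"))
  purrr::iwalk(report$models, function(fits, dev) {
    purrr::iwalk(fits, function(fit, res) {
      cm <- as.data.frame(unclass(fit$confusion_valid))
      cm <- cbind(truth = rownames(cm), cm)
      readr::write_csv(cm, file.path(dir, sprintf("confusion_%s_%s.csv", dev, res)))
    })
  })
  if (!is.null(report$comparisons)) {
    purrr::iwalk(report$comparisons, function(tb, res) {
      readr::write_csv(tb, file.path(dir, sprintf("comparison_%s.csv", res)))
    })
    readr::write_csv(report$mean_differences, file.path(dir, "mean_differences.csv"))
  }
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Write a ready-to-run synthetic session to disk
#'
#' Generates a session (small: 2 min of behaviour; full: ~12 min), records
#' it through both built-in devices, and writes one trace CSV per device, a
#' label interval CSV, and the session plan YAML (seed included) into
#' `dir`. Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory.
#' @param size `"small"` or `"full"`.
#' @param seed Integer seed.
#' @return Named list of the written file paths, invisibly.
#' @export
make_fixture <- function(dir, size = c("small", "full"), seed = 1L) {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan <- cheetah_session_plan(size, seed = seed)
  ses <- compose_session(plan)
  devices <- cheetah_devices()
  paths <- list(
    plan = file.path(dir, "plan.yaml"),
    labels = file.path(dir, "labels.csv"),
    trace_cefas = file.path(dir, "trace_cefas.csv"),
    trace_gcdc = file.path(dir, "trace_gcdc.csv")
  )
  write_session_plan(plan, paths$plan)
  write_labels_csv(ses$intervals, paths$labels)
  write_trace_csv(apply_device(ses$trace, devices$cefas), paths$trace_cefas)
  write_trace_csv(apply_device(ses$trace, devices$gcdc), paths$trace_gcdc)
  invisible(paths)
}
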