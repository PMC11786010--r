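#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: where the data come from
#' (a dataset CSV, a landmark file to be measured, or — when both are `NULL`
#' — a simulated cohort), the split fraction, the augmentation settings, the
#' stack configuration, and one master seed from which every stage seed is
#' derived deterministically.
#'
#' @param data_path Optional path to a dataset CSV (see [read_dataset()]).
#' @param landmarks_path Optional path to a landmark file; measured with the
#'   error-reduction settings below. Requires labels to be joined from
#'   `data_path` or supplied simulated.
#' @param seed Master integer seed for the whole run.
#' @param test_fraction Held-out test proportion.
#' @param stratify Stratify the split by maturation class?
#' @param n_per_class Augmentation rows per class (training data only).
#' @param augment_mode `"uniform"` or `"matched"` (see [cvd_generate()]).
#' @param aer_iters,max_disp,target_width Measurement settings (see
#'   [measure_landmarks()]).
#' @param stack A [stack_config()].
#' @param rho Latent C3-C4 correlation for the simulated cohort.
#' @param importance Also compute permutation feature importance?
#' @param out_dir Optional directory; when set, intermediate CSVs and the
#'   JSON report are written there.
#' @param write_intermediates Write stage CSVs when `out_dir` is set?
#' @return A `cvd_pipeline_config` list.
#' @export
pipeline_config <- function(data_path = NULL, landmarks_path = NULL,
                            seed = 1, test_fraction = 0.2, stratify = TRUE,
                            n_per_class = 1000,
                            augment_mode = c("uniform", "matched"),
                            aer_iters = 1000, max_disp = 4,
                            target_width = 2000,
                            stack = stack_config(), rho = 0.9,
                            importance = FALSE, out_dir = NULL,
                            write_intermediates = TRUE) {
  augment_mode <- match.arg(augment_mode)
  if (!inherits(stack, "cvd_stack_config")) {
    abort("Config error in field `stack`: must be a stack_config().")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("Config error in field `seed`: must be a single integer.")
  }
  structure(
    list(data_path = data_path, landmarks_path = landmarks_path,
         seed = as.integer(seed), test_fraction = test_fraction,
         stratify = stratify, n_per_class = n_per_class,
         augment_mode = augment_mode, aer_iters = aer_iters,
         max_disp = max_disp, target_width = target_width, stack = stack,
         rho = rho, importance = importance, out_dir = out_dir,
         write_intermediates = write_intermediates),
    class = "cvd_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()];
#' `stack` may be a mapping with `base_learners`, `params`, `cv_folds`,
#' `features`.
#'
#' @param path YAML file path.
#' @return A `cvd_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$stack)) {
    raw$stack <- do.call(stack_config, raw$stack)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Config error: unknown field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

.pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full staging pipeline
#'
#' Stages, in order: obtain the feature table (read a CSV, measure a
#' landmark file, or simulate the default cohort), split into train/test,
#' augment the training partition, train the stacking classifier, evaluate
#' on the held-out test set, and derive the class cutoff report on the full
#' non-augmented table. Every stage seed derives from the config's master
#' seed, so an identical config yields an identical report.
#'
#' @param config A [pipeline_config()] (or path handled by
#'   [read_pipeline_config()]).
#' @return A `cvd_report` list: stage row counts, the evaluation
#'   `cvd_metrics`, the `cvd_cutoffs` report, optional feature importance,
#'   the fitted model, and the seeds used.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 11, n_per_class = 50,
#'                        stack = stack_config(c("knn", "extra_trees")))
#' report <- run_pipeline(cfg)
#' glance(report$metrics)
#' }
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  }
  if (!inherits(config, "cvd_pipeline_config")) {
    abort("`config` must be a cvd_pipeline_config.")
  }
  seeds <- fan_out_seeds(config$seed, 6)
  names(seeds) <- c("simulate", "measure", "split", "augment", "train",
                    "importance")
  out_dir <- config$out_dir
  emit <- function(df, name) {
    if (!is.null(out_dir) && isTRUE(config$write_intermediates)) {
      readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  step <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("Pipeline stage `", stage, "` failed: ",
                   conditionMessage(e)))
    })
  }

  data <- step("data", {
    if (!is.null(config$landmarks_path)) {
      lm <- read_landmarks(config$landmarks_path)
      feats <- measure_landmarks(lm, target_width = config$target_width,
                                 n_iter = config$aer_iters,
                                 max_disp = config$max_disp,
                                 seed = seeds[["measure"]])
      if (is.null(config$data_path)) {
        abort("Labels are required: give `data_path` alongside `landmarks_path`.")
      }
      labels <- read_dataset(config$data_path)
      joined <- dplyr::left_join(
        feats, labels[c("id", "age", "gender", "Maturation")], by = "id")
      .validate_dataset(joined)
      joined[.dataset_cols]
    } else if (!is.null(config$data_path)) {
      read_dataset(config$data_path)
    } else {
      .pipeline_log("data", "no input path; simulating the default cohort")
      simulate_cohort(seed = seeds[["simulate"]], rho = config$rho)
    }
  })
  emit(data, "dataset")

  parts <- step("split", {
    split_dataset(data, test_fraction = config$test_fraction,
                  seed = seeds[["split"]], stratify = config$stratify)
  })
  .pipeline_log("split", sprintf("train %d rows, test %d rows",
                                 nrow(parts$train), nrow(parts$test)))
  emit(parts$train, "train")
  emit(parts$test, "test")

  augmented <- step("augment", {
    cvd_generate(parts$train, n_per_class = config$n_per_class,
                 seed = seeds[["augment"]], mode = config$augment_mode)
  })
  .pipeline_log("augment", sprintf("%d training rows after augmentation",
                                   nrow(augmented)))
  emit(augmented, "train_augmented")

  model <- step("train", {
    train_stack(augmented, build_stack(config$stack),
                seed = seeds[["train"]])
  })

  metrics <- step("evaluate", {
    compute_metrics(parts$test$Maturation,
                    predict(model, parts$test),
                    predict(model, parts$test, type = "prob"))
  })
  .pipeline_log("evaluate", sprintf("test accuracy %.4f, log loss %.4f",
                                    metrics$accuracy, metrics$log_loss))

  cutoffs <- step("cutoffs", cutoff_report(data))

  importance <- NULL
  if (isTRUE(config$importance)) {
    importance <- step("importance", {
      feature_importance(model, parts$test, seed = seeds[["importance"]])
    })
  }

  report <- structure(
    list(
      seed = config$seed, seeds = as.list(seeds),
      n_total = nrow(data), n_train = nrow(parts$train),
      n_test = nrow(parts$test), n_train_augmented = nrow(augmented),
      metrics = metrics, cutoffs = cutoffs, importance = importance,
      model = model, split = parts
    ),
    class = "cvd_report"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Serializable view of a pipeline report (drops the fitted model object).
report_to_list <- function(report) {
  list(
    seed = report$seed,
    seeds = report$seeds,
    n_total = report$n_total,
    n_train = report$n_train,
    n_test = report$n_test,
    n_train_augmented = report$n_train_augmented,
    metrics = as.list(glance(report$metrics)),
    confusion = unname(apply(report$metrics$confusion, 1, as.list)),
    cut_points = report$cutoffs$cut_points,
    final_cutoffs = report$cutoffs$final,
    importance = if (is.null(report$importance)) NULL else
      report$importance[c("feature", "importance")]
  )
}

#' @export
print.cvd_report <- function(x, ...) {
  cat(sprintf(
    "<cvd_report> seed %d | %d rows (train %d, test %d; %d after augmentation)\n",
    x$seed, x$n_total, x$n_train, x$n_test, x$n_train_augmented))
  print(x$metrics)
  print(x$cutoffs)
  if (!is.null(x$importance)) {
    cat("permutation importance:\n")
    print(x$importance)
  }
  invisible(x)
}
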