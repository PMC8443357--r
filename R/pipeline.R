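# End-to-end orchestration: load or simulate data, split, optional DEG
# screen, optional GA-SVM feature/hyperparameter search, final fit and
# held-out evaluation.  The four scenarios mirror the classical comparison
# grid: plain SVM vs GA-SVM, each on the full or the pre-screened feature
# space.
#
# Leakage discipline: the DEG screen runs on the training partition only by
# default (screen_on = "train"), and test labels are read for the first time
# at the evaluation stage; the report records where they were first read.

PIPELINE_SCENARIOS <- c("svm_all", "gasvm_all", "svm_screened", "gasvm_screened")

#' Configure a pipeline run
#'
#' Exactly one data source must be given: file paths (`expression_path` +
#' `labels_path`) or a [synthetic_spec()].
#'
#' @param scenario One of `"svm_all"`, `"gasvm_all"`, `"svm_screened"`,
#'   `"gasvm_screened"`.  `*_screened` scenarios run the DEG pre-screen;
#'   `gasvm_*` scenarios run the GA search.
#' @param expression_path,labels_path Paths to the TSV inputs (see
#'   [read_expression()], [read_labels()]).
#' @param synthetic A [synthetic_spec()] (or plain list of its fields).
#' @param n_train Training-set size for the stratified split (default 50).
#' @param seed Root seed; stage streams (split, synth, cv, ga) are derived
#'   from it.
#' @param fc_threshold,alpha,fc_scale Screen settings, see [screen_degs()].
#' @param screen_on `"train"` (default) screens on the training partition
#'   only; `"all"` reproduces the screen-before-split ordering (leaks label
#'   information into feature selection and is flagged in the report).
#' @param ga A [ga_config()] or list of overrides for one; its seed is
#'   forced to the pipeline seed.
#' @param svm_C,svm_gamma Defaults for the non-GA scenarios; `svm_gamma =
#'   NULL` means `1 / p` with p the current feature count.
#' @param standardize Center/scale features inside the SVM.
#' @param out_dir Optional directory to persist the report and tables into.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(scenario,
                            expression_path = NULL, labels_path = NULL,
                            synthetic = NULL,
                            n_train = 50, seed = 1,
                            fc_threshold = 1.0, alpha = 0.05,
                            fc_scale = "log2", screen_on = c("train", "all"),
                            ga = NULL, svm_C = 1, svm_gamma = NULL,
                            standardize = FALSE, out_dir = NULL) {
  scenario <- match.arg(scenario, PIPELINE_SCENARIOS)
  screen_on <- match.arg(screen_on)
  from_files <- !is.null(expression_path) || !is.null(labels_path)
  if (from_files && !is.null(synthetic)) {
    stop("give either file paths or a synthetic spec, not both", call. = FALSE)
  }
  if (from_files && (is.null(expression_path) || is.null(labels_path))) {
    stop("both 'expression_path' and 'labels_path' are required", call. = FALSE)
  }
  if (!from_files && is.null(synthetic)) {
    stop("no data source: give file paths or a synthetic spec", call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_spec")) {
    synthetic <- do.call(synthetic_spec, synthetic)
  }
  ga_cfg <- if (inherits(ga, "ga_config")) {
    ga$seed <- assert_count(seed, "seed")
    ga
  } else {
    do.call(ga_config, c(ga %||% list(), list(seed = seed)))
  }
  structure(list(
    scenario = scenario,
    expression_path = expression_path,
    labels_path = labels_path,
    synthetic = synthetic,
    n_train = assert_count(n_train, "n_train", min = 4L),
    seed = assert_count(seed, "seed"),
    fc_threshold = fc_threshold,
    alpha = alpha,
    fc_scale = fc_scale,
    screen_on = screen_on,
    ga = ga_cfg,
    svm_C = svm_C,
    svm_gamma = svm_gamma,
    standardize = isTRUE(standardize),
    out_dir = out_dir
  ), class = "pipeline_config")
}

scenario_uses_screen <- function(scenario) grepl("_screened$", scenario)
scenario_uses_ga <- function(scenario) grepl("^gasvm_", scenario)

# test labels live behind an accessor that records the pipeline stage at
# which they are first read, so leakage is auditable from the report
make_label_vault <- function(y) {
  first_read <- NA_character_
  list(
    get = function(stage) {
      if (is.na(first_read)) first_read <<- stage
      y
    },
    first_read = function() first_read
  )
}

#' Run the full screen / GA-SVM / evaluate pipeline
#'
#' Stages: (1) load or generate data; (2) stratified train/test split; (3)
#' optional DEG screen; (4) optional GA search for the feature mask and
#' (C, gamma); (5) final SVM fit on the full training partition; (6)
#' held-out evaluation (accuracy, AUC, ROC); (7) optional persistence.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: scenario, per-stage feature counts, final
#'   [svm_params()], the test-set `evaluation_report`, selected probe IDs,
#'   the DEG table and GA history (when those stages ran), ground truth
#'   (synthetic source only), and provenance (seeds, stage at which test
#'   labels were first read, timestamps).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  started <- Sys.time()
  stage <- "load"
  fail <- function(e) stop(sprintf("pipeline stage '%s' failed: %s",
                                   stage, conditionMessage(e)), call. = FALSE)
  tryCatch({
    truth <- NULL
    if (!is.null(config$synthetic)) {
      ds <- generate_dataset(config$synthetic)
      x <- ds$x
      y <- ds$y
      truth <- ds$truth
    } else {
      x <- read_expression(config$expression_path)
      y <- read_labels(config$labels_path)
    }
    n_initial <- nrow(x)

    stage <- "split"
    parts <- split_train_test(x, y, config$n_train,
                              seed = derive_seed(config$seed, "split"))
    train <- parts$train
    test_x <- parts$test$x
    vault <- make_label_vault(parts$test$y)

    stage <- "screen"
    deg_table <- NULL
    if (scenario_uses_screen(config$scenario)) {
      if (config$screen_on == "all") {
        y_all <- c(train$y, vault$get(stage))
        scr <- screen_degs(x[, names(y_all), drop = FALSE], y_all,
                           config$fc_threshold, config$alpha, config$fc_scale)
      } else {
        scr <- screen_degs(train$x, train$y, config$fc_threshold,
                           config$alpha, config$fc_scale)
      }
      deg_table <- scr$results
      kept <- deg_table$probe_id[deg_table$keep]
      if (length(kept) == 0L) {
        stop("the DEG screen kept no probes; relax fc_threshold or alpha")
      }
      train$x <- train$x[kept, , drop = FALSE]
      test_x <- test_x[kept, , drop = FALSE]
    }
    n_screened <- nrow(train$x)

    stage <- "ga"
    ga_history <- NULL
    if (scenario_uses_ga(config$scenario)) {
      ga_res <- evolve(train$x, train$y, config$ga)
      ga_history <- ga_res$history
      params <- ga_res$params
      train$x <- train$x[ga_res$selected, , drop = FALSE]
      test_x <- test_x[ga_res$selected, , drop = FALSE]
      cv_fitness <- ga_res$best_fitness
    } else {
      gamma <- config$svm_gamma %||% (1 / nrow(train$x))
      params <- svm_params(config$svm_C, gamma)
      cv_fitness <- NA_real_
    }
    n_final <- nrow(train$x)

    stage <- "final_fit"
    model <- train_svm(train$x, train$y, params,
                       standardize = config$standardize)

    stage <- "evaluate"
    evaluation <- evaluate_model(model, test_x, vault$get(stage))

    report <- structure(list(
      scenario = config$scenario,
      n_features = list(initial = n_initial, post_screen = n_screened,
                        post_ga = n_final),
      svm_params = params,
      train_cv_fitness = cv_fitness,
      evaluation = evaluation,
      selected_probe_ids = model$feature_ids,
      deg_table = deg_table,
      ga_history = ga_history,
      truth = truth,
      provenance = list(
        seed = config$seed,
        screen_on = config$screen_on,
        n_train = config$n_train,
        test_labels_first_read = vault$first_read(),
        started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ), class = "run_report")

    stage <- "persist"
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    report
  }, error = fail)
}

#' Persist a run report and its tables
#'
#' Writes `report.json`, `roc.tsv`, `selected_probes.tsv`, and, when the
#' stages ran, `deg_table.tsv` and `ga_history.tsv`.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_as_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$evaluation$roc, file.path(dir, "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$selected_probe_ids, file.path(dir, "selected_probes.tsv"))
  if (!is.null(report$deg_table)) {
    utils::write.table(report$deg_table, file.path(dir, "deg_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$ga_history)) {
    utils::write.table(report$ga_history, file.path(dir, "ga_history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

# JSON-friendly view of a report (timestamps separated so that determinism
# can be checked on the remainder)
report_as_list <- function(report, drop_timestamps = FALSE) {
  out <- unclass(report)
  out$evaluation <- unclass(out$evaluation)
  out$svm_params <- unclass(out$svm_params)
  out$truth <- NULL
  if (drop_timestamps) {
    out$provenance$started <- NULL
    out$provenance$finished <- NULL
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  ev <- x$evaluation
  cat(sprintf("GA-SVM pipeline run: scenario '%s'\n", x$scenario))
  cat(sprintf("  features: %d initial -> %d post-screen -> %d used\n",
              x$n_features$initial, x$n_features$post_screen,
              x$n_features$post_ga))
  cat(sprintf("  SVM params: C = %.6g, gamma = %.6g\n",
              x$svm_params$C, x$svm_params$gamma))
  if (!is.na(x$train_cv_fitness)) {
    cat(sprintf("  GA best CV fitness (train): %.4f\n", x$train_cv_fitness))
  }
  cat(sprintf("  test accuracy: %.4f (tp %d, tn %d, fp %d, fn %d)\n",
              ev$accuracy, ev$tp, ev$tn, ev$fp, ev$fn))
  cat(sprintf("  test AUC: %.4f\n", ev$auc))
  invisible(x)
}

#' Run several scenarios on the same data and tabulate them
#'
#' The analogue of the classical SVM vs GA-SVM comparison grid: one row per
#' scenario with the number of features the final model used and its
#' held-out accuracy and AUC.  All configs must share the data source and
#' seed.
#'
#' @param configs Nonempty list of [pipeline_config()]s.
#' @param out_path Optional TSV path for the table.
#' @return A list with `table` (data.frame: `scenario`, `n_features_used`,
#'   `accuracy`, `auc`) and `reports` (the individual run reports).
#' @export
compare_scenarios <- function(configs, out_path = NULL) {
  if (!length(configs)) stop("'configs' must be a nonempty list", call. = FALSE)
  src <- function(cfg) {
    list(cfg$expression_path, cfg$labels_path, cfg$synthetic, cfg$seed,
         cfg$n_train)
  }
  ref <- src(configs[[1L]])
  for (cfg in configs[-1L]) {
    if (!identical(src(cfg), ref)) {
      stop("all configs must share the data source, seed and split",
           call. = FALSE)
    }
  }
  reports <- lapply(configs, run_pipeline)
  table <- do.call(rbind, lapply(reports, function(r) {
    data.frame(scenario = r$scenario,
               n_features_used = r$n_features$post_ga,
               accuracy = r$evaluation$accuracy,
               auc = r$evaluation$auc,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_path)) {
    utils::write.table(table, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(table = table, reports = reports)
}
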