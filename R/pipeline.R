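# End-to-end orchestration: simulate (or load) -> preprocess -> LASSO
# selection -> RR/OLS fits -> detection -> validation, with deterministic
# seed propagation to every stage, persisted intermediates and a run report.

default_pipeline_config <- function() {
  list(
    seed = 1,
    methods = c("rr", "ols", "cutoff"),
    input_csv = NULL,
    truth_csv = NULL,
    out_dir = NULL,
    synthetic = list(n_exams = 20000),
    preprocess = list(max_missing_fraction = 0.5, correlation_cutoff = 0.06,
                      rare_category_min_count = 100, train_fraction = 0.8),
    selection = list(n_runs = 5, lambda_rule = "cv_min", lambda = NULL,
                     train_fraction = 0.8, n_folds = 5),
    rr = list(penalty_weight = 0.01, cv_penalty = FALSE),
    detection = list(sd_multiplier = 3)
  )
}

merge_config <- function(defaults, override, path = "", problems) {
  for (k in names(override)) {
    full <- if (path == "") k else paste0(path, "$", k)
    if (!k %in% names(defaults)) {
      problems$msgs <- c(problems$msgs, paste0("unknown key: ", full))
    } else if (is.list(defaults[[k]]) && !is.null(override[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]],
                                    as.list(override[[k]]), full, problems)
    } else {
      defaults[[k]] <- override[[k]]
    }
  }
  defaults
}

#' Validate and complete a pipeline configuration
#'
#' Merges a partial configuration over the documented defaults, checks value
#' ranges, and reports every problem at once (unknown keys, out-of-range
#' values). An empty input yields the full default configuration.
#'
#' @param config named list of overrides (possibly nested), e.g. parsed from
#'   a JSON config file with [read_pipeline_config()].
#' @return the completed configuration, of class `pipeline_config`.
#' @export
validate_pipeline_config <- function(config = list()) {
  stop_if(!is.list(config), "config must be a list")
  problems <- new.env()
  problems$msgs <- character()
  cfg <- merge_config(default_pipeline_config(), config, "", problems)
  check <- function(ok, msg) if (!ok) problems$msgs <- c(problems$msgs, msg)
  check(is_count(cfg$seed + 1), "seed must be an integer")
  check(all(cfg$methods %in% c("rr", "ols", "cutoff")) &&
          length(cfg$methods) >= 1,
        "methods must be a subset of rr, ols, cutoff")
  check(is.null(cfg$input_csv) || file.exists(cfg$input_csv),
        "input_csv does not exist")
  check(cfg$detection$sd_multiplier > 0, "detection$sd_multiplier must be > 0")
  check(is_count(cfg$selection$n_runs), "selection$n_runs must be a count")
  check(cfg$selection$lambda_rule %in% c("cv_min", "fixed"),
        "selection$lambda_rule must be cv_min or fixed")
  check(is.null(cfg$rr$penalty_weight) || cfg$rr$penalty_weight >= 0,
        "rr$penalty_weight must be >= 0")
  tf <- cfg$preprocess$train_fraction
  check(is.numeric(tf) && tf > 0 && tf < 1,
        "preprocess$train_fraction must be in (0, 1)")
  if (length(problems$msgs) > 0) {
    stop("invalid pipeline config:\n  - ",
         paste(problems$msgs, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname validate_pipeline_config
#' @param file path of a JSON configuration file.
#' @export
read_pipeline_config <- function(file) {
  stop_if(!file.exists(file), "config file not found: ", file)
  validate_pipeline_config(jsonlite::read_json(file, simplifyVector = TRUE))
}

#' Run the full outlier-detection pipeline
#'
#' Executes simulate (or load) -> preprocess -> select -> fit -> detect ->
#' validate. All stage seeds are derived deterministically from the base
#' seed, so rerunning with the same configuration reproduces every artifact.
#' Validation against reference labels runs when simulator truth flags are
#' available (from the generator or a sidecar truth CSV).
#'
#' @param config a [validate_pipeline_config()] result, or a plain list of
#'   overrides.
#' @return an object of class `ct_run_report`: per-stage record/column
#'   counts, the selection ranking, model summaries, per-method flagged
#'   fractions and (when truth is available) the metric comparison table.
#'   When `config$out_dir` is set, all intermediates are persisted there as
#'   CSV/JSON.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_pipeline_config(config)
  }
  seed <- as.integer(config$seed)

  # stage 1: cohort
  if (!is.null(config$input_csv)) {
    cohort <- read_cohort(config$input_csv, config$truth_csv)
  } else {
    syn_args <- config$synthetic
    syn_args$seed <- derive_seed(seed, 1)
    cohort <- generate_cohort(do.call(synthetic_config, syn_args))
  }

  # stage 2: preprocess
  pc <- config$preprocess
  pp <- preprocess(cohort, preprocess_config(
    max_missing_fraction = pc$max_missing_fraction,
    correlation_cutoff = pc$correlation_cutoff,
    rare_category_min_count = pc$rare_category_min_count,
    train_fraction = pc$train_fraction,
    seed = derive_seed(seed, 2)))

  # stage 3: LASSO selection
  sc <- config$selection
  sel <- average_lasso_runs(pp$train, n_runs = sc$n_runs,
                            lambda_rule = sc$lambda_rule, lambda = sc$lambda,
                            train_fraction = sc$train_fraction,
                            n_folds = sc$n_folds,
                            seed = derive_seed(seed, 3))
  selected <- sel$selected_set
  if (length(selected) == 0) {
    warning("LASSO selected no predictors; using all columns")
    selected <- colnames(pp$design$values)
  }
  train_sel <- design_columns(pp$train, selected)
  all_sel <- design_columns(pp$design, selected)

  # stage 4: models on the training split, over the selected set
  models <- list()
  diagnostics <- list()
  if ("rr" %in% config$methods) {
    eps <- if (isTRUE(config$rr$cv_penalty)) NULL else config$rr$penalty_weight
    models$rr <- fit_rr(train_sel, penalty_weight = eps,
                        seed = derive_seed(seed, 4))
    diagnostics$rr <- model_diagnostics(models$rr, train_sel)
  }
  if ("ols" %in% config$methods) {
    models$ols <- fit_ols(train_sel)
    diagnostics$ols <- model_diagnostics(models$ols, train_sel)
  }

  # stage 5: detection over all retained exams
  dcfg <- config$detection$sd_multiplier
  calls <- list()
  for (m in intersect(c("rr", "ols"), config$methods)) {
    calls[[m]] <- detect_residual(
      models[[m]], all_sel, diagnostics[[m]],
      detection_config(dcfg, method = models[[m]]$method))
  }
  if ("cutoff" %in% config$methods) {
    calls$cutoff <- detect_cutoff(
      pp$train$response, pp$design$response,
      detection_config(dcfg, method = "cutoff"),
      exam_ids = pp$design$exam_ids)
  }
  test_ids <- pp$split$test_ids
  flagged_fraction <- lapply(calls, function(cc) {
    list(overall = mean(cc$flagged),
         test = mean(cc$flagged[cc$exam_id %in% test_ids]))
  })

  # stage 6: validation against truth, when available
  comparison <- NULL
  confusions <- NULL
  if ("is_injected_outlier" %in% names(cohort) &&
      !all(is.na(cohort$is_injected_outlier))) {
    truth <- setNames(as.logical(cohort$is_injected_outlier), cohort$exam_id)
    truth <- truth[pp$design$exam_ids]
    confusions <- lapply(calls, build_confusion, truth = truth)
    comparison <- compare_methods(confusions)
  }

  report <- structure(list(
    seed = seed,
    n_input = pp$report$n_input,
    n_retained = pp$report$n_retained,
    p_encoded = pp$report$p_encoded,
    p_final = pp$report$p_final,
    preprocess_report = pp$report,
    ranking = sel$ranking,
    top_numeric = top_predictors(sel, 5),
    n_selected = length(selected),
    models = lapply(models, function(m) list(
      method = m$method, intercept = m$intercept,
      penalty_weight = m$penalty_weight,
      coefficients = m$coefficients)),
    r_squared = lapply(diagnostics, function(d) d$r_squared),
    residual_sd = lapply(diagnostics, function(d) d$residual_sd),
    flagged_fraction = flagged_fraction,
    comparison = comparison
  ), class = "ct_run_report")

  if (!is.null(config$out_dir)) {
    persist_run(config$out_dir, cohort, pp, sel, models, calls,
                confusions, comparison, report)
  }
  attr(report, "pp") <- pp
  attr(report, "selection") <- sel
  attr(report, "models") <- models
  attr(report, "diagnostics") <- diagnostics
  attr(report, "calls") <- calls
  attr(report, "confusions") <- confusions
  report
}

persist_run <- function(dir, cohort, pp, sel, models, calls, confusions,
                        comparison, report) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(dir, "cohort.csv"),
               file.path(dir, "cohort_truth.csv"))
  jsonlite::write_json(pp$report, file.path(dir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  write_selection(sel, file.path(dir, "selection.json"))
  for (m in names(models)) {
    write_model(models[[m]], file.path(dir, paste0("model_", m, ".json")),
                center = pp$design$center, scale = pp$design$scale)
  }
  for (m in names(calls)) {
    write_calls(calls[[m]], file.path(dir, paste0("calls_", m, ".csv")))
  }
  if (!is.null(comparison)) {
    write_metrics(comparison, file.path(dir, "metrics.json"))
  }
  out <- unclass(report)
  out$preprocess_report <- NULL
  jsonlite::write_json(out, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows",
                       na = "null")
  invisible(dir)
}

#' @export
print.ct_run_report <- function(x, ...) {
  cat(sprintf("ct_run_report (seed %d)\n", x$seed))
  cat(sprintf("  exams: %d in, %d retained; columns: %d encoded, %d kept, %d selected\n",
              x$n_input, x$n_retained, x$p_encoded, x$p_final, x$n_selected))
  cat("  top numeric predictors:", paste(x$top_numeric, collapse = " > "), "\n")
  for (m in names(x$flagged_fraction)) {
    cat(sprintf("  %-6s flagged %.2f%% overall (%.2f%% test)%s\n", m,
                100 * x$flagged_fraction[[m]]$overall,
                100 * x$flagged_fraction[[m]]$test,
                if (!is.null(x$r_squared[[m]]))
                  sprintf(", R^2 = %.3f", x$r_squared[[m]]) else ""))
  }
  if (!is.null(x$comparison)) {
    cat("  validation vs injected truth (2 dp):\n")
    print(x$comparison[, c("method", "sensitivity_2dp", "specificity_2dp",
                           "ppv_2dp", "npv_2dp", "f1_2dp")],
          row.names = FALSE)
  }
  invisible(x)
}
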