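# Outlier detectors. The proposed method flags an exam when the absolute
# difference between its actual and model-predicted dose exceeds
# sd_multiplier (default 3) times the standard deviation of the training
# residuals; the same rule driven by OLS residuals and a simple
# mean + 3*SD dose cutoff serve as comparison methods.

#' Detection configuration
#'
#' @param sd_multiplier positive multiple of the residual SD (or dose SD for
#'   the cutoff method) defining the flagging threshold; default 3.
#' @param method which detector the calls belong to: `"RR"`, `"OLS"` or
#'   `"cutoff"`.
#' @param degenerate_sd_tolerance residual SDs below this are treated as
#'   degenerate (a near-interpolating model would otherwise flag everything).
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(sd_multiplier = 3,
                             method = c("RR", "OLS", "cutoff"),
                             degenerate_sd_tolerance = 1e-8) {
  stop_if(!is.numeric(sd_multiplier) || sd_multiplier <= 0,
          "sd_multiplier must be positive")
  structure(list(sd_multiplier = sd_multiplier, method = match.arg(method),
                 degenerate_sd_tolerance = degenerate_sd_tolerance),
            class = "detection_config")
}

new_outlier_calls <- function(exam_id, method, actual, predicted, threshold,
                              flagged) {
  data.frame(exam_id = exam_id, method = method, actual = actual,
             predicted = predicted, residual = actual - predicted,
             threshold = threshold, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Residual-based outlier detection
#'
#' Flags exam `i` iff `|y_i - yhat_i| > sd_multiplier * residual_sd`, where
#' `residual_sd` comes from the training-set diagnostics and is frozen when
#' scoring held-out or new exams (so contaminated new data cannot widen its
#' own threshold). The rule is two-sided: both unexpectedly high and
#' unexpectedly low doses are flagged.
#'
#' @param model a fitted `ct_model` (RR or OLS).
#' @param data design matrix of the exams to score (with response).
#' @param diagnostics [model_diagnostics()] computed on the model's training
#'   set.
#' @param config a [detection_config()].
#' @return a data.frame of outlier calls: `exam_id`, `method`, `actual`,
#'   `predicted`, `residual`, `threshold`, `flagged`.
#' @export
detect_residual <- function(model, data, diagnostics,
                            config = detection_config(method = model$method)) {
  stop_if(!inherits(diagnostics, "fit_diagnostics"),
          "diagnostics must come from model_diagnostics()")
  stop_if(diagnostics$residual_sd < config$degenerate_sd_tolerance,
          "degenerate residual spread; refusing to flag")
  pred <- predict(model, data)
  thr <- config$sd_multiplier * diagnostics$residual_sd
  new_outlier_calls(data$exam_ids, model$method, data$response, pred, thr,
                    abs(data$response - pred) > thr)
}

#' Cutoff outlier detection
#'
#' The naive comparison method: the threshold is the training-dose mean plus
#' `sd_multiplier` times the training-dose SD, and an exam is flagged iff its
#' dose is strictly greater — one-sided by construction. With constant
#' training doses the SD is zero, the threshold equals the mean, and nothing
#' strictly exceeds it. Because gross outliers inflate both the mean and the
#' SD of the training doses, moderate outliers can escape this rule (masking)
#' while still being caught by [detect_residual()].
#'
#' @param train_doses training-set doses (mGy) defining the threshold.
#' @param doses doses of the exams to score.
#' @param config a [detection_config()].
#' @param exam_ids identifiers for `doses` (defaults to `names(doses)`).
#' @return a data.frame of outlier calls; `predicted` holds the training
#'   mean.
#' @export
detect_cutoff <- function(train_doses, doses,
                          config = detection_config(method = "cutoff"),
                          exam_ids = names(doses)) {
  stop_if(length(train_doses) == 0, "train_doses is empty")
  if (is.null(exam_ids)) exam_ids <- as.character(seq_along(doses))
  m <- mean(train_doses)
  s <- if (length(train_doses) > 1) sd(train_doses) else 0
  thr <- m + config$sd_multiplier * s
  new_outlier_calls(exam_ids, "cutoff", doses, m, thr, doses > thr)
}

#' Rank outliers for a top-k review list
#'
#' Orders one method's calls by outlyingness — absolute residual for the
#' residual-based methods, actual dose for the cutoff method — with a
#' deterministic tie-break on `exam_id`.
#'
#' @param calls outlier calls from a single method.
#' @param k number of exams to return; if larger than the number of calls,
#'   all calls are returned with a warning.
#' @return the top-`k` rows of `calls`, most outlying first.
#' @export
rank_outliers <- function(calls, k) {
  stop_if(length(unique(calls$method)) != 1,
          "calls must come from a single method")
  if (k > nrow(calls)) {
    warning("k exceeds the number of calls; returning all ", nrow(calls))
    k <- nrow(calls)
  }
  key <- if (calls$method[1] == "cutoff") calls$actual else abs(calls$residual)
  ord <- order(-key, calls$exam_id)
  out <- calls[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag counts by patient weight class
#'
#' Summarizes how many flagged exams fall in each weight class (S/M/L/XL/XXL);
#' the per-class counts sum to the total flag count.
#'
#' @param calls outlier calls.
#' @param weights patient weights (kg) aligned with `calls` rows.
#' @return data.frame with `weight_class` and `flagged` counts.
#' @export
flags_by_class <- function(calls, weights) {
  stop_if(length(weights) != nrow(calls), "weights must align with calls")
  cls <- factor(weight_class(weights), levels = WEIGHT_CLASSES)
  counts <- tapply(calls$flagged, cls, sum, default = 0L)
  data.frame(weight_class = WEIGHT_CLASSES,
             flagged = as.integer(counts[WEIGHT_CLASSES]),
             stringsAsFactors = FALSE)
}

#' Write outlier calls / review lists as CSV
#'
#' @param calls outlier calls (or a [rank_outliers()] top-k table).
#' @param file CSV destination.
#' @return `file`, invisibly.
#' @export
write_calls <- function(calls, file) {
  write.csv(calls, file, row.names = FALSE)
  invisible(file)
}
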