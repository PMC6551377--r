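# Validation of a detector against a reference labeling (expert review or
# injected simulator truth): 2x2 confusion matrices, the
# sensitivity/specificity/PPV/NPV/F1 metric suite with confidence intervals,
# and the side-by-side method comparison table.

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn nonnegative counts: flagged & true, flagged & false,
#'   unflagged & true, unflagged & false.
#' @return an object of class `confusion_matrix`.
#' @export
#' @examples
#' confusion_matrix(84, 16, 8, 92)
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stop_if(any(counts < 0) || any(counts != floor(counts)),
          "counts must be nonnegative integers")
  stop_if(sum(counts) == 0, "empty confusion matrix")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("flagged", "not flagged"),
                              c("true outlier", "not outlier")))
  print(m)
  invisible(x)
}

#' Build a confusion matrix from per-exam flags
#'
#' @param calls named logical vector of algorithm flags (names are exam ids),
#'   or an outlier-calls data.frame from a detector.
#' @param truth named logical vector of reference labels over the same exams.
#' @return a `confusion_matrix`. Mismatching exam-id sets are an error
#'   listing the discrepancies.
#' @export
build_confusion <- function(calls, truth) {
  if (is.data.frame(calls)) {
    calls <- setNames(calls$flagged, calls$exam_id)
  }
  missing_ids <- setdiff(names(truth), names(calls))
  extra_ids <- setdiff(names(calls), names(truth))
  stop_if(length(missing_ids) > 0 || length(extra_ids) > 0,
          "exam-id mismatch; missing from calls: [",
          paste(head(missing_ids, 5), collapse = ", "),
          "], extra in calls: [",
          paste(head(extra_ids, 5), collapse = ", "), "]")
  truth <- truth[names(calls)]
  confusion_matrix(tp = sum(calls & truth), fp = sum(calls & !truth),
                   fn = sum(!calls & truth), tn = sum(!calls & !truth))
}

wald_ci <- function(p, n, z) {
  if (!is.finite(p) || n == 0) return(c(NA_real_, NA_real_))
  half <- z * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}

wilson_ci <- function(p, n, z) {
  if (!is.finite(p) || n == 0) return(c(NA_real_, NA_real_))
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(center - half, center + half)
}

#' Classification-accuracy metrics with confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and F1 (the harmonic mean of PPV and sensitivity), each
#' with a binomial confidence interval (except F1). A zero denominator makes
#' the corresponding metric `NA` — reported as undefined, never an error.
#'
#' The default interval is the normal-approximation (Wald) interval
#' `p +/- z * sqrt(p(1-p)/n)` with `z = qnorm((1 + ci_level)/2)`; a Wilson
#' score option is available for small counts. `z_value` overrides `z`
#' directly — e.g. `z_value = 2`, the two-sigma rule many published clinical
#' tables use for their "95%" intervals.
#'
#' @param cm a [confusion_matrix()].
#' @param ci_level confidence level (default 0.95).
#' @param ci_method `"wald"` (default) or `"wilson"`.
#' @param z_value optional explicit critical value overriding
#'   `qnorm((1 + ci_level)/2)`.
#' @return an object of class `validation_metrics`: a list with the five
#'   metrics, a `ci` matrix (rows sensitivity/specificity/ppv/npv, columns
#'   low/high), and the inputs.
#' @export
#' @examples
#' compute_metrics(confusion_matrix(84, 16, 8, 92))
compute_metrics <- function(cm, ci_level = 0.95,
                            ci_method = c("wald", "wilson"), z_value = NULL) {
  stop_if(!inherits(cm, "confusion_matrix"), "cm must be a confusion_matrix")
  ci_method <- match.arg(ci_method)
  stop_if(!is_prop(ci_level, open_hi = TRUE) || ci_level <= 0,
          "ci_level must be in (0, 1)")
  z <- if (is.null(z_value)) qnorm((1 + ci_level) / 2) else z_value
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  ppv <- ratio(cm$tp, cm$tp + cm$fp)
  npv <- ratio(cm$tn, cm$tn + cm$fn)
  f1 <- if (is.finite(ppv) && is.finite(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  ci_fun <- if (ci_method == "wald") wald_ci else wilson_ci
  ci <- rbind(sensitivity = ci_fun(sens, cm$tp + cm$fn, z),
              specificity = ci_fun(spec, cm$tn + cm$fp, z),
              ppv = ci_fun(ppv, cm$tp + cm$fp, z),
              npv = ci_fun(npv, cm$tn + cm$fn, z))
  colnames(ci) <- c("low", "high")
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, f1 = f1, ci = ci, ci_level = ci_level,
                 ci_method = ci_method, z = z, counts = cm),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.2f", round_half_up(v)), "NA")
  cat(sprintf(
    "sensitivity %s [%s-%s]  specificity %s [%s-%s]  PPV %s  NPV %s  F1 %s\n",
    fmt(x$sensitivity), fmt(x$ci["sensitivity", 1]), fmt(x$ci["sensitivity", 2]),
    fmt(x$specificity), fmt(x$ci["specificity", 1]), fmt(x$ci["specificity", 2]),
    fmt(x$ppv), fmt(x$npv), fmt(x$f1)))
  invisible(x)
}

#' Side-by-side method comparison table
#'
#' One row of metrics per method, with full-precision values and a rounded
#' presentation column set (2 decimal places, half away from zero — the
#' convention of published summary tables).
#'
#' @param matrices named list mapping method name to its
#'   [confusion_matrix()].
#' @param ... passed to [compute_metrics()].
#' @return data.frame with columns `method`, the five metrics at full
#'   precision, and their `*_2dp` presentation versions.
#' @export
compare_methods <- function(matrices, ...) {
  stop_if(length(matrices) < 1 || is.null(names(matrices)),
          "matrices must be a named list of confusion matrices")
  rows <- lapply(names(matrices), function(m) {
    met <- compute_metrics(matrices[[m]], ...)
    vals <- c(sensitivity = met$sensitivity, specificity = met$specificity,
              ppv = met$ppv, npv = met$npv, f1 = met$f1)
    out <- data.frame(method = m, t(vals), stringsAsFactors = FALSE)
    pres <- as.data.frame(t(round_half_up(vals, 2)))
    names(pres) <- paste0(names(vals), "_2dp")
    cbind(out, pres)
  })
  do.call(rbind, rows)
}

#' Read a confusion matrix from a 4-count CSV
#'
#' Expects a single-row CSV with columns `tp,fp,fn,tn`, for standalone use of
#' the metric suite on externally produced counts.
#'
#' @param file CSV path.
#' @return a `confusion_matrix`.
#' @export
read_confusion <- function(file) {
  d <- read.csv(file)
  stop_if(!all(c("tp", "fp", "fn", "tn") %in% names(d)) || nrow(d) != 1,
          "expected one row with columns tp, fp, fn, tn")
  confusion_matrix(d$tp, d$fp, d$fn, d$tn)
}

#' Write a metrics report as JSON
#'
#' @param metrics a `validation_metrics` object or a [compare_methods()]
#'   table.
#' @param file JSON destination.
#' @return `file`, invisibly.
#' @export
write_metrics <- function(metrics, file) {
  obj <- if (inherits(metrics, "validation_metrics")) {
    list(sensitivity = metrics$sensitivity, specificity = metrics$specificity,
         ppv = metrics$ppv, npv = metrics$npv, f1 = metrics$f1,
         ci = apply(metrics$ci, 1, as.list),
         ci_level = metrics$ci_level, ci_method = metrics$ci_method)
  } else metrics
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(file)
}
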