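# LASSO estimation (cyclic coordinate descent with soft-thresholding),
# regularization paths with warm starts, cross-validated penalty choice, and
# the five-run coefficient-averaging / ranking procedure used to report the
# most important dose predictors.

resolve_xy <- function(x, y) {
  if (inherits(x, "design_matrix")) list(x = x$values, y = x$response,
                                         info = x$column_info)
  else {
    stop_if(is.null(y), "y is required when x is a plain matrix")
    list(x = as.matrix(x), y = as.numeric(y), info = NULL)
  }
}

#' Largest useful LASSO penalty
#'
#' The smallest penalty at which every coefficient is exactly zero:
#' `max_j |<x_j - mean(x_j), y - mean(y)>| / N` (the intercept is unpenalized).
#'
#' @param x design matrix ([preprocess()] output) or numeric matrix.
#' @param y response (when `x` is a plain matrix).
#' @return the scalar penalty bound. A relative headroom of 1e-10 is added so
#'   that fitting exactly at the returned value yields the all-zero model
#'   regardless of floating-point summation order.
#' @export
lasso_lambda_max <- function(x, y = NULL) {
  d <- resolve_xy(x, y)
  xc <- sweep(d$x, 2, colMeans(d$x))
  max(abs(crossprod(xc, d$y - mean(d$y)))) / nrow(d$x) * (1 + 1e-10)
}

#' Fit the LASSO at a single penalty
#'
#' Minimizes `(1/(2N)) * sum_i (y_i - b0 - x_i'b)^2 + lambda * sum_j |b_j|`
#' by cyclic coordinate descent with soft-thresholding updates; the intercept
#' is unpenalized. Convergence is declared when the largest coefficient change
#' in a full sweep falls below `tol`; shrunken coefficients are exactly zero,
#' not merely small.
#'
#' @param x design matrix or numeric predictor matrix.
#' @param y response vector (when `x` is a plain matrix).
#' @param lambda nonnegative penalty weight.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter maximum number of full sweeps.
#' @return an object of class `lasso_fit`: `coefficients` (named),
#'   `intercept`, `lambda`, `n_iterations`, `converged`, and the per-sweep
#'   `objective_trace` (non-increasing by construction of the updates).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4); y <- x[, 1] * 2 + rnorm(50, 0, .1)
#' fit_lasso(x, y, lambda = 0.05)
fit_lasso <- function(x, y = NULL, lambda, tol = 1e-7, max_iter = 100000L) {
  d <- resolve_xy(x, y)
  stop_if(!is.numeric(lambda) || length(lambda) != 1 || lambda < 0,
          "lambda must be a single nonnegative value")
  res <- lasso_cd_path(d$x, d$y, lambda, tol, as.integer(max_iter))
  if (!res$converged[1]) {
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  }
  beta <- drop(res$beta)
  names(beta) <- colnames(d$x)
  structure(list(coefficients = beta, intercept = res$intercept[1],
                 lambda = lambda, n_iterations = res$iterations[1],
                 converged = res$converged[1],
                 objective_trace = res$objective_trace[[1]],
                 column_info = d$info),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso_fit: lambda = %.4g, %d/%d nonzero, %s in %d sweeps\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' @export
coef.lasso_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' LASSO regularization path
#'
#' Fits the LASSO along a decreasing penalty grid with warm starts. The
#' default grid has 100 log-spaced points from the all-zero penalty
#' [lasso_lambda_max()] down to `lambda_max * lambda_min_ratio`.
#'
#' @inheritParams fit_lasso
#' @param lambda_grid optional decreasing positive grid; overrides the default.
#' @param n_lambda grid length for the default grid.
#' @param lambda_min_ratio ratio of the smallest to the largest grid value.
#' @return an object of class `lasso_path`: `lambda`, coefficient matrix
#'   `beta` (p x n_lambda), `intercept`, `df` (nonzero counts), `converged`.
#' @export
lasso_path <- function(x, y = NULL, lambda_grid = NULL, n_lambda = 100,
                       lambda_min_ratio = 1e-4, tol = 1e-7,
                       max_iter = 100000L) {
  d <- resolve_xy(x, y)
  if (is.null(lambda_grid)) {
    lmax <- lasso_lambda_max(d$x, d$y)
    lambda_grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = n_lambda))
  }
  stop_if(length(lambda_grid) == 0, "empty lambda grid")
  stop_if(any(lambda_grid <= 0) || is.unsorted(rev(lambda_grid)),
          "lambda_grid must be positive and decreasing")
  res <- lasso_cd_path(d$x, d$y, lambda_grid, tol, as.integer(max_iter))
  beta <- res$beta
  rownames(beta) <- colnames(d$x)
  structure(list(lambda = lambda_grid, beta = beta,
                 intercept = res$intercept, df = colSums(beta != 0),
                 converged = res$converged, column_info = d$info),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("lasso_path: %d penalties in [%.3g, %.3g], df %d..%d\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              min(x$df), max(x$df)))
  invisible(x)
}

#' Long-format path table for coefficient-path plots
#'
#' @param path a [lasso_path()] result.
#' @param file optional CSV destination.
#' @return data.frame with columns `lambda`, `predictor`, `coefficient`.
#' @export
path_table <- function(path, file = NULL) {
  out <- data.frame(
    lambda = rep(path$lambda, each = nrow(path$beta)),
    predictor = rep(rownames(path$beta), length(path$lambda)),
    coefficient = as.vector(path$beta),
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Cross-validated penalty choice
#'
#' K-fold cross-validation of the squared prediction error over a penalty
#' grid; returns the minimum-error penalty (`lambda_min`).
#'
#' @inheritParams lasso_path
#' @param n_folds number of folds.
#' @param seed integer seed for the fold assignment.
#' @return list with `lambda_min`, the grid `lambda`, and mean CV error `cvm`.
#' @export
cv_lasso <- function(x, y = NULL, n_folds = 5, lambda_grid = NULL,
                     n_lambda = 100, lambda_min_ratio = 1e-4, seed = 1,
                     tol = 1e-7, max_iter = 100000L) {
  d <- resolve_xy(x, y)
  n <- nrow(d$x)
  stop_if(n_folds < 2 || n_folds > n, "invalid n_folds")
  if (is.null(lambda_grid)) {
    lmax <- lasso_lambda_max(d$x, d$y)
    lambda_grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = n_lambda))
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  err <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    res <- lasso_cd_path(d$x[tr, , drop = FALSE], d$y[tr], lambda_grid,
                         tol, as.integer(max_iter))
    pred <- d$x[!tr, , drop = FALSE] %*% res$beta
    pred <- sweep(pred, 2, res$intercept, "+")
    err[k, ] <- colMeans((d$y[!tr] - pred)^2)
  }
  cvm <- colMeans(err)
  list(lambda = lambda_grid, cvm = cvm,
       lambda_min = lambda_grid[which.min(cvm)])
}

#' Multi-run LASSO coefficient averaging and predictor ranking
#'
#' Runs the LASSO `n_runs` times, each on a fresh random training subset of
#' the data, with the penalty chosen per run (5-fold cross-validated minimum
#' by default), then averages the coefficients arithmetically across runs and
#' ranks predictors by the magnitude of the averaged coefficient. Because the
#' sign question (average first vs take magnitudes first) is genuinely
#' ambiguous, both `averaged_coefficients` (signed mean) and
#' `mean_abs_coefficients` are reported; the ranking uses `|signed mean|`.
#'
#' @param x design matrix (standardized) or numeric matrix.
#' @param y response (when `x` is a plain matrix).
#' @param n_runs number of runs (>= 1).
#' @param lambda_rule `"cv_min"` (default) or `"fixed"` (supply `lambda`).
#' @param lambda fixed penalty when `lambda_rule = "fixed"`.
#' @param train_fraction fraction of rows drawn (without replacement) for each
#'   run's training subset.
#' @param n_folds folds for the per-run cross-validation.
#' @param seed base seed; each run derives its own subsample/fold seeds.
#' @return an object of class `selection_summary`: `per_run_coefficients`
#'   (n_runs x p), `averaged_coefficients`, `mean_abs_coefficients`,
#'   `ranking` (all column names, decreasing `|average|`), `selected_set`
#'   (nonzero averaged coefficient), `lambdas`, `runs_converged`.
#' @export
average_lasso_runs <- function(x, y = NULL, n_runs = 5,
                               lambda_rule = c("cv_min", "fixed"),
                               lambda = NULL, train_fraction = 0.8,
                               n_folds = 5, seed = 1, tol = 1e-7,
                               max_iter = 100000L) {
  d <- resolve_xy(x, y)
  lambda_rule <- match.arg(lambda_rule)
  stop_if(!is_count(n_runs), "n_runs must be a positive integer")
  stop_if(lambda_rule == "fixed" && is.null(lambda),
          "lambda_rule = 'fixed' needs a lambda")
  n <- nrow(d$x)
  p <- ncol(d$x)
  per_run <- matrix(NA_real_, n_runs, p, dimnames = list(NULL, colnames(d$x)))
  lambdas <- numeric(n_runs)
  converged <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, r))
    idx <- sample.int(n, round(train_fraction * n))
    xr <- d$x[idx, , drop = FALSE]
    yr <- d$y[idx]
    lam <- if (lambda_rule == "fixed") lambda else
      cv_lasso(xr, yr, n_folds = n_folds, seed = derive_seed(seed, 100 + r),
               tol = tol, max_iter = max_iter)$lambda_min
    fit <- suppressWarnings(fit_lasso(xr, yr, lam, tol = tol,
                                      max_iter = max_iter))
    per_run[r, ] <- fit$coefficients
    lambdas[r] <- lam
    converged[r] <- fit$converged
  }
  if (any(!converged)) {
    warning("run(s) ", paste(which(!converged), collapse = ", "),
            " did not converge; averaging over converged runs")
  }
  use <- if (any(converged)) converged else rep(TRUE, n_runs)
  averaged <- colMeans(per_run[use, , drop = FALSE])
  mean_abs <- colMeans(abs(per_run[use, , drop = FALSE]))
  ranking <- names(sort(abs(averaged), decreasing = TRUE))
  structure(list(per_run_coefficients = per_run,
                 averaged_coefficients = averaged,
                 mean_abs_coefficients = mean_abs,
                 ranking = ranking,
                 selected_set = names(averaged)[averaged != 0],
                 lambdas = lambdas, runs_converged = converged,
                 column_info = d$info),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("selection_summary: %d runs, %d/%d predictors selected\n",
              nrow(x$per_run_coefficients), length(x$selected_set),
              length(x$averaged_coefficients)))
  cat("top of ranking:", paste(head(x$ranking, 5), collapse = " > "), "\n")
  invisible(x)
}

#' Top-ranked predictors
#'
#' The leading entries of a selection ranking. With `numeric_only = TRUE`
#' (the default) categorical indicator columns are excluded, matching the
#' reporting convention for the headline predictor table, since one
#' categorical field may expand to many dummy columns.
#'
#' @param summary an [average_lasso_runs()] result.
#' @param k number of predictors.
#' @param numeric_only restrict to raw numeric predictors.
#' @return character vector of predictor names, strongest first.
#' @export
top_predictors <- function(summary, k = 5, numeric_only = TRUE) {
  ranking <- summary$ranking
  if (numeric_only && !is.null(summary$column_info)) {
    numeric_cols <- summary$column_info$name[summary$column_info$type == "numeric"]
    ranking <- ranking[ranking %in% numeric_cols]
  }
  head(ranking, k)
}

#' Write a selection report
#'
#' @param summary an [average_lasso_runs()] result.
#' @param file JSON destination.
#' @return `file`, invisibly.
#' @export
write_selection <- function(summary, file) {
  jsonlite::write_json(list(
    ranking = summary$ranking,
    averaged_coefficients = as.list(summary$averaged_coefficients),
    mean_abs_coefficients = as.list(summary$mean_abs_coefficients),
    selected_set = summary$selected_set,
    lambdas = summary$lambdas
  ), file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
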