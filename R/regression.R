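# Dose prediction models: the outlier-robust regularized regression (RR,
# least-absolute-deviation loss plus an l2-norm coefficient penalty) and the
# ordinary-least-squares baseline, with shared prediction and goodness-of-fit
# diagnostics. The RR program
#   min_{b0, b} (1/N) * sum_i |y_i - b0 - x_i'b| + eps * ||b||_2
# is convex but nonsmooth; it is solved by ADMM with the splitting
# z = y - b0 - Xb (soft-threshold prox) and w = b (norm-shrink prox), with a
# cached Cholesky factor for the quadratic step. The intercept is never
# penalized: the dose scale should not be shrunk.

new_ct_model <- function(coefficients, intercept, method, penalty_weight,
                         solver_status, column_info = NULL) {
  structure(list(coefficients = coefficients, intercept = intercept,
                 method = method, penalty_weight = penalty_weight,
                 solver_status = solver_status, column_info = column_info),
            class = "ct_model")
}

#' @export
print.ct_model <- function(x, ...) {
  cat(sprintf("ct_model [%s]: intercept %.4g, %d coefficients%s (%s)\n",
              x$method, x$intercept, length(x$coefficients),
              if (x$method == "RR") sprintf(", eps = %.4g", x$penalty_weight)
              else "",
              x$solver_status))
  invisible(x)
}

#' @export
coef.ct_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

# ADMM for min_theta sum_i |y_i - a_i'theta| + (N*eps) * ||S theta||_2
# (the mean-loss objective times N, which keeps the prox step sizes on the
# scale of the residuals for any N). Splitting: z = y - A theta, w = S theta;
# the quadratic step reuses one Cholesky factor of A'A + S'S, which does not
# depend on rho, so the penalty parameter can be adapted for free.
rr_admm <- function(X, y, eps, rho = 1, max_iter = 20000L,
                    abstol = 1e-6, reltol = 1e-6) {
  n <- nrow(X)
  p <- ncol(X)
  A <- cbind(`(Intercept)` = 1, X)
  M <- crossprod(A)
  M[-1, -1] <- M[-1, -1] + diag(p) # + S'S from the w = b constraint
  R <- chol(M)
  gamma <- n * eps # penalty weight in the sum-loss scale
  theta <- numeric(p + 1)
  z <- numeric(n); w <- numeric(p)
  u <- numeric(n); v <- numeric(p)
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    rhs <- crossprod(A, y - z - u)
    rhs[-1] <- rhs[-1] + (w + v)
    theta_new <- backsolve(R, forwardsolve(t(R), rhs))
    Ath <- drop(A %*% theta_new)
    z_new <- soft_threshold(y - Ath - u, 1 / rho)
    t_w <- theta_new[-1] - v
    nt <- sqrt(sum(t_w^2))
    w_new <- if (nt > 0) max(0, 1 - gamma / (rho * nt)) * t_w else t_w
    # residuals of the two constraints
    r1 <- z_new - (y - Ath)
    r2 <- w_new - theta_new[-1]
    u <- u + r1
    v <- v + r2
    pri <- sqrt(sum(r1^2) + sum(r2^2))
    dua <- rho * sqrt(sum((z_new - z)^2) + sum((w_new - w)^2))
    z <- z_new; w <- w_new; theta <- theta_new
    scale_p <- max(sqrt(sum(z^2) + sum(w^2)),
                   sqrt(sum(Ath^2) + sum(theta[-1]^2)), sqrt(sum(y^2)))
    scale_d <- rho * sqrt(sum(u^2) + sum(v^2))
    if (pri < sqrt(n + p) * abstol + reltol * scale_p &&
        dua < sqrt(p + 1) * abstol + reltol * scale_d) {
      status <- "converged"
      break
    }
    # residual balancing (with rescaling of the scaled duals)
    if (it %% 10 == 0) {
      if (pri > 10 * dua) {
        rho <- rho * 2; u <- u / 2; v <- v / 2
      } else if (dua > 10 * pri) {
        rho <- rho / 2; u <- u * 2; v <- v * 2
      }
    }
  }
  # report the slopes from the proximal variable w: it carries the exact
  # zeros of the norm-shrink step (w and S*theta agree at convergence)
  list(intercept = theta[1], beta = drop(w), status = status,
       iterations = it, rho = rho)
}

rr_objective <- function(X, y, intercept, beta, eps) {
  mean(abs(y - intercept - drop(X %*% beta))) + eps * sqrt(sum(beta^2))
}

#' Fit the outlier-robust regularized regression
#'
#' Minimizes the mean absolute prediction error plus an l2-norm penalty on
#' the slope vector (intercept unpenalized). The absolute-error loss makes
#' the fitted plane track the non-outlying exams instead of being dragged
#' toward gross dose outliers, which is the property the residual-based
#' detector relies on.
#'
#' When `penalty_weight` is `NULL` it is chosen by 5-fold cross-validated
#' mean absolute error over the log grid `10^seq(-4, 0, length.out = 5)`.
#'
#' @param x design matrix (standardized) or numeric matrix.
#' @param y response (when `x` is a plain matrix).
#' @param penalty_weight nonnegative penalty `eps`, or `NULL` for the
#'   cross-validated default.
#' @param cv_folds,cv_grid,seed cross-validation controls (used only when
#'   `penalty_weight` is `NULL`).
#' @param rho,max_iter,abstol,reltol ADMM controls; tighten the tolerances for
#'   high-precision solutions on small problems.
#' @return an object of class `ct_model` with `method = "RR"`.
#' @export
fit_rr <- function(x, y = NULL, penalty_weight = NULL, cv_folds = 5,
                   cv_grid = 10^seq(-4, 0, length.out = 5), seed = 1,
                   rho = 1, max_iter = 20000L, abstol = 1e-6, reltol = 1e-6) {
  d <- resolve_xy(x, y)
  stop_if(any(!is.finite(d$x)) || any(!is.finite(d$y)),
          "non-finite values in the data")
  if (is.null(penalty_weight)) {
    penalty_weight <- cv_rr_eps(d$x, d$y, cv_folds, cv_grid, seed,
                                rho, max_iter)
  }
  stop_if(penalty_weight < 0, "penalty_weight must be >= 0")
  sol <- rr_admm(d$x, d$y, penalty_weight, rho, max_iter, abstol, reltol)
  if (sol$status != "converged") {
    warning("RR ADMM stopped at max_iter before reaching tolerance")
  }
  beta <- sol$beta
  names(beta) <- colnames(d$x)
  new_ct_model(beta, sol$intercept, "RR", penalty_weight, sol$status, d$info)
}

cv_rr_eps <- function(X, y, n_folds, grid, seed, rho, max_iter) {
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  err <- vapply(grid, function(eps) {
    mean(vapply(seq_len(n_folds), function(k) {
      tr <- fold != k
      sol <- rr_admm(X[tr, , drop = FALSE], y[tr], eps, rho,
                     max_iter, 1e-5, 1e-5)
      pred <- sol$intercept + drop(X[!tr, , drop = FALSE] %*% sol$beta)
      mean(abs(y[!tr] - pred))
    }, numeric(1)))
  }, numeric(1))
  grid[which.min(err)]
}

#' Fit the ordinary-least-squares baseline
#'
#' Plain least squares on the same design. With a rank-deficient design the
#' minimum-norm solution is returned with a warning (the situation a very
#' wide dummy-encoded design produces, and one reason variable selection
#' precedes the final model).
#'
#' @inheritParams fit_rr
#' @return an object of class `ct_model` with `method = "OLS"` and
#'   `penalty_weight = 0`.
#' @export
fit_ols <- function(x, y = NULL) {
  d <- resolve_xy(x, y)
  A <- cbind(`(Intercept)` = 1, d$x)
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    warning("rank-deficient design; returning the minimum-norm solution")
    sv <- svd(A)
    pos <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1]
    theta <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], d$y) / sv$d[pos])
    status <- "min_norm"
  } else {
    theta <- qr.coef(qr_A, d$y)
    status <- "ok"
  }
  theta <- drop(theta)
  beta <- theta[-1]
  names(beta) <- colnames(d$x)
  new_ct_model(beta, theta[1], "OLS", 0, status, d$info)
}

#' Predict doses from a fitted model
#'
#' `intercept + x'b` per exam. Columns are aligned by name; a mismatch
#' between the model's predictors and the matrix columns is an error listing
#' the missing and extra names.
#'
#' @param object a `ct_model`.
#' @param newdata design matrix or numeric matrix with named columns.
#' @param ... unused.
#' @return numeric vector of predicted doses (mGy).
#' @export
predict.ct_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "design_matrix")) newdata$values else
    as.matrix(newdata)
  have <- colnames(X)
  need <- names(object$coefficients)
  if (!identical(have, need)) {
    missing_cols <- setdiff(need, have)
    extra_cols <- setdiff(have, need)
    stop_if(length(missing_cols) > 0 || length(extra_cols) > 0,
            "column mismatch; missing: [",
            paste(missing_cols, collapse = ", "), "], extra: [",
            paste(extra_cols, collapse = ", "), "]")
    X <- X[, need, drop = FALSE]
  }
  object$intercept + drop(X %*% object$coefficients)
}

#' Model fit diagnostics
#'
#' Residuals (actual minus predicted dose), their sample standard deviation
#' (which the 3-SD outlier rule consumes), and the coefficient of
#' determination `R^2 = 1 - SSR / (N * Var(y))` with the population-variance
#' convention in the denominator (`Var(y) = mean((y - mean(y))^2)`), so that
#' predicting the mean for every exam gives exactly `R^2 = 0`.
#'
#' @param model a `ct_model`.
#' @param data design matrix (with response) to evaluate on — the training
#'   set, for the diagnostics the detector consumes.
#' @return an object of class `fit_diagnostics`: `residuals`, `residual_sd`,
#'   `r_squared`, `n`.
#' @export
model_diagnostics <- function(model, data) {
  stop_if(!inherits(data, "design_matrix"),
          "data must be a design_matrix (response needed)")
  y <- data$response
  stop_if(length(y) < 2, "need at least two exams")
  var_pop <- mean((y - mean(y))^2)
  stop_if(var_pop <= 0, "zero response variance")
  res <- y - predict(model, data)
  structure(list(residuals = res, residual_sd = sd(res),
                 r_squared = 1 - sum(res^2) / (length(y) * var_pop),
                 n = length(y)),
            class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("fit_diagnostics: n = %d, residual SD = %.4g mGy, R^2 = %.4f\n",
              x$n, x$residual_sd, x$r_squared))
  invisible(x)
}

#' Serialize / restore a fitted model
#'
#' Writes method, column names, intercept, coefficients, penalty weight and
#' (when available) the training standardization parameters as JSON, so a
#' saved model can score new CSV exports reproducibly.
#'
#' @param model a `ct_model`.
#' @param file JSON path.
#' @param center,scale optional standardization parameters to store alongside.
#' @return `file` invisibly; `read_model()` returns the restored `ct_model`
#'   with `center`/`scale` attributes when stored.
#' @export
write_model <- function(model, file, center = NULL, scale = NULL) {
  jsonlite::write_json(list(
    method = model$method,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    penalty_weight = model$penalty_weight,
    solver_status = model$solver_status,
    center = if (is.null(center)) NULL else as.list(center),
    scale = if (is.null(scale)) NULL else as.list(scale)
  ), file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_model
#' @export
read_model <- function(file) {
  o <- jsonlite::read_json(file, simplifyVector = TRUE)
  m <- new_ct_model(unlist(o$coefficients), o$intercept, o$method,
                    o$penalty_weight, o$solver_status)
  if (!is.null(o$center)) attr(m, "center") <- unlist(o$center)
  if (!is.null(o$scale)) attr(m, "scale") <- unlist(o$scale)
  m
}
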