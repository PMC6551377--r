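test_that("RR interpolates exactly-linear noiseless data at zero penalty", {
  set.seed(1)
  x <- matrix(rnorm(200 * 3), 200, 3)
  beta <- c(2, -1, 0.5)
  y <- 4 + drop(x %*% beta)
  fit <- fit_rr(x, y, penalty_weight = 0, abstol = 1e-10, reltol = 1e-10)
  expect_close(unname(fit$coefficients), beta, 1e-6)
  expect_close(fit$intercept, 4, 1e-6)
  expect_lt(max(abs(y - predict(fit, x))), 1e-5)
})

test_that("a gross outlier drags the OLS slope but not the RR slope", {
  x <- matrix(1:7, ncol = 1)
  y_clean <- 2 * (1:7)
  y <- y_clean
  y[7] <- y[7] + 20
  rr <- fit_rr(x, y, penalty_weight = 1e-3, abstol = 1e-10, reltol = 1e-10)
  ols <- fit_ols(x, y)
  expect_lt(abs(rr$coefficients - 2) / 2, 0.10)
  expect_gt(abs(ols$coefficients - 2) / 2, 0.25)
})

test_that("the RR solution matches a dense grid search on small instances", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(5), 5, 1)
    y <- 1 + 2 * x[, 1] + rnorm(5, 0, 0.5)
    eps <- 0.05
    fit <- fit_rr(x, y, penalty_weight = eps,
                  abstol = 1e-11, reltol = 1e-11, max_iter = 100000L)
    obj <- function(b0, b1) mean(abs(y - b0 - b1 * x[, 1])) + eps * abs(b1)
    grid <- expand.grid(b0 = seq(-1, 3, 2e-3), b1 = seq(0, 4, 2e-3))
    oracle <- min(mapply(obj, grid$b0, grid$b1))
    achieved <- obj(fit$intercept, fit$coefficients)
    expect_lt(achieved - oracle, 1e-4)
  }
})

test_that("OLS matches the normal equations and falls back to the
           minimum-norm solution when rank-deficient", {
  set.seed(2)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- drop(x %*% c(1, 2, -1, 0.5)) + rnorm(60, 0.3)
  fit <- fit_ols(x, y)
  oracle <- qr.coef(qr(cbind(1, x)), y)
  expect_close(c(fit$intercept, unname(fit$coefficients)), unname(oracle), 1e-8)

  xd <- cbind(x, dup = x[, 1]) # exact collinearity
  expect_warning(fitd <- fit_ols(xd, y), "minimum-norm")
  expect_equal(fitd$solver_status, "min_norm")
  # predictions still reproduce the least-squares fit
  expect_close(predict(fitd, xd), predict(fit, x), 1e-6)
  # the duplicated predictor's weight is split evenly (minimum norm)
  expect_close(fitd$coefficients[1], fitd$coefficients[5], 1e-8)
})

test_that("prediction is the affine map and checks column alignment", {
  m <- ctoutliers:::new_ct_model(c(a = 2, b = -1), 10, "OLS", 0, "ok")
  x <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(m, x), c(10 + 2 - 3, 10 + 4 - 4))
  m0 <- ctoutliers:::new_ct_model(c(a = 0, b = 0), 7, "OLS", 0, "ok")
  expect_equal(predict(m0, x), c(7, 7))
  bad <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "c")))
  expect_error(predict(m, bad), "missing: \\[b\\], extra: \\[c\\]")
})

test_that("R^2 uses the population-variance denominator", {
  dm <- make_design(cbind(x = c(1, 2, 4)), c(1, 2, 3))
  m <- ctoutliers:::new_ct_model(c(x = 1), 0, "OLS", 0, "ok")
  d <- model_diagnostics(m, dm)  # predictions {1,2,4}, SSR = 1
  expect_equal(d$r_squared, 0.5)
  expect_equal(d$residual_sd, sd(c(0, 0, -1)))

  # predicting the mean gives exactly zero
  dm2 <- make_design(cbind(x = c(1, 2, 3)), c(4, 5, 9))
  mean_model <- ctoutliers:::new_ct_model(c(x = 0), 6, "OLS", 0, "ok")
  expect_equal(model_diagnostics(mean_model, dm2)$r_squared, 0)

  perfect <- ctoutliers:::new_ct_model(c(x = 1), 0, "OLS", 0, "ok")
  dm3 <- make_design(cbind(x = c(1, 5, 7)), c(1, 5, 7))
  expect_equal(model_diagnostics(perfect, dm3)$r_squared, 1)

  const <- make_design(cbind(x = c(1, 2, 3)), c(2, 2, 2))
  expect_error(model_diagnostics(perfect, const), "zero response variance")
})

test_that("the returned RR solution beats the OLS coefficients under the
           RR objective", {
  set.seed(5)
  x <- matrix(rnorm(300 * 3), 300, 3)
  y <- 10 + drop(x %*% c(2, 1, -1)) + rnorm(300)
  y[1:6] <- y[1:6] * 3
  eps <- 0.01
  rr <- suppressWarnings( # the objective comparison below is the check
    fit_rr(x, y, penalty_weight = eps, abstol = 1e-9, reltol = 1e-9,
           max_iter = 100000L))
  ols <- fit_ols(x, y)
  obj <- function(m) mean(abs(y - predict(m, x))) +
    eps * sqrt(sum(m$coefficients^2))
  expect_lt(obj(rr), obj(ols) + 1e-8)
})

test_that("a large enough penalty shrinks RR to the median-only model", {
  set.seed(6)
  x <- matrix(rnorm(101 * 2), 101, 2)
  y <- 5 + x[, 1] + rnorm(101)
  fit <- suppressWarnings( # exact zeros and the 1e-3 intercept check follow
    fit_rr(x, y, penalty_weight = 50, abstol = 1e-10, reltol = 1e-10,
           max_iter = 100000L))
  expect_identical(unname(fit$coefficients), c(0, 0)) # exact zeros
  expect_close(fit$intercept, median(y), 1e-3)
})

test_that("rising contamination hurts OLS coefficients faster than RR", {
  beta <- c(3, 1.5, -1)
  err <- function(m) sqrt(sum((m$coefficients - beta)^2))
  gap <- vapply(c(0, 0.025, 0.05), function(contam) {
    mean(vapply(1:2, function(seed) {
      set.seed(100 + seed)
      n <- 1500
      x <- matrix(rnorm(n * 3), n, 3)
      y <- 20 + drop(x %*% beta) + rnorm(n)
      n_out <- round(contam * n)
      if (n_out > 0) {
        idx <- sample.int(n, n_out)
        y[idx] <- y[idx] * runif(n_out, 1.5, 3)
      }
      rr <- fit_rr(x, y, penalty_weight = 1e-3)
      ols <- fit_ols(x, y)
      err(ols) - err(rr)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gap) > 0)) # the OLS-RR error gap widens with contamination
  expect_gt(gap[3], 0)            # and OLS is strictly worse at 5%
})

test_that("model JSON serialization round-trips and scores identically", {
  set.seed(7)
  x <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + drop(x %*% c(1, 0.5, -2)) + rnorm(50, 0, 0.2)
  fit <- suppressWarnings(fit_rr(x, y, penalty_weight = 0.01,
                                 max_iter = 100000L))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f, center = c(a = 0, b = 0, c = 0), scale = c(a = 1, b = 1, c = 1))
  back <- read_model(f)
  expect_close(back$coefficients, fit$coefficients, 1e-10)
  expect_close(predict(back, x), predict(fit, x), 1e-10)
  expect_equal(attr(back, "scale"), c(a = 1, b = 1, c = 1))
})
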