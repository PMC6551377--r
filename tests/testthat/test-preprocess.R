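test_that("record filters drop the documented cases and keep order", {
  rec <- tiny_records()
  out <- filter_exams(rec, preprocess_config(max_missing_fraction = 0.5))
  # T1 complete body record survives; T2 missing weight; T3 head;
  # T4 has 6/8 predictor fields missing; T5 missing CTDIvol; T6 missing weight
  expect_equal(out$exam_id, "T01")
  log <- attr(out, "drop_log")
  expect_equal(setNames(log$reason, log$exam_id),
               c(T02 = "missing_weight", T03 = "head_exam",
                 T04 = "too_many_missing_fields", T05 = "missing_ctdi",
                 T06 = "missing_weight"))
  # 60% of fields missing vs a 0.75 threshold -> retained
  out2 <- filter_exams(rec, preprocess_config(max_missing_fraction = 0.9))
  expect_false("T04" %in% attr(out2, "drop_log")$exam_id)
  expect_error(filter_exams(rec[rec$exam_id == "T05", ], preprocess_config()),
               "no exams survive")
})

test_that("dummy encoding emits one indicator per retained level", {
  set.seed(4)
  n <- 60
  rec <- data.frame(
    exam_id = sprintf("E%02d", 1:n),
    gender = rep(c("F", "M"), n / 2),
    ctdi_vol = rnorm(n, 15),
    x1 = rnorm(n), stringsAsFactors = FALSE
  )
  dm <- encode_categoricals(rec, preprocess_config(rare_category_min_count = 1))
  expect_setequal(colnames(dm$values), c("x1", "gender=F", "gender=M"))
  gcols <- dm$values[, c("gender=F", "gender=M")]
  expect_true(all(rowSums(gcols) == 1))
  expect_true(all(gcols %in% c(0, 1)))
})

test_that("rare category levels are deleted; counts drive p", {
  n <- 203
  rec <- data.frame(
    exam_id = sprintf("E%03d", 1:n),
    scanner_type = c(rep("A", 100), rep("B", 100), rep("C", 3)),
    ctdi_vol = 10 + seq_len(n) / n,
    stringsAsFactors = FALSE
  )
  dm <- encode_categoricals(rec, preprocess_config(rare_category_min_count = 100))
  expect_setequal(colnames(dm$values), c("scanner_type=A", "scanner_type=B"))
  log <- attr(dm, "encode_log")
  expect_equal(log$level, "C")
  expect_equal(log$count, 3L)
  # rows carrying the deleted level keep zeros in the sibling dummies
  expect_true(all(dm$values[201:203, ] == 0))

  # 4 categoricals x 5 levels + 10 numerics -> p = 30
  set.seed(1)
  rec2 <- data.frame(exam_id = sprintf("E%03d", 1:100),
                     ctdi_vol = rnorm(100, 15))
  for (j in 1:10) rec2[[paste0("num", j)]] <- rnorm(100)
  for (j in 1:4) rec2[[paste0("cat", j)]] <- sample(LETTERS[1:5], 100, TRUE)
  dm2 <- encode_categoricals(rec2, preprocess_config(rare_category_min_count = 1))
  expect_equal(ncol(dm2$values), 30)
})

test_that("low-correlation pruning keeps |r| >= cutoff and drops constants", {
  set.seed(7)
  n <- 200
  y <- rnorm(n)
  e1 <- scale(y)[, 1] / sqrt(n - 1)           # unit vector along y
  u <- rnorm(n)
  u <- u - e1 * sum(e1 * u)
  u <- u / sqrt(sum(u^2))                     # unit vector orthogonal to y
  x_mid <- 0.30 * e1 + sqrt(1 - 0.09) * u    # cor exactly 0.30
  x_low <- 0.01 * e1 + sqrt(1 - 1e-4) * u    # cor exactly 0.01
  x <- cbind(identical_to_y = y, mid = x_mid, low = x_low, const = rep(2, n))
  dm <- make_design(x, y)
  out <- drop_low_correlation(dm, cutoff = 0.06)
  expect_setequal(colnames(out$values), c("identical_to_y", "mid"))
  log <- attr(out, "correlation_log")
  expect_equal(log$reason[log$name == "const"], "constant_column")
  expect_equal(log$reason[log$name == "low"], "low_correlation")
  expect_error(drop_low_correlation(dm, cutoff = 1.1), "all columns removed")
})

test_that("correlation uses pairwise-complete observations before imputation", {
  y <- c(1, 2, 3, 4, 5, 6)
  x <- cbind(a = c(1, 2, 3, NA, NA, NA), b = 6:1)
  dm <- make_design(x, y)
  out <- drop_low_correlation(dm, cutoff = 0.5)
  r <- attr(out, "correlation_log")$r
  expect_equal(r[1], 1)   # perfect on the three complete pairs
  expect_equal(r[2], -1)
})

test_that("imputation fills numeric means and categorical modes", {
  rec <- data.frame(
    exam_id = sprintf("E%02d", 1:8),
    num = c(1, NA, 3, 1, 2, 3, 2, 2),
    cat_mode = c("A", "A", "B", NA, "A", "B", "A", "B"),
    cat_tie = c("A", "A", "B", "B", NA, "A", "B", NA),
    ctdi_vol = 1:8, stringsAsFactors = FALSE
  )
  dm <- encode_categoricals(rec, preprocess_config(rare_category_min_count = 1))
  out <- impute_missing(dm)
  expect_false(anyNA(out$values))
  expect_equal(unname(out$values[2, "num"]), 2)       # mean of observed {1,3,1,2,3,2,2}
  expect_equal(unname(out$values[4, "cat_mode=A"]), 1) # mode A (4 vs 3)
  expect_equal(unname(out$values[4, "cat_mode=B"]), 0)
  # tie A=3, B=3 -> lexicographically smallest level
  expect_equal(unname(out$values[5, "cat_tie=A"]), 1)
  expect_equal(unname(out$values[8, "cat_tie=A"]), 1)
})

test_that("fully missing columns are an error naming the column", {
  dm <- make_design(cbind(ok = c(1, 2, 3), bad = c(NA, NA, NA)), 1:3)
  expect_error(impute_missing(dm), "bad")
})

test_that("standardization uses the sample-SD convention and stored
           training parameters for held-out rows", {
  dm <- make_design(cbind(x = c(0, 2)), c(1, 2))
  out <- standardize(dm)
  expect_equal(out$values[, "x"], c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # idempotence: standardizing an already-standardized column is a no-op
  out2 <- standardize(out)
  expect_equal(out2$values, out$values, tolerance = 1e-12)

  # held-out rows are transformed with the training mean/SD, not their own
  dm3 <- make_design(cbind(x = c(0, 2, 10)), c(1, 2, 3))
  out3 <- standardize(dm3, rows = 1:2)
  expect_equal(unname(out3$values[3, "x"]), (10 - 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(out3$center[["x"]], 1)

  const <- make_design(cbind(x = c(1, 1, 1)), 1:3)
  expect_error(standardize(const), "zero-SD")
})

test_that("the random split partitions ids reproducibly", {
  ids <- sprintf("E%02d", 1:10)
  s <- split_exams(ids, 0.8, seed = 3)
  expect_length(s$train_ids, 8)
  expect_length(s$test_ids, 2)
  expect_setequal(c(s$train_ids, s$test_ids), ids)
  expect_identical(s, split_exams(ids, 0.8, seed = 3))
  parts <- vapply(1:5, function(sd)
    paste(split_exams(ids, 0.8, seed = sd)$test_ids, collapse = ","),
    character(1))
  expect_gt(length(unique(parts)), 1)
  expect_error(split_exams(ids, 1.0), "train_fraction")
  expect_error(split_exams(ids[1], 0.5), "at least two")
})

test_that("the fitted pipeline transform is reproducible on its own
           training data and transfers to new exports", {
  cohort <- generate_cohort(synthetic_config(n_exams = 1500, seed = 13))
  cfg <- preprocess_config(rare_category_min_count = 20, seed = 5)
  pp <- preprocess(cohort, cfg)
  # training columns are standardized on the training rows
  expect_close(colMeans(pp$train$values), rep(0, ncol(pp$train$values)), 1e-8)
  expect_close(apply(pp$train$values, 2, sd), rep(1, ncol(pp$train$values)), 1e-8)
  # re-applying the stored transform reproduces the matrix exactly
  re <- apply_preprocess(pp, cohort)
  expect_identical(re$exam_ids, pp$design$exam_ids)
  expect_equal(re$values, pp$design$values, tolerance = 1e-12)
  # the report accounts for every drop
  rep_ <- pp$report
  expect_equal(rep_$n_input - rep_$n_retained,
               sum(unlist(rep_$drops_by_reason)))
  expect_true(all(c("tube_current", "kvp", "weight") %in%
                    colnames(pp$design$values)))
  # decoys are pruned by the correlation rule
  expect_false(any(c("age", "pitch_factor") %in% colnames(pp$design$values)))
})
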