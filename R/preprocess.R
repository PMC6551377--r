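# Pre-processing of the exam table into a model-ready design matrix:
# record filters, dummy encoding with rare-level deletion, low-correlation
# pruning, mean/mode imputation, standardization, and the random train/test
# split. All data-driven statistics (correlations, imputation values, column
# means/SDs) are computed on the training rows only and reused for test rows,
# so the held-out set cannot leak into the fitted transform.

META_FIELDS <- c("exam_id", "body_region", "ctdi_vol", "is_injected_outlier")

#' Pre-processing configuration
#'
#' @param max_missing_fraction drop a record when more than this fraction of
#'   its predictor fields is missing.
#' @param correlation_cutoff drop a column when the absolute Pearson
#'   correlation between it and CTDIvol falls below this value (default 0.06,
#'   the threshold separating informative from uninformative predictors).
#' @param rare_category_min_count delete a categorical level observed in fewer
#'   than this many exams (no indicator column is emitted for it).
#' @param train_fraction fraction of exams assigned to the training split.
#' @param seed integer seed for the random split.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(max_missing_fraction = 0.5,
                              correlation_cutoff = 0.06,
                              rare_category_min_count = 100,
                              train_fraction = 0.8,
                              seed = 1) {
  stop_if(!is_prop(max_missing_fraction) || max_missing_fraction <= 0,
          "max_missing_fraction must be in (0, 1]")
  stop_if(!is.numeric(correlation_cutoff) || correlation_cutoff < 0 ||
            correlation_cutoff >= 1, "correlation_cutoff must be in [0, 1)")
  stop_if(!is.numeric(rare_category_min_count) || rare_category_min_count < 0,
          "rare_category_min_count must be a nonnegative count")
  stop_if(!is_prop(train_fraction, open_hi = TRUE) || train_fraction <= 0,
          "train_fraction must be in (0, 1)")
  structure(list(max_missing_fraction = max_missing_fraction,
                 correlation_cutoff = correlation_cutoff,
                 rare_category_min_count = as.integer(rare_category_min_count),
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

predictor_fields <- function(records) setdiff(names(records), META_FIELDS)

#' Filter exam records
#'
#' Discards records with a missing CTDIvol, a missing patient weight, a head
#' body region (only body exams are analyzed), or more than
#' `max_missing_fraction` of their predictor fields missing. Record order is
#' preserved; every drop is logged with a reason code in the `"drop_log"`
#' attribute.
#'
#' @param records exam data.frame (see [generate_cohort()] for the layout).
#' @param config a [preprocess_config()].
#' @return the retained records, with a `drop_log` attribute
#'   (`exam_id`, `reason`).
#' @export
filter_exams <- function(records, config = preprocess_config()) {
  stop_if(nrow(records) == 0, "records is empty")
  fields <- predictor_fields(records)
  miss_frac <- rowMeans(is.na(records[fields]))
  reason <- rep(NA_character_, nrow(records))
  reason[miss_frac > config$max_missing_fraction] <- "too_many_missing_fields"
  if ("body_region" %in% names(records)) {
    reason[records$body_region == "head"] <- "head_exam"
  }
  if ("weight" %in% names(records)) reason[is.na(records$weight)] <- "missing_weight"
  reason[is.na(records$ctdi_vol)] <- "missing_ctdi"
  keep <- is.na(reason)
  stop_if(!any(keep), "no exams survive filtering")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- data.frame(exam_id = records$exam_id[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Encode predictors into a partial design matrix
#'
#' Numeric predictors are carried through unchanged; each categorical field is
#' expanded into one {0,1} indicator column per level. Levels observed in
#' fewer than `rare_category_min_count` exams get no column (rows carrying a
#' rare level keep zeros in all sibling indicators); a field whose levels are
#' all rare is removed entirely and logged. Rows where the categorical value
#' is missing get `NA` in all sibling indicators, to be filled by
#' [impute_missing()] with the modal level.
#'
#' @param records filtered exam data.frame (must contain `ctdi_vol`).
#' @param config a [preprocess_config()].
#' @return an unstandardized [design matrix][print.design_matrix] (may contain
#'   `NA`s), with an `encode_log` attribute listing deleted rare levels.
#' @export
encode_categoricals <- function(records, config = preprocess_config()) {
  fields <- predictor_fields(records)
  is_num <- vapply(records[fields], is.numeric, logical(1))
  num_fields <- fields[is_num]
  cat_fields <- fields[!is_num]

  cols <- list()
  info <- list()
  log <- list()
  for (f in num_fields) {
    cols[[f]] <- as.numeric(records[[f]])
    info[[f]] <- data.frame(name = f, type = "numeric", source = f,
                            level = NA_character_, stringsAsFactors = FALSE)
  }
  for (f in cat_fields) {
    v <- as.character(records[[f]])
    counts <- table(v[!is.na(v)])
    keep_levels <- sort(names(counts)[counts >= config$rare_category_min_count])
    dropped <- setdiff(names(counts), keep_levels)
    if (length(dropped) > 0) {
      log[[f]] <- data.frame(field = f, level = dropped,
                             count = as.integer(counts[dropped]),
                             stringsAsFactors = FALSE)
    }
    if (length(keep_levels) == 0) next # whole field removed, logged above
    for (lev in keep_levels) {
      nm <- paste0(f, "=", lev)
      x <- as.numeric(v == lev)
      x[is.na(v)] <- NA
      cols[[nm]] <- x
      info[[nm]] <- data.frame(name = nm, type = "dummy", source = f,
                               level = lev, stringsAsFactors = FALSE)
    }
  }
  stop_if(length(cols) == 0, "no predictor columns could be encoded")
  dm <- new_design_matrix(do.call(cbind, cols), records$ctdi_vol,
                          records$exam_id, do.call(rbind, info))
  rownames(dm$column_info) <- NULL
  empty_log <- data.frame(field = character(), level = character(),
                          count = integer(), stringsAsFactors = FALSE)
  attr(dm, "encode_log") <-
    if (length(log)) do.call(rbind, unname(log)) else empty_log
  dm
}

#' Prune columns with low dose correlation
#'
#' Computes the Pearson correlation between each column and CTDIvol on
#' pairwise-complete observations (before imputation, so imputed values cannot
#' manufacture correlation) and keeps columns with `|r| >= cutoff`. Columns
#' that are constant on the complete pairs have undefined correlation and are
#' removed. The decision can be made on a row subset (`rows`, typically the
#' training split) and is then applied to the whole matrix.
#'
#' @param dm a design matrix with response.
#' @param cutoff absolute-correlation threshold.
#' @param rows optional integer row subset used to compute correlations.
#' @return the pruned design matrix, with a `correlation_log` attribute
#'   (`name`, `r`, `dropped`, `reason`).
#' @export
drop_low_correlation <- function(dm, cutoff = 0.06, rows = NULL) {
  x <- if (is.null(rows)) dm$values else dm$values[rows, , drop = FALSE]
  y <- if (is.null(rows)) dm$response else dm$response[rows]
  r <- suppressWarnings(
    apply(x, 2, function(col) cor(col, y, use = "pairwise.complete.obs"))
  )
  constant <- !is.finite(r)
  keep <- !constant & abs(r) >= cutoff
  log <- data.frame(name = dm$column_info$name, r = r,
                    dropped = !keep,
                    reason = ifelse(constant, "constant_column",
                                    ifelse(keep, NA, "low_correlation")),
                    stringsAsFactors = FALSE)
  stop_if(!any(keep), "all columns removed by the correlation filter")
  out <- design_columns(dm, dm$column_info$name[keep])
  attr(out, "correlation_log") <- log
  out
}

# Imputation statistics from a row subset: numeric column means of observed
# values; per categorical field the modal level among observed rows
# (ties broken by the lexicographically smallest level).
impute_stats <- function(dm, rows = NULL) {
  x <- if (is.null(rows)) dm$values else dm$values[rows, , drop = FALSE]
  info <- dm$column_info
  means <- colMeans(x, na.rm = TRUE)
  fully_missing <- !is.finite(means)
  stop_if(any(fully_missing), "column(s) fully missing: ",
          paste(info$name[fully_missing], collapse = ", "))
  modes <- list()
  for (f in unique(info$source[info$type == "dummy"])) {
    idx <- which(info$source == f & info$type == "dummy")
    sums <- colSums(x[, idx, drop = FALSE], na.rm = TRUE)
    lev <- info$level[idx]
    best <- lev[sums == max(sums)]
    modes[[f]] <- sort(best)[1]
  }
  list(numeric_means = means[info$type == "numeric"], modes = modes)
}

#' Impute missing design-matrix entries
#'
#' Numeric gaps are replaced by the column mean of observed values; a missing
#' categorical value is replaced by the field's modal level (its indicator set
#' to 1, siblings to 0), equivalent to mode imputation before encoding. When
#' the mode is tied, the lexicographically smallest level wins. Statistics are
#' computed on `rows` (training split) unless precomputed `stats` are given.
#'
#' @param dm a design matrix (possibly with `NA`s).
#' @param stats optional precomputed statistics (from a previous call's
#'   `"impute_stats"` attribute) to reuse, e.g. on new data.
#' @param rows optional integer row subset from which statistics are computed.
#' @return the design matrix without missing entries; the statistics used are
#'   attached as attribute `"impute_stats"`.
#' @export
impute_missing <- function(dm, stats = NULL, rows = NULL) {
  if (is.null(stats)) stats <- impute_stats(dm, rows)
  x <- dm$values
  info <- dm$column_info
  for (j in which(info$type == "numeric")) {
    x[is.na(x[, j]), j] <- stats$numeric_means[[info$name[j]]]
  }
  for (f in names(stats$modes)) {
    idx <- which(info$source == f & info$type == "dummy")
    if (length(idx) == 0) next
    na_rows <- which(is.na(x[, idx[1]]))
    if (length(na_rows) == 0) next
    x[na_rows, idx] <- 0
    mode_col <- idx[info$level[idx] == stats$modes[[f]]]
    if (length(mode_col) == 1) x[na_rows, mode_col] <- 1
  }
  stop_if(anyNA(x), "missing entries remain after imputation")
  out <- new_design_matrix(x, dm$response, dm$exam_ids, info)
  attr(out, "impute_stats") <- stats
  out
}

#' Standardize design-matrix columns
#'
#' Z-scores every column: subtract the mean, divide by the sample (n-1)
#' standard deviation. The sample-SD convention is deliberate and documented:
#' the column `{0, 2}` becomes `{-0.707, +0.707}`, not `{-1, +1}`. Means and
#' SDs are computed on `rows` (training split) unless `center`/`scale` are
#' supplied, and are stored on the result so held-out or new exams are
#' transformed with the training parameters, never their own.
#'
#' @param dm an imputed design matrix (no `NA`s, no constant columns).
#' @param center,scale optional per-column means/SDs to apply.
#' @param rows optional integer row subset from which means/SDs are computed.
#' @return the standardized design matrix with `center` and `scale` filled in.
#' @export
standardize <- function(dm, center = NULL, scale = NULL, rows = NULL) {
  stop_if(anyNA(dm$values), "impute before standardizing")
  if (is.null(center) || is.null(scale)) {
    x <- if (is.null(rows)) dm$values else dm$values[rows, , drop = FALSE]
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
  }
  zero <- scale <= 0 | !is.finite(scale)
  stop_if(any(zero), "zero-SD column(s), should have been pruned: ",
          paste(dm$column_info$name[zero], collapse = ", "))
  vals <- sweep(sweep(dm$values, 2, center, "-"), 2, scale, "/")
  new_design_matrix(vals, dm$response, dm$exam_ids, dm$column_info,
                    center = center, scale = scale)
}

#' Random train/test split
#'
#' Uniform random partition of the exam identifiers, reproducible under the
#' seed.
#'
#' @param exam_ids vector of identifiers (N >= 2).
#' @param train_fraction fraction assigned to the training set.
#' @param seed integer seed.
#' @return list with disjoint `train_ids` and `test_ids` covering all ids.
#' @export
split_exams <- function(exam_ids, train_fraction = 0.8, seed = 1) {
  n <- length(exam_ids)
  stop_if(n < 2, "need at least two exams to split")
  stop_if(train_fraction <= 0 || train_fraction >= 1,
          "train_fraction must be in (0, 1)")
  set.seed(seed)
  n_train <- round(train_fraction * n)
  stop_if(n_train < 1 || n_train >= n, "degenerate split")
  train <- sort(sample.int(n, n_train))
  list(train_ids = exam_ids[train], test_ids = exam_ids[-train])
}

#' Run the full pre-processing pipeline
#'
#' Applies, in order: record filters, dummy encoding with rare-level deletion,
#' the random train/test split, low-correlation pruning, mean/mode imputation
#' and standardization — with every data-driven statistic computed on the
#' training rows and applied unchanged to the test rows.
#'
#' @param records exam data.frame.
#' @param config a [preprocess_config()].
#' @return an object of class `ct_preprocessed`: `design` (all retained
#'   exams, standardized), `train` / `test` (row subsets), `split`, and a
#'   `report` list of per-rule drop counts and column decisions.
#' @export
preprocess <- function(records, config = preprocess_config()) {
  filtered <- filter_exams(records, config)
  drop_log <- attr(filtered, "drop_log")
  dm <- encode_categoricals(filtered, config)
  encode_log <- attr(dm, "encode_log")
  split <- split_exams(dm$exam_ids, config$train_fraction, config$seed)
  train_rows <- which(dm$exam_ids %in% split$train_ids)

  dm <- drop_low_correlation(dm, config$correlation_cutoff, rows = train_rows)
  corr_log <- attr(dm, "correlation_log")
  dm <- impute_missing(dm, rows = train_rows)
  stats <- attr(dm, "impute_stats")
  dm <- standardize(dm, rows = train_rows)

  report <- list(
    n_input = nrow(records),
    n_retained = nrow(dm$values),
    drops_by_reason = as.list(table(drop_log$reason)),
    p_encoded = nrow(corr_log),
    rare_levels_deleted = encode_log,
    columns_pruned = corr_log[corr_log$dropped, c("name", "r", "reason")],
    p_final = ncol(dm$values),
    n_train = length(split$train_ids),
    n_test = length(split$test_ids)
  )
  structure(list(
    design = dm,
    train = design_rows(dm, train_rows),
    test = design_rows(dm, setdiff(seq_along(dm$exam_ids), train_rows)),
    split = split,
    impute_stats = stats,
    report = report,
    config = config
  ), class = "ct_preprocessed")
}

#' @export
print.ct_preprocessed <- function(x, ...) {
  r <- x$report
  cat(sprintf("ct_preprocessed: %d of %d exams retained, %d of %d columns kept\n",
              r$n_retained, r$n_input, r$p_final, r$p_encoded))
  cat(sprintf("  train %d / test %d\n", r$n_train, r$n_test))
  invisible(x)
}

#' Apply a fitted pre-processing transform to new records
#'
#' Re-applies the record filters, the stored dummy columns, the stored
#' imputation statistics and the stored training means/SDs to a new exam
#' table, so a saved model can score new CSV exports with exactly the
#' training-time transform.
#'
#' @param pp a [preprocess()] result.
#' @param records new exam data.frame with the same fields.
#' @return a standardized design matrix aligned to the fitted columns.
#' @export
apply_preprocess <- function(pp, records) {
  filtered <- filter_exams(records, pp$config)
  info <- pp$design$column_info
  n <- nrow(filtered)
  x <- matrix(NA_real_, n, nrow(info))
  for (j in seq_len(nrow(info))) {
    if (info$type[j] == "numeric") {
      stop_if(!info$source[j] %in% names(filtered),
              "missing field in new records: ", info$source[j])
      x[, j] <- as.numeric(filtered[[info$source[j]]])
    } else {
      v <- as.character(filtered[[info$source[j]]])
      xi <- as.numeric(v == info$level[j])
      xi[is.na(v)] <- NA
      x[, j] <- xi
    }
  }
  dm <- new_design_matrix(x, filtered$ctdi_vol, filtered$exam_id, info)
  dm <- impute_missing(dm, stats = pp$impute_stats)
  standardize(dm, center = pp$design$center, scale = pp$design$scale)
}
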