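# The design_matrix is the package's working container: an N x p numeric
# predictor grid together with the CTDIvol response, exam identifiers,
# per-column provenance (raw numeric vs dummy of a categorical level) and,
# once standardized, the training column means/SDs used for the transform.

new_design_matrix <- function(values, response, exam_ids, column_info,
                              center = NULL, scale = NULL) {
  stopifnot(is.matrix(values), nrow(values) == length(response),
            length(exam_ids) == length(response),
            nrow(column_info) == ncol(values))
  colnames(values) <- column_info$name
  structure(list(values = values, response = response, exam_ids = exam_ids,
                 column_info = column_info, center = center, scale = scale),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d exams x %d columns (%d numeric, %d dummy)%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$column_info$type == "numeric"),
              sum(x$column_info$type == "dummy"),
              if (is.null(x$center)) "" else ", standardized"))
  if (anyNA(x$values)) cat(sprintf("  missing entries: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.design_matrix <- function(x) dim(x$values)

# Row subset (used to carve out train/test splits).
design_rows <- function(dm, idx) {
  new_design_matrix(dm$values[idx, , drop = FALSE], dm$response[idx],
                    dm$exam_ids[idx], dm$column_info, dm$center, dm$scale)
}

# Column subset by name (used to feed the LASSO-selected set to RR/OLS).
design_columns <- function(dm, cols) {
  keep <- match(cols, dm$column_info$name)
  stop_if(anyNA(keep), "unknown columns: ",
          paste(cols[is.na(keep)], collapse = ", "))
  new_design_matrix(dm$values[, keep, drop = FALSE], dm$response, dm$exam_ids,
                    dm$column_info[keep, , drop = FALSE],
                    dm$center[keep], dm$scale[keep])
}
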