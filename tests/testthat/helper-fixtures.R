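# Shared fixtures, all built in code.

# A tiny hand-made exam table exercising every filter rule.
tiny_records <- function() {
  data.frame(
    exam_id = sprintf("T%02d", 1:6),
    body_region = c("body", "body", "head", "body", "body", "body"),
    tube_current = c(200, 210, 190, NA, 220, NA),
    kvp = c(120, 120, 100, NA, 140, 120),
    weight = c(70, NA, 80, 75, 85, NA),
    reference_mas = c(150, 140, 160, NA, NA, NA),
    scan_length = c(40, 38, 20, NA, 45, NA),
    gender = c("F", "M", "F", NA, "M", NA),
    scanner_type = c("A", "A", "B", NA, "B", NA),
    ctdi_vol = c(15, 14, 40, 16, NA, 13),
    stringsAsFactors = FALSE
  )
}

# Plain design matrix wrapper around a numeric matrix + response.
make_design <- function(x, y, ids = sprintf("E%03d", seq_along(y)),
                        type = rep("numeric", ncol(x))) {
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  info <- data.frame(name = colnames(x), type = type,
                     source = colnames(x), level = NA_character_,
                     stringsAsFactors = FALSE)
  ctoutliers:::new_design_matrix(x, y, ids, info)
}

# n x p design whose centered columns are orthogonal with mean squared
# norm 1 (so the lasso solution is the analytic soft-threshold).
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  q <- sweep(q, 2, colMeans(q)) # recentre
  q <- qr.Q(qr(q))              # re-orthogonalize the centered columns
  sweep(q, 2, sqrt(colMeans(q^2)), "/")
}

expect_close <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max |diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
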