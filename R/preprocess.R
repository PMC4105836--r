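# Flag filtering and quantile normalization, mirroring the array-software
# preprocessing the study describes.

#' Keep genes detected on enough arrays
#'
#' Retains exactly the genes whose detection flag is set on at least
#' `min_flagged_arrays` arrays ("flags" read as Present/detected calls; the
#' study keeps genes flagged on at least two of its six arrays). Gene order is
#' preserved.
#'
#' @param x An `expr_matrix` with flags attached.
#' @param min_flagged_arrays Minimum number of detected arrays (default 2).
#' @return The filtered `expr_matrix` (flags retained).
#' @export
filter_by_flags <- function(x, min_flagged_arrays = 2L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$flags)) stop("expression matrix carries no detection flags", call. = FALSE)
  assert_scalar_number(min_flagged_arrays, "min_flagged_arrays", 0, ncol(x$values))
  keep <- rowSums(x$flags) >= min_flagged_arrays
  expression_matrix(x$values[keep, , drop = FALSE], x$design,
                    flags = x$flags[keep, , drop = FALSE])
}

#' Quantile-normalize arrays
#'
#' After normalization every array's sorted values equal the across-array mean
#' of order statistics, so all arrays share one empirical distribution. Ties
#' within an array receive the mean of the normalized values they span. The
#' operation is idempotent and preserves gene and array order.
#'
#' @param x An `expr_matrix` (at least two arrays, no missing values).
#' @return The normalized `expr_matrix`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (ncol(v) < 2L) stop("quantile normalization needs at least two arrays", call. = FALSE)
  if (anyNA(v) || any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  mu <- rowMeans(apply(v, 2L, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    q <- mu[rank(col, ties.method = "first")]
    # ties get the mean of the order-statistic means they span
    out[, j] <- stats::ave(q, match(col, col), FUN = mean)
  }
  expression_matrix(out, x$design, flags = x$flags)
}
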