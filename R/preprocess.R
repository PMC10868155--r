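#' Log-transform an expression matrix
#'
#' Replaces every entry x by log2(x + 1). The pseudocount of 1 keeps zeros
#' at zero and makes the transform well defined on sparse count matrices;
#' log scaling models proportional rather than additive changes and damps
#' the influence of extreme values before the matrix is fed to the
#' autoencoder.
#'
#' @param m Expression matrix (non-negative; see [expression_matrix()]).
#' @return Matrix of the same shape and dimnames with entries log2(x + 1).
#' @export
log_transform <- function(m) {
  assert_expression_matrix(m)
  if (any(m < 0)) stop("log_transform requires non-negative values",
                       call. = FALSE)
  log2(m + 1)
}

#' Scale each row of a matrix to [0, 1] by its maximum
#'
#' Divides every row by its own maximum value so each gene's profile lies
#' in [0, 1], the output range of the autoencoder's sigmoid layer. All-zero
#' rows are left untouched (no division by zero); such genes carry no
#' signal and are excluded from pair scoring downstream.
#'
#' @param m Expression matrix (non-negative).
#' @return Matrix of the same shape with every non-degenerate row attaining
#'   a maximum of exactly 1. The identifiers of all-zero rows are attached
#'   as attribute `"zero_rows"`.
#' @export
row_max_scale <- function(m) {
  assert_expression_matrix(m)
  if (any(m < 0)) stop("row_max_scale requires non-negative values",
                       call. = FALSE)
  mx <- apply(m, 1L, max)
  zero <- mx == 0
  scale_by <- ifelse(zero, 1, mx)
  out <- m / scale_by
  attr(out, "zero_rows") <- rownames(m)[zero]
  out
}

#' Standard preprocessing: log transform then row-max scaling
#'
#' The two-step transform the autoencoder consumes: log2(x + 1) (optional,
#' skip for already-logged proteomics intensities) followed by scaling each
#' row to [0, 1] by its maximum.
#'
#' @param m Expression matrix.
#' @param log2_transform Apply the log step first? Default `TRUE`.
#' @return Scaled matrix with attribute `"zero_rows"` naming all-zero
#'   genes.
#' @export
preprocess_matrix <- function(m, log2_transform = TRUE) {
  if (log2_transform) m <- log_transform(m)
  row_max_scale(m)
}
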