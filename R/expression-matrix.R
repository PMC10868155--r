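#' Construct and validate an expression matrix
#'
#' An expression matrix holds non-negative expression values with genes as
#' rows and conditions (cells, samples, tissues) as columns. It is stored as
#' a plain numeric matrix whose `rownames` are gene identifiers and whose
#' `colnames` are condition identifiers; this constructor enforces the
#' invariants every downstream step relies on.
#'
#' @param values Numeric matrix of expression values, genes x conditions.
#' @param genes Character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param conditions Character vector of unique condition identifiers;
#'   defaults to `colnames(values)`.
#'
#' @details Missing values (`NA`) are replaced by 0, matching the sparse
#'   semantics of droplet scRNA-seq counts and label-free proteomics, where
#'   an unobserved entry is a (possibly technical) zero. Negative or
#'   non-finite values are an error: abundances must be non-negative.
#'
#' @return A numeric matrix with gene rownames and condition colnames.
#' @export
#' @examples
#' m <- expression_matrix(matrix(0:5, nrow = 2,
#'                               dimnames = list(c("g1", "g2"), NULL)))
expression_matrix <- function(values, genes = rownames(values),
                              conditions = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("an expression matrix needs at least 2 genes and 2 conditions",
         call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- sprintf("gene_%d", seq_len(nrow(values)))
  }
  if (is.null(conditions)) {
    conditions <- sprintf("cond_%d", seq_len(ncol(values)))
  }
  genes <- as.character(genes)
  conditions <- as.character(conditions)
  if (length(genes) != nrow(values)) {
    stop("length of 'genes' does not match the number of rows", call. = FALSE)
  }
  if (length(conditions) != ncol(values)) {
    stop("length of 'conditions' does not match the number of columns",
         call. = FALSE)
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene identifiers: ",
         paste(utils::head(dup, 10L), collapse = ", "),
         if (length(dup) > 10L) ", ..." else "", call. = FALSE)
  }
  values[is.na(values)] <- 0
  if (any(!is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  dimnames(values) <- list(genes, conditions)
  values
}

#' @keywords internal
#' @noRd
assert_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || is.null(rownames(m))) {
    stop("expected a gene-by-condition matrix as built by expression_matrix()",
         call. = FALSE)
  }
  invisible(m)
}
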