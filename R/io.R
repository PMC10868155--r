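#' Read an expression matrix from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`tsv` / `csv`}{Dense table with a header row of condition names
#'     and gene identifiers in the first column.}
#'   \item{`mtx`}{MatrixMarket sparse matrix (genes x conditions) with
#'     sidecar text files `<path>.rows` and `<path>.cols` holding one gene /
#'     condition identifier per line.}
#'   \item{`adx`}{An AnnData-style annotated matrix directory: a folder
#'     containing `matrix.mtx` stored in the conventional cells-by-genes
#'     orientation plus `obs_names.txt` (cells) and `var_names.txt` (genes).
#'     The matrix is transposed on load so that genes become rows, because
#'     the autoencoder treats each gene as one observation across
#'     conditions.}
#' }
#'
#' Empty cells and `NA` entries are read as 0 (sparse-count semantics);
#' negative values and duplicate gene identifiers are errors.
#'
#' @param path File (or, for `adx`, directory) to read.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`, `"adx"`.
#'   `"auto"` infers from the file extension (a directory implies `adx`).
#' @return A validated expression matrix (see [expression_matrix()]).
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx", "adx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "adx"
    } else {
      switch(tolower(tools::file_ext(path)),
             tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
             stop("cannot infer format from '", path,
                  "'; pass format= explicitly", call. = FALSE))
    }
  }
  if (format == "adx") {
    if (!dir.exists(path)) stop("adx path is not a directory: ", path,
                                call. = FALSE)
  } else if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }

  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, check.names = FALSE)
    if (ncol(dt) < 3L) {
      stop("malformed ", format, " matrix '", path,
           "': need a gene id column plus >= 2 condition columns",
           call. = FALSE)
    }
    genes <- as.character(dt[[1L]])
    vals <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- colnames(dt)[-1L][!vapply(dt[-1L], is.numeric, logical(1L))]
      stop("malformed ", format, " matrix '", path,
           "': non-numeric column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    return(expression_matrix(vals, genes = genes,
                             conditions = colnames(dt)[-1L]))
  }

  if (format == "mtx") {
    rows_file <- paste0(path, ".rows")
    cols_file <- paste0(path, ".cols")
    if (!file.exists(rows_file) || !file.exists(cols_file)) {
      stop("mtx sidecar files missing: expected ", rows_file, " and ",
           cols_file, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(rows_file)
    conditions <- readLines(cols_file)
    return(expression_matrix(m, genes = genes, conditions = conditions))
  }

  # adx: cells x genes on disk, transposed to genes x conditions on load
  mtx_file <- file.path(path, "matrix.mtx")
  obs_file <- file.path(path, "obs_names.txt")
  var_file <- file.path(path, "var_names.txt")
  for (f in c(mtx_file, obs_file, var_file)) {
    if (!file.exists(f)) stop("adx bundle incomplete, missing ", f,
                              call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(mtx_file))
  cells <- readLines(obs_file)
  genes <- readLines(var_file)
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    stop("adx bundle shape mismatch in ", path, call. = FALSE)
  }
  expression_matrix(t(m), genes = genes, conditions = cells)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix()]; see that function for the formats.
#'
#' @param m Expression matrix (genes x conditions).
#' @param path Output file, or directory for `format = "adx"`.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`, `"adx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "csv", "mtx", "adx")) {
  format <- match.arg(format)
  assert_expression_matrix(m)
  if (format %in% c("tsv", "csv")) {
    dt <- data.table::data.table(gene = rownames(m))
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::fwrite(dt, path, sep = if (format == "tsv") "\t" else ",")
  } else if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(m), paste0(path, ".rows"))
    writeLines(colnames(m), paste0(path, ".cols"))
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(t(m), sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(m), file.path(path, "obs_names.txt"))
    writeLines(rownames(m), file.path(path, "var_names.txt"))
  }
  invisible(path)
}

#' Write a scored network to a TSV file
#'
#' Emits one row per unordered gene pair with columns `gene1`, `gene2`,
#' `score` and, when present, `probability`. Pairs are written with
#' `gene1 < gene2` lexicographically, sorted by score descending with ties
#' broken by (`gene1`, `gene2`) ascending, so serialization is a total
#' order: re-serializing a parsed network is byte-identical.
#'
#' @param net A scored network (see [pairwise_pcc()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  net <- as_scored_network(net)
  if (nrow(net) == 0L) stop("refusing to write an empty network",
                            call. = FALSE)
  data.table::fwrite(net, path, sep = "\t",
                     col.names = TRUE, scipen = 50L)
  invisible(path)
}

#' Read a scored network from a TSV file
#'
#' @param path TSV written by [write_network()] (columns `gene1`, `gene2`,
#'   `score`, optional `probability`).
#' @return A scored network data frame, re-canonicalized and re-sorted.
#' @export
read_network <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("gene1", "gene2", "score")
  if (!all(need %in% colnames(dt))) {
    stop("network file '", path, "' lacks columns ",
         paste(setdiff(need, colnames(dt)), collapse = ", "), call. = FALSE)
  }
  as_scored_network(dt)
}

#' Canonicalize a pair table into a scored network
#'
#' Orients every pair so `gene1 < gene2`, drops self-pairs and duplicates,
#' and sorts by score descending, ties by (`gene1`, `gene2`) ascending.
#'
#' @param x Data frame with columns `gene1`, `gene2`, `score` and optional
#'   `probability`.
#' @return Canonical scored network data frame.
#' @export
as_scored_network <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (inherits(x, "vaenet_network") && isTRUE(attr(x, "canonical"))) {
    return(x)
  }
  g1 <- as.character(x$gene1)
  g2 <- as.character(x$gene2)
  flip <- g1 > g2
  tmp <- g1[flip]; g1[flip] <- g2[flip]; g2[flip] <- tmp
  keep <- g1 != g2
  out <- data.frame(gene1 = g1[keep], gene2 = g2[keep],
                    score = as.numeric(x$score)[keep],
                    stringsAsFactors = FALSE)
  if ("probability" %in% colnames(x)) {
    out$probability <- as.numeric(x$probability)[keep]
  }
  out <- out[!duplicated(paste(out$gene1, out$gene2, sep = "\r")), ,
             drop = FALSE]
  ord <- order(-out$score, out$gene1, out$gene2, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vaenet_network", "data.frame")
  attr(out, "canonical") <- TRUE
  out
}

#' Read a gold standard for benchmarking
#'
#' Two modes are supported, mirroring the two kinds of reference sets used
#' to label predicted pairs:
#' \describe{
#'   \item{`membership`}{Two-column TSV of (gene, group), e.g. pathway or
#'     complex membership. Two genes are a true positive pair when their
#'     group sets intersect.}
#'   \item{`pairs`}{Two-column TSV of interacting gene pairs, e.g. a
#'     physical interaction network. Pairs are canonicalized to unordered
#'     form; self-pairs are dropped (with a message reporting how many).}
#' }
#'
#' @param path Two-column TSV, no header.
#' @param mode `"membership"` or `"pairs"`.
#' @return An object of class `vaenet_gold`: for membership mode a list
#'   with `mode` and `membership` (named list gene -> character vector of
#'   groups); for pairs mode `mode`, `pair_keys` (canonical "a|b" keys) and
#'   `member_genes`.
#' @export
read_gold_standard <- function(path, mode = c("membership", "pairs")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty gold standard file: ", path,
                                  call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE, colClasses = "character")
  if (nrow(dt) == 0L) stop("empty gold standard file: ", path, call. = FALSE)
  if (ncol(dt) < 2L) stop("gold standard '", path,
                          "' must have two tab-separated columns",
                          call. = FALSE)
  if (mode == "membership") {
    gold_membership(dt[[1L]], dt[[2L]])
  } else {
    gold_pairs(dt[[1L]], dt[[2L]])
  }
}

#' Build a membership-mode gold standard in memory
#'
#' @param genes,groups Parallel character vectors: gene i belongs to
#'   group i.
#' @return A `vaenet_gold` object in membership mode.
#' @export
gold_membership <- function(genes, groups) {
  genes <- as.character(genes); groups <- as.character(groups)
  stopifnot(length(genes) == length(groups))
  membership <- lapply(split(groups, genes), unique)
  structure(list(mode = "membership", membership = membership),
            class = "vaenet_gold")
}

#' Build a pairs-mode gold standard in memory
#'
#' @param gene_a,gene_b Parallel character vectors of interacting pairs.
#' @return A `vaenet_gold` object in pairs mode. Self-pairs are dropped
#'   with a message.
#' @export
gold_pairs <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  stopifnot(length(gene_a) == length(gene_b))
  self <- gene_a == gene_b
  if (any(self)) {
    message("dropping ", sum(self), " self-pair(s) from gold standard")
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]
  }
  if (!length(gene_a)) stop("gold standard has no usable pairs",
                            call. = FALSE)
  keys <- pair_key(gene_a, gene_b)
  structure(list(mode = "pairs",
                 pair_keys = unique(keys),
                 member_genes = unique(c(gene_a, gene_b))),
            class = "vaenet_gold")
}

# canonical unordered-pair key; "|" is assumed absent from identifiers
#' @keywords internal
#' @noRd
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' @export
print.vaenet_gold <- function(x, ...) {
  if (x$mode == "membership") {
    cat("Gold standard (membership): ", length(x$membership), " genes, ",
        length(unique(unlist(x$membership))), " groups\n", sep = "")
  } else {
    cat("Gold standard (pairs): ", length(x$pair_keys), " pairs over ",
        length(x$member_genes), " genes\n", sep = "")
  }
  invisible(x)
}

#' @export
print.vaenet_network <- function(x, ...) {
  cat("Scored network: ", nrow(x), " pairs, ",
      length(unique(c(x$gene1, x$gene2))), " genes",
      if ("probability" %in% colnames(x)) ", calibrated" else "",
      "\n", sep = "")
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("... (", nrow(x) - 5L, " more pairs)\n", sep = "")
  invisible(x)
}
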