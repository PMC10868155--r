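#' Score all gene pairs by Pearson correlation in the latent space
#'
#' Computes the Pearson correlation between the latent embedding rows of
#' every pair of genes and returns the ranked association network: scores
#' descending, ties broken by (`gene1`, `gene2`) ascending, each pair
#' stored once with `gene1 < gene2`. Genes whose embedding has zero
#' variance across latent dimensions have no defined correlation; they are
#' excluded and recorded in the `"excluded_genes"` attribute.
#'
#' The correlation matrix is computed in row blocks so that networks over
#' many genes never require the full dense pair list in memory at once;
#' `score_floor` discards pairs below a threshold as blocks are streamed
#' out (the default -1 keeps everything).
#'
#' @param ls A `vaenet_latent` object from [train_vae()], or a plain
#'   numeric matrix of embeddings (genes x dimensions, gene rownames).
#' @param score_floor Drop pairs with score below this value (default -1,
#'   i.e. keep all pairs).
#' @param block_size Number of genes per block in the blocked correlation
#'   computation (default 512).
#' @return A scored network data frame (`gene1`, `gene2`, `score`) of
#'   class `vaenet_network`, with attribute `"excluded_genes"`.
#' @export
pairwise_pcc <- function(ls, score_floor = -1, block_size = 512L) {
  emb <- if (inherits(ls, "vaenet_latent")) ls$mu else as.matrix(ls)
  if (is.null(rownames(emb))) {
    stop("embedding matrix must have gene rownames", call. = FALSE)
  }
  if (nrow(emb) < 2L || ncol(emb) < 2L) {
    stop("need at least 2 genes and 2 latent dimensions", call. = FALSE)
  }
  vars <- apply(emb, 1L, stats::var)
  excluded <- rownames(emb)[vars == 0]
  if (length(excluded) == nrow(emb)) {
    stop("degenerate latent space: every gene embedding has zero variance",
         call. = FALSE)
  }
  if (length(excluded)) {
    emb <- emb[vars > 0, , drop = FALSE]
  }
  genes <- rownames(emb)
  k <- nrow(emb)
  te <- t(emb)                     # dims x genes; cor() works on columns

  blocks <- split(seq_len(k), ceiling(seq_len(k) / block_size))
  chunks <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    rows <- blocks[[bi]]
    cols <- seq(min(rows), k)      # upper triangle only
    cm <- stats::cor(te[, rows, drop = FALSE], te[, cols, drop = FALSE])
    ij <- which(outer(rows, cols, "<") & cm >= score_floor,
                arr.ind = TRUE)
    chunks[[bi]] <- data.frame(
      gene1 = genes[rows[ij[, 1L]]],
      gene2 = genes[cols[ij[, 2L]]],
      score = cm[ij],
      stringsAsFactors = FALSE)
  }
  net <- as_scored_network(do.call(rbind, chunks))
  attr(net, "excluded_genes") <- excluded
  net
}

#' Truncate or threshold a ranked network
#'
#' Takes the top-scoring prefix and/or applies a minimum-score threshold,
#' preserving the ranked order.
#'
#' @param net A scored network.
#' @param top_n Keep at most the first `top_n` pairs of the ranked list.
#' @param min_score Keep only pairs with `score >= min_score`.
#' @return The filtered scored network.
#' @export
filter_network <- function(net, top_n = NULL, min_score = NULL) {
  net <- as_scored_network(net)
  if (is.null(top_n) && is.null(min_score)) {
    stop("give at least one of top_n or min_score", call. = FALSE)
  }
  if (!is.null(min_score)) {
    net <- net[net$score >= min_score, , drop = FALSE]
  }
  if (!is.null(top_n)) {
    if (top_n <= 0) stop("top_n must be positive", call. = FALSE)
    net <- utils::head(net, top_n)
  }
  rownames(net) <- NULL
  class(net) <- c("vaenet_network", "data.frame")
  attr(net, "canonical") <- TRUE
  net
}

#' Annotate network pairs with a gene category
#'
#' Labels every pair by how many of its two genes belong to a category of
#' interest — typically an understudied-protein list such as the IDG
#' "Tdark" targets — so the network's coverage of that category can be
#' quantified.
#'
#' @param net A scored network.
#' @param category_genes Character vector of category member identifiers.
#' @return The network data frame with an added integer column
#'   `n_category` (0, 1 or 2), plus attribute `"category_summary"`: a list
#'   with `pairs_with_category` (pairs having at least one category gene)
#'   and `category_genes_covered` (distinct category genes present).
#' @export
annotate_categories <- function(net, category_genes) {
  net <- as_scored_network(net)
  category_genes <- unique(as.character(category_genes))
  n_cat <- (net$gene1 %in% category_genes) + (net$gene2 %in% category_genes)
  out <- net
  out$n_category <- as.integer(n_cat)
  covered <- intersect(category_genes, unique(c(net$gene1, net$gene2)))
  attr(out, "category_summary") <- list(
    pairs_with_category = sum(n_cat >= 1L),
    category_genes_covered = length(covered))
  out
}
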