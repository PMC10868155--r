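#' Classify gene pairs against a gold standard
#'
#' Applies the standard pathway-benchmark rules. In membership mode a pair
#' is a true positive (TP) when the two genes share at least one group
#' (pathway, complex), a false positive (FP) when both genes are annotated
#' but share no group, and EXCLUDED when either gene has no annotation at
#' all — unmappable pairs must not count against a method. In pairs mode a
#' pair is TP when it is in the reference pair set; by default a pair is
#' FP only when both genes occur somewhere in the reference set and
#' EXCLUDED otherwise, mirroring the unmappable rule. `strict_fp = TRUE`
#' instead counts every non-TP pair as FP.
#'
#' @param gene_a,gene_b Character vectors of equal length (no self-pairs).
#' @param gs A `vaenet_gold` object ([read_gold_standard()],
#'   [gold_membership()], [gold_pairs()]).
#' @param strict_fp Pairs mode only: count every absent pair as FP.
#' @return Character vector of labels `"TP"`, `"FP"`, `"EXCLUDED"`.
#' @export
classify_pairs <- function(gene_a, gene_b, gs, strict_fp = FALSE) {
  stopifnot(inherits(gs, "vaenet_gold"), length(gene_a) == length(gene_b))
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  if (any(gene_a == gene_b)) stop("self-pairs cannot be classified",
                                  call. = FALSE)
  n <- length(gene_a)
  if (gs$mode == "membership") {
    groups_a <- gs$membership[gene_a]
    groups_b <- gs$membership[gene_b]
    mapped <- !vapply(groups_a, is.null, logical(1L)) &
      !vapply(groups_b, is.null, logical(1L))
    out <- rep("EXCLUDED", n)
    shared <- logical(n)
    idx <- which(mapped)
    shared[idx] <- mapply(function(a, b) any(a %in% b),
                          groups_a[idx], groups_b[idx])
    out[mapped] <- ifelse(shared[mapped], "TP", "FP")
  } else {
    tp <- pair_key(gene_a, gene_b) %in% gs$pair_keys
    if (strict_fp) {
      out <- ifelse(tp, "TP", "FP")
    } else {
      mapped <- gene_a %in% gs$member_genes & gene_b %in% gs$member_genes
      out <- ifelse(tp, "TP", ifelse(mapped, "FP", "EXCLUDED"))
    }
  }
  out
}

#' @rdname classify_pairs
#' @param a,b Single gene identifiers.
#' @export
classify_pair <- function(a, b, gs, strict_fp = FALSE) {
  classify_pairs(a, b, gs, strict_fp = strict_fp)
}

#' Cumulative TP/FP curve of a ranked network
#'
#' Walks the network in rank order, labels each pair with
#' [classify_pairs()], skips EXCLUDED pairs, and accumulates true- and
#' false-positive counts — the standard way to visualize how well the top
#' of a ranked association list agrees with known pathways or
#' interactions.
#'
#' @param net A scored network, already ranked.
#' @param gs A `vaenet_gold` gold standard.
#' @param prefixes Optional integer vector: report the TP/FP summary after
#'   these many evaluable pairs (e.g. 10000).
#' @param strict_fp Passed to [classify_pairs()].
#' @return A list of class `vaenet_curve`: `points` (data frame `cum_fp`,
#'   `cum_tp`, one row per evaluable pair), `labels` (full TP/FP/EXCLUDED
#'   stream aligned with `net`), `scores` (scores of evaluable pairs),
#'   `n_excluded`, and `summary` (data frame with `prefix`, `tp`, `fp`,
#'   `ratio`, and `rank_in_full_list` — the position in the unfiltered
#'   ranking at which the prefix of evaluable pairs is reached).
#' @export
cumulative_curve <- function(net, gs, prefixes = NULL, strict_fp = FALSE) {
  net <- as_scored_network(net)
  labels <- classify_pairs(net$gene1, net$gene2, gs, strict_fp = strict_fp)
  eval_idx <- which(labels != "EXCLUDED")
  if (!length(eval_idx)) {
    genes_in_net <- unique(c(net$gene1, net$gene2))
    universe <- if (gs$mode == "membership") names(gs$membership) else
      gs$member_genes
    stop("no evaluable pairs: ", length(intersect(genes_in_net, universe)),
         " of ", length(genes_in_net),
         " network genes are covered by the gold standard", call. = FALSE)
  }
  is_tp <- labels[eval_idx] == "TP"
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  points <- data.frame(cum_fp = cum_fp, cum_tp = cum_tp)
  summary <- NULL
  if (!is.null(prefixes)) {
    prefixes <- pmin(as.integer(prefixes), length(eval_idx))
    summary <- data.frame(
      prefix = prefixes,
      tp = cum_tp[prefixes],
      fp = cum_fp[prefixes],
      ratio = ifelse(cum_fp[prefixes] > 0,
                     cum_tp[prefixes] / cum_fp[prefixes], Inf),
      rank_in_full_list = eval_idx[prefixes])
  }
  structure(list(points = points, labels = labels,
                 scores = net$score[eval_idx],
                 n_excluded = sum(labels == "EXCLUDED"),
                 summary = summary),
            class = "vaenet_curve")
}

#' @export
print.vaenet_curve <- function(x, ...) {
  n <- nrow(x$points)
  cat("Benchmark curve: ", n, " evaluable pairs (",
      x$n_excluded, " excluded); final TP=", x$points$cum_tp[n],
      " FP=", x$points$cum_fp[n], "\n", sep = "")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' True positives at a given false-positive count
#'
#' Reads the cumulative curve at (up to) `fp` false positives — the
#' natural way to compare two ranked networks at matched specificity.
#'
#' @param curve A `vaenet_curve`.
#' @param fp Number of false positives.
#' @return The number of true positives accumulated when the curve reaches
#'   `fp` false positives (the last point with `cum_fp <= fp`).
#' @export
tp_at_fp <- function(curve, fp) {
  pts <- curve$points
  idx <- which(pts$cum_fp <= fp)
  if (!length(idx)) return(0L)
  pts$cum_tp[max(idx)]
}

#' Write a benchmark curve to TSV
#'
#' @param curve A `vaenet_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  data.table::fwrite(curve$points, path, sep = "\t")
  invisible(path)
}
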