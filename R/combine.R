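#' Combine evidence probabilities with prior-corrected noisy-OR
#'
#' The probabilistic evidence-combination rule used by the STRING
#' database: each source probability is first corrected for the prior
#' chance of a functional link, the corrected probabilities are merged
#' assuming independence (noisy-OR), and the prior is added back:
#' `q_i = max(0, (p_i - prior) / (1 - prior))`,
#' `p = prior + (1 - prod(1 - q_i)) * (1 - prior)`.
#' With `prior = 0` this is plain noisy-OR, `1 - (1 - p1)(1 - p2)`, under
#' which absent evidence (`p = 0`) is neutral.
#'
#' @param p1,p2 Probabilities in [0, 1] (vectorized).
#' @param prior Prior probability in [0, 1); default 0.
#' @return Combined probabilities, same length as the inputs.
#' @export
combine_probs <- function(p1, p2, prior = 0) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1),
            prior >= 0, prior < 1)
  q1 <- pmax(0, (p1 - prior) / (1 - prior))
  q2 <- pmax(0, (p2 - prior) / (1 - prior))
  prior + (1 - (1 - q1) * (1 - q2)) * (1 - prior)
}

#' Merge calibrated networks into one probabilistic network
#'
#' Takes the union of the pair sets of two (or more) calibrated networks.
#' A pair present in several sources gets its probabilities combined with
#' [combine_probs()]; a pair present in one source keeps that source's
#' probability combined against the prior (unchanged when `prior = 0`).
#' The operation is symmetric in its arguments.
#'
#' @param ... Two or more calibrated scored networks (must carry a
#'   `probability` column; see [calibrate_network()]).
#' @param prior Prior probability passed to [combine_probs()]; default 0.
#' @return A scored network over the union of pairs whose `score` and
#'   `probability` both hold the combined probability, with one
#'   `p_source<k>` column per input holding that source's probability
#'   (`NA` where the source lacks the pair). Sorted by combined
#'   probability descending, ties by (`gene1`, `gene2`) ascending.
#' @export
combine_networks <- function(..., prior = 0) {
  nets <- list(...)
  if (length(nets) == 1L && is.list(nets[[1L]]) &&
      !is.data.frame(nets[[1L]])) {
    nets <- nets[[1L]]
  }
  if (length(nets) < 2L) stop("need at least two networks", call. = FALSE)
  nets <- lapply(nets, as_scored_network)
  for (i in seq_along(nets)) {
    if (!"probability" %in% colnames(nets[[i]])) {
      stop("network ", i, " has no probability column; run ",
           "calibrate_network() first", call. = FALSE)
    }
  }
  keys <- lapply(nets, function(n) paste(n$gene1, n$gene2, sep = "\r"))
  all_keys <- unique(unlist(keys))
  src <- matrix(NA_real_, length(all_keys), length(nets))
  for (i in seq_along(nets)) {
    src[match(keys[[i]], all_keys), i] <- nets[[i]]$probability
  }
  filled <- ifelse(is.na(src), prior, src)
  # fold the pairwise rule across sources; associative for fixed prior
  p <- filled[, 1L]
  for (i in seq_len(ncol(filled) - 1L)) {
    p <- combine_probs(p, filled[, i + 1L], prior = prior)
  }
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  out <- data.frame(gene1 = parts[, 1L], gene2 = parts[, 2L],
                    score = p, probability = p,
                    stringsAsFactors = FALSE)
  colnames(src) <- paste0("p_source", seq_along(nets))
  out <- cbind(out, as.data.frame(src))
  ord <- order(-out$probability, out$gene1, out$gene2, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vaenet_network", "data.frame")
  attr(out, "canonical") <- TRUE
  out
}

#' Filter a combined network at a confidence cutoff
#'
#' Retains pairs whose combined probability meets the cutoff (e.g. 0.15,
#' the conventional low-confidence threshold, or 0.70 for
#' high-confidence subnetworks) and reports the resulting size.
#'
#' @param cn A combined (or any calibrated) network.
#' @param cutoff Probability cutoff in [0, 1].
#' @return The filtered network, with attribute `"filter_summary"` (list
#'   with `n_pairs` and `n_genes`).
#' @export
confidence_filter <- function(cn, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  cn <- as_scored_network(cn)
  if (!"probability" %in% colnames(cn)) {
    stop("network has no probability column", call. = FALSE)
  }
  out <- cn[cn$probability >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vaenet_network", "data.frame")
  attr(out, "canonical") <- TRUE
  attr(out, "filter_summary") <- list(
    n_pairs = nrow(out),
    n_genes = length(unique(c(out$gene1, out$gene2))))
  out
}
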