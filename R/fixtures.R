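#' Specification for a synthetic sparse expression fixture
#'
#' Describes a synthetic single-cell-like count matrix with planted
#' co-expression modules, heavy dropout, and redundant (near-duplicate)
#' conditions — the three properties of real scRNA-seq matrices that
#' latent-space network inference is designed to cope with.
#'
#' Each module is "on" in a random subset of cell clusters and silent
#' elsewhere; genes of the same module therefore share a cluster-level
#' expression program and form the ground-truth association modules.
#' Background genes express cluster-independent noise and belong to no
#' module. Counts in "on" cells are lognormal around `mean_expression`
#' with multiplicative noise `noise_sd`. Every base cell is then
#' replicated `redundancy_factor` times and entrywise Bernoulli dropout
#' (probability `dropout_rate`) is applied independently to every
#' replicate, so replicates are near-duplicates rather than exact copies.
#'
#' @param n_modules Number of planted modules (default 5).
#' @param genes_per_module Genes per module (default 40).
#' @param n_background_genes Unassigned noise genes (default 20).
#' @param n_cell_clusters Number of cell clusters (default 10).
#' @param cells_per_cluster Base cells per cluster (default 50).
#' @param dropout_rate Entrywise zeroing probability in [0, 1)
#'   (default 0.8, typical of droplet scRNA-seq sparsity).
#' @param redundancy_factor Near-duplicate replicates per base cell,
#'   >= 1 (default 3).
#' @param mean_expression Median "on" count (default 10).
#' @param noise_sd Lognormal sdlog of the multiplicative noise
#'   (default 0.4).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `vaenet_fixture_spec`.
#' @export
fixture_spec <- function(n_modules = 5L, genes_per_module = 40L,
                         n_background_genes = 20L, n_cell_clusters = 10L,
                         cells_per_cluster = 50L, dropout_rate = 0.8,
                         redundancy_factor = 3L, mean_expression = 10,
                         noise_sd = 0.4, seed = 1L) {
  stopifnot(n_modules >= 1L, genes_per_module >= 2L,
            n_background_genes >= 0L, n_cell_clusters >= 2L,
            cells_per_cluster >= 1L, dropout_rate >= 0, dropout_rate < 1,
            redundancy_factor >= 1L, mean_expression > 0, noise_sd > 0)
  structure(list(n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 n_background_genes = as.integer(n_background_genes),
                 n_cell_clusters = as.integer(n_cell_clusters),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 dropout_rate = dropout_rate,
                 redundancy_factor = as.integer(redundancy_factor),
                 mean_expression = mean_expression,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "vaenet_fixture_spec")
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Builds the count matrix described by a [fixture_spec()] together with
#' its ground truth: a membership-mode gold standard assigning each module
#' gene to its module (background genes stay unannotated, so pairs
#' touching them are EXCLUDED in benchmarks, exactly like genes absent
#' from a pathway database).
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `matrix` (genes x conditions count
#'   matrix), `gold` (`vaenet_gold`, membership mode), `modules` (named
#'   list module -> gene ids) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "vaenet_fixture_spec"))
  set.seed(spec$seed)
  n_mod_genes <- spec$n_modules * spec$genes_per_module
  n_genes <- n_mod_genes + spec$n_background_genes
  n_base <- spec$n_cell_clusters * spec$cells_per_cluster

  genes <- sprintf("g%03d", seq_len(n_genes))
  module_of <- rep(NA_character_, n_genes)
  module_of[seq_len(n_mod_genes)] <-
    rep(sprintf("module_%d", seq_len(spec$n_modules)),
        each = spec$genes_per_module)
  cluster_of_cell <- rep(seq_len(spec$n_cell_clusters),
                         each = spec$cells_per_cluster)

  # each module is on in a random, proper, non-empty subset of clusters
  on_clusters <- vector("list", spec$n_modules)
  for (k in seq_len(spec$n_modules)) {
    repeat {
      on <- which(stats::runif(spec$n_cell_clusters) < 0.5)
      if (length(on) >= 1L && length(on) < spec$n_cell_clusters) break
    }
    on_clusters[[k]] <- on
  }

  meanlog <- log(spec$mean_expression)
  base <- matrix(0, n_genes, n_base)
  for (k in seq_len(spec$n_modules)) {
    g_idx <- which(module_of == sprintf("module_%d", k))
    c_idx <- which(cluster_of_cell %in% on_clusters[[k]])
    base[g_idx, c_idx] <- stats::rlnorm(length(g_idx) * length(c_idx),
                                        meanlog, spec$noise_sd)
  }
  bg_idx <- which(is.na(module_of))
  if (length(bg_idx)) {
    base[bg_idx, ] <- stats::rlnorm(length(bg_idx) * n_base,
                                    meanlog, spec$noise_sd)
  }

  # replicate cells, then fresh dropout per replicate entry
  full <- base[, rep(seq_len(n_base), each = spec$redundancy_factor),
               drop = FALSE]
  if (spec$dropout_rate > 0) {
    drop <- matrix(stats::runif(length(full)) < spec$dropout_rate,
                   nrow(full), ncol(full))
    full[drop] <- 0
  }
  full <- round(full)
  cells <- sprintf("c%04d_r%d",
                   rep(seq_len(n_base), each = spec$redundancy_factor),
                   rep(seq_len(spec$redundancy_factor), times = n_base))
  m <- expression_matrix(full, genes = genes, conditions = cells)

  mapped <- !is.na(module_of)
  gold <- gold_membership(genes[mapped], module_of[mapped])
  modules <- split(genes[mapped], module_of[mapped])
  list(matrix = m, gold = gold, modules = modules, spec = spec)
}
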