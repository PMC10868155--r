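# Small shared fixtures for the unit tests. The acceptance-scale fixture
# is built inside test-acceptance.R at its own (larger) size.

tiny_fixture <- function(seed = 3L) {
  generate_fixture(fixture_spec(
    n_modules = 2L, genes_per_module = 10L, n_background_genes = 5L,
    n_cell_clusters = 4L, cells_per_cluster = 10L, dropout_rate = 0.5,
    redundancy_factor = 2L, seed = seed))
}

tiny_vae_config <- function(seed = 7L, epochs = 30L) {
  vae_config(hidden_dim = 32L, latent_dim = 4L, epochs = epochs,
             batch_size = 8L, seed = seed)
}

# independent scalar Pearson correlation, written as the textbook sums
pcc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# independent scalar evaluation of the 5-parameter calibration function
calib_oracle <- function(x, a) {
  vapply(x, function(xi) a[1] + a[2] * xi +
           a[3] / (1 + exp(a[4] * (xi - a[5]))), numeric(1))
}

random_membership_gold <- function(n_genes, n_groups, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", sample.int(n_genes * 2L, n_genes))
  groups <- sprintf("K%d", sample.int(n_groups, n_genes, replace = TRUE))
  list(genes = genes, groups = groups,
       gold = gold_membership(genes, groups))
}
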