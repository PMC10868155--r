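# vaenet

Functional association networks from sparse omics matrices via
variational autoencoders.

## The problem

Single-cell RNA-seq count matrices and large label-free proteomics
compendia are enormous, extremely sparse (80–95% zeros from dropout) and
highly redundant (thousands of near-identical cells or runs). Classic
co-expression networks built by correlating genes directly across such
conditions are dominated by the dropout noise and double-count the
redundant conditions. `vaenet` addresses this for computational
biologists who want a weighted gene/protein functional association
network — "these two genes act together" — out of exactly such matrices.

## The method

For an expression matrix **X** (genes × conditions, non-negative):

1. **Preprocess** — `x ← log2(x + 1)`, then divide every row by its own
   maximum, so each gene profile lies in [0, 1].
2. **Compress** — train a variational autoencoder with genes as
   observations: encoder `input → hidden (ReLU) → (μ, log σ²)`, decoder
   `z → hidden (ReLU) → sigmoid output`, reparameterization `z = μ + σ·ε`.
   The loss is `0.9 · BCE(x, x̂) + 0.1 · KL( N(μ, σ²) ‖ N(1, 0.1²) )`,
   minimized with Adam at learning rate 10⁻³. The per-gene mean vector μ
   is the gene's embedding: a compact summary of its expression program
   with the redundant conditions collapsed and much of the dropout noise
   averaged out.
3. **Score** — the network edge weight for genes *a*, *b* is the Pearson
   correlation `r(μₐ, μᵦ)` in the latent space; all pairs are ranked by
   score.
4. **Calibrate** — against a pathway gold standard, local precision
   `y = TP/(TP+FP)` in a sliding window is fitted as a function of the
   mean window score `x` with `y = a₀ + a₁x + a₂ / (1 + exp(a₃(x − a₄)))`
   (Nelder–Mead simplex on squared error), converting every raw score
   into a posterior probability of shared pathway membership.
5. **Combine** — calibrated networks from different data types are merged
   over the union of pairs with prior-corrected noisy-OR,
   `p = 1 − (1 − p₁)(1 − p₂)` at prior 0, the evidence-combination rule
   used by the STRING database.

A synthetic-data generator (`generate_fixture()`) produces sparse count
matrices with planted co-expression modules, entrywise dropout and
near-duplicate conditions, together with the matching membership gold
standard, so the whole pipeline is testable end to end without any
external downloads.

## Worked example

A synthetic matrix with 3 planted modules of 15 genes plus 10 background
genes, 6 cell clusters × 30 cells duplicated twice, 70% dropout (86%
observed zeros):

```r
library(vaenet)

fx <- generate_fixture(fixture_spec(
  n_modules = 3L, genes_per_module = 15L, n_background_genes = 10L,
  n_cell_clusters = 6L, cells_per_cluster = 30L, dropout_rate = 0.7,
  redundancy_factor = 2L, seed = 42L))

scaled <- preprocess_matrix(fx$matrix)
latent <- train_vae(scaled, vae_config(hidden_dim = 64L, latent_dim = 8L,
                                       epochs = 150L, seed = 42L))
net <- pairwise_pcc(latent)
net
#> Scored network: 1485 pairs, 55 genes
#>   gene1 gene2     score
#> 1  g009  g015 0.9955548
#> 2  g001  g004 0.9909633
#> ...
```

Benchmarking against the planted modules (background genes are
unannotated, so their pairs are excluded, exactly like genes missing
from a pathway database):

```r
curve <- cumulative_curve(net, fx$gold, prefixes = 300L)
curve
#> Benchmark curve: 990 evaluable pairs (495 excluded); final TP=315 FP=675
#>   prefix  tp fp    ratio rank_in_full_list
#> 1    300 258 42 6.142857               443
```

Of the top 300 evaluable pairs, 258 are within-module (TP/FP ratio 6.1).
The raw-correlation baseline on the same matrix
(`cumulative_curve(pairwise_pcc(scaled), fx$gold, prefixes = 300L)`)
reaches 242 TP / 58 FP — the latent-space network is cleaner at equal
depth, and the gap widens with sparsity. Calibration then turns scores
into probabilities:

```r
pts   <- window_points(curve, window = 100L, step = 20L)
calib <- fit_calibration(pts)
calib
#> Calibration curve y = a0 + a1*x + a2/(1 + exp(a3*(x - a4)))
#>       a0       a1       a2       a3       a4
#>  0.03565  0.03561  0.98449 -4.88933  0.53295
#> SSE: 0.022193
head(calibrate_network(net, calib, isotonic = TRUE), 3)
#>   gene1 gene2     score probability
#> 1  g009  g015 0.9955548   0.9627158
#> 2  g001  g004 0.9909633   0.9606468
#> 3  g009  g012 0.9898556   0.9601425
```

The top pair has a 96% posterior probability of shared module
membership. Two calibrated networks are merged with
`combine_networks(n1, n2, prior = 0)` and thresholded with
`confidence_filter(cn, 0.15)`.

The whole flow is also available as one call:
`run_pipeline(matrix_path, "out/", gold = gold_path)` writes the ranked
network, the benchmark curve, the fitted calibration parameters and the
calibrated network, plus the resolved configuration and loss history for
reproducibility.

## Vignette

`vignettes/latent-space-networks.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical
choices, and known limitations.
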