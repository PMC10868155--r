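---
title: "Latent-space co-expression networks: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space co-expression networks: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaenet)
```

## The model

`vaenet` infers a weighted functional association network from a single
genes-by-conditions expression matrix. The premise is that direct
gene-gene correlation across raw conditions fails on modern matrices for
two reasons: *dropout* (technical zeros in scRNA-seq; missing
identifications in proteomics) injects massive noise into per-condition
comparisons, and *redundancy* (thousands of near-identical cells or
runs) makes the effective sample size much smaller than the column count
while still dominating the correlation. Both problems live in the
condition dimension, so the method compresses it: a variational
autoencoder (VAE) is trained with **genes as observations and conditions
as features**, and each gene's posterior mean vector in the bottleneck
is used as its embedding. Genes with similar expression programs land
close together in this latent space even when, condition by condition,
their observed profiles rarely overlap; near-duplicate conditions are
collapsed into the same latent directions instead of being counted
repeatedly.

The pipeline is: preprocess → train VAE → correlate all gene pairs in
the latent space → (optionally) benchmark against a gold standard,
calibrate scores to probabilities, and combine networks from several
data types.

### Preprocessing

Each entry is mapped through `log2(x + 1)` and each row is divided by
its own maximum, putting every gene profile in [0, 1] — the output range
of the decoder's sigmoid. Log scaling makes the model attend to
proportional rather than additive changes. The pseudocount of 1 is the
standard choice for count data: it keeps zeros at zero, which matters
when 80%+ of the matrix is zeros. All-zero genes are retained but
flagged, and are excluded from pair scoring, where their correlation
would be undefined (0/0). No library-size normalization is applied: the
row-max scaling already makes genes comparable, and per-cell depth
effects are left to the VAE to absorb. For proteomics intensities that
are already log-scale, the log step can be skipped
(`preprocess_matrix(m, log2_transform = FALSE)`).

### The autoencoder

Architecture (single hidden layer on each side):

* encoder: `input (D conditions) → hidden (ReLU) → μ, log σ² (linear)`
* decoder: `z (L dims) → hidden (ReLU) → output (sigmoid)`

with the reparameterization `z = μ + σ·ε`, `ε ~ N(0, I)`. The loss is

```
0.9 · BCE(x, x̂)  +  0.1 · KL( N(μ, diag σ²) ‖ N(1, 0.1² I) )
```

optimized with Adam at learning rate 10⁻³. Binary cross-entropy is the
natural reconstruction loss when inputs and outputs both live in [0, 1]
through a sigmoid; squared error is available via
`vae_config(recon_loss = "mse")` for users who prefer a Gaussian
observation model. BCE is summed over features and averaged over the
batch, KL summed over latent dimensions and averaged over the batch, so
the 0.9/0.1 weighting has a stable meaning across input widths.

The latent prior is `N(1, 0.1²)` — deliberately not the standard
`N(0, 1)`. A tight prior keeps the posteriors concentrated and the
latent geometry well regularized; its mean and spread are exposed as
`prior_mean` / `prior_sd` for users who want the conventional prior.
The embedding handed downstream is **μ**, the posterior mean, never a
stochastic sample: downstream correlations must be deterministic.

### Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `hidden_dim` | 256 | hidden width; generous relative to typical latent sizes, cheap at gene-as-row scale |
| `latent_dim` | 48 | embedding length; must be well below the condition count (warned otherwise), large enough to hold several expression programs |
| `epochs` | 50 | full passes; loss history is returned so convergence can be inspected |
| `batch_size` | 32 genes | standard minibatch size |
| `learning_rate` | 1e-3 | Adam step size |
| `w_recon`, `w_kl` | 0.9, 0.1 | loss weights, must sum to 1 |
| `prior_mean`, `prior_sd` | 1, 0.1 | latent prior |
| `seed` | 42 | drives weight init, shuffling, and reparameterization noise |

The architecture defaults (`hidden_dim`, `latent_dim`, `epochs`,
`batch_size`) are implementation choices of this package, tuned for
matrices from a few hundred to tens of thousands of genes; they are not
derived quantities and should be revisited for unusual shapes (e.g.
`latent_dim` below the condition count for very narrow matrices).

### Scoring and ranking

Every pair of genes is scored by the Pearson correlation of their μ
vectors. The correlation matrix is computed in row blocks
(`block_size`, default 512) and pairs are streamed out above
`score_floor` (default −1, keep everything), so all-against-all on tens
of thousands of genes does not require the full pair list in memory.
Genes whose embedding has zero variance are excluded (their correlation
is undefined) and reported via the `excluded_genes` attribute. The
ranking is made bit-reproducible by a documented total order: score
descending, ties broken by (`gene1`, `gene2`) ascending, each pair
stored once with `gene1 < gene2`.

## Benchmarking rules

Against a **membership** gold standard (pathways, complexes): a pair
sharing at least one group is a true positive, a pair of annotated genes
sharing none is a false positive, and a pair where either gene is
unannotated is excluded — unmappable pairs say nothing about the method.
Against a **pairs** gold standard (interaction lists), a predicted pair
present in the list is a TP; by default a missing pair counts as FP only
when both genes occur somewhere in the list, mirroring the unmappable
rule, because an interaction database never assays all genes. The
literal reading — everything absent is an FP — is available as
`strict_fp = TRUE`. Cumulative TP/FP curves are emitted as tables, not
plots.

## Calibration

Raw correlations are hard to interpret; the calibration step converts
them into posterior probabilities of shared pathway membership. Local
precision `y = TP/(TP+FP)` is computed in a sliding window over the
ranked evaluable pairs (defaults `window = 1000`, `step = 100`; both are
package choices — large windows smooth the precision estimate at
atlas scale, and both shrink automatically in `run_pipeline()` when the
network is small) and fitted with

```
y = a0 + a1·x + a2 / (1 + exp(a3·(x − a4)))
```

by Nelder–Mead simplex on the sum of squared errors. The fit restarts
from a fixed grid (`a2 ∈ {0.5, 1}`, `a3 ∈ {−20, −5, 5}`,
`a4 = median(x)`, `a0 = min(y)`, `a1 = 0`); the best SSE wins with ties
to the first start, so the fit is deterministic. Non-convergence within
`maxit` returns the best-so-far parameters with a warning.

Two silent assumptions of this functional form are made explicit and
checkable here. First, the function is unbounded, so fitted values are
clamped to [0, 1] when used as probabilities, and the number of clamped
pairs is reported. Second, the conversion preserves the ranking only if
the fitted curve is non-decreasing over the observed score range; an
unconstrained five-parameter fit can violate that locally. The package
fits unconstrained (faithful to the functional form), then checks
monotonicity on the observed scores and warns with the inversion count;
`isotonic = TRUE` substitutes the isotonic regression of the fitted
curve, which restores order preservation while staying as close as
possible to the fit.

## Combination

Calibrated networks from different data types are merged over the union
of their pairs with prior-corrected noisy-OR — the evidence-combination
rule of the STRING database:

```
qᵢ = max(0, (pᵢ − prior) / (1 − prior))
p  = prior + (1 − Π(1 − qᵢ)) · (1 − prior)
```

The prior defaults to 0 (plain noisy-OR), under which absent evidence is
neutral and a pair present in one source keeps its probability
unchanged. The rule is associative, so any number of sources can be
folded in. `confidence_filter()` thresholds the result (0.15 is the
conventional low-confidence cutoff, 0.70 high confidence).

## The synthetic generator

`generate_fixture()` emulates the two properties the method targets:

* **modules** — each planted module is "on" (lognormal counts around
  `mean_expression` with multiplicative noise `noise_sd`) in a random
  proper subset of cell clusters and zero elsewhere, so its genes share
  a cluster-level program; background genes express cluster-independent
  noise and are left unannotated, providing EXCLUDED pairs;
* **sparsity and redundancy** — every base cell is replicated
  `redundancy_factor` times and entrywise Bernoulli dropout
  (`dropout_rate`) is applied independently per replicate, giving
  near-duplicate, heavily zeroed columns.

Defaults (5 modules × 40 genes, 20 background genes, 10 clusters × 50
cells, 3× redundancy, 80% dropout, median on-count 10, `noise_sd` 0.4)
describe a small but realistically sparse scRNA-seq-like problem: the
on-count and noise level were picked once as typical of moderately
expressed genes in droplet data. What the generator does **not**
emulate: regulatory-network dynamics, library-size variation between
cells, batch effects, ambient RNA, or count overdispersion beyond the
lognormal — so passing benchmarks here demonstrates recovery of planted
co-expression structure under sparsity and redundancy, not performance
on every artifact of real data.

## Numerical choices and degenerate inputs

* VAE gradients are analytic (verified against finite differences in the
  test suite); `log σ²` is clipped to [−15, 15] before exponentiation.
* Weight init is Glorot-uniform; all RNG derives from `config$seed`, so
  identical config + data ⇒ byte-identical outputs.
* BCE is computed in logit form (`softplus(logit) − x·logit`), avoiding
  `log(0)`.
* The logistic term of the calibration function saturates instead of
  overflowing for |a₃(x−a₄)| > 700.
* All-zero genes: kept through preprocessing, excluded from scoring.
* All-zero rows never divide by zero (row max of 0 ⇒ row left as is).
* Missing cells on input are zeros; negative values are errors.
* Ties everywhere break lexicographically, making every ranked artifact
  reproducible bit for bit.

The test suite exercises the full pipeline at a 220-gene × 1500-cell
problem size (the generator defaults), which keeps the complete run in
minutes on one CPU while leaving the planted structure non-trivial to
recover at 80% dropout.

## Known limitations

* The VAE trains on the same matrix it embeds; there is no held-out
  reconstruction monitoring. The loss history is exposed for inspection.
* Pearson correlation in the latent space is symmetric and undirected;
  no attempt is made to orient edges or remove indirect associations.
* Calibration requires a gold standard with usable coverage of the
  network's genes; identifier harmonization between matrix and gold
  standard is the user's responsibility (mismatches surface as coverage
  diagnostics, not errors).
* Probabilities are calibrated against *shared pathway membership*, so
  they inherit the gold standard's biases; combining networks calibrated
  against different standards mixes semantics.
* The HDF5-based AnnData container is not read directly; an equivalent
  plain-text bundle (`adx`: MatrixMarket matrix in cells × genes
  orientation plus observation/variable name files) is supported
  instead, and conversion from `.h5ad` is a one-liner in Python
  (`scanpy`/`anndata`) or R (`zellkonverter`).
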