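# scSPaC: self-paced NMF clustering for single-cell RNA-seq

Clustering cells from scRNA-seq count matrices is hard: the data are
sparse, noisy, and full of dropout zeros, and the nonnegative matrix
factorization (NMF) models often used for it are non-convex, so a fit can
easily stall in a poor local optimum seeded by the hardest, noisiest
cells. This package implements **self-paced NMF clustering**: instead of
fitting all cells at once, cells are admitted into the factorization from
*easy* (low reconstruction loss) to *hard*, under a self-paced learning
controller, and the final cluster assignment comes from K-means on the
learned cell embedding.

## The model

Given a preprocessed, nonnegative expression matrix `X ∈ R^{m×n}` (m
genes, n cells), the method seeks nonnegative factors `U ∈ R^{m×r}` and
`V ∈ R^{n×r}` together with per-cell weights `w ∈ [0,1]^n` minimizing

    min_{U,V ≥ 0, w ∈ [0,1]^n}   Σ_i w_i · ℓ_i(U, V)  +  f(λ, w)

where `ℓ_i = ‖x_i − U vᵢ‖²` (Frobenius variant, **scSPaC**) or
`ℓ_i = ‖x_i − U vᵢ‖₂` (robust l2,1 variant, **sscSPaC**), and `f(λ, w)`
is a self-paced regularizer. Two schemes are provided:

* **hard**: `f = −λ Σ w_i`, giving binary selection `w_i = 1{ℓ_i < λ}`;
* **mixture** (default): `f = −Σ ζ ln(w_i + ζ/λ)` with `ζ = λ/2`, giving a
  continuous ramp — `w_i = 1` for easy cells, 0 for cells with `ℓ_i ≥ λ`,
  and `ζ/ℓ_i − ζ/λ` in a soft transition zone.

The pace parameter λ is scheduled automatically: it starts so that the
easiest 60% of cells are admitted and rises by 10 percentage points per
outer iteration until every cell is in, at which point the fit runs to
convergence. U and V are updated by multiplicative (Lee–Seung-style)
rules with the cell-weight matrix `W = diag(w)` folded in; K-means
(k-means++ seeding, best of 10 restarts) on the rows of V yields the
clusters. ARI, purity and NMI are computed against ground-truth labels
when available.

The package also ships the surrounding pipeline: dense-TSV / MatrixMarket
readers and writers, the four-step preprocessing (gene filtering, top-1000
highly variable genes by binned normalized dispersion, log transform,
per-gene scaling), a gamma-Poisson count simulator with group differential
expression, library-size variation and logistic dropout, and benchmark
drivers. See the methods vignette (`vignettes/self-paced-clustering.Rmd`)
for the full account of the model, parameter choices and limitations.

## Worked example

Simulate a well-separated two-group experiment, run the full method, and
evaluate against the simulated ground truth:

```r
library(scSPaC)

params <- sim_params(n_genes = 2000, cells_per_group = 100,
                     de_prob = 0.5, de_facscale = 1.5, seed = 1)
counts <- simulate_counts(params)
counts
#> CountMatrix: 2000 genes x 200 cells
#>   sparsity: 35.5% zeros
#>   labels: Group1 (100), Group2 (100)

pm  <- preprocess_pipeline(counts, preprocess_config(n_hvg = 1000),
                           verbose = TRUE)
#> preprocess: 2000 genes -> 1893 after filtering -> 1000 HVGs

fit <- spac_fit(pm, spac_config(norm = "frobenius", r = 2, seed = 1))
fit
#> SPaCFit (frobenius norm, mixture weighting, r = 2): 11 outer iterations, converged
#>   final objective 5.494e+04, 200/200 cells selected

cl  <- kmeans_embed(fit$factors, K = 2, seed = 1)
metric_report(cl, pm$labels, percent = TRUE)
#> MetricReport (x100): ARI = 100, purity = 100, NMI = 100 (N = 200)
```

The fit history shows the self-paced schedule at work — the admitted-cell
count climbs 120 → 140 → … → 200 as λ rises:

```r
head(fit$history[, c("outer", "lambda", "fraction", "n_selected")], 5)
#>   outer lambda fraction n_selected
#> 1     1  914.7      0.6        120
#> 2     2 4047.5      0.7        140
#> 3     3 4650.6      0.8        160
#> 4     4 4976.4      0.9        180
#> 5     5 6782.0      1.0        200
```

An ARI of 100 (scale ×100) means the two simulated groups are recovered
exactly; on the default, much harder simulation (22,002 genes, subtle
fold-changes, heavy overdispersion and dropout) the same pipeline scores
well below that — see below.

A thin command-line front end over the same functions lives at
`inst/cli/spac.R` (subcommands `simulate`, `preprocess`, `fit`, `cluster`,
`scan-k`, `evaluate`, `run`, `hvg-sweep`).

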