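# resdec

Interpretable factor discovery for single-cell RNA-seq via residual
decomposition.

Factor models (PCA, NMF, ...) compress single-cell expression into latent
axes, but the axes that come out are usually a mix of biology and
technical structure, and deciding what each one means is manual work.
resdec is for analysts who want that interpretation step to be explicit,
quantitative and calibrated. It:

1. removes known technical covariates per gene with a **Poisson GLM** and
   factorizes the **Pearson residual** matrix with **varimax-rotated PCA**;
2. matches factors to covariate levels with an **ensemble classifier
   association score** (logistic regression, Mann–Whitney AUC, decision
   tree, gradient boosting), binarized by an **Otsu threshold**;
3. profiles every factor with **interpretability metrics** — separability
   (silhouette, bimodality index, dip, variance-ratio scores), effect size
   (variance), specificity (Simpson, Shannon) and homogeneity (average
   scaled variance);
4. calibrates the associations with a **permutation benchmark** (empirical
   p-values, per-level and global **Gini** indices) and validates the
   metrics with a **Gaussian-mixture factor simulator** with analytic
   component overlap.

## The model

Counts are modelled as
`Y = C β + F A + U H + ε`, with `C` the known technical covariates,
`F A` factors annotated by covariate association and `U H` unannotated
factors. Stage one fits, per gene, a Poisson GLM of the counts on `C`
(log link) and keeps Pearson residuals `(y − ŷ)/√ŷ`; stage two rotates the
top-k PCA of those residuals with varimax to maximize the Kaiser
criterion, yielding sparse, interpretable loadings. Associations,
interpretability metrics and calibration operate on the resulting score
and loading matrices. See `vignette("factor-discovery")` for the full
account.

## Worked example

The package ships a synthetic benchmark generator emulating a cell-line
mixture experiment: 3 lines × 3 protocols × 50 cells, 300 genes, each line
carrying a 20-gene program, protocols differing only in depth.

```r
library(resdec)

fx  <- make_fixture_dataset(fixture_config(seed = 1))
res <- factor_discovery(fx$counts, fx$covariates,
                        regress = c("protocol", "library_size"),
                        k = 10, seed = 1)

res$fca$values[1:3, 1:5]
#>              F1   F2   F3    F4    F5
#> line:line1 0.33 0.05 2.63 -0.24 -0.49
#> line:line2 0.11 2.68 0.18 -0.47 -0.30
#> line:line3 2.34 0.35 0.62 -0.43 -0.51
```

Each row is a covariate level, each column a factor; entries are
ensemble-classifier importances, standardized across factors. Each line
locks onto its own factor (line1–F3, line2–F2, line3–F1). Otsu
thresholding binarizes the table:

```r
res$calls
#> association_calls: threshold 0.8133; 9 significant pairs; 7 unannotated factors
res$calls$significant[1:3, 1:5]
#>            F1 F2 F3 F4 F5
#> line:line1  0  0  1  0  0
#> line:line2  0  1  0  0  0
#> line:line3  1  0  0  0  0
```

The interpretability table says why: the three line factors separate cells
into two populations (high silhouette and bimodality index), carry most of
the variance, and are heterogeneous across line levels (low `asv_line`),
while factors F4+ are noise-like and homogeneous:

```r
round(res$fis$values[, 1:5], 3)
#>                      F1     F2     F3    F4    F5
#> silhouette        0.684  0.710  0.688 0.557 0.554
#> bimodality_index  0.584  0.433  0.713 0.308 0.379
#> variance         22.477 22.784 22.108 3.182 3.138
#> simpson           0.239  0.258  0.484 1.000 0.167
#> asv_line          0.322  0.355  0.261 0.968 0.988
#> asv_protocol     1.004  1.004  1.004 1.004 1.004
```

The permutation benchmark confirms the calibration — exactly one
significant factor per line level, and shuffling labels flattens the
association profile:

```r
permutation_benchmark(res$model, fx$covariates,
                      covariate_names = "line", n_perm = 200, seed = 1)
#> permutation_result: 200 permutations, alpha = 0.05
#>   mean significant factors per level: 1.00
#>   global Gini: observed 0.555 vs permuted mean 0.322
#>   minimum attainable p-value: < 0.005
```

Ranked loadings feed external enrichment tools:

```r
top_genes(res$model, "F3", n = 5)
#> [1] "gene004" "gene011" "gene015" "gene018" "gene008"
```

(`gene001`–`gene020` are line1's planted program, which F3 tracks.)

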