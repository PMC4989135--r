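# hicats

Wrapper gene selection for expression-based sample classification, using a
binary imperialist competition algorithm hybridized with tabu search
(HICATS).

## The problem

Tumour expression datasets routinely have 50–200 samples and 2 000–12 000
genes. Classifiers built on all genes overfit and explain nothing; the
useful product is a *small* gene subset on which a classifier predicts
held-out samples well. That is a combinatorial search problem scored by an
expensive, noisy objective — exactly the territory of population
metaheuristics.

## The method

A candidate subset is a bit vector ("country") over the genes. Its fitness
combines cross-validated classification accuracy `A(X)` with a parsimony
reward:

```
fitness(X) = w1 * A(X) + w2 * (n - D(X)) / n,   w2 = 1 - w1
```

with `D(X)` the subset size, `n` the gene count and `w1 = 0.8` by default.
`A(X)` comes from a pluggable classifier (linear SVM by default; kNN and
nearest-centroid available) under leave-one-out or stratified k-fold
cross-validation, with training-fold-only standardization and memoization
of repeated subsets.

The population of 15 countries is split into 4 empires led by its fittest
members. Each of 50 generations:

1. **Tabu search** refines every imperialist over sampled single-bit-flip
   neighborhoods, with a recency tabu list and a best-so-far aspiration
   criterion (skippable: `tabu = FALSE` gives the plain-ICA ablation
   baseline).
2. **Assimilation** pulls every colony toward its imperialist: a random
   fraction β of the genes the imperialist has and the colony lacks is
   transferred, while a random binary template halves the colony's own
   genes — the move that steadily shrinks subset sizes.
3. Colonies that overtake their imperialist are **promoted**; empires
   **compete** (the weakest empire's weakest colony moves to a roulette-
   chosen stronger empire) and colony-less empires are **dissolved**.

An elitist archive keeps the best country ever evaluated; a per-generation
log records best/mean fitness, accuracy, subset size and cumulative
evaluations. Everything is reproducible from a single seed.

## Worked example

```r
library(hicats)

# 40 samples x 200 genes, 3 classes, 5 planted informative genes
syn <- make_synthetic(n_samples = 40, n_genes = 200, n_informative = 5,
                      n_classes = 3, effect_size = 3, noise_sd = 1, seed = 1)
syn$planted
#> [1]  43  68 129 162 167

cfg <- hicats_config(cv = "kfold", generations = 15, seed = 42)
res <- run_hicats(syn$dataset, cfg)
print(res)
#> <hicats_result>
#>   best accuracy : 100.00%
#>   best fitness  : 0.9980
#>   genes selected: 2 (g68, g167)
#>   generations   : 15, evaluations: 4042
```

The search found a 2-gene subset — both genes among the five actually
planted — that classifies every sample correctly under 5-fold
cross-validation. The fitness 0.998 is `0.8 * 1.0 + 0.2 * 198/200`:
perfect accuracy plus the parsimony reward for using 2 of 200 genes.
`res$log` holds the convergence trace (best fitness is non-decreasing by
construction); `write_result(res, "out/run1")` writes a text summary, a
TSV convergence log and a JSON manifest.

Real data comes in through `read_expression_table()` (CSV/TSV, samples or
genes in rows, labels as a column or separate file). A command-line front
end with the same options lives at `inst/cli/hicats.R`
(`Rscript inst/cli/hicats.R run --data X.csv --label-column class --seed 1
--out prefix`; `synth` generates datasets).

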