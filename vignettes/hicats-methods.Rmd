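---
title: "Gene subset selection with hybrid imperialist competition and tabu search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene subset selection with hybrid imperialist competition and tabu search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicats)
```

## The problem

Expression profiling of tumours produces matrices with tens of samples and
thousands to tens of thousands of genes. Classifying such samples (tumour
subtype, prognosis group) works best — and is only biologically
interpretable — when it rests on a handful of informative genes. Finding
that handful is a combinatorial search over $2^n$ subsets, scored by how
well a classifier trained on the candidate subset predicts held-out samples.
`hicats` implements a wrapper feature-selection metaheuristic for this
search: a binary imperialist competition algorithm (ICA) for global
exploration, hybridized with a tabu-search (TS) local refinement that keeps
the population's leaders from stagnating in local optima.

## The model

**Encoding.** A candidate solution ("country") is a bit vector
$X \in \{0,1\}^n$ over the $n$ genes; bit $i = 1$ selects gene $i$. The
search population holds `n_pop` countries; the `n_imp` fittest are
*imperialists*, each owning a share of the remaining countries as
*colonies* — together an *empire*.

**Fitness.** A subset $X$ with $D(X)$ selected genes is scored
$$\mathrm{fitness}(X) = w_1\, A(X) \;+\; w_2\, \frac{n - D(X)}{n},
\qquad w_2 = 1 - w_1,$$
where $A(X) \in [0,1]$ is the cross-validated classification accuracy of a
classifier restricted to the selected columns. With the default $w_1 = 0.8$
accuracy dominates, and the second term breaks accuracy ties in favour of
smaller subsets; removing one gene is worth $w_2/n$, so parsimony never
trades away measurable accuracy on small datasets.

**Empire formation.** Imperialist fitness values are min-shifted
($\mathrm{Fit}_m = \mathrm{fit}_m - \min_i \mathrm{fit}_i$), normalized to
powers $p_m = \mathrm{Fit}_m / \sum_i \mathrm{Fit}_i$, and each imperialist
receives $\mathrm{round}(p_m N_{col})$ of the shuffled colonies.

**Assimilation.** Each generation every colony moves toward its
imperialist by a binary Baldwinian-learning step. The *difference genes*
are those the imperialist selects and the colony does not (the asymmetric
difference $X_{IM} - X_{CO}$); a learning rate $\beta \sim U(0,1)$, drawn
per colony per generation, fixes how many of them — $\beta\,|diff|$ rounded
to the nearest integer, halves up — transfer into the colony, chosen
uniformly without replacement. Simultaneously a fair-coin binary template
of length $\max(|X_{IM}|, |X_{CO}|)$ is drawn; the colony keeps only those
of its own genes whose position (in ascending gene order) carries a 1 in
the template's complement. The union of transferred and kept genes is the
new colony. The template halves the colony's own genes in expectation, so
assimilation is also the algorithm's dimension-reduction engine: subsets
shrink steadily without any explicit size cap.

**Tabu refinement.** Before assimilation, each imperialist is refined by a
short tabu search over the single-bit-flip neighborhood. Evaluating all $n$
flips per step is impossible at microarray dimension with cross-validated
fitness, so each step samples `ts_neighbors` distinct positions uniformly.
The best *admissible* neighbor — its flipped position not on the tabu list,
or its fitness above the best seen so far (the aspiration criterion) —
becomes the new current solution *even when it is worse*, which is what
lets the search walk out of a local optimum; its position then becomes tabu
for `ts_tenure` iterations. The search returns the best country visited,
so refinement never loses fitness.

**Competition and elimination.** After assimilation, any colony that
overtook its imperialist swaps roles with it. Empire total power is
imperialist fitness plus `xi` times the mean colony fitness; the weakest
empire loses its weakest colony to a winner drawn by roulette over
min-shifted total powers, and an empire with no colonies left is dissolved,
its imperialist demoted to a colony of the strongest surviving empire (so
the population size is invariant). A fixed number of generations is the
only stopping rule, and an elitist archive retains the best country ever
evaluated regardless of what survives in the final population.

## Parameters

| parameter      | default | meaning |
|----------------|---------|---------|
| `n_pop`        | 15      | countries in the population |
| `n_imp`        | 4       | imperialists (so 11 colonies initially) |
| `generations`  | 50      | outer iterations |
| `w1`           | 0.8     | fitness weight on accuracy (`w2 = 0.2`) |
| `init_density` | 0.1     | initial probability a gene is selected |
| `ts_iters`     | 5       | tabu steps per imperialist per generation |
| `ts_neighbors` | 20      | flip neighbors sampled per tabu step |
| `ts_tenure`    | 7       | iterations a flipped position stays tabu |
| `xi`           | 0.1     | colony weight in empire total power |
| `classifier`   | `"svm"` | `"svm"`, `"knn"` or `"centroid"` |
| `cv`           | `"loocv"` | `"loocv"` or stratified `"kfold"` |

The first five rows are the method's published setting; the rest are open
knobs of any concrete implementation. `init_density = 0.1` keeps initial
subsets small: a 0.5 start at $10^4$ genes would make every fitness call a
cross-validation over thousands of columns and contradicts the small
subsets the search is meant to find. The tabu budget (5 steps × 20
neighbors × 4 imperialists = 400 extra evaluations per generation) is
chosen so the local search, not the colony updates, consumes most of the
evaluation budget — that is its role. `ts_tenure = 7` is the classical
short-term-memory scale; `xi = 0.1` weights colonies just enough that a
large empire of mediocre colonies can outrank a lone strong imperialist.

## The evaluator

Fitness calls dominate runtime, so the evaluator memoizes accuracy by exact
bit pattern (unbounded, per run) and counts distinct evaluations — the
convergence log records the cumulative count, which is the honest cost axis
for comparing runs. The default classifier is a linear-kernel support
vector machine (`e1071`, default regularization); multiclass problems use
libsvm's native pairwise (one-vs-one) voting, which costs a single model
fit per fold at these sample sizes and is standard practice for SVMs on
microarray panels. `"knn"` (k = 3) and `"centroid"` (nearest class
centroid) are cheaper alternatives and useful in tests. Features are
standardized to zero mean and unit variance *on the training folds only*,
and the held-out samples are transformed with the training-fold statistics
— the usual guard against leakage with scale-sensitive classifiers.
Leave-one-out cross-validation is the reference scheme; stratified k-fold
(default 5 folds, assignment drawn once per evaluator so accuracy is a
pure function of the subset within a run) trades a little variance for a
several-fold speedup and is what the bundled experiments use.

## The synthetic generator

`make_synthetic()` emulates the regime of the public tumour panels this
kind of algorithm is benchmarked on — tens of samples, hundreds to
thousands of genes, 2–11 classes, and only a few genes that truly carry
class signal. `n_informative` planted genes get an additive ladder of class
means ($c \cdot \mathrm{effect} \cdot \sigma$ for 0-based class $c$); all
other genes are $N(0, \sigma^2)$ noise for every class. The default
experiment (40 samples, 200 genes, 5 informative, 3 classes, effect 3)
is separable but not trivially so: a single planted gene classifies at
roughly 90%, so perfect accuracy requires combining planted genes, which is
exactly the behaviour a subset-search benchmark should reward.

What the generator does *not* emulate: correlated gene blocks,
heavy-tailed and heteroscedastic microarray noise, batch effects, class
imbalance beyond the even split, or interactions where a gene is
informative only jointly with another. Passing the bundled experiments
therefore demonstrates that the search machinery works — operators correct,
fitness pressure in the right direction, planted signal recoverable — not
that the defaults are tuned for any particular real platform.

## Numerical choices and degenerate inputs

- **Empty subsets** have undefined accuracy; any operator that could
  produce one repairs it. Random initialization and bit-flips repair to one
  uniformly chosen gene; assimilation repairs inside the union of the two
  parents' genes, so it never invents a gene foreign to both.
- **Colony allocation** rounds $p_m N_{col}$ to the nearest integer, which
  can break the total; excess is shed from (deficit added to) the entries
  with the largest fractional remainder, and every empire is floored at one
  colony when enough colonies exist — a powerless imperialist would
  otherwise be eliminated at generation 1, collapsing the multi-empire
  structure at cold start.
- **Ties** in population ranking break toward the lowest index; exact
  fitness ties among tabu neighbors break uniformly at random, because once
  accuracy saturates every redundant-gene removal ties exactly and a
  positional tie-break would always prune low-index genes first, biasing
  which of several equivalent subsets a run reports. Both rules are
  bit-reproducible under a fixed seed.
- **All-equal imperialists** make the power normalization 0/0; powers fall
  back to uniform.
- **Tabu bookkeeping** stores, per position, the iteration at which its
  tabu status expires; a position is tabu while that expiry exceeds the
  current iteration, so tenure 0 disables the memory exactly (used by the
  steepest-ascent equivalence tests).
- **Transfer rounding** follows the half-up rule (`floor(x + 0.5)`), so 2.5
  difference genes round to 3, and the count never exceeds the number of
  difference genes.
- **RNG**: all stochastic operators draw from R's global stream, seeded
  once per run (`hicats_config(seed = )`); a run is a pure function of
  (dataset, config).

## Design choices that were genuinely open

- *Which difference genes transfer*: uniformly at random without
  replacement — the only mechanism consistent with a randomly drawn
  learning proportion.
- *Role of the imperialist-side template prefix*: it is constructed (for
  symmetry with the colony-side prefix) but does not shape the output;
  the assimilation result is fully determined by the transferred difference
  genes plus the template-masked colony genes, which is the arithmetic the
  worked unit tests pin down.
- *Aspiration criterion*: global-best override, the canonical choice.
- *Collapsed imperialists are demoted, not deleted*, keeping `n_pop` fixed
  for the whole run.
- *Multiclass SVM scheme*: libsvm's pairwise voting rather than a
  hand-assembled one-vs-rest ensemble; at 30–40 training samples per fold
  the two agree closely, and pairwise voting is one classifier fit per fold
  instead of one per class.

## Problem sizes in the bundled experiments

The packaged tests and `scripts/acceptance.R` exercise the full algorithm
on the 40 × 200 planted dataset (ten 50-generation runs, roughly
9&nbsp;000–10&nbsp;000 distinct subset evaluations each with 5-fold SVM
fitness) and the operator-level suites on enumerable landscapes
($n \le 10$, brute-force oracles). These sizes keep a complete run of the
suite in the tens of minutes on one CPU while still running every code path
at realistic population and generation counts. Real microarray panels
($10^4$ genes, LOOCV) use the same code and are supported as CSV/TSV input
via `read_expression_table()`; only wall-clock time grows.

## Known limitations

- Wrapper selection with cross-validated fitness *selects with* the
  classifier; the reported best accuracy is an optimistic estimate of
  generalization unless validated on data never touched by the search
  (no nested cross-validation is built in).
- The tabu neighborhood subsample (20 of $n$ positions) makes local search
  lighter but means the refinement is not a full steepest-ascent; at
  $n \gg 10^3$ informative flips can be missed for many steps.
- No microarray-specific preprocessing (normalization, imputation) is
  included; input matrices are taken as-is apart from per-fold
  standardization.
- Fitness caching is unbounded; at extreme run lengths memory grows with
  the number of distinct subsets evaluated.
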