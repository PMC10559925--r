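---
title: "Wrapper gene selection with BWO, IG and their hybrid: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper gene selection with BWO, IG and their hybrid: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene-expression classification problems are extreme *p >> n* settings: tens
to a few hundred labelled samples against thousands of gene columns, most of
which carry no class information. Wrapper feature selection searches the
space of gene subsets directly, scoring each candidate subset by the
cross-validated performance of a classifier trained on it. The search space
is `2^m` for `m` genes, so the search is delegated to stochastic
metaheuristics. This package implements three searchers over a common
objective:

* **BWO** — black widow optimization, a population metaheuristic with
  convex-crossover "procreation", survivor selection by "cannibalism", and
  swap mutation;
* **IG** — iterated greedy local search: destroy part of the current subset,
  greedily rebuild it, and accept the result under a constant-temperature
  simulated-annealing rule;
* **BWO-IG** — the hybrid: periodic IG refinement of the best widow found by
  BWO, with the refined solution injected back into the population.

## The objective

A candidate solution ("widow") is a continuous genotype
`x ∈ [0, 1]^m` decoded to a binary gene mask by strict thresholding,
`mask[i] = 1 ⇔ x[i] > 0.5`. A mask `R` is scored by

```
fitness(R) = α · γ_R(D) + β · |R| / N,   β = 1 − α,
```

where `γ_R(D)` is the stratified k-fold cross-validated error of a
k-nearest-neighbour classifier (k = 5, Euclidean distance) restricted to the
selected columns, `|R|` is the number of selected genes and `N` the total.
Fitness is minimized; it always lies in `[0, 1]`. The default `α = 0.99`
makes accuracy dominate while subset size breaks near-ties — the usual
convention for this family of wrapper objectives. The empty mask is given
fitness 1 (the worst attainable value) rather than raising an error, so a
search trajectory may pass through it.

Two determinism choices matter here. First, CV folds are drawn **once per
optimization run** (from `cv_seed`) and reused for every fitness call;
otherwise the objective is noisy and best-so-far monotonicity is
unverifiable. Second, KNN is fully deterministic: `knn_k` is odd, exact
distance ties go to the lower sample index, and residual label ties go to
the label of the single nearest neighbour. This is why the KNN is
implemented inside the package rather than delegated to a library
classifier with randomized tie handling (a library KNN is used as an
independent cross-check in the test suite on a tie-free fixture).

Reported "accuracy" is `1 − γ_R(D)` of the final mask **on the same folds
used during the search**. Because the search optimizes over those folds,
this estimate is optimistically biased relative to a nested or held-out
protocol; the package reports it anyway because it is the quantity the
search actually optimizes, and documents the bias here.

## BWO

The population (default `Npop = 10`) is initialized uniformly on
`[0, 1]^m`. Each generation:

1. **Procreation.** `Nr/2` matings, where `Nr = round(pr · Npop)` rounded
   down to even (default `pr = 0.6` gives `Nr = 6`). Each mating draws two
   distinct parents uniformly, then one application of the per-coordinate
   convex crossover `y1 = a∘x1 + (1−a)∘x2`, `y2 = a∘x2 + (1−a)∘x1` with a
   fresh uniform vector `a`. Offspring conserve `y1 + y2 = x1 + x2` exactly
   and stay within bounds by convexity.
2. **Cannibalism.** Of each mating's four solutions, the better parent and
   the better child survive (ties: fewer selected genes, then the first
   argument). There is no separate cannibalism-rate parameter: the
   keep-the-better rule *is* the survivor selection.
3. **Mutation.** `Nm = round(mr · Npop)` widows (default `mr = 0.4`,
   `Nm = 4`) drawn without replacement from the sorted population, each with
   two distinct positions' values exchanged (a swap preserves the genotype
   multiset, hence the bounds).

The closure `Nr + Nm = Npop` is validated at construction, so the
population size is exactly `Npop` after every generation. The best solution
ever evaluated (`W*`) — including cannibalized children — is tracked by the
evaluator itself, which makes the best-fitness trace non-increasing by
construction. Fitness-proportional selection probabilities
(`selection_probability()`) are exposed as a utility but are not a gate in
the main loop, which is self-consistent without them. The iteration budget
(default 100) is the only hard stopping rule; an optional `patience`
parameter stops early after a configurable number of iterations without
improvement beyond a tolerance (default `1e-2`, the one way the package
gives meaning to an otherwise ambiguous "maximum distance" setting of this
method family).

## IG

One IG invocation runs `ig_iterations` (default 10) cycles of:

* **Destruction** — remove `d` randomly chosen selected genes (recorded in
  removal order; entries set to the lower bound). The default is
  proportional, `d = max(1, round(0.2 · |R|))`, which scales from
  hundred-gene test instances to ten-thousand-gene matrices. At least one
  gene always remains selected; a one-gene solution is passed through
  unchanged.
* **Greedy construction** — for each removed gene in removal order, re-add
  it iff that strictly lowers fitness (a tie keeps the smaller subset).
  Position-wise insertion heuristics from permutation problems have no
  analogue in an unordered subset, so re-insertion is by fitness test; a
  `swap_aware` mode additionally tries one-for-one exchanges against each
  selected gene at `|R|`-fold higher evaluation cost.
* **Acceptance** — improving candidates are always accepted; a worse
  candidate is accepted with probability `exp(−ΔE / T)`. The temperature is
  **constant** (no cooling): `T = t_scale · mean(P) / 10` over the
  normalized expression matrix `P`, so `T ∈ [0, 0.1]` — the same order as
  typical fitness differences, which keeps the acceptance curve useful.
  `t_scale = 0` degenerates to improve-only acceptance. The incumbent may
  therefore worsen, but a separately tracked best-so-far guarantees the
  returned solution is never worse than the start.

The acceptance test compares against the incumbent, not the best-so-far:
incumbent-based acceptance is what gives the walk its diversification, and
the best is kept on the side.

## The hybrid

BWO runs its normal generations; after every `ig_period` iterations
(default 10, i.e. ten handoffs in a 100-iteration run) and once more after
the final iteration, IG refines the current `W*`. The refined solution
replaces `W*` and is injected over the worst population member — replacing,
never appending, so the population size is preserved and the improvement
can propagate through subsequent procreation.

One master seed spawns private streams for initialization, the BWO
generation loop, and IG. BWO therefore consumes identical random draws
whether or not IG fires, and with IG disabled (`ig_period = Inf`,
`final_refine = FALSE`) the hybrid's trace is bit-identical to plain
`run_bwo()` — a contract the test suite asserts exactly. The finer
stream-per-operator split (pairing vs crossover vs mutation) was
considered and dropped: the testable property only requires BWO/IG
isolation.

## Data handling

Loaders read samples-as-rows delimited text with a header of gene
identifiers and a designated label column (`--transpose` handles
genes-as-rows dumps). Missing values are rejected by default; per-gene mean
imputation must be requested explicitly, because silent imputation changes
results. Every gene column is min-max normalized to `[0, 1]` before any
evaluation, so KNN distances are scale-comparable across genes and the IG
temperature lands on the fitness scale; normalization is idempotent and
maps constant columns to 0. The source data of this problem family is
typically not distributed with fixed preprocessing, so normalization is
this package's own choice, stated here rather than assumed.

Stratified folds deal each class's shuffled samples round-robin across
folds (continuing across classes so remainders spread), giving per-fold
class counts within one sample of proportionality. The default fold count
is `min(10, smallest class size)`, reducing with a warning — 10-fold is
conventional for wrapper selection at these sample sizes.

## Synthetic data

`generate_synthetic()` plants `n_informative` genes whose per-class means
are spaced `effect_size · noise_sd` apart (class order permuted per gene so
planted genes are not collinear); all other genes are class-independent
Gaussian noise. The model is deliberately Gaussian rather than log-normal:
the objective of the generator is planted-truth recovery under a
controllable signal-to-noise knob, not biological realism. It produces no
correlated gene blocks, no dropout or zero inflation, and no heavy tails —
so passing tests demonstrate that the optimizers recover separable planted
structure, not that they are robust to the full pathology of real
microarray data. The truth (informative indices, class means) is returned
beside the data, never encoded in it.

`generate_tiny_separable()` builds the oracle fixture: at most 12 genes
(so all `2^m` masks are enumerable), one gene whose class-0 values lie in
`[0.1, 0.2]` and class-1 values in `[0.8, 0.9]`. The within-class spread
(0.1) is far below the class gap (0.6), so leave-one-out 5-NN on that gene
alone has error exactly 0, and the global optimum of the objective is that
single gene — `exhaustive_search()` confirms it by enumeration, and
optimizer tests measure how often each method reaches it.

### What the planted-gene experiments show — and a redundancy caveat

At the test scale (60 samples × 200 genes, 5 informative genes at effect
size 3), two or three informative genes already separate the classes with
cross-validated error 0. Past that point every additional gene —
informative or not — strictly raises fitness by `β/N`. A well-functioning
optimizer therefore returns a *subset* of the planted genes (measured
precision ≈ 0.9–1.0, final subsets of 2–6 genes), not all five: with a
redundant planted set, full recall is in direct tension with the objective
being optimized. The recovery experiments accordingly measure precision,
subset reduction, and hybrid-vs-plain dominance; a full-recall expectation
fails by design of the objective, not by failure of the search.

## Experiment harness

`run_experiment()` runs `n_runs` (default 30, the scale at which standard
errors of this family's published comparisons are computed) independently
seeded runs per method; per-run seeds and per-run fold seeds derive from
one master seed, so the whole experiment is bit-reproducible. Summaries are
mean, sample standard deviation and `SE = sd/√n` of accuracy, fitness,
subset size and iterations-to-best; method pairs are compared with Welch's
unequal-variance two-sided t-test (the variance columns of published
comparisons in this area are visibly unequal, so the pooled-variance
flavour would be wrong more often than not). Degenerate zero-variance
cases follow a documented policy: equal means → `t = 0, p = 1`; unequal
means → `p = 0`. Reports round-trip losslessly through `summary.json`,
`per_run.csv`, `convergence.csv` and per-run selected-gene lists.

## Numerical choices and degenerate inputs

* Crossover conservation holds to `1e-12` (pure floating-point convexity).
* An all-zero fitness vector yields uniform selection probabilities.
* `T = 0` rejects every non-improving candidate (the `exp(−ΔE/0)`
  singularity is special-cased).
* Constant gene columns normalize to 0 rather than erroring.
* A destruction request larger than the subset is capped so one gene
  remains.
* Training folds smaller than `knn_k` reduce `k` for that fold with a
  warning.
* Evaluations are cached per mask within a run (the fold assignment is
  fixed, so a mask's score is immutable); caching changes run time, never
  results.

## Problem sizes used in the shipped tests and scripts

The test suite and the acceptance script run entirely on generated data:
the 20 × 8 oracle fixture (10 paired seeds, 100 iterations), the 60 × 200
planted-gene instance (10 paired seeds, 100 iterations), and 20 short runs
on a 30 × 25 instance for structural invariants. These sizes were chosen so
the full suite exercises every operator and both optimizers end-to-end in
about a minute on one core while still being large enough for the planted
signal to dominate sampling noise.

## Known limitations

* Single objective only; no Pareto treatment of the error/size trade-off.
* No alternative classifiers (SVM, trees) and no nested CV — the reported
  accuracy is the search-time CV estimate discussed above.
* The optimizers are specialized to the subset-selection objective; there
  is no continuous-benchmark mode.
* No parallel execution; runs are sequential for exact reproducibility.
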