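---
title: "Methods: chaotic oppositional fruit fly optimization and wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaotic oppositional fruit fly optimization and wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coffo)
```

This vignette is the package's own account of the methods it implements:
the continuous optimizers, their binary adaptation for wrapper feature
selection, the synthetic data used to validate them, and the rank-based
statistics for comparing optimizers. It also records the design choices
that were genuinely open, and what the validation results do and do not
show.

## The continuous optimizers

**FFO.** A swarm of `N` candidate solutions in a box `[LB, UB]^D`.
Each iteration every member proposes a candidate by a uniform random step
(`osphresis_step()`): each coordinate moves by `step_scale * u`,
`u ~ U(-1, 1)`, and is clamped to the box. The signed draw absorbs the
"±" of the usual formulation — a separate sign coin would be redundant.
If any candidate improves the global best, the entire swarm relocates
onto the new best (the vision phase, `vision_update()`); otherwise the
swarm keeps its positions. Ties never replace the incumbent: strictly
better only, which keeps behaviour stable on plateaus.

The step is an *absolute* length, by default 1, regardless of the box
width. On wide boxes (e.g. half-width 8192) this makes the walk slow by
construction; `step_scale` is exposed for users who want range-relative
steps, but the default stays literal to the classic formulation.

**Budgets.** Every call to the objective passes through one accounting
point (`evaluate_problem()`) and costs exactly one fitness function
evaluation (FFE). The budget is the sole termination criterion; an
iteration that would overrun it is truncated member by member. The
conventional schedules are `maxFFE = N (1 + maxIter)`: with `N = 50`,
`maxIter = 500` that is 25,050; with `N = 10`, `maxIter = 100` it is
1,010 (`ffe_budget()`).

**COFFO** adds three mechanisms:

1. *Chaotic-opposition initialization* (`chaotic_opposition_init()`).
   `N` uniform candidates are drawn; the first `N/2` contribute their
   opposites `LB + UB - x`; the last `N/2` contribute chaotic variants,
   so every member feeds exactly one derived candidate. All `2N`
   candidates are evaluated (2N FFEs) and the best `N` survive (stable
   sort, insertion order breaks ties). Because the survivors are selected
   from a superset of the plain random population, the initial best can
   never be worse than a random start, and empirically it is strictly
   better in ~99 of 100 seeded trials on the 10-D sphere.
2. *Logistic chaos*. The map `beta <- mu * beta * (1 - beta)` with
   `mu = 4` is chaotic on (0, 1). Seeds are redrawn if they fall within
   1e-12 of the degenerate orbit starts {0.25, 0.5, 0.75}, whose orbits
   collapse onto fixed points (0.75 maps to itself; 0.5 maps to 1 and
   then to 0). The chaotic variant of a solution is by default the
   literal product `beta * x` clamped to the box; because that shrinks
   toward the origin and is asymmetric in the bounds, a `normalized`
   mode `LB + beta (x - LB)` is offered as a config flag.
3. *Chaotic local search* (`chaotic_local_search()`). Once the spent
   budget passes the trigger `clst` (default `maxFFE / 3`), every
   iteration attempts at most `K = 4` improvements around the best:
   a fresh chaotic vector places `S = LB + beta (UB - LB)` and the
   candidate is the blend `(1 - lambda) x* + lambda S`. The shrinkage
   `lambda = (maxFFE - FFE + 1) / maxFFE` decays linearly from 1 to
   `1/maxFFE`, so early CLS explores the whole box and late CLS makes
   fine corrections. The first strictly better candidate replaces the
   best immediately; each candidate costs one FFE (the search evaluates
   what it proposes — up to `K` per trigger, not one), and an exhausted
   budget truncates the search with the incumbent retained. CLS can
   therefore never worsen the best.

Why the trigger: running CLS from the start spends budget on wide jumps
around a best that is still moving quickly; empirically (and by the
shrinkage schedule's design) it pays only after the swarm has settled.

**Result objects.** Both drivers return an `ffo_result` with the
best-so-far trace recorded at every improving FFE plus the loop
boundaries — enough to draw convergence plots cheaply — and the exact
number of FFEs spent. Identical `(problem, config, seed)` triples give
bitwise-identical results; all randomness derives from one root seed
through named substreams (initialization, search, folds, synthesis,
replicates), so each component is reproducible in isolation.

## The benchmark suite

The registry (`make_benchmark()`, `list_problems()`) carries the three
data-free problems of the CEC2019 "100-digit" set with their published
dimensions and ranges — Chebyshev polynomial fitting (D = 9, ±8192),
inverse Hilbert matrix (D = 16, ±16384), Lennard-Jones minimum energy
(D = 18, ±4, pair potential `r^-12 - 2 r^-6`, offset by the known 6-atom
minimum energy 12.7120622568, with a 1e-12 minimum-distance guard so
random points cannot divide by zero) — and, for the remaining seven
slots, *unshifted, unrotated analogues* of the classic Rastrigin,
Griewank, Weierstrass, Schwefel, Happy-Cat, Ackley and expanded Schaffer
functions on D = 10, ±100, each offset so the global minimum value is 1.
The official shifted/rotated versions require external data files; the
analogues keep the suite self-contained, at the price that absolute
fitness values are not comparable with results produced by the official
suite. The Schwefel analogue scales its variable by 5 internally so the
known minimizer (z = 420.9687463599820, x = z/5) lies inside the box;
the registry stores minimizers only where the offset identity
`f(x*) = 1` holds to 1e-9, and the test suite verifies exactly that.

## Binary adaptation for wrapper feature selection

The subset-selection fitness is

`Fit(S) = alpha * ER(S) + (1 - alpha) * |S|/|O|`, `alpha = 0.99`,

with `ER` the stratified 10-fold cross-validated error of KNN (`k = 5`,
majority vote, Euclidean distance) restricted to the masked features.
Features are min-max scaled to [0, 1] per column first — Euclidean KNN is
scale-sensitive. `alpha = 0.99` is the convention of the protocol this
fitness follows; both weights are exposed. One seeded fold partition is
built per optimization run and reused by every fitness evaluation in that
run: this removes partition noise from the search signal and makes the
mask-to-error cache exact. Cached or not, every fitness evaluation costs
one FFE. The reported accuracy of the final mask is recomputed under the
same CV protocol on a fixed reporting partition (no separate holdout is
carved out of the small datasets this targets).

Each swarm member carries a bit mask paired with a continuous *companion*
position in `[-4, 4]` (a box spanning the effective range of all four
V-shaped transfer functions). V-shaped transfer functions
(`transfer_v()`) measure displacement magnitude: `T(0) = 0`,
`T(x) -> 1` as `|x|` grows. The flip rule (`binarize_step()`) complements
bit `j` with probability `T(v_j)` and repairs an empty mask by setting
one uniformly random bit, so no fitness evaluation ever sees an empty
subset. `V2 = |tanh x|` is the default; all four are selectable.

Four design choices here were genuinely open, and the package settles
them as follows:

* **The transfer argument is the companion displacement, not the
  absolute companion position.** With companions uniform in [-4, 4],
  `T(position)` averages ≈ 0.9 per bit and every candidate mask is
  near-random — no exploitation is possible within a 1,010-FFE budget.
  Displacement (velocity) semantics is also how V-shaped transfer
  functions are used by the binary swarm algorithms this layer follows.
* **Size-balanced displacement scaling.** Raw displacements are scaled
  per bit so a candidate flips, in expectation, about one selected and
  one unselected feature whatever the current subset size (the classic
  1/n-mutation principle, applied separately to the subset and its
  complement). Without the balance, a sparse incumbent in a
  50-feature problem would almost never see a deletion proposed. The
  osphresis step half-width defaults to `4 / n_features`; chaotic-local-
  search displacements, which span the whole companion box, are rescaled
  by `step_scale / 4` to the same units before binarization.
* **Sparse-first initialization.** Each initial member draws a subset
  density uniformly in (0, 0.2] and thresholds its companion position.
  The rationale is an asymmetry we measured directly: growing a sparse
  mask under this fitness is reliable (informative additions yield large
  error reductions), while pruning a dense mask is not — dense masks are
  a local-optimum trap in which single deletions raise the partition
  error more than the size term refunds, and overfitting pressure
  actively *grows* masks (an added feature that fixes a single CV error
  gains `0.99 * 0.005`, twenty-five times the size cost at 50 features).
  Opposition is applied in companion space with a mirrored threshold, so
  an opposite member selects a *disjoint* subset of the same size —
  opposition in feature choice rather than in subset size, which is the
  meaningful mirror for selection problems. Chaotic initialization
  variants use the normalized chaotic map (the literal product preserves
  companion signs and would duplicate the parent mask).
* **No evaluation is wasted on the incumbent.** A candidate whose flips
  all miss (possible since flips are Bernoulli) flips one uniformly
  random bit instead, so every FFE scores a genuine neighbour. This
  matters late in COFFO runs, where the shrinking CLS displacement would
  otherwise propose the incumbent itself.

The driver (`coffo_select()`) repeats the optimization over independent
runs (default 20; each run derives its own substreams from the root
seed), reports per-run best fitness, the best run's mask, its CV accuracy
and selection ratio `|S|/|O|`, and the per-feature selection frequency
across runs — the frequency profile is often more informative than any
single mask.

## Synthetic data: what it emulates, what it does not

`generate_classification()` plants `s` informative columns among `O`:
class-conditional means at `±Delta/2` with unit Gaussian noise,
label-independent standard-normal noise columns elsewhere, columns
randomly permuted with the planted indices reported. This reproduces the
one structural property wrapper selection assumes — a small predictive
subset hidden among irrelevant measurements — with a controllable
signal-to-noise ratio. It does not emulate real biomedical marginals:
no correlated blocks, no heavy tails, no class-dependent covariance, no
missingness. Passing the recovery tests therefore demonstrates the
search and fitness machinery work as designed, not that any particular
real dataset will yield a stable subset.

One measured limit deserves emphasis. At the validation operating point
(`n = 200`, `O = 50`, `s = 5`, `Delta = 2`), some noise columns are
label-correlated by sampling luck, and under the fitness above a feature
that fixes a single cross-validated error pays for itself many times
over. The *optimum* of the fitness therefore contains a few such columns:
an exhaustive steepest forward-plus-swap search run to convergence
attains a median Jaccard overlap with the planted set of about 0.5–0.67
depending on the data realization, and the swarm — which often finds
*fitter* masks than that oracle — lands in the same band (observed
medians 0.44–0.55). Better optimization of this fitness does not improve
recovery beyond that band; it is a property of the objective at this
sample size, not of the optimizer. The accuracy clause is unaffected:
selected masks beat the all-features baseline by a wide margin.

`generate_covidlike()` produces a 15-column patient table (id, location,
country, gender, age, two date stamps, two exposure indicators, six
symptom codes; all numerically encoded) with a binary death/recovery
outcome at a 30% death rate and `n = 400` by default. Signal is carried
by gender, age and symptom_2 through class-conditional distributions
(age shifted about 26 years between outcomes, calibrated to a low-90s selected-subset accuracy); id is a permutation of
the row indices and carries none. Its validation role is narrow: an
end-to-end selector run must discard the zero-signal id column
essentially always (observed: 10 of 10 runs).

## The comparison toolkit

`friedman_ranks()` ranks methods within each problem (midranks for ties;
every row sums to `k(k+1)/2`), `friedman_statistic()` and
`iman_davenport()` give the two test statistics, `critical_values()` the
chi-square and F critical points, and `holm_stepdown()` the post-hoc
comparisons against a control: `z = (Rbar_j - Rbar_c) /
sqrt(k(k+1)/(6n))`, one-sided upper-tail p-values by default (the control
is hypothesized better; only one-sided tails reproduce the magnitudes
such tables report — two-sided is a flag), ordered ascending and compared
against `alpha / (m - i)` for `m = k - 1` comparisons, rejecting
sequentially until the first failure. The implementation applies the
strictly sequential rule; tables in the field sometimes mark each row
against its own threshold without stopping, which can differ by one
rejection at the margin (both counts are exercised in the test suite).
Scores are lower-is-better by default, with a flag for accuracy-style
tables.

`wilcoxon_signed_rank()` drops zero differences, midranks ties, and for
up to 25 retained pairs computes the exact null distribution of the
positive-rank sum by a dynamic-programming convolution over doubled
ranks (so tied half-integer ranks are handled exactly — equivalent to
enumerating all `2^n` sign assignments at a tiny fraction of the cost);
beyond that a tie-corrected, continuity-corrected normal approximation
takes over, which agrees with the exact tail within 10% relative error
at `n = 20` mid-range statistics. With `n = 21` uniformly-signed
differences the one-sided exact p is `2^-21 ≈ 4.77e-7` — the floor such
comparisons bottom out at.

`compare_methods()` chains the whole pipeline and prints a report shaped
like the rank/statistic/post-hoc tables of the comparative literature.

## Numerical choices and degenerate inputs

* Out-of-box candidates are clamped to the nearest bound (simplest rule
  preserving the bounds invariant); the chaotic variant's product is
  likewise clamped rather than reflected.
* Fitness ties never replace an incumbent, anywhere.
* Logistic seeds avoid {0.25, 0.5, 0.75} within 1e-12; a chaotic orbit
  that lands exactly on 0 or 1 (measure zero, but possible in floating
  point) is reseeded.
* The initialization sort is stable with insertion order as tie-break,
  so determinism survives tied fitness values.
* Degenerate bounds (`lower >= upper`), odd population sizes for the
  split initialization, budgets smaller than the initialization cost,
  empty masks, single-class datasets, classes smaller than the fold
  count, and exhausted budgets all raise immediate, specific errors.
* Dataset loading label-encodes non-numeric columns and mean-imputes
  missing values with a warning; the label is always the last column.

## Validation scale

The test suite and the acceptance script run at deliberately small
scale so the full battery completes in a few minutes on one CPU: budget
conservation, trace monotonicity and bounds closure are checked over 100
seeded runs per algorithm cycling through every registered problem at 60
FFEs each; initialization dominance over 100 seeds at `N = 50`;
convergence on the 2-D sphere at 5,000 FFEs (median best below 1e-2
across 10 seeds; observed ≈ 3e-5); the feature-selection checks at the
full study budget (1,010 FFEs, 10 runs). The published-table statistics
are exact recomputations and run in milliseconds.

## Known limitations

* The optimizers handle box constraints only; no general constraint
  handling, no discrete spaces beyond the feature-mask layer.
* The absolute step length makes the continuous walk slow on very wide
  boxes unless `step_scale` is raised; this is the literal classic
  behaviour, kept deliberately.
* Wrapper selection inherits the fitness's partition overfitting at
  small sample sizes (quantified above); selection frequencies across
  runs are the more trustworthy output.
* KNN is the only wrapped classifier, majority vote only; multi-class
  vote ties (possible when distance ties enlarge the neighbour set) are
  broken at random.
* The benchmark analogues are not the official shifted/rotated
  functions; cross-paper numerical comparisons on those slots are not
  meaningful.
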