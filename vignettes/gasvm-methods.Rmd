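---
title: "Methods: hybrid GA-SVM classification of expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid GA-SVM classification of expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasvm)
```

## The model

`gasvm` classifies two-class expression data (cases coded −1, controls +1)
with an RBF-kernel soft-margin SVM whose hyperparameters *and* feature
subset are chosen by a genetic algorithm — wrapper feature selection: the
feature set is judged by the cross-validated performance of the downstream
classifier, not by a filter statistic alone.

The SVM decision function is

$$f(x) = \sum_j \alpha_j y_j K(x_j, x) + b, \qquad
  K(x, x') = \exp(-\gamma \lVert x - x'\rVert^2),$$

with the box constraint $|\alpha_j| \le C$.  The quadratic program is
solved by libsvm's SMO through `e1071::svm`; the package's contract is the
decision function itself, which `decision_values()` recomputes from the
stored support vectors, dual coefficients and bias, with the sign
normalized so that positive scores always predict the control class.
A decision value of exactly zero predicts the case class — an arbitrary
but fixed tie rule, chosen so that "no evidence" resolves to the
clinically cautious side.

A GA chromosome is a bit string: one 32-bit gene per hyperparameter
followed by one mask bit per feature.  A parameter gene with integer value
$B = \sum_{i=1}^{32} b_i 2^{i-1}$ decodes linearly onto its search
interval,

$$v = \mathrm{lo} + \frac{B}{2^{32}-1}(\mathrm{hi} - \mathrm{lo}),$$

attaining both endpoints exactly (the all-zero and all-one genes are
special-cased so no floating-point rounding can miss them).  Fitness is
the stratified 10-fold cross-validated accuracy, $(TP + TN)/N$, of the SVM
the chromosome decodes to, computed on the training partition only.
Selection is roulette-wheel ($p_j = f_j / \sum f$), recombination is
single-point crossover at rate 0.8, and mutation flips each bit
independently at rate 0.01; the population holds 5 chromosomes.  The
best-so-far chromosome across *all* generations is returned, so the
answer never degrades as the budget grows.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `C` search interval | $[2^{-5}, 2^{15}]$ | soft-margin tradeoff, unitless |
| `gamma` search interval | $[2^{-15}, 2^{3}]$ | 1/(log2 intensity)², RBF width |
| `decode_scale` | `"log"` | interval is traversed in log space |
| `population_size` | 5 | chromosomes per generation |
| `crossover_rate` | 0.8 | per parent pair |
| `mutation_rate` | 0.01 | per bit |
| `k_folds` | 10 | CV folds of the fitness |
| `max_generations` | 30 | generation budget |
| `fc_threshold` | 1.0 | log2 units: ≥ 2-fold change |
| `alpha` | 0.05 | adjusted-p cutoff |
| `n_train` | 50 | training samples of the 74-sample split |

**Why log-scale decoding is the default.**  The linear decode is offered
(`decode_scale = "linear"`), but the viable region of both hyperparameters
spans orders of magnitude.  On log2-intensity data, squared distances
between samples are of order tens, so any $\gamma \gtrsim 0.1$ collapses
the kernel to the identity-like regime and the classifier to the majority
vote.  Under a linear decode of $\gamma \in [10^{-4}, 10]$, a uniformly
random gene lands in that degenerate regime almost surely; the fitness
landscape is then flat at the majority-class rate, roulette selection has
no gradient, and a population of five cannot locate the viable sliver of
code space.  Mapping the bits linearly onto $[\log \mathrm{lo}, \log
\mathrm{hi}]$ — the same convention as the standard libsvm grid search —
makes roughly two thirds of random genes useful while preserving the
linear bit-to-interval map.

**Fold-change scale.**  `|FC| ≥ 1` is interpreted on the log2 scale
(≥ 2-fold linear change), because the matrix stores log2 intensities and
the linear reading of the same threshold is vacuous — every probe passes
it.  `fc_scale = "linear"` switches the interpretation.

## The DEG screen

The screen is a per-probe Welch two-sample *t* with Satterthwaite degrees
of freedom, Benjamini–Hochberg adjustment (`stats::p.adjust`), and the
joint fold-change + significance filter.  A moderated
(empirical-Bayes-shrunken) *t* would differ mainly at very small sample
sizes; at ~37 samples per group, the variance moderation has little effect
on which probes pass a joint |FC| and FDR filter, and the screen's role
here is dimension reduction before the GA, not inference.  The Welch
statistic is computed vectorized over probe rows and is cross-checked
against `stats::t.test` in the test suite.  Degenerate probes (zero
variance in both groups) are defined to have $t = 0, p = 1$ when the
means agree and $t = \pm\infty, p = 0$ otherwise.

By default the screen runs on the **training partition only**: screening
on all samples before splitting leaks test-label information into feature
selection and optimistically biases the held-out estimate.
`screen_on = "all"` reproduces the screen-before-split ordering for
comparison; the report's provenance then records that test labels were
first read at the screen stage rather than at evaluation, so the leakage
is auditable.

## The synthetic generator

`generate_dataset()` emulates the shape of a whole-blood microarray
case/control cohort: 44 cases vs 30 controls by default, each probe with a
baseline mean drawn uniformly from 4–12 log2 units, i.i.d. Gaussian noise
(sd 0.7 log2 units), and a planted subset of probes (default 25 of 500)
carrying a constant +2 log2-unit shift in cases.  Defaults were fixed
once, as a realistic strong-signal regime for a blood transcriptome
classifier at this cohort size, and the compact probe count keeps full
pipeline runs in the seconds range.

What it does **not** emulate — and hence what passing tests do not show
about real data: probe–probe correlation (co-regulated gene blocks),
batch/array effects, heavy-tailed or intensity-dependent noise,
normalization artifacts, and class-dependent variance.  Real cohorts are
harder than this generator in exactly those directions; results on it
bound the method's behavior under its stated assumptions, no more.

## Numerical and procedural choices

- **RNG streams.**  Every stage draws from its own sub-seed derived from
  one root seed (streams: synth, split, cv, ga), and seeded
  sub-operations restore the ambient RNG state, so the GA's stream is
  unaffected by the CV folds drawn inside a fitness evaluation.  Full
  runs are bit-reproducible.
- **Stratified split and folds.**  With 44/30 class imbalance, unstratified
  50/24 splits and 10-fold CV risk single-class folds; both are stratified
  (largest-remainder apportionment for the split, per-class shuffled
  round-robin for the folds), and a `k` larger than the smaller class is
  refused with advice rather than silently producing single-class folds.
- **Mask repair.**  Crossover or mutation can empty the feature mask; an
  SVM on zero features is undefined, so an all-zero mask is repaired by
  setting one uniformly random bit with the run RNG.
- **Fitness memoization.**  CV dominates the cost and a population of five
  duplicates chromosomes often; fitness is memoized on the exact bit
  string within a run.  Folds are fixed per run, so the memo is exact.
- **Epsilon gene.**  The chromosome can carry a third 32-bit gene for an
  ε tolerance (`epsilon_bounds`); it is decoded for fidelity to the
  regression-style encoding tradition but ignored by the C-classifier,
  whose loss has no ε.
- **Elitism** is off by default but available: with a population of five,
  pure roulette is drift-prone; best-so-far tracking already guarantees
  the returned solution never degrades.
- **Parent pairing** draws two parents independently per pair, with
  replacement; an individual may pair with itself.  With odd population
  sizes the surplus child of the final pair is dropped, keeping the
  population size exact.
- **Solver tolerance.**  libsvm's KKT tolerance (1e-3) bounds how exactly
  unbounded support vectors sit on the unit margin; tests check the KKT
  condition at that tolerance, not at machine precision.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
500–2,000 probes × 74 samples for the screen calibration and recovery
checks, 20 probes for the planted-feature GA recovery (population 10, 30
generations, 5 seeds), and the full four-scenario grid at 500 probes
across 5 seeds.  These sizes were chosen so a complete run takes minutes
on one core while keeping every statistical check's sampling error well
inside its asserted band.

## Known limitations

- The screen tests each probe marginally; a multivariate signal spread
  over individually weak probes can pass the GA yet fail the screen, which
  is why the unscreened scenarios exist.
- CV accuracy as a fitness on 50 samples is a noisy objective; with a
  population of 5 the GA is a stochastic search, not an optimizer with
  guarantees, and different seeds can select different (equally
  well-scoring) probe subsets.
- Accuracy is threshold-dependent and the 44/30 imbalance makes the
  majority rate 59%; AUC is reported alongside it for a
  threshold-free view.
- No probability calibration, no kernels beyond the RBF, no multiclass.
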