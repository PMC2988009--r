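---
title: "Polytomous risk models for ovarian tumor diagnosis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polytomous risk models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrisk)
```

# The problem

A woman presenting with a persistent adnexal mass may have a benign tumor,
a borderline (low-malignant-potential) tumor, a primary invasive cancer, or
a metastasis to the ovary from another site. These four events call for
different management, so a useful preoperative model should output four
probabilities, not one benign-vs-malignant score. This package implements
and compares the main strategies for building such polytomous models from
case-level ultrasound and clinical data, together with the evaluation
machinery those comparisons need.

Three structural strategies are covered:

* **All-at-once**: one multinomial model distinguishes all four events
  simultaneously (`MLR`, `MKLR`). Parsimonious, but every selected variable
  must serve every contrast.
* **One-versus-one + pairwise coupling**: one dichotomous model per pair of
  events, trained only on the cases of those two events, applied to every
  case, and recombined (`LR-PC`, `LR-PC2`, `KLR-PC`, `LSSVM-PC`,
  `stepLR-PC`). Each pair can use the variables that matter for *that*
  contrast; a variable may separate borderline from metastatic tumors yet
  be useless elsewhere.
* **Nested tree**: sequential dichotomies — benign vs malignant, then
  borderline vs invasive, then primary vs metastatic — whose conditional
  probabilities multiply into event probabilities (`nested-LR`).

# Models and their assumptions

## Logistic building blocks

`logit_fit()` and `mnlogit_fit()` are plain maximum likelihood by
Newton/IRLS, deliberately without shrinkage: one question the package lets
you study is whether unpenalized regression holds up against regularized
kernel methods when variable selection is careful. Convergence requires the
maximum absolute score below `1e-8` (cap 100 iterations). With only a
handful of borderline or metastatic cases in a pairwise subset,
(quasi-)separation is a real possibility; since the score also vanishes as
coefficients diverge, separation is flagged on coefficient magnitude
(any |coefficient| > 15) with a loud warning, and the capped fit remains
usable — its saturated probabilities still rank cases sensibly. Continuous
predictors enter untransformed.

## Least squares support vector machines

`lssvm_fit()` solves the single KKT linear system of the squared-slack
margin problem. The regularization parameter `gamma` (> 0, larger = less
regularized) and the Gaussian bandwidth `sigma` are tuned by stratified
5-fold cross-validation on the c-index. LS-SVM output is a latent score,
not a probability; `lssvm_posterior()` converts it by modelling the
training latent outputs with one Gaussian per class and applying Bayes'
rule with prior event probabilities (by default the training prevalences).
This is a deliberate, documented approximation: the full hierarchical
Bayesian evidence framework for LS-SVMs (moderated outputs,
evidence-maximized hyperparameters) is **not** reproduced. The
approximation preserves the operative contract — prevalence-weighted
probabilistic output from the LS-SVM latent value — and is fully testable;
its known weakness is that unequal class-conditional latent SDs can make
the posterior non-monotone far in the tails.

## Kernel logistic regression

`klr_fit()`/`mklr_fit()` minimize a penalized negative log-likelihood over
a kernel expansion `f(x) = sum_j beta_j K(x_j, x) + b` with penalty
`(lambda/2) beta' K beta`. Each IRLS iteration solves a system with the
structure of an LS-SVM; the update is accepted under step-halving against
the true penalized objective, so the objective trace is monotone. The inner
system is solved by block elimination (`b = (1'A^{-1}z)/(1'A^{-1}1)`),
which stays well-scaled even when working weights collapse at extreme
`lambda`. MKLR cycles blockwise Newton updates over the non-reference
classes; with two classes it reduces exactly to KLR, and as
`lambda -> Inf` both shrink to the prevalence model. A small jitter
(`1e-10 * (trace/n + 1)`) stabilizes kernel diagonals before solves.
Predictors are standardized inside all kernel models (training mean/SD,
stored with the model), because Gaussian kernels are scale-sensitive and
diameters in mm live on a very different scale than 0/1 markers.

## Pairwise coupling

`couple()` solves the printed linear system (each event's probability as
the pairwise-weighted average of pair totals) with the normalization row
stacked, by least squares. When the pairwise estimates are consistent with
a positive simplex vector, this recovers it exactly — a property the tests
verify on 1000 random draws. When the unconstrained solution leaves the
simplex (possible for wildly inconsistent pairwise estimates, e.g. from
models applied to cases outside their pair), an exact nonnegativity-
constrained least-squares solution is found by enumerating the 2^k - 1
active sets — trivially cheap at k = 4 and free of iterative-solver
tolerance questions. Pair models are applied to *all* cases at face value,
including cases of events outside the pair; coupling is what reconciles
those six opinions.

# Variable selection

Two tracks mirror the two model families:

* **Logistic track** (`LR-PC`, `MLR`): candidate sets from stepwise and
  backward likelihood-ratio procedures (entry/removal p = 0.05) or
  user-supplied lists, judged by AIC (`-2L + 2p`), BIC (`-2L + p log n`)
  and — most importantly — the per-event c-index averaged over repeated
  stratified 5-fold cross-validation. "Manual" selection is exposed as
  user-fixed lists; a human-in-the-loop step cannot be automated honestly.
  For `MLR` without a fixed list, the package scores the stepwise union,
  the backward union and the full set with `evaluate_candidate()` and
  keeps the best mean CV c-index (ties to the smaller set). This
  codification of an exploratory human procedure is a design choice of
  this package.
* **R1U track** (`LR-PC2`, `KLR-PC`, `LSSVM-PC`, `MKLR`): for each pair, a
  linear-kernel LS-SVM forward selection where adding variable `v` updates
  the kernel by the rank-one matrix `x_v x_v'`, the bordered system inverse
  by Sherman–Morrison, and the exact leave-one-out outputs come from the
  inverse diagonal (`loo residual_i = beta_i / Minv_ii`), so no refit is
  ever needed; `gamma` is re-tuned over a grid at every step by maximal
  LOO c-index. The suite proves the shortcut identical to naive
  refit-everything selection. MKLR uses the union of the six pair sets.

The published study controlled the *total* number of variables across the
six pairwise models but did not print the coordination algorithm.
`coordinate_1v1_selection()` is this package's formalization: greedily
grant the single (pair, variable) addition with the largest mean-CV
c-index gain; once the budget of distinct variables is reached, only
variables already in the union may still be granted; stop when every pair
has at least `min_per_pair` (default 3) variables and the budget is
exhausted. Defaults: budget 10 for the logistic track, 11 for the R1U
track, matching the study's totals. Ties break by higher gain, then pair
order, then column order — determinism everywhere.

# The polytomous c-index

Evaluation centers on a four-event extension of the ROC area: draw one
case from each event; count the events whose own predicted probability is
strictly largest for the case truly having that event; average this count
over all such quadruples and divide by 4. It is the probability of
correctly identifying the case of a randomly chosen event within a
four-case set; 0.25 is chance. The implementation factorizes the quadruple
sum per event into products of strict-exceedance counts — O(N log N)
instead of O(N1 N2 N3 N4) — and the factorization is tested against brute
force enumeration on hundreds of random instances.

**Tie rule.** "Strictly largest" is read literally: tied maxima earn no
credit. With continuous model outputs ties have measure zero, but the rule
makes degenerate cases well-defined — and has one consequence worth
knowing: a constant (prevalence-only) classifier scores 0, *below* the
0.25 chance anchor, because every comparison ties. The 0.25 anchor applies
to continuous random scores independent of the labels; the test suite
checks both behaviors.

Pairwise c-indexes for a one-versus-one ensemble use each pair model's own
output on the pair's cases; for true polytomous models the score is the
renormalized conditional probability `pi_i / (pi_i + pi_j)` — the coherent
conditional, which reduces to the pair model's output under consistency.
Both routes are exposed. Calibration uses local-linear loess (tricube
weights, span 0.75 by default) of the event indicator on the predicted
probability, per event, on a 100-point grid clipped to [0, 1]. Confidence
intervals use a stratified (by event) percentile bootstrap, B = 1000 by
default; the study's CI method is not stated, so this is a documented
substitution, with paired resampling for model differences.

# The synthetic cohort generator

The real development (n = 1066) and validation (n = 1938) cohorts are not
deposited. The generator emulates the development cohort's class-
conditional structure from its published descriptive statistics, and is a
first-class, tested module: prevalences 75/5/16/4; per-class medians for
age and diameters; the mean papillation count; percentages for eight
binary markers.

Choices where the publication gives only marginals:

* **Continuous variables**: log-normal with location `log(median)` and a
  log-scale SD of 0.5. Positive, right-skewed, median exactly
  controllable; 0.5 puts ~90% of draws within a factor ~2.3 of the median,
  a realistic spread for clinical diameters.
* **Zero inflation**: where the printed median is 0 (solid-part diameter
  in benign tumors) a structural-zero mass is mixed with a log-normal
  positive part (median 12 mm). The zero mass is 0.6, not 0.5: with mass
  exactly 0.5 the population median sits on a boundary and the *sample*
  median of an even-sized draw is positive about half the time, making the
  stated calibration property (sample median equal to the target 0)
  ill-posed; 0.6 makes the median strictly 0 and is clinically sensible —
  40.3% of benign masses are unilocular without any solid component, and
  other benign masses also lack solid tissue.
* **Ordinal counts**: Poisson truncated at 4 papillations, rate
  moment-matched to the printed mean on the truncated support.
* **Independence within class**: the publication carries no correlation
  information, so predictors are drawn independently given the class. This
  is the honest default and the generator's main departure from real data,
  where ultrasound features correlate strongly (a solid tumor and its
  solid-part diameter are not independent). Consequently synthetic
  discrimination is *optimistic*: a green end-to-end test establishes that
  the machinery works and ranks obvious signals correctly, not that real
  cohorts would yield the published performance figures.
* **Class counts**: largest-remainder exact allocation by default (stable
  fixtures; multinomial sampling by flag). Note that at n = 1066 exact
  allocation gives (799, 53, 171, 43); the observed cohort counts
  (800, 55, 169, 42) are an empirical draw, so the generator contract is
  agreement with n x prevalence within 2 cases.

# Numerical choices

* Coupling: least squares with stacked normalization; exact active-set
  enumeration for the constrained fallback; pair probabilities clipped to
  [0, 1] before coupling.
* LS-SVM/KLR solves: kernel-diagonal jitter `1e-10 (trace/n + 1)`; KLR
  working weights floored at `1e-10`; leave-one-out refuses cases with
  system-inverse diagonal below `1e-12` (leverage one).
* Tuning grids: `gamma`, `lambda` log-spaced over 10^-3..10^3 (13 points);
  `sigma` log-spaced over 1.5 decades around the median pairwise distance
  (7 points). All overridable; CV ties break to the most regularized
  point, then the larger bandwidth.
* Stratified splitting: per-stratum training count is round-half-up of
  `fraction * n`; membership randomized under the seed.
* All randomness flows through explicit integer seeds; no wall-clock
  defaults anywhere.
* Model documents are JSON at full numeric precision; a reloaded model
  reproduces predictions to machine accuracy (tested at `1e-12`).

# Scaled defaults in the shipped checks

The end-to-end replica exercised by the test suite runs all eight methods
on a simulated cohort of n = 1000 with 5-point regularization grids and
single-run selection CV, so the whole suite stays within a desk-scale time
budget; the procedures are identical to the full-effort configuration, only
the grid resolution and CV repetitions are reduced. The published study's
effort level (13-point grids, 20 CV runs) is the package default for real
use.

# Known limitations

* The Bayesian LS-SVM output is the documented approximation above, not
  the full evidence framework.
* The coordination of pairwise variable selection is this package's
  formalization of a procedure the publication describes only in outline.
* The generator cannot emulate inter-variable correlation (none is
  published) or center effects; a Gaussian-copula hook would be the
  natural extension.
* Real-data temporal/external validation cannot be reproduced here; the
  package provides the machinery (`validate_model()` on any conforming
  dataset, subgroup evaluation via `filter_cases()`), not the data.
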