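---
title: "The sparsity-ranked lasso: model, choices, and limits"
author: "srlasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sparsity-ranked lasso: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srlasso)
```

## The model

Given an outcome $y$ and covariates $x_1, \dots, x_p$, the sparsity-ranked
lasso (SRL) expands the covariates into a candidate matrix
$X = [A\,B\,C]$: the main effects $A$, all pairwise (or, with `k > 1`,
higher-order) interaction products $B$, and polynomial terms $C$ of orders
$2 \dots$ `poly` for continuous covariates.  It then minimizes

$$
\frac{1}{2n}\lVert y - X\beta \rVert^2 \;+\;
\lambda \sum_{j} w_j \lvert \beta_j \rvert ,
$$

replacing the least-squares term with twice the negative binomial
log-likelihood for binary outcomes.  The L1 penalty sets coefficients
exactly to zero, so tuning $\lambda$ (by 10-fold cross-validation) performs
selection.  What distinguishes the SRL from a plain lasso on the expanded
matrix is the *ranked* penalty weights $w_j$: each candidate term is
penalized by the size of the block it belongs to,

$$
w_j = p_j^{\gamma}, \qquad \gamma = 0.5 \text{ by default},
$$

where $p_j$ is the number of candidate terms in $j$'s block (all mains form
one block; all order-$m$ interactions another).  With $p$ mains and
$\binom{p}{2}$ pairwise interactions, an interaction must therefore carry
roughly $\sqrt{\binom{p}{2}/p}$ times more evidence than a main effect to
enter.  This calibrates the total prior information contributed by the
interaction block to match that of the mains — the model is skeptical of
complexity a priori, without any extra tuning parameter.  Setting
`gamma = 0` recovers the plain lasso on the same expanded matrix, and
`gamma = 0, k = 0, poly = 1` recovers a plain lasso on main effects only.

Two conventions here deserve a note:

* **The exponent.**  The weight is the square root of the block size
  ($\gamma = 0.5$), which is what the information-calibration argument
  yields; writing the weight as "$w_j = p_j$" leaves the exponent implicit.
  `gamma` is exposed so other calibrations can be explored.
* **Polynomial weights.**  Polynomial blocks are penalized by a
  *cumulative dimension*: an order-$m$ polynomial term gets
  $w = (\#\{\text{terms of polynomial order} \le m\})^{\gamma}$, with mains
  counted at order 1.  For 4 continuous mains and `poly = 2` the quadratic
  weight is $\sqrt{4 + 4}$.  This preserves the hierarchy — higher orders
  are never cheaper than lower ones — while keeping low-order polynomials
  only mildly more expensive than mains.  `assign_penalty_weights()` takes
  a `poly_weight_fun` hook so an alternative rule can be swapped in; no
  installed reference implementation was available to cross-check this
  interpretation, so it is frozen as the package's own convention and
  tested against its closed form.

Block sizes are computed on the candidate set that actually enters the
penalized fit (after the variance filter below).  When nothing is filtered
the counts coincide with the combinatorial ones.

## Preprocessing

`srl_fit()` runs a fit-on-train / apply-anywhere recipe:

1. **Rare-level collapsing** — categorical levels observed in less than
   `rare_threshold` (default 10%) of the training rows are pooled into
   `"other"` (`"other_merged"` if a literal `"other"` level exists).
2. **Dummy coding** — each categorical becomes $L - 1$ indicators against
   its most frequent level.  Dummies from one source are never multiplied
   together (their product is identically zero or a duplicate), and binary
   columns get no polynomial terms ($x^2 = x$ under 0/1 coding).
3. **Term construction** — interaction and polynomial columns are computed
   from centered-and-scaled *continuous* parents, while binary parents
   (including dummies) enter products raw, so a dummy product is the joint
   cell indicator — the object the variance filter and the coefficient
   table should see.  Every design column is then standardized (population
   scaling, so $\sum_i x_{ij}^2 = n$), which makes the penalty comparable
   across term types regardless.
4. **Variance filtering** — runs *after* expansion, because its most
   consequential action is on derived columns.  `filter = "nzv"` (default)
   drops near-zero-variance columns: most-frequent to second-most-frequent
   value ratio above 95/5 *and* fewer than 10% distinct values.
   `filter = "zv"` drops only exact constants; `"none"` drops nothing.
5. **Missing data** are a hard error: silent imputation would change the
   method.

The nzv default is a double-edged sword, and the package deliberately
reproduces both edges.  A product of two uncommon indicator levels is
almost always zero; nzv treats it as noise and removes it before the
supervised step.  When such a cell is exactly where the signal lives —
as in zero-inflated outcomes driven by one extreme factor combination —
the default silently deletes the only informative candidate, and
`filter = "zv"` is the documented fix.  `gen_zero_inflated_outcome()`
exists to make this mechanism testable: it plants a huge mean shift
(+13,000 by default) in a ~2% two-factor cell, so the nzv arm must fail
and the zv arm must recover the planted product term.

## Tuning and evaluation

The solver computes the whole path on a decreasing log-spaced grid of 100
$\lambda$ values from $\lambda_{\max}$ (the smallest $\lambda$ with an
all-null penalized fit) down to `lambda_min_ratio` $\times\,\lambda_{\max}$
(1e-3 when $n > p$, else 1e-2), with warm starts, full cyclic coordinate
descent plus an active-set refinement pass, and convergence declared when
the largest coefficient change falls below `tol` (1e-8).  Binomial fits use
iteratively reweighted least squares with working weights floored at 1e-5
and probabilities clipped to $[10^{-10}, 1 - 10^{-10}]$; a saturation guard
stops refinement once under 1% of the null deviance remains.  Correctness,
not speed, is the contract: tests certify solutions against a
sign-enumeration quadratic-programming oracle and
Karush–Kuhn–Tucker residuals at $10^{-6}$.

Cross-validation holds the full-data $\lambda$ grid fixed across folds,
scores folds by RMSE (Gaussian) or mean deviance per observation
(binomial; stratified folds), and reports per-$\lambda$ means with
standard errors $\mathrm{sd}(\text{fold losses})/\sqrt{K}$.  Two selections
are kept: `lambda_min` (ties broken toward the larger, sparser $\lambda$)
and the compact `lambda_1se` model, the largest $\lambda$ within one
standard error of the minimum.  Prediction-oriented summaries
(`predict()`, the bakeoff) default to `lambda_min`; interpretation
(`effect_profile()`) defaults to the compact model.

Held-out evaluation uses the sum-of-squared-errors R², RMSE, the
Mann–Whitney AUC with midrank ties, and binomial deviance.  Negative
held-out R² values are clamped to zero *only* where results feed
meta-analysis or benchmark summaries — never inside tuning losses.

## The benchmark harness and meta-model

`run_bakeoff()` reproduces an out-of-the-box comparison protocol: one
80/20 train–test split per dataset (stratified for binary endpoints),
shared by every algorithm; each arm tuned by its own default 10-fold CV;
binary arms evaluated by test AUC and continuous arms by test R².  The
built-in arms are the SRL and the plain lasso (the SRL under
`gamma = 0, k = 0, poly = 1`, which the tests require to match the lasso
arm row-for-row); black-box arms plug in as functions, so the harness runs
offline with any subset of arms.  `within_pct_of_best()` computes, per
algorithm, how often it is the best on a dataset and how often it lands
within 5% (relative, on the higher-is-better metric — the rule is exposed
as `tolerance`) of the best.  `meta_analyze()` fits
`metric ~ algorithm + (1 | dataset)` with the SRL as the fixed-effect
reference, so each estimate reads as the expected change in performance
relative to the SRL after absorbing dataset difficulty into a random
intercept.  Inference uses normal-approximation Wald intervals and
p-values; with 40+ datasets the difference from small-sample
degrees-of-freedom corrections is immaterial, and a singular
random-intercept fit falls back to fixed dataset effects with a warning.

## What the generators emulate — and what they do not

Each generator states one adversarial structure from real benchmark data;
none attempts to reproduce raw values.

* `gen_parity()` — 10 i.i.d. fair binary bits, outcome 1 exactly when a
  hidden 5-bit subset has even sum (n = 1124 by default).  Every feature
  and every pair of features is marginally independent of the outcome, so
  any method restricted to main effects, pairwise interactions and
  quadratics must score AUC ≈ 0.5 out of sample.  A green test here
  establishes honest failure, not success.
* `gen_interaction_signal()` — standard-normal mains with a planted
  pairwise product effect; used to verify that ranked weights still find a
  true interaction (effect 1.0, noise SD 1, n = 500) while selecting fewer
  false products than the unranked lasso.
* `gen_zero_inflated_outcome()` — point mass at zero, log-normal right
  tail, and a +13,000 shift when two independent 4-level factors both take
  their rarest level.  Marginals (0.49, 0.18, 0.18, 0.15) are chosen so
  every level survives 10% collapsing while every pairwise dummy product
  stays under the 95/5 nzv bound; all covariates are categorical or binary
  because the frequency-ratio rule cannot remove products of centered
  continuous parents.  The real scoring datasets' zero-mass proportion and
  scale are not public; these defaults are the package's own stated world.
* `gen_polynomial_signal()` — 120 observations, a binary `Official`, an
  integer `Round` 1–12, and log-odds $2.5\,T_7((\text{Round}-6.5)/5.5)$
  where $T_7$ is the degree-7 Chebyshev polynomial: bounded, oscillatory,
  and orthogonal to all lower-order polynomials, so `poly = 2` cannot
  represent it and `poly = 7` can.  The small n mirrors the motivating
  dataset and makes single-split AUCs noisy by design; claims are made on
  medians over 50 splits.
* `gen_benchmark_suite()` — small regression/classification datasets with
  known attainable R²/AUC for offline harness tests.

Real tabular data differ from all of these in correlated covariates,
non-Gaussian noise, measurement artifacts and distribution shift; a green
synthetic suite establishes that the machinery implements the stated
model, not that the SRL wins on any particular real dataset.

## Numerical choices and degenerate inputs

* $\lambda_{\max}$ is inflated by $1 + 10^{-10}$: without it,
  $(g/w) \times w$ can round one ulp below the gradient bound and activate
  a coefficient at the top of the path, breaking the all-null invariant.
  The first grid point is set to $\lambda_{\max}$ exactly rather than
  through `exp(log(...))`.
* Standardization uses population (divide-by-$n$) scales; zero-variance
  columns are left centered, flagged, and removed by every filter mode
  except `"none"`.
* Ties in the CV minimum go to the larger $\lambda$; a fold whose training
  complement has a constant binary response is skipped with a warning.
* A constant target, duplicate covariate names, missing values, and
  all-zero penalty weights are hard errors.
* Unseen categorical levels at prediction time map to the pooled level if
  one exists, else to the reference level.

## Known limitations

* Only the L1 penalty and Gaussian/binomial families are implemented — no
  elastic-net mixing, MCP/SCAD, multinomial or survival families.
* Coordinate descent on highly collinear high-order polynomial columns
  converges slowly near the unpenalized end of the path; such fits are
  flagged rather than silently accepted.
* Skewed or zero-inflated outcomes are modeled on the identity scale; the
  package reproduces the diagnosis and the `filter = "zv"` workaround, not
  a zero-inflation-aware likelihood.
* Effect profiles hold non-focal covariates at medians/modes; with strong
  interactions among non-focal covariates a profile is a slice, not a
  marginal effect.
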