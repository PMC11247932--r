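---
title: "IRT-based categorical imputation: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IRT-based categorical imputation: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtci)
```

## The idea

Most categorical imputers either treat category codes as numbers (and then
round), or condition on a handful of neighbours. `irtci` instead assumes the
features of a table are all noisy indicators of **one latent trait** θ per
case — the working assumption of unidimensional item response theory. Fitting
that model uses *every observed cell of every case*; a case's missing cells
are then the most probable categories of their items at the case's estimated
θ. The outcome column of a prediction task can be declared and is then
excluded from fitting, so imputations can never leak the label.

This document records the model, the numerical choices, and the places where
the design was genuinely open — and what a green test suite does and does not
establish.

## Model families and likelihood

Three logistic-metric families cover binary, ordinal and nominal features
(continuous features are quantile-discretized first; see below). With slope
$a_i > 0$:

* **2-PL** (binary): $P(U_{ij}=1\mid\theta_j) = \sigma(a_i(\theta_j - b_i))$
  with $\sigma(x) = e^x/(1+e^x)$.
* **GRM** (ordinal, $m_i$ categories): boundary curves
  $P^*_{ik}(\theta) = \sigma(a_i(\theta - b_{ik}))$ with strictly increasing
  thresholds; category probabilities are adjacent differences, with
  $P^*_{i0} \equiv 1$ and $P^*_{im_i} \equiv 0$. The subtraction telescopes,
  so the vector always sums to one.
* **NRM** (nominal): softmax over per-category linear predictors
  $a_{ik}\theta + c_{ik}$, identified by $a_{i1} = c_{i1} = 0$ (the
  lowest-category constraint; the alternative sum-to-zero constraint is a
  reparameterization of the same model).

No 1.7 normal-ogive rescaling constant is applied anywhere: parameters live
in the plain logistic metric.

Cases are assumed conditionally independent given θ, and items conditionally
independent within a case (local independence). A case's likelihood is the
product over its **observed** items only; a missing cell contributes a factor
of one. This is exactly where the method's missing-data tolerance comes from,
and it is valid under MCAR/MAR — under MNAR the missingness process itself
would carry information the model ignores.

## Estimation

Item parameters are estimated by **marginal maximum likelihood** via
Bock–Aitkin EM, not joint ML: joint ML (estimating every case's θ as a fixed
parameter simultaneously) is statistically inconsistent as cases grow, and
marginal estimation is what mature IRT software does. The θ prior is fixed at
standard normal, which also pins the latent scale.

* **Quadrature**: 41 equally spaced nodes on $[-6, 6]$, weights proportional
  to the standard-normal density, renormalized (`make_grid()`, both
  configurable). Equally spaced rules on rapidly decaying integrands are
  near-spectrally accurate, which is why the 41-node EAP matches a
  10,001-point trapezoid oracle to $10^{-3}$ in the acceptance suite.
* **E-step**: posterior weights of each case over the nodes.
* **M-step**: per item, BFGS on the expected complete-data log-likelihood in
  an unconstrained parameterization — $\log a$ for slopes, and GRM thresholds
  as $b_1, \log(b_{k+1}-b_k)$ increments so ordering can never be violated
  (violated ordering in *supplied* parameters is an error, never a silent
  reorder). An update is accepted only if it improves the objective
  (generalized EM), which guarantees the marginal log-likelihood is monotone
  across cycles; the suite asserts this at $10^{-8}$ tolerance in every fit.
  Expected counts are normalized before optimization so that duplicating
  every case reproduces bit-identical estimates.
* **Convergence**: maximum absolute parameter change $< 10^{-4}$, at most
  500 cycles; on non-convergence the best-so-far fit is returned with
  `converged = FALSE` and a warning. Everything is deterministic given data
  and settings.
* **Starting values**: $a = 1$; 2-PL/GRM thresholds at normal quantiles of
  the observed cumulative category proportions. For the NRM the slopes start
  at $0.25\,(k-1)$, *not* all at zero: with all slopes zero the likelihood is
  flat in θ, every posterior equals the prior, and the M-step gradient
  vanishes identically — an exact EM fixed point (a saddle) that a pure-NRM
  fit would never leave. The small increasing offsets break that symmetry
  deterministically; BFGS is free to reorder or flip them.
* **Degenerate items**: an item with fewer than two observed categories is an
  error naming the item. An item observed in fewer categories than declared
  is collapsed to its observed codes with a warning; the remap is kept and
  imputations are decoded back to the declared coding.

Scoring is **EAP**: posterior mean (and SD) of θ on the fitted grid. An
all-missing row receives the prior mean 0 and prior SD.

## Imputation rules

A missing cell gets the **argmax category** of its item's probability vector
evaluated at the case's EAP point. For binary items this reproduces the
50%-threshold rule exactly. Two open points were decided as follows:

* **Point-EAP vs posterior-averaged probabilities**: whether the reference
  implementation in the source workflow plugged in the EAP point or
  integrated over the posterior is unstated. Point-EAP is the default (it
  matches the "impute from each case's θ score" description);
  `impute_cell(..., posterior = TRUE)` provides the posterior-averaged
  alternative. For binary and GRM items at moderate posterior spread the two
  rarely disagree.
* **Exact 50% tie**: unspecified ("below… above…"). Resolved to the lowest
  category index, consistent with the general argmax tie rule, and
  deterministic.

Single imputation only: one completed table, no multiple-imputation variance
pooling. Discretized continuous features are imputed as bin codes; mapping a
bin back to a continuous value is out of scope.

## Discretization

Continuous features are binned into empirical-quantile bins (default 4 —
quartiles), left-closed/right-open except the last. Quantile bins are
rank-based, so any monotone transform of the feature yields identical codes,
and heavily skewed features keep balanced bins — the reason quantiles were
chosen over equal-width cuts. Constant or nearly constant features are a
degenerate-feature error. The discretization is used only to *fit* the
model; raw values are preserved for output.

## Amputation and Little's test

For benchmarking, complete tables are damaged in two controlled ways:

* **MCAR**: exactly `round(f·N)` cells of the target column, uniformly at
  random under a seed.
* **MAR**: stable sort on a complete conditional column (descending by
  default — the "remove from the top" convention is ambiguous, so the
  direction is configurable), delete the target in the first `round(f·N)`
  rows, restore order. Deterministic.

**Little's test** groups rows by missingness pattern and compares each
pattern's observed means with EM estimates of the grand mean/covariance
(tolerance $10^{-6}$, max 200 iterations, started from available-case
moments with a tiny ridge if needed), summing
$n_j(\bar y_j - \hat\mu_j)^\top \hat\Sigma_j^{-1}(\bar y_j - \hat\mu_j)$
against a $\chi^2$ with $\sum_j p_j - p$ degrees of freedom. Complete data
yield a not-applicable report (df 0, p 1). The test assumes multivariate
normal sufficient statistics; integer-coded categorical columns make it an
approximation — adequate for detecting the sort-and-delete MAR mechanism,
which shifts pattern means strongly. The suite verifies a type-I error
inside [0.03, 0.08] at α = 0.05 under MCAR and ≥ 80% power under MAR with a
0.6 conditional correlation.

## What the simulator emulates — and what it does not

`simulate_responses()` draws θ from a standard normal and each cell from its
item's category distribution at that θ: data that satisfy the model exactly,
with known parameters. Defaults used across the tests reflect realistic
psychometric ranges — slopes in roughly $[0.8, 2.2]$, thresholds/difficulties
standard-normal-ish, sample sizes 1000–3000.

Green recovery and benchmark tests therefore establish *correctness of the
implementation under its own assumptions*: unidimensionality, local
independence, logistic link, MCAR/MAR missingness. They do not establish
robustness to multidimensional traits, violated local independence,
MNAR missingness, or the messiness of real epidemiological tables — the
simulator deliberately does not emulate those.

## Evaluation

`imputed_cell_f1()` scores only cells that were imputed, from the confusion
matrix: per-category precision, recall, F1 = 2PR/(P+R). The aggregate default
is **macro** (the averaging scheme behind the source study's single F1 per
experiment is unstated; macro treats rare categories equitably, and micro —
which equals accuracy for single-label assignment — and weighted are
selectable). A category absent from both vectors has undefined F1 and is
excluded from the macro mean; a category present but never correctly
predicted scores 0.

## Known limitations

* One latent dimension; no 3-PL guessing parameter; no normal-ogive link.
* No standard errors or model-fit statistics for item parameters.
* Little's test on coded categorical columns is an approximation.
* Continuous cells cannot be imputed on their original scale.
* MNAR mechanisms are out of scope throughout.
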