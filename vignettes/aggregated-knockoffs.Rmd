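---
title: "Aggregated knockoff filtering: model, design choices, and validation"
author: "akofilter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated knockoff filtering: model, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akofilter)
```

## The problem

Given $n$ observations of $p$ candidate variables and an outcome — in the
motivating application, log-transformed relative abundances of gut-microbiome
taxa and a binary obesity indicator — we want the set of truly associated
variables $S^* = \{j : \beta_j \neq 0\}$ while controlling the false
discovery rate
$\mathrm{FDR} = \mathbb{E}\,|\hat S \setminus S^*| / (|\hat S| \vee 1)$
at a target level $q$. Sparse penalized regression selects variables but
offers no FDR guarantee; the knockoff filter adds one, and this package
implements an aggregation of knockoff filters that keeps the guarantee while
recovering more of the signal in practice.

## The knockoff filter

For Gaussian rows $x_i \sim N(0, \Sigma)$, a knockoff copy $\tilde x_i$ is
drawn from the conditional law

$$\tilde x_i \mid x_i \sim N\!\big(x_i - x_i \Sigma^{-1}\mathrm{diag}(a),\;
  V\big), \qquad
  V = 2\,\mathrm{diag}(a) - \mathrm{diag}(a)\,\Sigma^{-1}\mathrm{diag}(a),$$

so the joint covariance of $(x_i, \tilde x_i)$ is
$[[\Sigma, \Sigma - \mathrm{diag}(a)], [\Sigma - \mathrm{diag}(a), \Sigma]]$
and originals and knockoffs are exchangeable for null variables. The vector
$a > 0$ only has to keep $V$ positive definite; `computeSVector()` uses the
closed-form equicorrelated choice, every entry equal to
$\min(2\lambda_{\min}(\Sigma), \min_j \Sigma_{jj})$ shrunk by $10^{-6}$ for
strict definiteness. A semidefinite-programming choice of $a$ exists in the
literature; no SDP solver is among this package's dependencies, so
`method = "sdp"` falls back to the equicorrelated value with a warning.

The path statistic compares how early each variable and its knockoff enter a
penalized fit on the augmented design $[X\ \tilde X]$: with entry values
$Z_j$ (original) and $\tilde Z_j$ (knockoff) — the largest penalty at which
the coefficient is nonzero — the signed-max statistic is
$W_j = \max(Z_j, \tilde Z_j)\cdot\mathrm{sign}(Z_j - \tilde Z_j)$.
Selection uses the data-dependent threshold

$$T_q = \min\Big\{t \in \mathcal W :
  \frac{\#\{j : W_j \le -t\}}{\#\{j : W_j \ge t\} \vee 1} \le q\Big\},$$

over the candidate set $\mathcal W$ of strictly positive $|W_j|$; knockoff+
adds 1 to the numerator and controls FDR exactly in finite samples.

## Aggregation

The aggregation scheme chooses per-run levels $q_1, \dots, q_k$, runs the
filter once per level — each run with a freshly sampled knockoff matrix —
and returns the union of the selections. If every run uses knockoff+ and
$\sum_i q_i = q$, the union controls FDR at $q$: the false-discovery
proportion of the union is bounded by the sum of the per-run proportions
computed with their own (smaller) denominators, and expectations add. The
recommended practical schedule is geometric, $q_i = q/2^{i-1}$ with
$k = 5$; its sum slightly exceeds $q$, so `makeSchedule()` also offers a
"strict" mode that rescales the same sequence to sum to $q$ exactly, for
use when the certified bound is wanted. With $k = 1$ both modes reduce to
the plain filter.

## Design choices

The literature leaves several things open; the package resolves them as
follows.

**Linear entry values are exact.** The lasso solution path is piecewise
linear in the penalty, so `lassoEntryTimes()` computes it by a LARS-style
homotopy and reads entry values off the breakpoints, avoiding
grid-resolution artifacts in $Z$. The outcome is centered and no intercept
is fit. A coefficient is considered nonzero above $10^{-8}$. The unit tests
cross-check these entries against a 2000-point grid fit.

**Logistic entry values use a warm-started grid.** No exact path exists for
the logistic loss; `logisticEntryTimes()` sweeps a log-spaced descending
grid of 100 points (50 in the reduced-scale simulations, configurable) from
$\lambda_{\max} = \max_j |A_j^\top(y - \bar y)|/n$ — the smallest penalty
with an all-zero solution — down to $10^{-3}\lambda_{\max}$, with an
unpenalized intercept. Doubling the grid density moves entries by less than
one grid step (tested).

**Ties select nothing.** $W_j = 0$ (simultaneous entry, or neither entering)
is excluded from the threshold's candidate set, a conservative choice.

**Fresh knockoffs per run.** Each aggregation run draws its own knockoff
matrix from a deterministic child seed of the master seed; the union then
aggregates genuinely different randomizations, which is where the power gain
comes from. A `sharedKnockoffs` ablation reuses one draw; the FDR bound
holds either way.

**Data mode standardizes.** When the covariance is unknown,
`aggregateKnockoffs()` centers and scales the design and estimates the
covariance on the correlation scale with analytic (Ledoit–Wolf-style)
shrinkage toward a scaled identity, which stays positive definite even with
$p \ge n$. Penalized paths are scale-sensitive, so operating on the
correlation scale makes the per-variable penalties comparable. In
simulations the known covariance is used directly. Positive definiteness is
checked after symmetrization with an eigenvalue tolerance of $10^{-8}$.

**Power denominator.** Empirical power is reported as
$|\hat S \cap S^*| / (|S^*| \vee 1)$, the standard true-positive proportion;
`evaluateSelection(denominator = "selected")` provides the variant that
divides by the selection size instead.

## The simulation designs

`runExperiment()` reproduces the two validation designs: rows of $X$ i.i.d.
$N(0, \Sigma)$ with AR(1) covariance $\Sigma_{ij} = \rho^{|i-j|}$,
$\rho = 0.5$, $(n, p) = (200, 100)$; 20 coefficients set to 1 at random
positions and rescaled so $\|X\beta\|^2/(n\sigma^2) = 5$ with
$\sigma^2 = 1$; outcomes linear ($y = X\beta + u$) or logistic
($\Pr(y_i = 1) = 1/(1 + e^{-x_i^\top\beta})$). KO (single run) and AKO
($k = 5$) share datasets and knockoff draws, so their comparison is paired.
Problem sizes used by the validation suite: 100 repetitions for the linear
FDR check, 60 for the paired power ordering, 30 for the logistic FDR check
(with the 50-point grid) — sizes at which the Monte-Carlo standard errors
are small enough for the $3\,\mathrm{SE}$ margins used in the tests.
The target-level grid for figures defaults to
$\{0.05, 0.1, \dots, 0.3\}$, the conventional range.

## The synthetic count-table generator

`generateSyntheticCounts()` is a synthetic stand-in for real gut-microbiome
count data, built to exercise the full pipeline with a known truth. It
emulates two salient features of such data — correlated taxa and zero
inflation — by drawing latent log-abundances with AR(1) correlation
($\rho = 0.5$, matching the simulation designs), exponentiating and
rounding to counts, then zeroing the smallest entries until a target zero
fraction (default 0.30) is reached, never emptying a sample row. BMI is
generated from a logistic model on the preprocessed, standardized signal
taxa (default 5 taxa with per-taxon log-odds effect 1 and intercept $-1$,
about 30% obese — a cohort-like rate rather than a population one), with
obese samples assigned BMI $\ge 30$ and the rest spread over the
underweight/normal/overweight range. Defaults of $n = 200$ samples and
$p = 50$ taxa correspond to a modest phylum/genus-level table.

What it does **not** emulate: compositional closure effects beyond the
per-sample normalization, taxon-specific dispersion, sequencing-depth
variation, phylogenetic correlation structure, or the extreme sparsity of
genus-level tables. Passing tests on this generator show the pipeline's
FDR machinery works end to end on correlated, zero-inflated inputs; they do
not certify behavior on any particular real dataset.

A granularity note relevant to sparse supports: a knockoff+ run at level
$q$ can only ever select $\lceil 1/q \rceil$ or more variables (the +1 in
the numerator forces $\#\{W_j \ge t\} \ge 1/q$). With a 5-taxon support and
$q = 0.1$, any selecting run must therefore include at least 10 taxa, and
most runs select nothing at all — so knockoff+ power on very sparse
fixtures is intrinsically near zero, while the standard threshold behaves
gracefully. This is a property of the method, not of the implementation.

## Preprocessing conventions

Count tables are converted to per-sample relative abundances by default
(disable with `relative = FALSE` if the table already holds abundances or
raw counts are wanted), zeros are replaced by half the minimum observed
positive abundance — globally by default, the simpler literal reading;
per-taxon on request — and the natural log is applied. The log base is a
column rescaling that the subsequent standardization removes, so the choice
is inconsequential. Preprocessing is applied exactly once by
`selectTaxa()`, after restricting to the requested BMI grouping so the
replacement minimum reflects the analyzed samples. BMI groups use the
standard cut points (underweight $<18.5$, normal $[18.5, 25)$, overweight
$[25, 30)$, obese $\ge 30$), with the binary outcome 1 exactly for the
obese group.

## Known limitations

* The Gaussian knockoff construction assumes (approximately) Gaussian
  designs; log-transformed relative abundances are only roughly so. The
  aggregation layer itself is agnostic — any knockoff sampler with the
  exchangeability property could be substituted — but only the Gaussian
  sampler is implemented.
* The logistic entry values inherit the grid resolution; ties induced by
  coarse grids inflate the number of $W_j = 0$ entries, which are treated
  conservatively.
* The standard (non-plus) threshold's FDR control is approximate, both for
  single runs and for the aggregation; only knockoff+ with a strictly
  summing schedule carries the finite-sample guarantee.
* Covariance shrinkage targets a scaled identity; strongly structured
  covariances with $p \gg n$ may warrant a structured estimator.

## A worked example

```{r example, eval = FALSE}
sim <- generateLinear(n = 200, p = 100, rho = 0.5, nSignal = 20,
                      snr = 5, seed = 1)
res <- aggregateKnockoffs(sim$X, sim$y, q = 0.1, k = 5, plus = TRUE,
                          scheduleMode = "strict",
                          sigma = ar1Covariance(100, 0.5), seed = 1)
res
evaluateSelection(selectedVariables(res), sim$support)
```
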