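---
title: "Measuring household socioeconomic status across study sites: methods behind wamindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring household socioeconomic status across study sites: methods behind wamindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wamindex)
```

## The measurement problem

Epidemiological studies that pool households from several low- and
middle-income settings need a socioeconomic status (SES) measure that means
the same thing in every site. Income is hard to collect and noisy; asset
ownership is easy to collect but must be selected and weighted somehow; and
indices fitted separately per country (as national wealth quintiles are) are
not comparable across countries. `wamindex` implements four household wealth
measures on a common footing and a composite SES index built from them, plus
the machinery to compare them against a child-growth outcome
(height-for-age Z-score, HAZ) that serves as the construct-validity anchor.

The five measures are:

1. **Maternal education** — completed years of schooling, the conventional
   single-variable proxy and the baseline every other measure must beat.
2. **Tetrachoric PCA** — the first principal component of the tetrachoric
   correlation matrix of screened binary asset indicators.
3. **Adapted MPI** — a household-level Multidimensional Poverty Index with
   three equally weighted dimensions (education, health, living standard),
   reported as wealth (one minus deprivation) so all measures point the
   same way.
4. **RF asset score** — the unweighted count of eight priority assets,
   selected by conditional permutation importance in a regression forest
   with HAZ as the outcome.
5. **WAMI** — the composite: **W**ater/sanitation + **A**ssets +
   **M**aternal education + **I**ncome, each scored 0–8, summed and divided
   by 32 so the index lives on the unit interval.

## Indicator screening

Candidate indicators are binary asset/housing variables plus electricity and
a dichotomized crowding indicator (1 when people per room is below 2, so
that every indicator points "wealthier = 1"). Screening proceeds in two
passes:

* **Variation**: indicators with fewer than 10% of households in their rarer
  category are dropped (`min_category_prop = 0.10`). Near-constant
  indicators carry no information and destabilize the tetrachoric fit.
* **Reliability**: Cronbach's alpha
  \(\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)\) is computed,
  and indicators are removed one at a time — always the one whose deletion
  raises alpha the most, ties broken by name order for determinism — while
  the improvement exceeds `alpha_drop_delta` (default 0.01). The threshold
  is a standard scale-purification heuristic; no canonical value exists, so
  it is exposed as a parameter. We apply the rule iteratively rather than in
  a single pass because a one-pass rule can drop an item whose apparent
  inconsistency disappears once a worse item is removed.

## Tetrachoric PCA

Binary indicators violate the linearity assumptions of ordinary PCA, so the
correlation input is the **tetrachoric** matrix: for each pair, the
correlation of the standard bivariate normal assumed to underlie the two
dichotomizations. Estimation is two-step maximum likelihood — thresholds
fixed at the inverse-normal of the margins, the correlation found by 1-D
maximization of the multinomial likelihood of the 2×2 table. The bivariate
normal rectangle probability is evaluated by adaptive quadrature of
\(\phi(x)\,\Phi\!\bigl((k-\rho x)/\sqrt{1-\rho^2}\bigr)\).

Numerical choices:

* **Zero cells** (perfect association) have no finite MLE; we add a 0.5
  continuity correction to every cell, clamp \(|\hat\rho| \le 0.999\), and
  flag the pair as a boundary case.
* **PSD repair**: a matrix assembled pairwise need not be positive
  semidefinite. If an eigenvalue falls below −1e−8 the matrix is projected
  to the nearest PSD correlation matrix (eigenvalue clipping, unit diagonal
  restored) and flagged.
* **Sign**: an eigenvector is defined up to sign. The component is oriented
  so that an anchor indicator loads positively; the default anchor is the
  indicator with the largest row sum of the correlation matrix (the one
  most positively correlated with the rest), which is stable under
  indicator reordering. If the two leading eigenvalues coincide within
  tolerance the component is not identified and the fit refuses to proceed.

Households are scored by the leading eigenvector applied to
prevalence-standardized indicators \((x_j-\bar x_j)/s_j\) (the
Filmer–Pritchett convention) and scores are standardized to mean 0, SD 1.
Held-out households are scored with the training means, SDs and loadings,
which is what the cross-validation machinery relies on.

## Random-forest asset selection

A regression forest of HAZ on the screened indicators is grown on bootstrap
resamples (defaults: 500 trees, \(\lceil p/3\rceil\) candidate features per
split, minimum node size 5 — conventional regression-forest settings; a seed
is mandatory). The forest fit itself is delegated to `ranger` with in-bag
tracking; everything downstream is computed here.

**Conditional permutation importance.** Marginal permutation importance
inflates correlated indicators: a variable can look important merely because
it is correlated with a truly predictive one. The conditional scheme
permutes indicator \(j\) only *within strata* defined by the covariates
associated with it (absolute phi coefficient above
`conditional_threshold = 0.2`, the most associated
`max_conditioning_vars = 5` covariates cross-classified, so at most
\(2^5\) strata stay populated). The importance of \(j\) is the mean over
trees of the increase in out-of-bag squared error after permutation,
averaged over `n_perm` seeded permutation replicates. A duplicated copy of
an informative indicator therefore scores near zero — the defining behavior
of the conditional scheme, and the property the test suite checks.

**Selection.** The default keeps the top eight indicators (`fixed_k`,
k = 8). A scree-style automatic mode (`largest_gap`) is also provided: the
kept prefix ends just before the largest consecutive drop in the ordered
importances, earliest gap on ties. The **asset score** is then the plain
unweighted count of selected assets owned — deliberately simple, so the
measure can be recomputed in the field without refitting anything.

## The WAMI composite

| Component | Rule | Range |
|---|---|---|
| Water/sanitation | 4 points per improved source, summed | 0–8 |
| Assets | count of the 8 selected assets | 0–8 |
| Maternal education | years (0–16, capped) divided by 2 | 0–8 |
| Income | USD octile score against fixed cutoffs 26 / 47 / 72 / 106 / 135 / 200 / 293 | 1–8 |

WAMI is the component sum divided by 32. Because the income component's
lowest score is 1, the literal composite ranges over \([1/32, 1]\), not
\([0, 1]\); we implement the canonical rule literally rather than silently
rescaling. Income bin bounds are upper-inclusive on a two-decimal USD
lattice (26.00 scores 1, 26.01 scores 2), and incomes are rounded to two
decimals before scoring. For cohorts whose income distribution differs from
the reference cutoffs, `empirical_octile_cutoffs()` recomputes octiles from
the analyzed sample.

The MPI adaptation scores education deprivation as fewer than 5 completed
years (configurable; the choice follows the years-of-schooling convention
of the UNDP index given household-level data), health deprivation as any
child having died, and living-standard deprivation as the mean of six
indicators (no electricity, unimproved water, unimproved sanitation,
natural flooring, solid cooking fuel, owning at most one of seven listed
assets). Child nutritional status is *not* an MPI component here because it
is the outcome.

## Validation framework

All evaluation regressions are ordinary least squares of HAZ on the score
**plus site indicator variables** (first site as reference). We include
site dummies in every evaluation model — including cross-validation — for
a single consistent evaluation model; `site_dummies = FALSE` ablates this.

* **Cross-validated MSE.** Leave-one-out refits the scoring pipeline on
  each training fold when `refit_selection` is on (the default for the PCA
  and RF measures, whose loadings/asset sets are data-derived; off for
  fixed-cutoff measures), then predicts the held-out HAZ. With refitting
  disabled, LOOCV of the linear model equals the closed-form PRESS
  statistic, which the tests verify against the hat-matrix formula.
  Refitting a forest per leave-one-out fold is \(O(n)\) forest fits, so the
  comparison table defaults to stratified 10-fold CV (fold membership dealt
  round-robin within site from a seed); k-fold with `k = n` reproduces
  LOOCV exactly.
* **Adjusted R²** of the same regression.
* **Scaled effect size.** Measures live on different scales, so scores are
  min–max rescaled to \([0,1]\) (WAMI is used as-is) and the reported
  effect is 0.25 × slope: the HAZ change associated with a 25% increase of
  the measure's range, with a t-based 95% CI (normal above 100 residual
  degrees of freedom).
* **Income association.** Pearson/Spearman correlation of each score with
  log(1 + income in USD) at household level and on site means — the
  construct-validity check that wealth measures should track income.

## The synthetic cohort generator

No household-level data ship with the package; every analysis is exercised
on synthetic cohorts with the statistical structure the methods assume:

* latent wealth \(w \sim N(\mu_s, \sigma_s)\) per site, with site means in
  a low / middle / high pattern;
* each binary indicator is a probit dichotomization
  \(x_j = \mathbf{1}\{\lambda w^* + \sqrt{1-\lambda^2}\,\varepsilon >
  \tau_j\}\) of standardized wealth, so the pairwise tetrachoric
  correlation is exactly \(\lambda^2\) — tetrachoric estimation on
  generated data is a genuine parameter-recovery test, not a smoke test;
* education, log-normal USD income, crowding, and the MPI fields are drawn
  from wealth-linked models; improved water/sanitation are site-level
  coverage draws;
* HAZ is linear in a scaled WAMI-like composite of the signal components
  (`true_effect`, default 1.5 HAZ per unit of the 0–1 composite, i.e.
  ≈ 0.38 SD per 25%), optionally plus direct per-asset effects and an
  independent water/sanitation effect, with Gaussian noise (SD 1.1);
* site HAZ intercepts are calibrated (`calibrate_stunting()`) so that about
  42% of children fall below HAZ −2 under the default conditions.

Defaults: 8 sites × 100 households, 14 assets + electricity + crowding
(16 candidate indicators), asset loading 0.7. What the generator does *not*
emulate: real surveys' missingness patterns, informative non-response,
intra-cluster correlation beyond the site level, reporting error in income,
or site-specific asset meanings. Passing recovery tests therefore
demonstrates that the estimators do what they claim under the model they
assume — not that any particular field dataset satisfies that model.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. The test suite and the acceptance script run the pipeline at
n = 800 households with forests of 150–300 trees and 2–3 permutation
replicates per indicator, and replicate-based checks use 20 seeded
replicates with an 18/20 pass criterion — sizes chosen to exercise the
full pipeline at the intended cohort scale while keeping a complete run in
minutes on one core. Larger forests sharpen the importance ranking but do
not change any qualitative behavior the tests assert.

## Known limitations

* The tetrachoric estimator assumes an underlying bivariate normal; heavily
  skewed latent traits will bias \(\hat\rho\).
* Conditional importance depends on the conditioning threshold and the
  strata cap; with many highly inter-correlated indicators the strata can
  fragment, and importances of near-duplicate indicators are split between
  them by design.
* The anthropometric filter takes HAZ as computed input; it does not
  recompute Z-scores from raw anthropometry.
* Fixed income octile cutoffs are only meaningful for cohorts on a
  comparable USD income scale; use empirical octiles otherwise.
* The 789-household behavior of any particular published survey is not
  reproducible from this package alone: all quantitative claims in the
  test suite are about synthetic cohorts from the generator above.
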