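---
title: "Methods: litter traits, environment and phylogeny"
author: "littertraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: litter traits, environment and phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littertraits)
```

This vignette documents the statistical methods implemented in
`littertraits`, the assumptions behind them, the numerical choices that
matter, and what the synthetic-data generators do and do not emulate.
It states no empirical result beyond what the package's own test suite
and `scripts/acceptance.R` compute.

## The scientific setting

A global litter-quality survey measures traits of freshly fallen leaves
— nitrogen and phosphorus concentration (% dry mass), their ratio N:P,
magnesium, condensed tannins, and specific leaf area (SLA, leaf area per
dry mass, an inverse proxy for toughness) — for species sampled at
geographically scattered stream sites, together with site-level climate
(MAT, MAP, temperature and precipitation seasonality, dry-quarter
precipitation) and soil descriptors (pH, organic carbon, soil N). Three
questions drive the analysis: which environmental factors explain trait
variation, how traits vary with latitude, and whether related species
carry similar trait values (phylogenetic signal).

## Grafting species onto a backbone phylogeny

Trait species are rarely all present in a published, time-calibrated
tree. `graft_species()` places the missing ones by taxonomy:

* one congener in the tree: the new species becomes that leaf's sibling
  with an equal pendant branch, so it surfaces at its relative's depth;
* several congeners: the new species is added as an extra child of their
  MRCA with a pendant equal to the relatives' mean depth below that node
  (exact under ultrametricity), again surfacing at the relatives' depth;
* no congener: the same logic at family rank; otherwise the species is
  reported unplaceable.

Insertions create polytomies, which `resolve_polytomies()` removes: at a
node with more than two children, two children are drawn uniformly at
random and grouped under a new internal node whose branch length is half
the shortest *current* child branch of the polytomous node; the grouped
children's branches shrink by the same amount, so no leaf-to-root
distance ever changes. The "current child set" reading matters: after a
grouping step the new internal edge participates in the next minimum, so
later edges can be shorter than earlier ones. A zero-length shortest
child yields a zero-length internal edge, which is legal throughout the
package.

Two design choices were genuinely open. First, insertion order: species
are processed alphabetically, and inserted species immediately count as
potential nearest relatives for later species; this makes runs
reproducible and lets dense genera assemble themselves. Second, the
pendant length at multi-congener attachments: we chose depth-equality
with the relatives (rather than copying the MRCA's own stem length)
because it is the reading under which an ultrametric backbone remains
ultrametric after grafting — a property the downstream λ machinery
benefits from and the test suite asserts. The single-relative case is
identical under both readings. All placements, ranks, pendant lengths
and the seed are recorded in the `graft_result` report.

## Pagel's λ by maximum likelihood

Under Brownian motion a trait vector is multivariate normal with
covariance σ²C, where `C[i, j]` is the shared root-to-MRCA path length
of tips i and j. Pagel's λ multiplies the off-diagonal of C: λ = 0 means
no phylogenetic dependence, λ = 1 pure Brownian motion. `fit_lambda()`
profiles the ancestral mean and rate analytically and maximises the
resulting 1-D likelihood on [0, 1] with a 21-point bracketing grid
followed by bounded scalar optimisation (tolerance 1e-6), also checking
the interval endpoints, which plain `optimize()` cannot return exactly.

Numerical choices:

* On ultrametric trees (constant `diag(C)` = t) the transform
  `C(λ) = λC + (1−λ)tI` shares C's eigenvectors, so one symmetric
  eigendecomposition makes every λ evaluation O(n). Non-ultrametric
  trees fall back to a Cholesky factorization per evaluation; both paths
  agree with a dense multivariate-normal density oracle to 1e-10 in the
  tests. No explicit matrix inversion is ever formed.
* λ is bounded above by 1. Some implementations allow the larger bound
  at which C(λ) stays positive definite; we keep the [0, 1]
  interpretation the trait literature uses. The bound is an argument
  (`lambda_max`) for users who want otherwise.
* The test of λ = 0 refers twice the log-likelihood ratio to χ² with one
  degree of freedom, without a 50:50 boundary mixture correction. At the
  λ = 0 boundary this is conservative — the acceptance suite measures a
  rejection rate well below the nominal 5% — which we prefer to an
  anti-conservative approximation. ML (not REML) is used since only an
  intercept is estimated.
* Species present in the trait table but absent from the tree are
  dropped with a warning and counted; species observed at several sites
  enter through their mean.

## The trait–environment modelling chain

For each trait the pipeline fits, on species-at-site observations:

1. **Transforms.** Predictors are z-scored (effects are then per SD);
   responses stay on their measurement scale except N:P and SLA, which
   are natural-log transformed — both show multiple extreme values
   within sites, and the log stabilises the spread. Natural rather than
   decimal log keeps intercepts interpretable as log-scale trait means.
2. **Outlier handling.** Exclusions are explicit (site, species, trait)
   and set single cells missing; additionally any value more than 3 SD
   from its trait's grand mean is flagged for inspection but never
   removed automatically. Note a lone outlier among n values cannot
   exceed `z = (n−1)/√n`, so the flag is only informative for reasonably
   sized tables.
3. **Collinearity screen.** While any predictor pair has |r| ≥ 0.60 the
   predictor with the most violating partners is dropped (ties: larger
   mean |r|, then alphabetical). VIFs (`1/(1−R²_j)`) are computed for
   the survivors and a warning is raised at 4 or above.
4. **Heteroscedastic GLS.** Residual variance may differ by site:
   `V = σ² diag(δ²_{s(i)})` with the first site as reference (δ ≡ 1).
   `gls_fit()` profiles β and σ² analytically and optimizes the per-site
   log variance ratios by bounded L-BFGS-B, under ML or REML. The need
   for the variance structure is decided by REML AIC at the full design.
   The log-ratios are confined to ±log(25): the per-group ML likelihood
   is unbounded whenever the weighted fit can interpolate a small site
   (its ratio then runs to zero), and a boundary estimate triggers a
   warning rather than a crash. Optimization starts from OLS per-site
   residual SD ratios with a flat start as a safety net.
5. **Backward selection.** From the full model (all retained predictors
   plus the MAT × MAP interaction), the least significant removable term
   is dropped and the reduction kept only if the ML AIC strictly
   decreases; candidates are tried in decreasing p order until one is
   accepted or none improves the AIC; the loop also stops when every
   removable term is significant at α = 0.05. Marginality is enforced:
   MAT and MAP cannot leave while MAT × MAP is present. Fixed-effect
   comparisons always use ML refits (REML likelihoods are not comparable
   across fixed-effect sets, and `compare_aic()` refuses to do so); the
   selected model is refit by REML for inference, with two-sided t tests
   on n − k degrees of freedom. The full trace (term, p, AIC before and
   after, accepted) is kept. A consequence of the dual stopping rule
   worth knowing: a null predictor whose |t| lies between √2 and 1.96
   blocks its own removal via AIC, so the selected set retains such
   borderline terms by design; the acceptance suite therefore scores the
   retention of true predictors, and reports the exact-set rate
   alongside.
6. **Relative importance.** The final model's R² is decomposed by the
   LMG metric — each predictor's sequential R² contribution averaged
   over all predictor orderings — computed exactly via subset
   enumeration (hence a 10-predictor cap), with the interaction treated
   as a predictor in its own right. Because the metric is defined for
   homoscedastic regression, rows are first whitened by the fitted
   1/δ_s (the minimal coherent extension; the unwhitened decomposition
   is available via `whiten = FALSE`). Shares are normalised to sum
   to 100. Uncertainty comes from a bootstrap stratified by site, with a
   mandatory seed; the pipeline default is B = 1000.

## Ordination and latitudinal trends

`trait_pca()` z-scores complete-case rows and applies the SVD; variance
fractions are `s²_k/Σs²` and each axis is sign-fixed so its dominant
loading is positive, making outputs platform-stable. `fit_latitude_smooth()`
fits each trait against absolute latitude with a penalized cubic
regression spline (basis dimension 10, knots at latitude quantiles,
smoothness by GCV via mgcv). Site structure enters through optional
per-site inverse-variance weights estimated from a preliminary
unweighted fit — a deliberate simplification of a random-intercept
additive model that keeps the stage light and fully testable. The
reported r² is the weighted working-scale `1 − RSS/TSS` (response-scale
residuals), and the p-value of the smooth term is approximate
(Wald-type) and labelled as such. Forcing the smoothing parameter to a
very large value collapses the fit to the penalty null space, i.e.
ordinary linear regression on latitude, which the tests verify; fits on
strongly clustered site data can use most of the basis (high effective
degrees of freedom) because the smooth absorbs between-site differences
a random intercept would otherwise take — a known limitation of the
weights-only simplification.

## What the synthetic data emulate

`sim_config()` encodes the study design the generators reproduce: 24
sites between 43°S and 64°N, 3–7 species per non-tropical and 6–14 per
tropical site with 151 species in total, r(MAT, MAP) ≈ 0.63 among site
predictors and r(N, P) ≈ 0.58 among traits, and per-site residual
variance heterogeneity (log-normal ratios, SD 0.3 on the log scale).
Trait scales mimic field measurements (litter N near 1% dry mass, SLA
near 150, i.e. ≈ 5 on the log scale) so the transform code paths are
exercised realistically.

* **Trees.** `simulate_yule_tree()` grows a pure-birth tree (ultrametric
  by construction — the simplest adequate stand-in for a dated
  backbone), then labels tips with synthetic binomials in contiguous
  genera of 1–5 tips and families of 1–4 genera, giving the grafting
  code both single-congener and MRCA cases.
* **Environments.** Site variables derive from a four-factor loading
  matrix (latitudinal gradient, moisture, soil fertility, elevation), so
  the target correlation matrix is positive semi-definite by
  construction; the configurable r(MAT, MAP) is injected afterwards and
  an eigenvalue-clipping repair guards against infeasible overrides
  (refusing repairs that move entries by more than 0.1). Absolute
  latitudes are uniform on the configured range with a southern
  hemisphere probability of 1/3 capped at 43°S; marginal scales are
  mapped to field units with physical clamps (pH 3.5–8.5, MAP ≥ 150 mm,
  and so on).
* **Traits.** Each trait follows its configured linear model in the
  z-scored environment (optionally with a MAT × MAP interaction), plus
  site-scaled noise and, when requested, a λ-scaled Brownian species
  effect drawn on the tree. The N–P residual correlation is solved at
  generation time so the realized total r(N, P) hits its target given
  the environmental signal actually drawn. N:P is derived as N/P, so
  the tabulated ratio is always consistent with its parts; the flip side
  is that a regression of log N:P on N and P in synthetic data is nearly
  saturated — real ratio measurements carry independent error that the
  generator does not add. Positivity is enforced by reflection at a
  small floor rather than truncation, because truncation ties values
  within a site and degenerates the per-site variance ratios.

What passing tests on these data do **not** show: robustness to real
measurement error structure, to spatially autocorrelated environments,
to trait–environment coevolution, or to backbone trees whose branch
lengths carry calibration uncertainty. The generators are a test harness
for the estimators, not a model of ecology.

## Problem sizes used in verification

The test suite and `scripts/acceptance.R` run: 1,000 fuzzed polytomies
(3–10 children, lengths uniform on (0, 10)) for distance conservation;
200 replicates per λ ∈ {0, 0.5, 1} on 100-tip trees for recovery, with
optimizer-versus-1001-point-grid agreement spot-checked; 1,000 null
replicates for test calibration; 500 replicates (n = 300, 3 sites,
ratios 1:2:4) for variance-ratio recovery and coefficient CI coverage;
dense-oracle REML comparisons at n = 12; and 200 selection replicates
(n = 500, two true effects of 0.5 SD, three nulls, a null interaction).
These sizes keep the whole verification run within a few minutes on one
CPU while leaving the Monte-Carlo margins comfortably inside the
asserted tolerances.

## Known limitations

* The grafting rules are taxonomy-driven; they cannot use molecular
  placement and do not re-estimate branch lengths.
* λ is estimated per trait with an intercept-only mean; no multivariate
  signal, no alternative evolution models (OU, EB), and no phylogenetic
  regression of traits on environment.
* The per-site variance model is a ratio model, not a spatial or
  distance-based covariance; sites are exchangeable given their ratios.
* The latitude smooths substitute variance weights for a true random
  site intercept; their r² and p-values are comparable in scale, not
  identical, to mixed-model output.
* The LMG decomposition is exact but exponential in the number of
  predictors; models with more than 10 predictors are refused rather
  than approximated.
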