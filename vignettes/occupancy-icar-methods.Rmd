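---
title: "Site-occupancy and binomial iCAR models for overlap-based exposure assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-occupancy and binomial iCAR models for overlap-based exposure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Marine spatial planning needs maps of where vulnerable species occur and
where their stressors concentrate. Boat-based cetacean surveys produce
presence records that confound two processes: whether a grid cell's habitat
is actually occupied, and whether an occupied cell's animals were detected
on a given visit (detection falls with sea state and wind, and rises with
repeated effort). Treating raw sightings as habitat truth biases every
downstream map. occuCAR implements the standard remedy — a hierarchical
site-occupancy model — together with an intrinsic CAR (iCAR) spatial random
effect on a regular lattice, a matching Bernoulli/binomial model for vessel
traffic, DIC model selection, repeated-split cross-validation scored by AUC
and the True Skill Statistic, and geographic niche-overlap statistics
(Schoener's D, Warren's I) between species and traffic prediction surfaces.

## The model

Work on a lattice of square cells (4 km cells for a study region of a few
thousand km²). For cell $i$ with standardized habitat covariates $X_i$:

$$z_i \sim \mathrm{Bernoulli}(\pi_i), \qquad
  \mathrm{logit}(\pi_i) = X_i\beta + \rho_i$$

$z_i$ is latent true occupancy. For visit $t$ to cell $i$ with detection
covariates $W_{it}$ (effort = number of visits to the cell, sea state,
wind):

$$y_{it} \sim \mathrm{Bernoulli}(z_i\,\delta_{it}), \qquad
  \mathrm{logit}(\delta_{it}) = W_{it}\gamma$$

A detection proves occupancy; an all-zero history is ambiguous between
unsuitable habitat and missed animals, and the model weighs the two via
$\delta$. The spatial effect $\rho$ has the intrinsic CAR prior: given its
neighbours (queen scheme by default, 8 neighbours for interior cells),

$$\rho_i \mid \rho_{j \in \partial i} \sim
  \mathcal N\!\Big(\tfrac{1}{n_i}\sum_{j\in\partial i}\rho_j,\; V_\rho/n_i\Big)$$

The iCAR density is improper, so each draw is constrained to sum to zero
per connected component. Vessel traffic uses the same structure without the
detection layer: per-cell presence (or successes out of trials) is
Binomial with $\mathrm{logit}(\pi_i) = X_i\beta + \rho_i$.

Priors: Normal(0, 100) on every coefficient; Uniform(0, 10) on $V_\rho$.
The model family's convention fixes the coefficient variance at 100; the
uniform upper bound is rarely stated in applications, so 10 is this
package's documented default (configurable in `model_spec()`). On the logit
scale a spatial variance of 10 already allows essentially deterministic
spatial structure, so the bound is not practically restrictive.

## Inference

`fit_site_occupancy_icar()` and `fit_binomial_icar()` run an adaptive
Metropolis-within-Gibbs sampler written in C++:

* scalar random-walk Metropolis for each $\beta_j$, $\gamma_j$ and each
  $\rho_i$ (the $\rho_i$ target combines the cell's likelihood term with
  the iCAR full-conditional prior above);
* Gibbs draws for latent $z_i$ — fixed at 1 where a detection occurred,
  otherwise $\Pr(z_i{=}1 \mid \cdot) =
  \pi_i\prod_t(1-\delta_{it}) \big/ [\pi_i\prod_t(1-\delta_{it}) + 1-\pi_i]$,
  which reduces to $\pi_i$ for never-visited cells;
* $V_\rho$ by random-walk Metropolis on the log scale (the uniform prior is
  non-conjugate), with proposals outside the prior bounds rejected;
* $\rho$ re-centred to zero mean per connected component every sweep;
  isolated cells keep $\rho_i = 0$.

Proposal scales adapt during burn-in toward the 0.44 per-scalar acceptance
optimum and are frozen afterwards, so the retained chain is a valid
fixed-kernel sampler. Pólya-Gamma augmentation was considered and rejected:
it would add a dependency for a speed-up that desk-scale problems (n ≤
~2,500 cells) do not need. Defaults are 2 chains × 10,000 iterations, 5,000
burn-in, thinning 5; split-chain Gelman–Rubin statistics are reported with
a warning (not an error) above 1.1. All randomness flows through R's RNG,
so a seed fixes every draw exactly.

`compute_dic()` reports DIC = D̄ + pD with pD = D̄ − D(posterior mean).
The occupancy deviance marginalizes $z$ per cell,
$L_i = \pi_i\prod_t \delta_{it}^{y_{it}}(1-\delta_{it})^{1-y_{it}} +
(1-\pi_i)\,\mathbf 1\{\text{all } y_{it}=0\}$, rather than conditioning on
the sampled $z$: the conditional version makes pD depend on the latent
configuration and is unstable under weak detection. The binomial deviance
drops the binomial coefficient, which cancels in all comparisons.

## Prediction, validation, selection, overlap

`predict_surface()` computes per-draw $\pi = \mathrm{logit}^{-1}(X\beta +
\rho)$ and summarizes by the posterior median and central 95% interval —
the median map is the study object compared downstream. Cells outside the
fitted lattice get $\rho = 0$ and the surface is flagged. The median (not
the mean) is the default summary because the mapped product in this model
family is the posterior median surface; a config switch is not offered —
callers can summarize draws themselves.

`enumerate_candidates()` builds all non-empty covariate subsets, plus
pairwise interactions only when both mains are present, and
`select_model()` takes the lowest DIC (ties → fewer terms, then
lexicographic order).

`cross_validate()` implements repeated random 75/25 splits. The survey
literature this package follows describes "10-fold cross validation" with
75%/25% training/test fractions — internally inconsistent with standard
10-fold (which implies 90/10). The quoted fractions are more specific than
the label, so the package does 10 repeated random 75/25 subsampling splits.
Splits are at cell level (visit-level splits would leak the cell's spatial
effect and covariates across folds). What is scored is a second open
choice: latent occupancy is unobservable in real data, so the held-out
target is the observable any-detection indicator, and the score is the
posterior median of $\pi_i\,[1 - \prod_t(1-\delta_{it})]$ over the held-out
cell's planned visits, with $\rho_i = 0$ (a held-out cell's spatial effect
is not identified by the training fold). AUC uses the Mann–Whitney form
with ties counting ½; TSS maximizes sensitivity + specificity over observed
cut-points (classification rule: score ≥ threshold).

`niche_overlap()` normalizes two median surfaces to probability
distributions over the shared cells and reports Schoener's
$D = 1 - \tfrac12\sum_i |p_{Xi} - p_{Yi}|$, the Hellinger distance
$H = \sqrt{\sum_i (\sqrt{p_{Xi}} - \sqrt{p_{Yi}})^2}$ and Warren's
$I = 1 - H^2/2$. Published typesettings of these formulas are frequently
corrupted (inner square roots dropped); the package follows the standard
definitions, which match the widely used `nicheOverlap()` implementation.
Cells missing in either surface are dropped pairwise and counted, never
imputed.

## The synthetic world

Real inputs (survey tracks, scan records, satellite covariates) are
proprietary or behind download services, so the package carries a
first-class generator that emulates exactly the structure the models
assume, on an abstract Cartesian lattice in km:

* **Grid**: default ~340 cells of 4 × 4 km (a ~5,500 km² study region).
* **Covariates**: Gaussian-kernel-smoothed white noise (bandwidth
  `smoothness` cells, default 2), z-scored exactly. Kernel smoothing was
  chosen over spectral Gaussian-random-field methods because it is exact,
  dependency-free and transparent on small grids.
* **Spatial effect**: exact iCAR draws by eigendecomposition of the graph
  Laplacian, sampling only the non-null eigenspace scaled by $V_\rho$
  (O(n³), fine at desk scale). Default $V_\rho = 1$ on the logit scale —
  spatial structure comparable in magnitude to a standardized covariate
  with coefficient 1.
* **Visit plan**: the survey literature reports effort as the number of
  times a cell was visited but not its distribution; the default plan
  draws visits as 1 + NegBin(size 1, mean 1.5) — most cells visited once
  or twice, a few often — and is configurable (tests that need a fixed
  design pass `visits_per_cell = 3`).
* **Detection conditions**: sea state and wind as correlated ordinal 0–4
  covariates sharing a latent calm/rough factor, concentrated at low
  values, as in a summer survey run only in workable weather. Detection
  covariates are z-scored before $\gamma$ applies, so simulated and fitted
  coefficients live on the same scale.
* **Traffic**: distance-to-coast is the distance from each cell centre to
  the nearest domain edge (the "coast" surrounds the rectangle),
  standardized; the default coefficient 0.67 matches the magnitude
  reported for real vessel data at this scale.

What a green test establishes: the estimators recover the parameters of
data generated under the model's own assumptions, at realistic sizes and
effect magnitudes. What it does not establish: robustness to
model misspecification (non-logit link, covariate measurement error,
preferential survey effort), realistic coastline geometry, or any claim
about real hot-spot locations.

Two deliberate consequences of the stated world are worth naming. With a
fixed `visits_per_cell`, effort is constant across cells and its
standardized column is zeroed, so the effort coefficient is not
identifiable in those designs — recovery tests therefore assess the
identified coefficients only. And under "pure-noise" cross-validation, the
null world must make *everything* uninformative (flat detection, fixed
visit plan): a heterogeneous visit plan genuinely predicts the
any-detection label through the observation layer, and an AUC above 0.5
there is signal, not bias.

## Numerical choices and degenerate inputs

* Half-open cell membership `[x, x + s)`; boundary points belong to the
  higher-index cell; points on the upper/right edge of the tiled extent are
  flagged `NA` with a warning, never dropped silently.
* Queen adjacency default (rook available): the common default for lattice
  CAR species-distribution models when the source does not state a scheme.
* Standardization is exact (|mean| < 1e-9, |sd − 1| < 1e-9) and invertible
  via stored center/scale; zero-variance covariates error by name.
* Correlation screening flags |r| ≥ 0.6 but never auto-drops — the
  screening report is for the analyst.
* Likelihood evaluations use a numerically stable log(1 + exp(·));
  per-cell likelihoods are floored at 1e-300 inside DIC.
* Degenerate data error descriptively: all cells detected (saturated
  occupancy), successes > trials, empty candidate lists, one-class
  AUC/TSS inputs (the missing class is named).
* Cross-validation re-draws one-class splits up to 50 times with a logged
  message, then errors.

## Scaling of the test suite

The full-scale properties (100-replicate coverage and DIC ranking) are run
at the prescribed scaled-down size of 20 replicates in
`tests/testthat/test-acceptance.R`, with the matching wider pass bands
(17–20/20 coverage; ≥ 17/20 DIC wins); MCMC budgets inside tests are
shortened (1 chain, 2,000–4,000 iterations) after verifying that posterior
summaries are stable at those budgets for the sizes tested. The
supplementary-database parsing criterion requires the publisher-hosted
supplement, which is unavailable offline; that test states the check and
fails honestly rather than skipping.

## Limitations

Single-season (static) occupancy only; no distance-sampling detection
functions; no abundance/N-mixture models; no spatially blocked CV; no
geographic projections (inputs must be pre-projected); no raster I/O —
surfaces are per-cell CSVs. The iCAR simulator's eigendecomposition and the
dense precision utilities are O(n³) and intended for lattices up to a few
thousand cells.
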