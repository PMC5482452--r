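# occuCAR

Hierarchical Bayesian species-distribution modelling on a regular lattice,
aimed at overlap-based exposure assessment: where do vulnerable species
occur, where does a stressor (here: vessel traffic) concentrate, and how
much do the two maps overlap?

It is written for ecologists and marine-spatial-planning analysts who have
(a) repeat-visit presence/absence survey records with imperfect detection,
(b) per-cell stressor presence records, and (c) gridded environmental
covariates — or who want to study these methods on fully synthetic data,
which the package generates with exactly the statistical structure the
models assume.

## Models

**Site occupancy with an iCAR spatial effect.** For cell *i* on a lattice
of square cells (adjacency: queen scheme by default) and visit *t*:

    z_i   ~ Bernoulli(pi_i),        logit(pi_i)      = X_i beta + rho_i
    y_it  ~ Bernoulli(z_i d_it),    logit(d_it)      = W_it gamma
    rho_i | rho_neighbours ~ Normal(mean(rho_neighbours), V_rho / n_i)

`z_i` is latent true occupancy, `d_it` the per-visit detection probability
(driven by effort = number of visits, sea state, wind), and `rho` an
intrinsic CAR (iCAR) spatial random effect constrained to sum to zero.
Priors: Normal(0, 100) on all coefficients, Uniform(0, 10) on `V_rho`.

**Binomial iCAR** for stressor presence: the same ecological layer without
the detection process (`s_i ~ Binomial(t_i, pi_i)`).

Inference is adaptive Metropolis-within-Gibbs MCMC (C++ core), with DIC
model selection over all covariate subsets (+ hierarchical pairwise
interactions), repeated 75/25 cross-validation scored by AUC and the True
Skill Statistic, posterior-median prediction surfaces, and niche-overlap
statistics between surfaces: Schoener's `D = 1 - 0.5 * sum|pX - pY|` and
Warren's `I = 1 - H^2/2` with `H` the Hellinger distance.

See `vignettes/occupancy-icar-methods.Rmd` for the full methods account.

## Worked example

```r
library(occuCAR)

## a ~5,500 km^2 study region at 4 x 4 km resolution
grid <- build_grid(c(0, 0, 80, 68), cell_size = 4)
grid
#> lattice_grid: 17 x 20 cells (n = 340), cell size 4, queen adjacency, 1251 edges

## synthetic survey: 2 habitat covariates, spatial effect, imperfect detection
sim <- simulate_occupancy_dataset(grid, beta = c(-1.2, 1.3, 0.8),
                                  gamma = c(0.4, 0.15, -0.25, -0.35),
                                  V_rho = 1, seed = 42)

spec <- model_spec(ecological = c("x1", "x2"),
                   detection = c("effort", "sea_state", "wind"))
fit <- fit_site_occupancy_icar(sim$data, spec,
         mcmc = mcmc_config(n_chains = 2, n_iter = 6000, burnin = 3000,
                            thin = 3, seed = 1))
fit
#> posterior_samples (siteocc): 2000 draws, 340 cells
#> beta posterior means:
#> (Intercept)          x1          x2
#>      -1.106       1.641       0.946
#> gamma posterior means:
#> (Intercept)      effort   sea_state        wind
#>       0.590       0.081       0.018      -0.628
```

The ecological coefficients (true values −1.2, 1.3, 0.8) are recovered;
detection covariates are weakly identified at ~61 detections, as expected.

```r
dic <- compute_dic(fit)
#> DIC = 616.7 (Dbar = 588.9, pD = 27.9)

surf <- predict_surface(fit)   # per-cell posterior median + 95% interval
head(as.data.frame(surf), 3)
#>   cell_id prob_median     prob_lo   prob_hi
#> 1       1   0.1019935 0.007662671 0.5368781
#> 2       2   0.1048597 0.013811382 0.4714234
#> 3       3   0.1550247 0.022556350 0.5309830

## vessel traffic: Bernoulli iCAR driven by distance to coast
tr <- simulate_traffic_dataset(grid, beta = c(0, 0.67), V_rho = 0.5, seed = 7)
tfit <- fit_binomial_icar(tr$X[, -1, drop = FALSE], tr$data$trials,
                          tr$data$presence, grid,
                          model_spec(ecological = "dist_coast"),
                          mcmc = mcmc_config(n_chains = 2, n_iter = 6000,
                                             burnin = 3000, thin = 3, seed = 2))
#> traffic dist_coast: median 0.75, 95% CrI [0.45, 1.18]   (truth 0.67)

## how much do the species and traffic surfaces overlap?
niche_overlap(surf, predict_surface(tfit))
#> overlap_result: D = 0.605, I = 0.880 (H = 0.490) over 340 cells
```

`D` and `I` run from 0 (disjoint) to 1 (identical distributions over
cells); here the species and traffic maps share a substantial fraction of
their probability mass, the quantity used to flag exposure risk.

Model selection and validation:

```r
cands <- enumerate_candidates(c("x1", "x2"), detection = spec$detection)
fits  <- lapply(cands, function(s) {
  f <- fit_site_occupancy_icar(sim$data, s, mcmc_config(n_chains = 1, seed = 3))
  list(spec = s, dic = compute_dic(f)$DIC)
})
best <- select_model(fits)

cv <- cross_validate(sim$data, best$spec, repeats = 10, seed = 4)
```

## Pipeline and CLI

The whole analysis — simulate, fit per species, fit traffic, predict,
overlap, manifest with checksums — runs from one JSON config:

```r
run_pipeline("config.json")   # or a list; see ?validate_config
```

or from the shell: `Rscript -e 'occuCAR::occucar_cli()' run config.json`
(also `simulate <dir> [seed]` and `overlap <a.csv> <b.csv>`). Reruns with
the same config are byte-identical; every stage derives its own seed from
the master seed.

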