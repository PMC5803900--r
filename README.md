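# elevrich

Where do threatened species sit on a mountain elevational gradient, and
why? `elevrich` is an R package plus analysis workflow for answering that
question with band-based macroecology: it bins species' elevational ranges
onto a 0–4900 m gradient of 49 × 100 m bands, interpolates per-band
richness, probes undersampling with a deterministic range-augmentation
sensitivity analysis, builds a Monte Carlo mid-domain-effect (MDE) null
model, and fits spatially correlated regressions of richness on geometry
and human pressure. It is aimed at biodiversity researchers who need each
of those stages as tested, reusable functions rather than spreadsheet
steps.

## The methods in brief

* **Interpolated richness.** A species recorded between `l` and `u` meters
  is snapped outward to band edges (floor the lower, ceil the upper) and
  assumed present in every 100 m band in between. Richness of band `b` is
  the number of species whose binned range covers it.
* **Range augmentation.** Species are classified by range size
  (a < 1300 m ≤ b ≤ 2550 m < c) and widened by scenario percentages of the
  5000 m gradient — (20, 10, 0)%, (30, 20, 10)%, (50, 25, 10)% — split
  equally across both limits and clamped to 67–4900 m. Augmented and
  empirical richness patterns are compared by Bonferroni-corrected Pearson
  correlations.
* **MDE null model.** Each of 5000 Monte Carlo simulations re-places the
  empirical range sizes (without replacement) at midpoints drawn uniformly
  over their feasible positions between the hard boundaries, yielding the
  expected richness curve `E[S(b)]` and a 95% envelope under geometric
  constraints alone.
* **Inference.** VIF screening (`1/(1-R²)`, flag > 10); GLS of
  log richness with residual correlation `exp(-(d/ρ)²)` (corGaus; also
  exponential/spherical/none) selected by AIC, with likelihood-ratio
  chi-square term tests; quasi-Poisson sequential analysis of deviance
  (F tests, Pearson dispersion) ordered area → null model → elevation
  first; cubic polynomial fit of partial residuals against elevation;
  fixed-df natural-spline smooths for display.
* **Synthetic communities.** A generator with known ground truth (lognormal
  range sizes, low-elevation-biased midpoints, exponentially decaying area
  and human density, logistic threat assignment driven by small range ×
  high density) makes every stage testable end to end without any data
  download.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
community (run them in order from the repository root; stage 1 writes the
fixture the others read):

```sh
Rscript analysis/01_simulate_community.R
Rscript analysis/02_band_richness.R
Rscript analysis/04_mde_null_model.R
```

which prints, for the default seeds:

```
simulated community: 74 threatened species
richness: peak 38 species at 1100 m; 5 of 49 bands empty
richness-elevation Spearman rho: -0.79
null richness: peak 20.9 at 2700 m (empirical peak at 1100 m)
```

Read: the simulated threatened fauna is concentrated at low elevations
(richness peaks at the 1100 m band and declines with elevation, Spearman
ρ = −0.79), while the geometric null expects a mid-domain peak near
2700 m — the empirical pattern is not explained by boundary geometry
alone. Stage 3 prints the augmentation correlations (empirical vs S1
r = 0.97 here) and stage 5 the VIF table, AIC ranking of correlation
structures, likelihood-ratio term tests and the sequential analysis of
deviance, writing all tables under `results/`.

The same pipeline is available in code via `run_report()`:

```r
library(elevrich)
com <- generate_community(community_params(seed = 1))
rep <- run_report(com$species, com$truth$covariates, n_sims = 1000, seed = 1)
```

## Layout

```
R/                  package code: grid, io, gridding, augmentation,
                    mde_null, stats, synthetic generator, pipeline
analysis/           numbered narrative drivers (simulate → fit)
scripts/acceptance.R  reference-quantity reproduction
tests/testthat/     unit, property and end-to-end tests (incl. oracles)
vignettes/          methods vignette
```
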