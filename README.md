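# geofav

Favourability-based species distribution modelling with a geographic
trend-surface predictor.

## The problem

Large-scale species distribution models (SDMs) built from gridded
presence/absence atlas data usually regress occurrence on climate alone, yet
species ranges are also shaped by land use, topography and pure spatial
structure (dispersal limits, history, site fidelity) that no environmental
layer carries. Ignoring that spatial structure can both misattribute
explained variation to climate and produce implausible range forecasts under
climate change. `geofav` implements a complete workflow for comparing a
*space-included* model (environmental predictors plus a geographic
trend-surface covariate) against a *space-excluded* model (environment
only), on current data and under future climate scenarios.

It is aimed at ecologists and biogeographers working with flat per-cell
tables (one row per grid cell: centroid coordinates, binary presence, named
covariates grouped into predictor sets).

## The model

For each species the workflow is:

1. **Trend surface.** The nine monomials of the standardised cell-centroid
   coordinates — X, Y, X², Y², X³, Y³, XY, X²Y, XY² — enter a backward
   stepwise logistic regression on presence; the logit of the resulting
   model is a single covariate, `Geog`, summarising pure spatial structure.
2. **Screening.** Within each predictor set (climate with quadratic terms,
   land use, topography, geographic), each variable is tested univariately
   against the intercept-only model and kept only if significant under a
   Benjamini–Hochberg false discovery rate of q < 0.05.
3. **Predictor-set and combined models.** Forward–backward stepwise logistic
   regression (likelihood-ratio tests; defaults p_enter = 0.05,
   p_remove = 0.10) is run within each set, then on the pooled survivors —
   twice: with and without `Geog` among the candidates. Models are trained
   on a 70 % random sample and evaluated on the remaining 30 %.
4. **Favourability.** Model probabilities P are converted to favourability

   F = [P/(1−P)] / [n₁/n₀ + P/(1−P)],

   with n₁ presences and n₀ absences; F = 0.5 marks conditions exactly as
   good as the species' average regardless of prevalence, so F is the
   classification threshold and is comparable across species.
5. **Evaluation and partitioning.** Sensitivity, specificity, CCR (at
   F ≥ 0.5), AUC, Nagelkerke R² and AIC per model; the explained variation
   is decomposed by inclusion–exclusion into pure and shared fractions of
   the predictor sets (shared fractions may be negative — suppression).
6. **Projection.** Future scenarios replace climatic values only (quadratic
   terms recomputed from their shifted parents); land use, topography and
   `Geog` stay fixed, and favourability is recomputed with unchanged
   coefficients.

All logistic machinery (IRLS, LR tests, stepwise selection, BH step-up, VIF,
Nagelkerke R², Mann–Whitney AUC) is implemented in the package and
cross-checked in the tests against independent references.

A seeded synthetic-landscape generator (`simulate_landscape()`,
`gen_spatial_field()`, `gen_occurrences()`, `gen_future_scenario()`)
produces spatially autocorrelated covariates and a logistic occurrence
process with a controllable pure spatial term, so the entire workflow is
testable without any data download.

## Worked example

```r
library(geofav)

land <- simulate_landscape(nx = 30, ny = 30, seed = 7, spatial_coefficient = 2)
sc   <- gen_future_scenario(land$data, c(Pannual = -0.5, Tapr_jul = 1),
                            names(land$sets)[land$sets == "climate"],
                            label = "2080")
run  <- run_favourability_pipeline(land$data, land$sets,
                                   scenarios = list(sc), split_seed = 3)
print(run)
#> Favourability modelling run: 900 cells, 45 presences
#> space_included: 3 term(s); DE 0.420  AUC 0.884  sens 0.889  spec 0.812  CCR 0.815  AIC 182.3
#> space_excluded: 3 term(s); DE 0.290  AUC 0.774  sens 0.444  spec 0.805  CCR 0.793  AIC 215.5

run$partition$space_included
#>                            sets n_sets  fraction     pct
#> 1                       climate      1  0.068157 16.2161
#> 2                    geographic      1  0.207817 49.4442
#> 3                    topography      1  0.016214  3.8576
#> 4            climate+geographic      2  0.055362 13.1718
#> 5            climate+topography      2 -0.000251 -0.0597
#> 6         geographic+topography      2  0.086864 20.6668
#> 7 climate+geographic+topography      3 -0.013857 -3.2969
```

The landscape was generated with a strong pure spatial (latitudinal) term,
and the run shows the expected pattern: the space-included model retains
`Geog` plus two environmental terms, explains more deviance (0.42 vs 0.29),
discriminates better on the held-out cells (AUC 0.884 vs 0.774) and is more
parsimonious (lower AIC); half of its explained variation is attributable
purely to the geographic predictor. Projected onto the 2080 scenario, the
space-included favourability map stays almost identical to the current one
(r = 0.994) — the geographic anchor constrains forecasts — while the
space-excluded map follows the shifted climate.

A command-line front end wrapping the same functions is installed at
`system.file("cli/geofav", package = "geofav")` with subcommands
`simulate`, `fit` and `project`, driven by a YAML config (see
`?geofav_cli`).

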