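---
title: "Favourability modelling with a trend-surface geographic predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Favourability modelling with a trend-surface geographic predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geofav)
```

## The modelling problem

`geofav` models binary species occurrence on a regular grid of cells, each
described by a centroid coordinate and named covariates grouped into
predictor sets (climate, land use, topography, geographic). The scientific
question it is built around: how much of a species' range is explained by
environment, how much by pure spatial structure, and how differently do the
two kinds of model behave when projected onto future climate?

Two combined models are fitted per species. The *space-included* model may
select a geographic trend-surface covariate alongside environmental terms;
the *space-excluded* model sees only environmental candidates. Both are
evaluated on a held-out sample and projected onto climate scenarios, and
their explained variation is decomposed across predictor sets.

## The favourability transformation

A logistic model's probability P depends on species prevalence: for a rare
species even highly suitable cells get small P. Favourability rescales P by
the prevalence odds,

$$F = \frac{P/(1-P)}{n_1/n_0 + P/(1-P)},$$

with $n_1$ presences and $n_0$ absences in the modelling data. Equivalently
$F = \mathrm{logit}^{-1}(\mathrm{logit}(P) - \ln(n_1/n_0))$ — the form the
package computes, because subtracting the constant on the logit scale is
numerically stable where the odds quotient overflows near $P \in \{0,1\}$;
the limits $F(0)=0$ and $F(1)=1$ are returned exactly. Key consequences,
each enforced by a test:

* $P$ equal to the prevalence $n_1/(n_1+n_0)$ gives exactly $F = 0.5$, the
  *neutral* value used as the classification threshold;
* with balanced classes ($n_1 = n_0$), $F \equiv P$;
* $F$ is strictly increasing in $P$, so AUC computed on favourability equals
  AUC computed on probability;
* the transformation is exactly invertible
  (`probability_from_favourability()`), round-tripping to $10^{-12}$.

The $(n_1, n_0)$ used are those of the model-fitting data: the training
split during evaluation, the full dataset for final maps.

## The logistic engine

All model fitting goes through one engine, `fit_logistic()`: maximum
likelihood by iteratively reweighted least squares, convergence when the
largest coefficient update falls below $10^{-8}$ (at most 50 iterations),
rank-deficient designs rejected with the aliased columns named, and
separation reported as a flag (coefficient magnitude above 15 while the
likelihood is still improving or the fit has not settled) rather than an
error, because univariate screening legitimately meets quasi-separated
columns. Tests pin the engine to `stats::glm` and to direct Nelder–Mead
likelihood maximisation on small instances.

Significance decisions everywhere use likelihood-ratio tests. Commercial
stepwise implementations often default to score or Wald tests for entry and
removal; the LR test is the more accurate of the family and using it for
both directions keeps entry and removal decisions mutually consistent. This
is a deliberate, documented divergence from the score/Wald convention.
Default thresholds are p_enter = 0.05 and p_remove = 0.10 (entry stricter
than removal, which also prevents cycling); both are configurable.

Forward–backward selection: each cycle adds the candidate with the smallest
LR p-value if below p_enter (ties broken by larger deviance reduction, then
by declared candidate order — deterministic), then drops the included term
with the largest removal p-value if above p_remove. Candidates whose
addition makes the design rank-deficient are skipped, so duplicated columns
enter at most once. The order of entry is recorded: early entrants describe
broad-scale structure, late entrants fine-scale adjustment. No
marginality constraint ties quadratic terms to their linear parents —
quadratic columns compete as free candidates, which matches how such models
are reported in this literature.

## The trend-surface geographic predictor

`build_basis()` standardises each coordinate (centre, scale by standard
deviation) before forming the nine monomials X, Y, X², Y², X³, Y³, XY, X²Y,
XY². Standardising first is a numerical choice: raw cubed longitudes reach
magnitudes that make the information matrix badly conditioned. The scaling
constants are stored so the basis — and hence the `Geog` values — are exactly
reproducible on the original or new cells.

`fit_geog()` is backward-only (no re-entry), starting from all nine terms
and repeatedly dropping the term with the largest LR p-value above p_remove
(default 0.10). The per-cell logit of the surviving model is the `Geog`
covariate. If everything is eliminated the variable is a constant and a
warning is raised.

By default `Geog` is fitted on the full dataset before the train/test split
and then treated as a fixed covariate — the trend surface is a
data-preparation step, computed once per species. This choice leaks
information from validation cells into one covariate; a `split-safe` mode
(`geog_mode = "split-safe"`) fits the surface on training cells only and
projects it onto the rest, for users who want strictly honest held-out
metrics. Under future scenarios `Geog` is always held at its current values:
coordinates do not change over time, which is exactly the "artificial
anchor" the space-included/space-excluded comparison is designed to expose.

## Screening, splitting, evaluation

Within each predictor set, variables are screened by the univariate LR
p-value against the intercept-only model, with the Benjamini–Hochberg
step-up applied within the set at q = 0.05. Univariate screening is the
standard reading of per-set FDR control and keeps the screen independent of
selection order.

The train/test split is a uniform 70/30 draw (sizes ⌊0.7n⌋ and the rest),
redrawn up to 100 times until both parts contain both classes; a stratified
option draws within class instead. Discrimination metrics on the test cells
use favourability at the neutral threshold (score ≥ 0.5 predicts presence —
the boundary is inclusive, stated bit-exactly because CCR at the neutral
threshold is a headline metric); AUC uses the Mann–Whitney formulation with
ties counted ½. Deviance explained (Nagelkerke R²) and AIC describe the
training fit; whether such tables are computed on training or all data is
rarely stated in applied papers, and training is the assumption made here.

## Variation partitioning

For the predictor sets represented in a combined model, every non-empty
subset S is refitted with exactly the combined model's terms belonging to S
— fixed variable lists, no reselection — giving Nagelkerke R²(S). Writing
u(S) for the variation lost when the sets in S are removed from the full
model, Möbius inversion of u over subsets yields one exclusive fraction per
subset: pure effects for singletons, shared effects for larger subsets. By
construction the fractions sum exactly (to $10^{-10}$, enforced every run)
to the full model's R². Nagelkerke R² is the "variation" currency for
consistency with the deviance-explained metric; shared fractions can be
negative and are reported as-is — a negative joint effect means two sets
act suppressively, not additively. `Geog` participates as its own
(geographic) set.

## Future projection

A scenario supplies replacement values for climatic columns only. Quadratic
columns (naming convention `<name>^2`) are recomputed as the square of their
shifted parent — shifting a square independently of its parent would be
physically incoherent — and the projection refuses to run if any climatic
term of the model lacks a replacement, naming the missing column. All other
terms keep their current values, and probabilities and favourability are
recomputed with the fitted coefficients unchanged.

## The synthetic-landscape generator

`simulate_landscape()` emulates the statistical structure the analysis
assumes, not any real geography:

* **Covariates** are white noise smoothed with a uniform kernel over a
  radius of 5 cell widths (then rescaled to unit variance). Kernel-smoothed
  noise is O(n·k) per field and produces the positive spatial
  autocorrelation (first-order Moran's I well above 0.3 at the default
  radius) that makes a trend surface informative; it does not reproduce the
  anisotropies or long-range gradients of real climate layers.
* **Occurrence** is Bernoulli with a logistic linear predictor combining
  environmental slopes and, optionally, a pure standardised-latitude term —
  the same family the pipeline fits, so parameter recovery is
  well-defined. The intercept is calibrated by bisection (tolerance 0.005
  on the mean probability, at most 100 iterations) so prevalence is
  controllable; the default 0.055 is the rare-species regime in which
  favourability's prevalence correction matters most, matching a
  continental atlas species with ~250 presences among ~4500 cells.
* **Scenarios** are additive shifts on climatic covariates, optionally with
  a south-to-north gradient multiplier.

Everything is seeded and byte-reproducible. Because the generating model is
a member of the fitted family, passing tests demonstrate correctness of the
machinery and the qualitative space-included/space-excluded contrast; they
do not demonstrate robustness to the misspecification, observation error and
spatially structured sampling effort of real atlas data.

## Problem sizes and numerical choices

The test suite exercises: parameter recovery at n = 2000 over 200
replicates; the space-included vs space-excluded contrast on 40 × 40 grids
(1600 cells) over 50 seeded replicates, with projection anchoring checked on
10; null-screening FDR control over 200 replicates. These sizes give stable
Monte-Carlo estimates at desk scale. Other defaults: probability clamping at
$10^{-15}$ inside log-likelihoods; IRLS weights floored at $10^{-10}$;
classification bands for presentation maps at 0.2/0.8 (the customary
favourability cuts, configurable because published maps rarely state
theirs).

## Known limitations

* The trend surface is the only spatial device: no Moran eigenvector maps,
  autocovariate models or spatially explicit random effects.
* Grids are abstract planar lattices; no raster I/O or great-circle
  geometry.
* The stepwise-plus-LR machinery is faithful to the workflow it implements;
  it inherits the known instabilities of stepwise selection under strong
  collinearity (mitigated, not removed, by the FDR screen and VIF report).
* One species, one scenario table per run; ensembles are outer loops left
  to the caller.
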