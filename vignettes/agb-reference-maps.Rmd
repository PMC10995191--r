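---
title: "Building reference AGB maps with propagated uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building reference AGB maps with propagated uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(agbref)
```

## The problem

Landscape-scale reference maps of tropical-forest aboveground biomass (AGB)
are built by calibrating airborne-LiDAR canopy height models (CHMs) against
co-located forest inventory plots. Because plot AGB is itself a model output
— assembled from tree diameters, partially measured heights, taxonomically
attributed wood density and a pantropical allometry — an honest map must
propagate uncertainty through *two* modelling levels:

1. **tree → plot**: Monte Carlo propagation of measurement and model errors
   to plot-level AGB, whose mean is the plot's reference value (AGB_REF);
2. **plot → landscape**: a log-log regression of AGB_REF on the mean
   top-of-canopy height (meanTCH) of the plot footprint, refit once per
   first-level realization and applied to the meanTCH raster with parameter
   and residual noise.

The map product is a three-layer GeoTIFF: per-pixel mean AGB, the SD over
the Monte Carlo realizations, and a bin number supporting compact
publication of pairwise pixel covariances.

## Level 1: tree to plot

Plots are first split into 100 m (1 ha) or 40 m (0.16 ha) subplots, tiled
from the plot edges; when a dimension is not a multiple of the target the
residual central band is excluded together with its trees, mirroring field
protocols where stem positions are known only to 20-m quadrat resolution
(quadrat-indexed inventories are placed at quadrat centroids).

Tree height follows the second-order log-log height–diameter (H-D) model

$$\ln H = a + b \ln D + c (\ln D)^2 + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma),$$

fit by OLS on height-measured trees; natural-scale predictions carry the
Baskerville correction $\exp(\sigma^2/2)$. We use $(\ln D)^2$ for the
quadratic term: the alternative reading $\ln(D^2) = 2\ln D$ would be
collinear with the linear term and cannot be a second-order model.

Tree AGB uses the pantropical allometry
$AGB = 0.0673\,(\mathrm{WD}\,D^2 H)^{0.976}$ (kg; WD in g cm⁻³, D in cm, H
in m). Wood density is attributed at the finest matching taxonomic level —
species, then genus mean, then family mean, then the plot mean of assigned
trees — and clipped to the physical range 0.08–1.39 g cm⁻³.

`plot_agb_mc()` draws, per simulation: diameters from a two-component
measurement-error mixture (95% small errors with SD $0.0062D + 0.0904$ cm,
5% gross errors with SD 2.54 cm, truncated at 0.1 cm); wood density from a
truncated normal around the attributed value; H-D coefficients from their
estimated covariance plus a per-tree lognormal residual (measured heights
are instead perturbed with a 5% CV — the field protocol for selecting and
re-measuring heights is not standardised, so this is a config default, not
a claim); and allometry parameters $(\ln c_0, e)$ from a configurable
covariance plus a per-tree log residual of SD 0.357.

**Allometry-parameter covariance.** Published allometry posteriors are not
printed as covariance matrices, and a naive diagonal choice misbehaves: an
independent SD of just 0.04 on the exponent contributes
$0.04 \times \ln(\mathrm{WD}D^2H) \approx 35\%$ CV to every tree
simultaneously, far outside the plot-level uncertainty magnitudes this
workflow is meant to reproduce (8–25% at plot scale). Real regression
posteriors have strongly anti-correlated intercept and slope, with minimal
prediction uncertainty at the calibration centroid. We therefore
parameterise the default covariance through a pivot: the log prediction has
SD 0.08 at $x = \ln(\mathrm{WD}D^2H) = 9.3$ (a mid-sized tropical tree) and
the exponent has SD 0.01, giving
$\mathrm{Var}(\ln c_0) = 0.08^2 + 9.3^2\times 0.01^2$ and
$\mathrm{Cov} = -9.3 \times 0.01^2$ (`allometry_coef_vcov()`). The 0.08
pivot SD matches the plot-level systematic allometry error in published
tropical error budgets. All constants are exposed in
`allometry_config()`.

With the defaults, first-level plot CVs land at roughly 8–10% for 1-ha and
9–17% for 0.16-ha subplots on the synthetic sites — the magnitudes, not any
specific reference posterior, are the contract, and every term can be
switched off (`allometry_config_exact()`), in which case the simulation
collapses exactly to the deterministic tree sum.

## Canopy metrics

`compute_metrics()` evaluates the 15 standard CHM metrics per window:
height percentiles H40–H98 (linear interpolation between order statistics,
the common default in both R and Python raster stacks; configurable),
meanTCH, sdH, CV = sdH/meanTCH (reported as no-data when meanTCH is 0, and
note that CV is the ratio in this orientation — the reverse reading that
sometimes appears in metric tables is a typo), the quadratic mean height,
canopy cover fractions CCF2/5/10, and the rumple index. Choices that matter
at edges:

* **CCF strict inequality** (`h > x`): a perfectly flat 10-m canopy has
  CCF10 = 0, not 100. "Above x m" is read strictly.
* **Rumple** triangulates each 1-m cell into two triangles from
  corner-interpolated heights (corner = mean of adjacent valid cells,
  one-sided at boundaries); a flat window gives exactly 1. Exact
  triangulations differ slightly at window edges between implementations,
  so comparisons should be tolerance-based.
* **Pixel membership** is by cell centre with half-open intervals, so
  adjacent subplots never share a cell and footprint metrics agree exactly
  with the matching `grid_metrics()` cell.
* `grid_metrics()` drops partial edge cells and masks output pixels whose
  valid-cell fraction falls below `min_valid_frac` (default 0.9; no
  published threshold exists, so this is our lever and is recorded in the
  output metadata).

## Model form selection and mapping models

`screen_lmm()` fits, for each candidate metric (or each of the 105
unordered pairs), the linear mixed-effects model

$$\ln AGB_{REF} = a + b\,\ln LCM + RE_{site} + \varepsilon$$

by **maximum likelihood** — REML likelihoods are not comparable across
fixed-effect structures, and AIC ranking is the point of the screen.
Goodness of fit is reported on back-transformed predictions
$\exp(\hat y + \sigma^2/2)$: since the screened plots belong to training
sites, predictions condition on the site intercept and only the residual
variance enters the correction. RMSE% uses the pooled observed mean as
denominator (a site-wise denominator is equally defensible; pooled is
simpler and documented). Exactly collinear pairs are flagged by a
condition-number cap rather than failing the screen.

Mapping models are plain OLS of $\ln AGB_{REF}$ on $\ln meanTCH$ per model
scope. Scope follows the 10-ha rule (`assign_scope()`): sites with at least
10 ha of cumulated inventory get their own model; smaller sites must join a
configured regional pool — pooling is config, not hard-coded geography, and
the same grouping governs H-D model pooling. Each model records its
training meanTCH range: that range *is* the calibration domain used by the
extrapolation accounting.

## Level 2: plot to landscape

`build_ensemble()` refits the mapping model once per first-level
realization, then draws parameters per fit. The target distribution — the
flat-prior posterior of a normal linear model — is normal-inverse-gamma and
can be sampled exactly:
$\sigma^{*2} \sim (n-2)s^2/\chi^2_{n-2}$,
$(a^*,b^*) \sim N(\hat\beta, \sigma^{*2}(X'X)^{-1})$. We sample it directly
instead of running a Metropolis chain: same distribution, no tuning, no
convergence diagnostics; a random-walk Metropolis sampler over the same
posterior remains available (`sampler = "metropolis"`) for fidelity
comparisons.

`predict_map()` then, per ensemble member, picks one parameter set at
random, predicts all pixels on the log scale, adds residual noise and
back-transforms. Two readings of the residual step are possible — one
shared draw per map pass, or an independent draw per pixel. We draw **per
pixel**: the shared-parameter pathway already carries spatially coherent
error, and an additional map-wide shift would make pixel SDs conflate two
very different error geometries; the alternative remains a documented open
reading. The residual is added on the log scale, as the model is log-log.
Pixel means therefore inherit the lognormal mean $\exp(\mu + s^2/2)$ rather
than $\exp(\mu)$ — a property, not a bug, checked analytically in the
tests. Pixels with meanTCH below the vegetation threshold (default 2 m,
per-site overridable down to 0.4 m for savanna mosaics) are no-data.

`n_sim` defaults to 1000 at both levels. The draw stack can be retained
(`keep_stack = TRUE`) or replaced by a streaming mean/SD accumulation when
memory matters; the covariance metadata needs the stack.

## Validation

**Buffered LOO-CV** (`buffered_loocv()`): for each test subplot, every
subplot whose *polygon* intersects the open disc of radius 100 m around the
test subplot's centre is excluded from training — polygon-based because the
plots are areal units, and this automatically removes sibling 0.16-ha
subplots of a shared 1-ha parent. Buffer 0 reduces exactly to classical
LOO. Folds whose buffer starves the training set below 5 plots are skipped
and counted. R² is reported as $1 - SS_{res}/SS_{tot}$ on back-transformed
values and may be negative (the squared-correlation convention is the other
candidate; ours is stated in the output). For regional models, exclusion
geometry operates within each site; sites are far apart so cross-site
buffers never bind.

**Extrapolation accounting** (`extrapolation_mask()`) classifies vegetated
pixels below/within/above the model's training meanTCH range; proportions
are over vegetated pixels only, and the classification raster partitions
them exactly.

## Covariance metadata

`assign_bins()` ranks valid pixels by mean AGB into equal-frequency bins
(default 25 — the binning recipe in the literature does not fix a count, so
it is config), ties broken by pixel scan order (column-major linear index;
stable, hence reproducible). `binned_covariance()` exploits bilinearity:
the covariance of two bin means across simulations *equals* the average of
all pairwise pixel covariances between the bins, so no $n^2$ pixel matrix
is ever formed. Within-bin entries exclude the $p = q$ self-pairs, with the
averaged pixel variance reported separately, so `subregion_uncertainty()`
can recombine

$$\mathrm{Var}(\overline{AGB}) = \frac{1}{n^2}\Big[\sum_p
\overline{var}(b_p) + \sum_{p \neq q} \overline{cov}(b_p, b_q)\Big]$$

without double counting. With one bin per pixel this reproduces the exact
Monte Carlo SE to machine precision; note that over the *full* map the
binned estimator is exact for any bin count (counts times bin averages
recover the exact sums), so binning accuracy is only informative on strict
subregions — on 500-pixel stacks with realistic shared-error structure, a
25-bin summary reproduces subregion SEs within a few percent.

## The synthetic-site generator

`gen_site()` exists so that every stage can be tested against known truth
without external downloads. It emulates:

* multi-site inventories with site-specific H-D laws, truncated-Weibull
  diameters (support within 10–250 cm), Poisson stem counts around 450
  stems ha⁻¹, a 15% height-measurement fraction, and a small wood-density
  taxon pool;
* per-plot lognormal stem-density multipliers (SD 0.4 log units) that
  spread plot AGB over roughly a factor of five, matching the AGB ranges
  reference sites exhibit;
* a 1-m CHM stamped from paraboloid crowns (apex at tree height, radius
  $0.5\,D^{0.6}$ m) plus Poisson background trees outside the plots and
  Gaussian cell noise clipped at zero.

The crown model is a simulation device, not science: any shape works
provided plot meanTCH stays monotone in stand height, which is tested. The
key construction is the **calibration step**: each plot window of the
stamped canopy is rescaled so that its meanTCH follows the inverse of the
site's generative law
$\ln AGB = \alpha + \beta \ln meanTCH + RE_{site} + N(0, rse)$ evaluated at
the plot's deterministic tree-sum AGB. Tree-level AGB thus stays exactly
consistent with the inventory while the CHM carries the known log-log
relation; regressions of AGB_REF on meanTCH recover $\beta$ within
sampling error (the inverse construction attenuates the slope by
$\beta\,rse^2/\mathrm{Var}(\ln AGB)$, under 5% at the default settings).
Because plot windows are rescaled, peak canopy heights inside plots can
exceed what the stamped trees alone would give; metrics remain internally
consistent.

Plots are laid out on a deterministic grid with a configurable gap
(default 100 m, so distributed plots sit outside one another's
cross-validation buffers, as real scattered 1-ha plots do). One master
integer seed fans out to per-stage child seeds through a documented hash
(`child_seed()`), so stages can be re-run independently and whole pipeline
runs are bit-reproducible.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: terrain (the ground is flat zero), temporal
offsets between LiDAR and field campaigns (real acquisitions differ by
years, uncorrected), point-cloud artefacts (we synthesise the CHM surface
directly), taxonomic misidentification, and spatial autocorrelation of AGB
beyond what shared mapping-law errors induce.

## Raster I/O

Map products are written as uncompressed little-endian GeoTIFFs with one
page per layer (meanAGB and sdAGB as float32 with no-data −9999, Nbin as
int16 with no-data 0), carrying ModelPixelScale/ModelTiepoint tags, a
minimal projected-CRS GeoKeyDirectory and a GDAL-style no-data tag; layer
names ride in the PageName tag. The codec is deliberately narrow — exactly
this profile, written and read back losslessly (float32 payloads round-trip
bit-for-bit) — and the files are readable by standard TIFF tooling.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
sites: two sites of 10 and 6 one-hectare plots on 35 ha and 21 ha
landscapes for end-to-end runs at `n_sim = 1000`, 2000-tree samples for H-D
recovery, 20-seed batteries for recovery/screening/coverage experiments,
and 500-pixel stacks for covariance checks. These sizes were chosen to
exercise every code path at full simulation depth while staying desk-scale;
all of them complete in well under a minute each on one core. Every random
quantity flows from explicit seeds; re-running any stage with the same
configuration yields byte-identical outputs.

## Known limitations

* The allometry-parameter covariance is a calibrated stand-in, not a
  published posterior; users with access to a real posterior should pass it
  via `allometry_config(coef_vcov = ...)`.
* Mapping models are strictly log-log in meanTCH; no heteroscedastic or
  nonlinear variants.
* No mosaicking across sites, no temporal adjustment, no point-cloud
  processing (CHMs are expected as inputs; only a max-per-cell rasteriser
  for synthetic point sets is included).
* The GeoTIFF codec does not read compressed or tiled files.
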