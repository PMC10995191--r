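# agbref

Reference aboveground-biomass (AGB) maps with per-pixel uncertainty, built
from co-located forest inventory plots and 1-m LiDAR canopy height models
(CHMs).

Calibration and validation of spaceborne biomass missions (GEDI, BIOMASS,
NISAR) needs landscape-scale reference AGB maps whose uncertainty is
honestly propagated — plot AGB is itself a model output, assembled from
tree diameters, partially measured heights, taxonomically attributed wood
density and a pantropical allometry. `agbref` implements the full two-level
Monte Carlo workflow that turns inventories and CHMs into such maps, for
forest scientists and remote-sensing groups producing or consuming
reference biomass products.

## The model

**Level 1 — tree to plot.** Tree height follows the second-order log-log
height–diameter model

    ln(H) = a + b·ln(D) + c·(ln D)² + ε,   ε ~ N(0, σ)

(Baskerville correction exp(σ²/2) on back-transformation), tree AGB the
pantropical allometry

    AGB [kg] = 0.0673 · (WD · D² · H)^0.976,

and `plot_agb_mc()` propagates diameter measurement error, wood-density
uncertainty, H-D coefficient and residual error, and allometry parameter
and residual error into 1000 plot-level AGB realizations per subplot; their
mean is the plot's reference value AGB_REF.

**Level 2 — plot to landscape.** Per realization, `build_ensemble()` refits

    ln(AGB_REF) = a + b·ln(meanTCH) + ε,   ε ~ N(0, RSE)

and draws parameters from the exact flat-prior posterior;
`predict_map()` applies one parameter set per ensemble member to the
meanTCH raster with per-pixel residual noise. The per-pixel mean and SD of
the 1000 back-transformed predictions form the meanAGB and sdAGB layers of
a three-layer GeoTIFF whose third layer (Nbin) assigns each pixel to an
equal-frequency covariance bin, enabling subregion mean-AGB standard
errors from the published binned covariance matrix.

Around this core: the 15 standard canopy metrics (`grid_metrics()`,
`plot_metrics()`), mixed-effects AIC screening of candidate predictors
(`screen_lmm()`), the 10-ha site/regional model rule (`assign_scope()`),
buffered spatial leave-one-out cross-validation (`buffered_loocv()`),
extrapolation-domain accounting (`extrapolation_mask()`), and a synthetic
multi-site forest generator (`gen_site()`) with known generative
parameters so the whole chain is testable offline.

## Worked example

```r
library(agbref)

cfg <- site_config("demo", n_plots = 10, plot_shape = c(100, 100),
                   landscape_extent = c(700, 500),
                   map_true = c(alpha = 2.0, beta = 1.2, rse = 0.1), seed = 42)
st <- gen_site(cfg)                      # inventory + co-registered 1-m CHM
sp <- split_plots(st$plots, st$trees, 100)
trees <- assign_wood_density(sp$trees, cfg$wd_pool)
hd <- fit_hd(st$trees)
print(hd)
#> Height-diameter model: ln(H) = a + b ln(D) + c (ln D)^2
#>   a = -0.5834, b = 1.4685, c = -0.1321, sigma = 0.2094 (n = 895)
#>   back-transformed R2 = 0.665, RMSE = 3.05 m

draws <- plot_agb_mc(sp$subplots, trees, hd, n_sim = 1000, seed = 1)
print(draws)
#> <plot_agb_draws> 10 subplots x 1000 simulations
#>   AGB_REF range [95.6, 347.6] Mg/ha; mean within-plot CV 9.1%

pm  <- plot_metrics(st$chm, sp$subplots)
mdl <- fit_mapping_model(data.frame(agb_ref = draws$agb_ref,
                                    mean_tch = pm$mean_tch))
print(mdl)
#> LiDAR-AGB mapping model (site, 1ha): ln(AGB) = a + b ln(meanTCH)
#>   a = 2.416 (0.232), b = 1.078 (0.083), sigma = 0.101, n = 10
#>   calibration domain: meanTCH in [6.9, 24.0] m
#>   back-transformed R2 = 0.91, RMSE = 25.7 Mg/ha (10.6%)

ens <- build_ensemble(draws, pm$mean_tch, n_draws = 1000, seed = 2)
gm  <- grid_metrics(st$chm, cell = 100)
map <- predict_map(ens, gm, veg_threshold = 2, seed = 3, keep_stack = TRUE)
map <- assign_bins(map, n_bins = 8)
print(map)
#> <agb_map> 5 x 7 pixels @ 100 m; 35 valid
#>   meanAGB [90.1, 345.0] Mg/ha; mean CV 17.3%
write_agb_map(map, "demo_agb.tif")       # meanAGB / sdAGB / Nbin layers

cv <- buffered_loocv(cbind(sp$subplots, agb_ref = draws$agb_ref,
                           mean_tch = pm$mean_tch))
print(cv)
#> Buffered LOO-CV (100 m buffer, 1ha): 10 folds
#>   R2 = 0.88, RMSE = 30.5 Mg/ha (12.5%)

cm <- binned_covariance(map)
su <- subregion_uncertainty(map$valid_idx[1:10], map, cm)
#> subregion of 10 pixels: mean 153.1 +/- 16.1 Mg/ha
```

Reading the numbers: the H-D refit recovers a curve close to the
generative law with ~21% residual height scatter; first-level propagation
puts ~9% CV on 1-ha plot AGB; the mapping model explains 91% of AGB_REF
variance with 10.6% calibration RMSE, which degrades honestly to 12.5%
under buffered cross-validation; the map's mean pixel CV of 17% combines
both modelling levels; and the binned covariance metadata prices a
10-pixel subregion mean at ±16 Mg/ha — more than the naive
independent-pixel SE, because ensemble members share mapping-model errors
across pixels.

`run_pipeline()` chains all stages for many sites and both mapping
resolutions (100 m and 40 m) with one master seed and writes
maps/tables/metadata under a per-site directory tree; a thin CLI wrapper
lives in `inst/cli/agbref-run.R`.

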