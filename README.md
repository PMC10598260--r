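# pollenscale

Timescale-dependent variability of vegetation composition from fossil
pollen records.

Sediment pollen assemblages record vegetation composition over millennia,
but irregularly and multivariately. This package turns a compilation of
dated pollen count tables into per-record and aggregated estimates of how
compositional variability depends on timescale, and relates that
variability to vegetation type. It is aimed at paleoecologists and
statistical ecologists working with Neotoma-style pollen compilations, and
at anyone needing a tested implementation of interpolation-free structure
functions for irregular series.

## The method in brief

For each record, counts become proportions (rows sum to 1), are square-root
transformed, and reduced to the PC1 score series of the column-centred
covariance PCA. Variability as a function of timescale is estimated with the
first-order **Haar structure function**: for an interval of width τ split in
half,

S(τ) = ⟨ | mean(x, second half) − mean(x, first half) | ⟩ over windows,

which needs no interpolation and is robust near the sampling resolution.
Assuming power-law scaling S(τ) ∝ τ^H, the fluctuation exponent H is fitted
by a gamma GLM with log link (scales weighted by their window counts); H
relates to the spectral exponent by β = 1 + 2H, so white noise (β = 0) has
H = −0.5 and 1/f noise (β = 1) has H = 0, the boundary between stationary
and drifting composition. Per record the package reports the centennial band
mean S_C (τ ∈ [50, 200] yr), the millennial band mean S_M (τ ∈ [500, 2000]
yr) and the exponent H_C−M fitted over τ ∈ [200, 3000] yr.

Records are classified into biomes by projecting their square-rooted
assemblages onto **difference axes** a_i − a_j between typical assemblages
(mean square-rooted recent assemblages of labelled surface sites); the sign
of the mean score over 8–2 ka BP assigns the record to biome i or j, and
equal-count score quantiles group sites for aggregated structure functions.
Spatial coherency of the variability metrics is tested with Moran's I, and
metric–score relationships use coverage-weighted correlations with
permutation significance.

A synthetic-data module generates irregular pollen records from latent
Gaussian drivers with a chosen exponent H (spectral synthesis), multinomial
counts in the simplex via a softmax link, and labelled surface sets — so the
full pipeline runs against known ground truth.

## Worked example

The `analysis/` scripts run the whole study on a synthetic two-biome world
(forest vs open land, 120 records, latent H = 0, open-land records given
stronger compositional drivers):

```sh
Rscript analysis/01_simulate_dataset.R
Rscript analysis/02_variability_scaling.R
Rscript analysis/03_biome_classification.R
Rscript analysis/04_spatial_correlations.R
Rscript analysis/05_scaling_calibration.R
```

Selected output, with what it means:

```
PC1 explains on average 75% (sd 13%) of single-record variance
mean H_CM = -0.051 (records generated with latent H = 0)
```

the PC1 captures the dominant compositional mode, and the fitted
centennial-to-millennial exponent recovers the latent H = 0 of the
generator to within estimator bias (about −0.05 here);

```
mean scores u_bar(Fo,Op): 55 positive (forested), 65 negative (open)
sign accuracy vs true mixture: 94.2%; Spearman rho = 0.979
```

the forest-vs-open difference axis classifies records by the sign of their
mean score, agreeing with the generator's true forest fraction for 94 % of
sites and ranking them almost perfectly;

```
weighted correlation u_bar(Fo,Op) vs S_M: r = -0.733, p = 0.0001 (n = 120)
```

millennial-scale variability falls with forest affinity — the open-land
records were generated with stronger drivers, and the coverage-weighted
correlation recovers that gradient with high significance.

In code, the same pipeline is one call:

```r
library(pollenscale)
world <- gen_two_biome_world(60, H_true = 0, seed = 1)
surface <- gen_surface_set(10, default_profiles(), c("forest", "open"), seed = 2)
out <- run_pipeline(world$records, surface, config = pipeline_config())
head(out$scaling)       # per-site S_C, S_M, H_CM, beta, coverage
out$correlations        # coverage-weighted r and permutation p per metric
out$moran               # spatial coherency of each metric
```

See `vignettes/methods.Rmd` for the model, the numerical conventions
(window placement, occupancy, fit bands), the design choices and their
rationale, and what the synthetic world does and does not emulate.

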