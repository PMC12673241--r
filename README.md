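# refugiaTrack

Microclimatic niches, refugia statistics and post-breeding movement for
partially migratory birds.

In hot open landscapes, small patches of shrubs and trees act as
*microclimate refugia*: at the height of the day they can be several
degrees cooler than the surrounding herbaceous matrix. For a partially
migratory grassland bird this matters twice — refugia make staying
bearable after breeding, and their absence may push individuals to move.
`refugiaTrack` implements the full analysis chain linking breeding-season
microclimate to post-breeding movement, for researchers working with GPS
tracking data and micro-scale (tens of metres, hourly) temperature
surfaces.

## What it computes

Given GPS relocations, an hourly 30 m temperature cube and an 8-day NDVI
series, the pipeline:

1. **Filters fixes** to on-ground (null velocity) daylight positions
   (06–17 h local in breeding, 07–20 h in post-breeding), detects each
   individual's **departure date** (first date followed by ≥30
   consecutive days outside the buffered 90% kernel of its May fixes;
   never-departing individuals are residents with a Jul 15 – Sep 15
   post-breeding window), and applies inclusion rules (captured before
   May 1, ≥7 tracked days before departure, most recent year only).
2. Attaches **eight microclimate variables** per fix from the 500 m
   buffer: point temperature; buffer mean, median, max, min, SD; and

       refugia use          = point temperature − buffer median
       refugia availability = buffer minimum    − buffer median

   (°C; more negative = cooler refugia used/available).
3. Builds the **realized microclimatic niche**: PCA of the eight
   standardised variables (axes retained to >70% cumulative variance;
   PC1 oriented to temperature, PC2 to refugia availability), then
   99.5% bivariate-normal-kernel highest-density regions of the PC1–PC2
   scores per species/population/individual and season, with overlap
   percentages (reference region as denominator) and mass-weighted
   centroids. Individual seasonal **niche dissimilarity** is the
   distance between an individual's breeding and post-breeding niche
   centroids in PC units.
4. Summarises **movement**: daily 90%-kernel utilization-distribution
   centroids, the mean breeding centroid, consecutive post-breeding
   centroids merged into areas (5 km collapse radius), and the **total
   distance travelled** as the summed centroid chain,
   `ln`-transformed with a 0.5 km floor.
5. Fits two **linear mixed-effects models** (REML, population random
   intercept, Satterthwaite p-values):
   * `ln(distance) ~ PC1 centroid (scaled) + PC2 centroid (scaled) + pre-departure NDVI`
   * `dissimilarity ~ breeding-niche overlap + PC1 + PC2 + ln(distance)` (all scaled)

   and runs the **5-individual subsampling robustness check** (all
   subsets up to 10,000, otherwise 10,000 sampled) of population niche
   overlap.

A fully seeded **synthetic world generator** (thermal landscape with
refugia patches, NDVI series, multi-population tracks with known effect
sizes) drives the test suite and the worked example; no external data
are needed.

## Worked example

```r
library(refugiaTrack)

cfg <- pipelineConfig(
  world = syntheticWorldConfig(seed = 1, individualsPerPopulation = 10,
                               fixIntervalMinutes = 120,
                               betaTracking = 6, latGradientDegCPerKm = 1),
  seed = 5001, outDir = "demo_out")
res <- runPipeline(cfg)

res$nicheModel
#> NicheModel (standardised PCA of microclimate variables)
#>   axis variance: 61.8% 21.9% 12.5% 3.8% 0.0% 0.0% 0.0% 0.0%
#>   retained axes: 2 (cumulative > 70%)

res$speciesOverlap
#>                 comparison overlap_pct
#> 1      breeding_vs_overall    90.01480
#> 2 post_breeding_vs_overall    95.03169
#> 3         post_vs_breeding    90.86460
#> 4         breeding_vs_post    87.00145

print(res$distModel)
#> Linear mixed model 'distance_model' (n = 50 individuals)
#>   (Intercept)                  est   -1.337  SE  0.801  p 0.12
#>   pc1_scaled                   est    0.059  SE  0.163  p 0.731
#>   pc2_scaled                   est   -0.509  SE  0.138  p 0.00358
#>   ndvi_pre_departure           est    7.469  SE  3.359  p 0.0426
#>   random intercept (population) SD: 0.338
#>   ...

print(res$dissModel)
#> Linear mixed model 'dissimilarity_model' (n = 50 individuals)
#>   ...
#>   ln_distance_scaled           est   -0.415  SE  0.073  p 9.54e-07
#>   random intercept (population) SD: 0.122
#>   ...
```

Reading the output: the first two principal axes (temperature and
refugia availability) carry 84% of the variance in the experienced
microclimate, so the niche is drawn in that plane. In this synthetic
world the slope of log distance on the z-scored refugia-availability
statistic was set to −0.6 when generating the tracks; the distance model
recovers −0.51 (SE 0.14) on the scaled PC2 centroid. The dissimilarity
model's negative `ln_distance` coefficient says long-distance movers
ended up in post-breeding microclimates more similar to their breeding
ones — the niche-tracking signal planted in the generator
(`betaTracking = 6`).

All tables are also written to `demo_out/` (fixes, exclusions, season
assignments, environment table, niche model, overlaps, movement summary,
model summaries, subsampling distributions, GeoJSON niche contours, a
JSON manifest and the YAML config). A thin command-line wrapper lives at
`inst/scripts/refugiatrack.R` (`init`, `simulate`, `all` subcommands).

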