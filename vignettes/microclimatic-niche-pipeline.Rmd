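---
title: "Quantifying microclimatic niches and post-breeding movement from GPS tracks"
author: "refugiaTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microclimatic niches and post-breeding movement from GPS tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Partially migratory birds in hot open landscapes face a choice at the end
of the breeding season: stay, and endure the hottest months where they
bred, or move — sometimes far — to cooler post-breeding areas. At the
scale animals actually experience temperature (metres, not kilometres),
small patches of shrubs and trees embedded in an open herbaceous matrix
act as *microclimate refugia*: they can be several degrees cooler than
the surrounding matrix at the height of the day. `refugiaTrack`
implements a complete analysis linking the microclimate an individual
experienced while breeding to how far it subsequently moved, and to how
similar its seasonal environmental niches remained.

The pipeline takes (a) GPS relocations (projected coordinates, timestamp,
ground speed), (b) hourly micro-scale (30 m) temperature grids, and (c) a
coarse NDVI composite series, and produces:

1. per-fix **buffer temperature statistics** and two refugia metrics,
2. an **environmental-space niche**: PCA of the microclimate variables
   with bivariate-kernel niche regions, overlaps and centroids,
3. **movement summaries**: daily utilization distributions, breeding
   centroids and a summed migration distance,
4. two **linear mixed-effects models** and a subsampling robustness
   check.

A seeded synthetic world generator with known effect sizes makes every
stage testable end-to-end without any external data.

# Fix filtering and season assignment

Analyses use ground positions only: fixes with speed above `speedTol`
(default exactly 0 m/s) are removed, as are nocturnal fixes. Daylight is
defined on the local clock — hours 06–17 in the breeding season and
07–20 in post-breeding — rather than by solar elevation, with local time
taken as UTC plus a fixed offset (`tzOffset`, default +1). Every removed
fix is retained in an exclusion table with a named reason, so the filter
conserves records and is idempotent.

The breeding season starts May 1 for all individuals. The breeding area
for the departure rule is the 90% kernel region of the individual's May
fixes buffered by 1 km (the source analyses do not formalise "breeding
area" for this rule; a kernel region of early-season fixes is the
standard home-range operationalisation). Departure is the first date
after which the daily fix centroid stays outside that area for at least
30 consecutive days; a return inside the window rejects the candidate
(strict consecutiveness — the tolerance to brief returns is exposed as
`minAwayDays` but not relaxed by default). Individuals whose tracking
ends less than 30 days after a candidate departure are flagged
indeterminate and excluded. Individuals that never leave are residents,
with the post-breeding window fixed at Jul 15 – Sep 15, the hottest part
of the year. Individuals captured on or after May 1, or with fewer than
7 tracked days before departure, are excluded; for individuals tracked
over several years only the most recent valid year is analysed.

# Microclimate variables

For each retained fix, temperature statistics are computed over all grid
cells whose *centres* lie within 500 m of the fix, at the hour nearest
the fix timestamp (single matched hour; pooling across hours is not
done). Eight variables result: the point temperature at the fix cell;
the buffer mean, median, maximum, minimum and standard deviation; and
two refugia metrics,

* refugia use = point − buffer median,
* refugia availability = buffer minimum − buffer median,

both in °C and never positive for availability (more negative = cooler
refugia available/used). Medians interpolate the midpoint on even cell
counts and standard deviations use the n−1 denominator. Buffers partly
outside the grid are accepted down to 50% cell coverage; below that the
record is flagged invalid. Cell-centre-in-circle membership was chosen
over area-weighted membership because it is unambiguous and directly
checkable against a brute-force loop (the test suite holds the compiled
path to exact agreement with an explicit R loop over every cell).

The food-availability covariate is the mean NDVI over the 8 days before
departure (residents: before Jul 15), averaged spatially over the
individual's breeding area and day-weighted across the 8-day composites
that intersect the window.

# The environmental-space niche

The eight variables are standardised (mean 0, SD 1) over *all* retained
fixes — both seasons, all individuals and years pooled; a season-wise
standardisation would prevent the seasonal niches from being compared in
one space — and decomposed by PCA. Axis signs are oriented so PC1
increases with the five temperature variables (a "hotter" axis) and PC2
increases with the refugia-availability loading. Axes are retained until
cumulative variance exceeds 70%; downstream niche geometry uses the
first two axes.

A niche region for any analysis level (species, population, individual;
per season and year) is the 99.5% bivariate-normal-kernel
highest-density region of that level's scores: a binned kernel density
estimate (reference bandwidth `0.8 * sd * n^(-1/6)` per axis — the
"href" rule scaled by 0.8, correcting both the rule's well-known
oversmoothing of utilization distributions and the coverage inflation
of smoothed-field contours) on a
400 × 400 grid spanning the scores plus three bandwidths, thresholded at
the density level whose highest-density cells accumulate 99.5% of the
kernel mass. The high mass level trims outlying scores; the
highest-density-region construction (sorting cell masses) matches the
kernel home-range convention rather than a density quantile of points.
Overlap between two regions is the percentage of the *reference* region's
cells whose centres fall inside the subject region — the reference is
always the denominator, and a region overlaps itself by exactly 100%.
Region centroids are kernel-mass-weighted means over the enclosed cells.
This is the package's definition of a niche centroid: it estimates the
mean of the occupied conditions and is insensitive to the shape of the
contour's outer fringe, which at 99.5% mass is essentially a convex
envelope of outliers. Niche dissimilarity between an individual's
seasons is the Euclidean distance between its two seasonal centroids in
PC units.

Grid discretisation keeps area errors under 1% (verified by translation
invariance tests); coverage calibration is verified against 10^5
standard bivariate normal samples.

# Movement

Daily utilization distributions are 90% kernel regions of each day's
fixes (at least 5 fixes per day), with the same kernel definition as the
niche space but evaluated in projected metres; because a day holds at
most a few dozen fixes the density is evaluated exactly on the grid
(direct Gaussian sums in compiled code) rather than by binned FFT. A
30 m bandwidth floor keeps days with nearly coincident fixes finite.

The mean breeding centroid is the mean of breeding-season daily
centroids. Post-breeding daily centroids are merged into *areas*:
consecutive centroids within `collapseRadiusKm` (default 5 km) of the
running area centroid join the current area, otherwise a new area
starts. The total distance is the leg from the mean breeding centroid to
the first area plus the legs between consecutive areas. Summing over
merged areas rather than over every daily centroid keeps the distance
independent of tracking duration — a literal per-day sum would grow
without bound for a stationary animal; setting `collapseRadiusKm = 0`
recovers the literal rule. The log distance floors the total at 0.5 km
so residents remain finite. Both knobs are config-exposed sensitivity
parameters.

# Inference

Model 1 explains log distance travelled with the scaled PC1
(temperature) and PC2 (refugia availability) coordinates of the
individual's breeding niche centroid plus pre-departure NDVI. Model 2
explains seasonal niche dissimilarity with the individual's
breeding-niche overlap with its population's breeding niche, the scaled
centroid coordinates, and log distance. Both are REML linear
mixed-effects models with a population random intercept; with a single
population the random effect is unidentifiable and the fit falls back to
ordinary least squares with a warning. p-values use Satterthwaite
degrees of freedom (via lmerTest): with ~46 individuals in 5 populations,
Wald z p-values are anti-conservative, and calibrated type-I error is a
tested property of this package. Covariate scaling constants are
recorded in the fit object so unscaled coefficients are recoverable
exactly. Singular random-effect fits are flagged, not silently refitted.

The subsampling robustness procedure rebuilds a population's seasonal
niche from every subset of 5 individuals — all subsets when there are at
most 10,000, otherwise 10,000 distinct subsets sampled without
replacement under a seed — and compares the spread of subset overlaps
(with the species-level seasonal niche as the fixed reference) with the
full-data overlap.

# The synthetic world

The generator emulates the study design the analysis assumes, not any
particular landscape: five breeding populations (46 individuals in the
default unequal split) tracked from late April to Sep 15 at a 10–120 min
cadence; an hourly 30 m thermal landscape; NDVI composites; and known
effect sizes. Its components:

* **Thermal landscape.** Per-hour temperature = a diurnal sinusoid
  (mean 22 °C at season start, half-range 8 °C, peak 15:00 local — so
  afternoons reach ~30 °C in May and approach 40 °C in August) + linear
  seasonal warming (7 °C over the season) + a northward cooling gradient
  + refugia patch cooling (4 °C inside discs of radius 30–120 m placed
  by a Poisson process, patch density differing between population
  sectors: 0.5–4 patches/km²) + spatially correlated Gaussian-smoothed
  noise (SD 0.6 °C, 90 m correlation scale). The field is separable
  (static space + scalar hour offset), which keeps a full season at 30 m
  resolution in memory and makes the refugia metrics time-invariant — a
  deliberate simplification; real refugia contrast varies diurnally.
* **Compressed geography.** The 16 km landscape stands in for a study
  region hundreds of kilometres across, so the meridional temperature
  contrast is compressed with it: the default gradient of 1.5 °C/km
  spans ~8 °C per ~5.5 km of northward movement at the scale of the
  landscape, mirroring the ~10 °C contrast real northern post-breeding
  areas offer. Population centres sit at different latitudes, in an
  order with zero rank correlation to the patch-density order — if
  climate and refugia supply were confounded across populations, the
  temperature and refugia niche axes would become collinear proxies and
  the mixed models could not attribute effects.
* **NDVI.** Greenness collapses from 0.62 to 0.25 between May 1 and
  Jun 1 as grasslands dry out, then drifts slowly; departures follow
  with a lag (mean Jun 14, SD 8 days). By every reference date greenness
  is similarly low everywhere, which mirrors the real system's late
  breeding season; an earlier design in which departures fell on the
  steep decline made the residents' Jul-15 NDVI reference systematically
  greener-to-browner than migrants' and thereby manufactured a spurious
  NDVI–distance association.
* **Distance.** Post-breeding displacement is drawn as
  `exp(log(1.8) - 0.6 * z(availability) + e)`, `e ~ N(0, 0.5)`, where
  availability is the individual's mean breeding refugia-availability
  statistic over its own breeding fixes and `z()` standardises across
  individuals. Draws under 0.6 km stay resident (partial migration).
  The intercept and landscape size are matched so draws rarely exceed
  the feasible on-landscape distance: truncating the long tail at the
  landscape boundary flattens exactly the informative extreme of the
  availability–distance relationship.
* **Niche tracking.** Destinations at the drawn distance are chosen
  among candidate directions with weights
  `exp(-betaTracking * mismatch)`, where the mismatch compares the
  candidate's buffer median and availability with the breeding values
  after discounting the shared seasonal warming. With `betaTracking = 0`
  destinations are random; at high values long-distance movers land in
  microclimates matching their breeding conditions while short-distance
  movers cannot escape the seasonal warming — producing the
  niche-tracking contrast the dissimilarity model detects.
* **Filter fodder.** Fixes are generated around the clock; ground fixes
  have speed exactly 0, a configurable fraction are in-flight fixes at
  5–15 m/s, and travel days interpolate breeding-to-destination
  positions at flight speeds, so the velocity and daylight filters have
  real work. An optional fraction of individuals receives a duplicate
  previous tracking year to exercise the last-year rule.

One direction deserves emphasis: with the generating slope acting
negatively on the *signed* availability metric (more negative = more
refugia), refugia-rich individuals draw the longer distances in this
synthetic system, and the recovered coefficient on the (positively
oriented) refugia-availability axis is negative. The synthetic world is
a device for verifying that the pipeline recovers whatever effect was
planted at the stated magnitude and sign convention — not a claim about
the ecology of any real population.

What passing tests on this world do **not** show: robustness to GPS
positional error (none is simulated beyond home-range scatter), to
diurnally varying refugia contrast, to NDVI cloud gaps, to non-Gaussian
movement (the tracks are an Ornstein–Uhlenbeck walk with a 6 h
relaxation time), or to mechanistically generated temperature surfaces.

# Problem sizes and numerical choices

The test suite exercises the full system at sizes chosen for a single
CPU: parameter recovery uses 50 replicate worlds of 25 individuals
(5 per population) at a 120-min cadence, null-world calibration 36
worlds of 20 individuals, the niche-tracking and subsampling checks one
46-individual world each, and the reproducibility check runs a
50-individual demo pipeline twice and compares outputs byte-for-byte.
Kernel grids are 400 × 400 for reported niche geometry and 200 × 200
inside replicate simulations; the subsampling procedure uses 200 × 200
subset niches (overlap is measured on the reference region's grid, so
the subset grid only sets membership resolution). The pre-registered
recovery bar — the refugia coefficient negative in ≥48/50 worlds and
within two standard errors of the generating value in ≥45/50 — and the
binomial band on null-world false-positive rates are fixed in the test
suite.

Other numerical choices: one master seed derives per-stage child seeds
(so stages can be rerun in isolation); KDE bandwidths floor at 10^-8 in
PC space and 30 m in geographic space; PCA rank deficiency (duplicated
variables) caps retained axes at the number of nonzero eigenvalues;
zero-variance variables are a named error; ties between departure
candidates resolve to the earliest qualifying date.

# Limitations

The niche is two-dimensional by construction and unreferenced to
availability: no background correction is attempted (computing hourly
30 m temperatures across an entire region to characterise *available*
microclimate is outside scope), so overlaps describe used conditions
only. Centroid dissimilarity summarises niche position, not breadth or
shape — two nested niches of very different size can have a small
centroid distance. Clock-hour daylight windows ignore day-length change
across the season. The resident/migrant dichotomy rests on the 30-day
rule; individuals with intermediate excursions are sensitive to
`minAwayDays`. The distance metric depends on the area-collapse radius;
both it and the 0.5 km resident floor are exposed in the configuration
and worth a sensitivity pass on real data.
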