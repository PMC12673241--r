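## S4 classes for the package's central data objects.
##
## Grid convention used throughout: a field is a numeric matrix indexed
## [ix, iy] with x = x0 + (ix - 0.5) * cellSize and y = y0 + (iy - 0.5) *
## cellSize, i.e. (x0, y0) is the lower-left corner of the grid and cell
## values sit at cell centres.


#' Synthetic world configuration
#'
#' Parameters of the synthetic study system: a thermal landscape of cool
#' refugia patches in a hot open matrix, an NDVI series declining from
#' spring to mid-summer, and multi-population GPS tracks of partially
#' migratory birds whose post-breeding displacement depends (with known
#' effect size) on breeding refugia availability.
#'
#' @slot nPopulations Number of breeding populations.
#' @slot individualsPerPopulation Individuals per population (recycled to
#'   `nPopulations`).
#' @slot landscapeSize Metres per side of the square landscape.
#' @slot cellSize Temperature grid cell size in metres (30 m).
#' @slot refugiaPatchDensity Refugia patches per km^2, one value per
#'   population (density applies to the landscape sector nearest that
#'   population's centre).
#' @slot refugiaCoolingDegC Mean temperature depression inside a patch, degC.
#' @slot baseMeanTemp Daily mean temperature at season start, degC.
#' @slot diurnalAmplitude Half peak-to-trough diurnal range, degC (peak 15:00).
#' @slot seasonalWarmingDegC Linear warming from May 1 to Sep 15, degC.
#' @slot latGradientDegCPerKm Cooling with northing, degC per km.
#' @slot betaRefugiaDistance Ground-truth slope of ln(distance km) on the
#'   z-scored breeding refugia availability (negative: poor refugia, long
#'   moves).
#' @slot betaTracking Strength of post-breeding niche tracking (0 = random
#'   destination; large = destination matches breeding microclimate).
#' @slot distanceInterceptLnKm Intercept of the ln-distance model.
#' @slot distanceSdLn Residual SD of ln(distance).
#' @slot residentThresholdKm Drawn displacement below which an individual
#'   remains resident.
#' @slot fixIntervalMinutes GPS fix cadence, minutes (10-120).
#' @slot noiseSd SD of the spatially correlated temperature noise, degC.
#' @slot homeRangeSd SD of within-home-range fix scatter, metres.
#' @slot flightFixProb Probability that a fix is an in-flight fix with
#'   nonzero speed (exercises the null-velocity filter).
#' @slot multiYearFraction Fraction of individuals also given a previous
#'   year of tracking (exercises the last-year rule).
#' @slot year Calendar year of the synthetic season.
#' @slot seed RNG seed; identical config + seed gives bit-identical output.
#' @export
setClass("SyntheticWorldConfig",
  representation(
    nPopulations = "numeric",
    individualsPerPopulation = "numeric",
    landscapeSize = "numeric",
    cellSize = "numeric",
    refugiaPatchDensity = "numeric",
    refugiaCoolingDegC = "numeric",
    baseMeanTemp = "numeric",
    diurnalAmplitude = "numeric",
    seasonalWarmingDegC = "numeric",
    latGradientDegCPerKm = "numeric",
    betaRefugiaDistance = "numeric",
    betaTracking = "numeric",
    distanceInterceptLnKm = "numeric",
    distanceSdLn = "numeric",
    residentThresholdKm = "numeric",
    fixIntervalMinutes = "numeric",
    noiseSd = "numeric",
    homeRangeSd = "numeric",
    flightFixProb = "numeric",
    multiYearFraction = "numeric",
    year = "numeric",
    seed = "numeric"
  )
)

setValidity("SyntheticWorldConfig", function(object) {
  msg <- character()
  if (object@nPopulations < 1) msg <- c(msg, "nPopulations must be >= 1")
  if (any(object@individualsPerPopulation < 1))
    msg <- c(msg, "individualsPerPopulation must all be >= 1")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
  if (object@landscapeSize < 10 * object@cellSize)
    msg <- c(msg, "landscape must span at least 10 cells")
  if (any(object@refugiaPatchDensity < 0))
    msg <- c(msg, "refugiaPatchDensity must be >= 0")
  if (object@refugiaCoolingDegC < 0)
    msg <- c(msg, "refugiaCoolingDegC must be >= 0")
  if (object@fixIntervalMinutes < 10 || object@fixIntervalMinutes > 120)
    msg <- c(msg, "fixIntervalMinutes must lie in [10, 120]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Hourly micro-scale temperature cube
#'
#' Hourly 30 m temperatures at 20 cm above ground over one season,
#' represented in separable form: a static spatial field (northing
#' gradient + refugia patch cooling + spatially correlated noise) plus an
#' hourly scalar offset (diurnal cycle + seasonal warming trend). Slices
#' are materialised on demand with [tempSlice()], which keeps a full
#' season at 30 m resolution in a few megabytes.
#'
#' @slot x0,y0 Lower-left corner of the grid, projected metres.
#' @slot cellSize Cell size in metres.
#' @slot staticField Matrix `[ix, iy]` of time-invariant temperature, degC.
#' @slot hourOffset Scalar temperature offset per hour, degC.
#' @slot hours Strictly increasing hourly `POSIXct` axis (UTC).
#' @slot patchMask Logical matrix flagging refugia patch cells (ground
#'   truth for synthetic worlds).
#' @slot meta List of generator metadata (cooling, gradient, ...).
#' @export
setClass("TemperatureCube",
  representation(
    x0 = "numeric", y0 = "numeric", cellSize = "numeric",
    staticField = "matrix", hourOffset = "numeric",
    hours = "POSIXct", patchMask = "matrix", meta = "list"
  )
)

setValidity("TemperatureCube", function(object) {
  msg <- character()
  if (!all(is.finite(object@staticField)))
    msg <- c(msg, "staticField must be finite")
  if (length(object@hourOffset) != length(object@hours))
    msg <- c(msg, "hourOffset and hours must have equal length")
  if (length(object@hours) > 1) {
    d <- as.numeric(diff(object@hours), units = "hours")
    if (any(abs(d - 1) > 1e-9))
      msg <- c(msg, "hours must be strictly increasing and hourly spaced")
  }
  if (!identical(dim(object@staticField), dim(object@patchMask)))
    msg <- c(msg, "patchMask must match staticField dimensions")
  if (length(msg)) msg else TRUE
})

#' NDVI composite series
#'
#' 8-day NDVI composites on a coarse (250 m) grid, as delivered by
#' satellite vegetation products.
#'
#' @slot x0,y0 Lower-left corner, projected metres.
#' @slot cellSize Cell size in metres (250 m).
#' @slot periodStarts Strictly increasing `Date` vector of composite period
#'   starts, 8 days apart.
#' @slot values 3-D array `[ix, iy, period]` of NDVI in `[-1, 1]`.
#' @export
setClass("NDVISeries",
  representation(
    x0 = "numeric", y0 = "numeric", cellSize = "numeric",
    periodStarts = "Date", values = "array"
  )
)

setValidity("NDVISeries", function(object) {
  msg <- character()
  v <- object@values
  if (length(dim(v)) != 3)
    msg <- c(msg, "values must be a 3-D array [x, y, period]")
  else if (dim(v)[3] != length(object@periodStarts))
    msg <- c(msg, "third dimension must match periodStarts")
  if (any(v < -1 | v > 1, na.rm = TRUE))
    msg <- c(msg, "NDVI values must lie in [-1, 1]")
  if (length(object@periodStarts) > 1 &&
      any(as.numeric(diff(object@periodStarts)) != 8))
    msg <- c(msg, "periodStarts must increase in 8-day steps")
  if (length(msg)) msg else TRUE
})

#' Environmental-space niche model (standardised PCA)
#'
#' PCA of the eight microclimate niche variables, fitted on all
#' relocations pooled across seasons, individuals and years. Axis signs
#' are oriented so PC1 increases with temperature and PC2 increases with
#' the refugia-availability loading, and the number of retained axes is
#' the smallest count whose cumulative variance fraction exceeds the
#' retention threshold (default 0.70).
#'
#' @slot center,scale Named per-variable standardisation constants.
#' @slot loadings Variable-by-axis loading matrix (orthonormal columns).
#' @slot varFrac Fraction of total variance per axis, non-increasing.
#' @slot retained Number of retained axes.
#' @slot threshold Cumulative-variance retention threshold.
#' @slot id Fingerprint used to refuse mixing scores across models.
#' @export
setClass("NicheModel",
  representation(
    center = "numeric", scale = "numeric", loadings = "matrix",
    varFrac = "numeric", retained = "integer", threshold = "numeric",
    id = "character"
  )
)

setValidity("NicheModel", function(object) {
  msg <- character()
  v <- object@varFrac
  if (any(v < -1e-12 | v > 1 + 1e-12)) msg <- c(msg, "varFrac must lie in [0, 1]")
  if (any(diff(v) > 1e-9)) msg <- c(msg, "varFrac must be non-increasing")
  if (sum(v) > 1 + 1e-6) msg <- c(msg, "varFrac must sum to at most 1")
  if (length(msg)) msg else TRUE
})

#' Kernel highest-density niche region
#'
#' A bivariate-normal-kernel highest-density region at a given mass level
#' (99.5% for environmental-space niches, 90% for daily utilization
#' distributions), held as a boolean membership grid together with its
#' area and area-weighted centroid. The same engine serves PC space and
#' geographic space.
#'
#' @slot xgrid,ygrid Cell-centre coordinates of the evaluation grid.
#' @slot mask Logical matrix `[ix, iy]`; TRUE inside the region.
#' @slot level Kernel density threshold defining the region.
#' @slot mass Nominal probability mass enclosed (e.g. 0.995).
#' @slot area Region area in squared grid units.
#' @slot centroid `(x, y)` centroid of the enclosed region
#'   (kernel-mass-weighted over member cells for KDE-derived regions).
#' @slot space `"pc"` or `"geo"`.
#' @slot modelId Niche model fingerprint (`NA` in geographic space).
#' @slot meta Labels: level (species/population/individual), season, year.
#' @export
setClass("NicheRegion",
  representation(
    xgrid = "numeric", ygrid = "numeric", mask = "matrix",
    level = "numeric", mass = "numeric", area = "numeric",
    centroid = "numeric", space = "character", modelId = "character",
    meta = "list"
  )
)

setValidity("NicheRegion", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!any(object@mask)) msg <- c(msg, "region must contain at least one cell")
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  if (length(object@centroid) != 2 || !all(is.finite(object@centroid)))
    msg <- c(msg, "centroid must be a finite (x, y) pair")
  if (length(msg)) msg else TRUE
})

#' End-to-end pipeline configuration
#'
#' All thresholds of the analysis with their standard defaults: null
#' velocity tolerance 0 m/s, daylight windows 06-17 h (breeding) and
#' 07-20 h (post-breeding), 30-day departure rule, 500 m buffer radius,
#' 99.5% niche kernel, 90% utilization kernel, 70% cumulative-variance
#' retention, 5 km area-collapse radius, 5-individual subsampling capped
#' at 10,000 combinations.
#'
#' @slot world A [SyntheticWorldConfig-class] driving the synthetic stage.
#' @slot speedTol Max speed (m/s) still counted as null velocity.
#' @slot tzOffset Local time = UTC + tzOffset hours.
#' @slot breedingWindow,postWindow Inclusive local-hour daylight windows.
#' @slot minAwayDays Consecutive days away defining departure.
#' @slot bufferRadius Buffer radius in metres.
#' @slot nicheMass,udMass Kernel mass for niches and daily UDs.
#' @slot varianceThreshold PCA cumulative-variance retention threshold.
#' @slot collapseRadiusKm Radius merging consecutive post-breeding daily
#'   centroids into one area.
#' @slot distanceFloorKm Floor on total distance before the log transform.
#' @slot minFixesPerDay Minimum fixes to fit a daily UD.
#' @slot minNichePoints Minimum score points to fit a niche region.
#' @slot subsampleK Individuals per robustness subsample.
#' @slot maxCombinations Cap on enumerated/sampled subsets.
#' @slot runRobustness Whether to run the subsampling robustness stage.
#' @slot nicheGrid,udGrid Kernel evaluation grid sizes.
#' @slot seed Master seed.
#' @slot outDir Output directory ("" = do not write files).
#' @export
setClass("PipelineConfig",
  representation(
    world = "SyntheticWorldConfig",
    speedTol = "numeric", tzOffset = "numeric",
    breedingWindow = "numeric", postWindow = "numeric",
    minAwayDays = "numeric", bufferRadius = "numeric",
    nicheMass = "numeric", udMass = "numeric",
    varianceThreshold = "numeric", collapseRadiusKm = "numeric",
    distanceFloorKm = "numeric", minFixesPerDay = "numeric",
    minNichePoints = "numeric", subsampleK = "numeric",
    maxCombinations = "numeric", nicheGrid = "numeric", udGrid = "numeric",
    runRobustness = "logical", seed = "numeric", outDir = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@speedTol < 0) msg <- c(msg, "speedTol must be >= 0")
  if (object@nicheMass <= 0 || object@nicheMass >= 1)
    msg <- c(msg, "nicheMass must lie in (0, 1)")
  if (object@udMass <= 0 || object@udMass >= 1)
    msg <- c(msg, "udMass must lie in (0, 1)")
  if (object@varianceThreshold <= 0 || object@varianceThreshold >= 1)
    msg <- c(msg, "varianceThreshold must lie in (0, 1)")
  if (object@bufferRadius <= 0) msg <- c(msg, "bufferRadius must be > 0")
  if (object@minAwayDays < 1) msg <- c(msg, "minAwayDays must be >= 1")
  if (length(msg)) msg else TRUE
})
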