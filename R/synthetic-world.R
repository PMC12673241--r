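## Synthetic study system with known ground truth.
##
## The generator emulates the study design the analysis assumes: five
## breeding populations of a partially migratory grassland bird tracked
## May-September; an hourly 30 m thermal landscape of cool refugia patches
## (shrub/tree clumps) in a hot open matrix, cooler towards the north;
## NDVI composites declining from spring to mid-summer; and GPS tracks in
## which post-breeding displacement depends on breeding refugia
## availability with a known slope, and long-distance movers track their
## breeding microclimate when choosing destinations.

#' Create a synthetic world configuration
#'
#' Defaults encode the study conditions the downstream analysis targets:
#' 5 populations totalling 46 males, fixes every 10-120 min from late
#' April to 15 September, refugia patches cooled by 4 degC whose density
#' differs between populations, NDVI declining May to July, displacement
#' distances of roughly 0.3-12 km on a 16 km landscape (a scaled-down
#' analog of the reported 1-421 km range), and a negative dependence of
#' ln(distance) on breeding refugia availability.
#'
#' @param nPopulations Number of populations (default 5).
#' @param individualsPerPopulation Individuals per population; recycled.
#'   Default `c(6, 9, 10, 5, 16)` (46 total, unequal like real capture
#'   effort).
#' @param landscapeSize Metres per side (default 16000).
#' @param cellSize Metres per temperature cell (default 30).
#' @param refugiaPatchDensity Patches per km^2 per population sector;
#'   default `c(0.5, 1, 1.5, 2.5, 4)`.
#' @param refugiaCoolingDegC Patch cooling, degC (default 4).
#' @param baseMeanTemp Daily mean at May 1, degC (default 22).
#' @param diurnalAmplitude Diurnal half-range, degC (default 8; peak 15:00
#'   local, so afternoons reach about 30 degC in May and close to 40 degC
#'   in August).
#' @param seasonalWarmingDegC Warming May 1 to Sep 15 (default 7).
#' @param latGradientDegCPerKm Northward cooling (default 1.5; the 12 km
#'   landscape compresses a regional study extent, and with it the
#'   meridional temperature contrast that real destinations offer).
#' @param betaRefugiaDistance Ground-truth slope of ln(km) on z-scored
#'   availability (default -0.6).
#' @param betaTracking Niche-tracking strength (default 0 = none).
#' @param distanceInterceptLnKm Intercept of ln(km) (default `log(1.8)`).
#' @param distanceSdLn Residual SD of ln(km) (default 0.5).
#' @param residentThresholdKm Displacements below this stay resident
#'   (default 0.6).
#' @param fixIntervalMinutes Fix cadence (default 30).
#' @param noiseSd SD of spatially correlated temperature noise (default 0.6).
#' @param homeRangeSd Within-range fix scatter SD, metres (default 150).
#' @param flightFixProb Probability of an in-flight (nonzero speed) fix
#'   (default 0.04).
#' @param multiYearFraction Fraction of individuals with an extra previous
#'   tracking year (default 0).
#' @param year Season calendar year (default 2018).
#' @param seed RNG seed (mandatory determinism anchor; default 1).
#' @return A validated [SyntheticWorldConfig-class].
#' @export
syntheticWorldConfig <- function(nPopulations = 5,
                                 individualsPerPopulation = c(6, 9, 10, 5, 16),
                                 landscapeSize = 16000,
                                 cellSize = 30,
                                 refugiaPatchDensity = c(0.5, 1, 1.5, 2.5, 4),
                                 refugiaCoolingDegC = 4,
                                 baseMeanTemp = 22,
                                 diurnalAmplitude = 8,
                                 seasonalWarmingDegC = 7,
                                 latGradientDegCPerKm = 1.5,
                                 betaRefugiaDistance = -0.6,
                                 betaTracking = 0,
                                 distanceInterceptLnKm = log(1.8),
                                 distanceSdLn = 0.5,
                                 residentThresholdKm = 0.6,
                                 fixIntervalMinutes = 30,
                                 noiseSd = 0.6,
                                 homeRangeSd = 150,
                                 flightFixProb = 0.04,
                                 multiYearFraction = 0,
                                 year = 2018,
                                 seed = 1) {
  new("SyntheticWorldConfig",
      nPopulations = nPopulations,
      individualsPerPopulation =
        rep_len(individualsPerPopulation, nPopulations),
      landscapeSize = landscapeSize, cellSize = cellSize,
      refugiaPatchDensity = rep_len(refugiaPatchDensity, nPopulations),
      refugiaCoolingDegC = refugiaCoolingDegC,
      baseMeanTemp = baseMeanTemp, diurnalAmplitude = diurnalAmplitude,
      seasonalWarmingDegC = seasonalWarmingDegC,
      latGradientDegCPerKm = latGradientDegCPerKm,
      betaRefugiaDistance = betaRefugiaDistance, betaTracking = betaTracking,
      distanceInterceptLnKm = distanceInterceptLnKm,
      distanceSdLn = distanceSdLn,
      residentThresholdKm = residentThresholdKm,
      fixIntervalMinutes = fixIntervalMinutes, noiseSd = noiseSd,
      homeRangeSd = homeRangeSd, flightFixProb = flightFixProb,
      multiYearFraction = multiYearFraction, year = year, seed = seed)
}

#' Season anchor dates
#'
#' Breeding starts May 1 for all individuals; the resident post-breeding
#' window is Jul 15 - Sep 15 (the hottest part of the year).
#'
#' @param year Calendar year.
#' @return List with Dates `may1`, `jul15`, `sep15`.
#' @export
seasonDates <- function(year) {
  list(may1 = as.Date(sprintf("%d-05-01", year)),
       jul15 = as.Date(sprintf("%d-07-15", year)),
       sep15 = as.Date(sprintf("%d-09-15", year)))
}

## Breeding population centres: spread across the southern part of the
## landscape, staggered in latitude (real populations sit in regions with
## different baseline temperatures). The latitude sequence has zero rank
## correlation with the default patch-density sequence, so climate and
## refugia supply are not confounded across populations.
populationCenters <- function(config) {
  L <- config@landscapeSize
  p <- seq_len(config@nPopulations)
  yFrac <- rep_len(c(0.30, 0.08, 0.20, 0.35, 0.14), config@nPopulations)
  cbind(x = (p - 0.5) / config@nPopulations * L, y = yFrac * L)
}

#' Generate the hourly thermal landscape
#'
#' Per-hour temperature = diurnal sinusoid (peak 15:00 local) + linear
#' seasonal warming + northward cooling gradient + refugia patch cooling +
#' spatially correlated (Gaussian-smoothed) noise. Patches are discs of
#' radius 30-120 m (small tree/shrub clumps well below the buffer scale)
#' placed by a Poisson process whose intensity in each
#' population's landscape sector is that population's
#' `refugiaPatchDensity`. The patch mask is kept on the cube as ground
#' truth.
#'
#' @param config A [SyntheticWorldConfig-class].
#' @return A [TemperatureCube-class] covering May 1 - Sep 15.
#' @export
generateLandscape <- function(config) {
  validObject(config)
  L <- config@landscapeSize
  cell <- config@cellSize
  nx <- ny <- as.integer(round(L / cell))
  nPop <- as.integer(config@nPopulations)
  stripArea <- (L / nPop) * L / 1e6                       # km^2 per sector
  # mean disc area for radius ~ U(30, 120): pi * E[r^2]
  meanPatchArea <- pi * (120^3 - 30^3) / (3 * 90) / 1e6   # km^2
  expFrac <- sum(config@refugiaPatchDensity * stripArea) * meanPatchArea /
    (L * L / 1e6)
  if (expFrac > 0.4)
    stop("landscape too small for the requested refugia patch density ",
         sprintf("(expected patch cover %.0f%%)", 100 * expFrac))

  withSeed(deriveSeed(config@seed, "landscape"), {
    patches <- do.call(rbind, lapply(seq_len(nPop), function(p) {
      np <- rpois(1, config@refugiaPatchDensity[p] * stripArea)
      if (np == 0) return(NULL)
      data.frame(population = p,
                 x = runif(np, (p - 1) / nPop * L, p / nPop * L),
                 y = runif(np, 0, L),
                 r = runif(np, 30, 120))
    }))
    mask <- matrix(FALSE, nx, ny)
    if (!is.null(patches)) {
      for (k in seq_len(nrow(patches))) {
        px <- patches$x[k]; py <- patches$y[k]; pr <- patches$r[k]
        ix <- max(1L, floor((px - pr) / cell)):min(nx, ceiling((px + pr) / cell) + 1L)
        iy <- max(1L, floor((py - pr) / cell)):min(ny, ceiling((py + pr) / cell) + 1L)
        cx <- (ix - 0.5) * cell; cy <- (iy - 0.5) * cell
        d2 <- outer((cx - px)^2, (cy - py)^2, "+")
        mask[ix, iy] <- mask[ix, iy] | (d2 <= pr^2)
      }
    }
    noise <- matrix(0, nx, ny)
    if (config@noiseSd > 0) {
      noise <- gaussSmooth(matrix(rnorm(nx * ny), nx, ny), sigmaCells = 3)
      noise <- noise / sd(as.vector(noise)) * config@noiseSd
    }
    ycoordKm <- (seq_len(ny) - 0.5) * cell / 1000
    static <- noise -
      config@refugiaCoolingDegC * mask -
      matrix(rep(config@latGradientDegCPerKm * ycoordKm, each = nx), nx, ny)

    dts <- seasonDates(config@year)
    t0 <- as.POSIXct(paste(dts$may1, "00:00:00"), tz = "UTC")
    t1 <- as.POSIXct(paste(dts$sep15, "23:00:00"), tz = "UTC")
    hours <- seq(t0, t1, by = 3600)
    hodLocal <- (as.numeric(hours - t0, units = "hours") %% 24 + 1) %% 24
    dayFrac <- as.numeric(hours - t0, units = "days") /
      as.numeric(t1 - t0, units = "days")
    offset <- config@baseMeanTemp +
      config@diurnalAmplitude * cos(2 * pi * (hodLocal - 15) / 24) +
      config@seasonalWarmingDegC * dayFrac

    new("TemperatureCube",
        x0 = 0, y0 = 0, cellSize = cell,
        staticField = static, hourOffset = offset, hours = hours,
        patchMask = mask,
        meta = list(patches = patches,
                    populationCenters = populationCenters(config),
                    cooling = config@refugiaCoolingDegC,
                    latGradientDegCPerKm = config@latGradientDegCPerKm))
  })
}

## Piecewise-linear seasonal NDVI baseline: steep decline from May into
## late June as grasslands dry out, then a slow drift at low greenness
## (so by any departure date greenness is similarly low everywhere).
ndviBaseline <- function(daysSinceMay1) {
  ifelse(daysSinceMay1 <= 31,
         0.62 - (0.62 - 0.25) * daysSinceMay1 / 31,
         0.25 - 0.0005 * (daysSinceMay1 - 31))
}

#' Generate the NDVI composite series
#'
#' 8-day composites at 250 m: a shared seasonal baseline declining from
#' 0.62 (May 1) to 0.25 (Jul 10) plus a static smoothed spatial pattern
#' and small per-composite noise, clamped to `[-1, 1]`.
#'
#' @param config A [SyntheticWorldConfig-class].
#' @return An [NDVISeries-class].
#' @export
generateNDVI <- function(config) {
  validObject(config)
  cell <- 250
  n <- as.integer(ceiling(config@landscapeSize / cell))
  dts <- seasonDates(config@year)
  starts <- seq(dts$may1, dts$sep15, by = 8)
  withSeed(deriveSeed(config@seed, "ndvi"), {
    spatial <- gaussSmooth(matrix(rnorm(n * n), n, n), sigmaCells = 2)
    spatial <- spatial / sd(as.vector(spatial)) * 0.04
    vals <- array(0, dim = c(n, n, length(starts)))
    for (k in seq_along(starts)) {
      base <- ndviBaseline(as.numeric(starts[k] - dts$may1) + 4)  # mid-period
      vals[, , k] <- pmin(1, pmax(-1, base + spatial +
                                    matrix(rnorm(n * n, 0, 0.01), n, n)))
    }
    new("NDVISeries", x0 = 0, y0 = 0, cellSize = cell,
        periodStarts = starts, values = vals)
  })
}

## Max distance (m) from point (x, y) along direction theta before leaving
## the margin box [m, L - m]^2.
maxFeasibleDistance <- function(x, y, theta, L, margin) {
  dx <- cos(theta); dy <- sin(theta)
  lim <- function(pos, d) {
    if (abs(d) < 1e-12) return(Inf)
    if (d > 0) (L - margin - pos) / d else (margin - pos) / d
  }
  max(0, min(lim(x, dx), lim(y, dy)))
}

#' Generate GPS tracks over a thermal landscape
#'
#' Each individual breeds in a home range near its population centre
#' (correlated random walk, fixes at the configured cadence around the
#' clock, ground fixes at speed 0 with occasional in-flight fixes at
#' 5-15 m/s). Departure dates follow the NDVI decline; post-breeding
#' displacement is drawn as `exp(a + b * z(availability) + e)` where
#' `availability` is the individual's mean breeding refugia-availability
#' statistic (buffer minimum minus median, averaged over its generated
#' breeding-season fixes) and `z()` standardises across the world's
#' individuals. Draws below `residentThresholdKm` stay
#' resident. Candidate destinations at the drawn distance are weighted by
#' how well their microclimate matches the breeding conditions (after
#' discounting the shared seasonal warming), with strength `betaTracking`;
#' infeasible destinations (outside the landscape) trigger a re-draw of a
#' feasible distance with a logged warning.
#'
#' @param config A [SyntheticWorldConfig-class].
#' @param cube The [TemperatureCube-class] for the same config.
#' @return A `data.frame` of fixes (`individual_id`, `population`,
#'   `timestamp`, `x`, `y`, `speed_ms`) with a `truth` attribute holding
#'   the per-individual generating values (availability, drawn distance,
#'   residency, departure date, destination).
#' @export
generateTracks <- function(config, cube) {
  validObject(config)
  dts <- seasonDates(config@year)
  t0 <- as.POSIXct(paste(dts$may1, "00:00:00"), tz = "UTC")
  tEnd <- as.POSIXct(paste(dts$sep15, "23:59:59"), tz = "UTC")
  L <- config@landscapeSize
  margin <- 650
  ctr <- cube@meta$populationCenters %||% populationCenters(config)
  nInd <- config@individualsPerPopulation
  static <- cube@staticField

  withSeed(deriveSeed(config@seed, "tracks"), {
    ## individual table -------------------------------------------------
    ind <- do.call(rbind, lapply(seq_len(config@nPopulations), function(p) {
      k <- nInd[p]
      data.frame(
        individual_id = sprintf("P%d_I%02d", p, seq_len(k)),
        population = sprintf("pop%d", p),
        hrX = pmin(L - margin, pmax(margin, rnorm(k, ctr[p, 1], 700))),
        hrY = pmin(L - margin, pmax(margin, rnorm(k, ctr[p, 2], 700))))
    }))
    n <- nrow(ind)

    ## departure follows the NDVI collapse with a lag: greenness bottoms
    ## out by early June and birds leave around mid June
    depBase <- 44
    depDay <- pmin(85, pmax(25, round(depBase + rnorm(n, 0, 8))))
    ind$departureDate <- dts$may1 + depDay

    ## breeding-phase fixes, then the availability statistic ------------
    dt <- config@fixIntervalMinutes * 60
    rho <- exp(-dt / (6 * 3600))
    innovSd <- config@homeRangeSd * sqrt(1 - rho^2)
    captureDate <- dts$may1 - sample(1:11, n, replace = TRUE)
    ouTrack <- function(nf, cX, cY) {
      ex <- rnorm(nf, 0, innovSd); ey <- rnorm(nf, 0, innovSd)
      cbind(cX + as.numeric(stats::filter(ex, rho, "recursive",
                                          init = rnorm(1, 0, config@homeRangeSd))),
            cY + as.numeric(stats::filter(ey, rho, "recursive",
                                          init = rnorm(1, 0, config@homeRangeSd))))
    }
    breedXY <- vector("list", n)
    for (i in seq_len(n)) {
      tsq <- seq(as.POSIXct(paste(captureDate[i], "00:00:00"), tz = "UTC"),
                 as.POSIXct(paste(ind$departureDate[i], "09:00:00"),
                            tz = "UTC") - 1, by = dt)
      breedXY[[i]] <- cbind(ouTrack(length(tsq), ind$hrX[i], ind$hrY[i]),
                            as.numeric(tsq))
    }
    avail <- vapply(seq_len(n), function(i) {
      xy <- breedXY[[i]]
      bs <- .bufferStatsCpp(static, cube@x0, cube@y0, cube@cellSize,
                            xy[, 1], xy[, 2], 500)
      mean(bs[, "min"] - bs[, "median"])
    }, 0)
    ind$availability <- avail
    bsc <- .bufferStatsCpp(static, cube@x0, cube@y0, cube@cellSize,
                           ind$hrX, ind$hrY, 500)
    ind$breedMedian <- bsc[, "median"]
    sdA <- sd(ind$availability)
    ind$zAvailability <-
      if (is.finite(sdA) && sdA > 0)
        (ind$availability - mean(ind$availability)) / sdA else 0

    ## displacement draw ------------------------------------------------
    lnd <- config@distanceInterceptLnKm +
      config@betaRefugiaDistance * ind$zAvailability +
      rnorm(n, 0, config@distanceSdLn)
    ind$distanceKm <- exp(lnd)
    ind$resident <- ind$distanceKm < config@residentThresholdKm
    ind$departureDate[ind$resident] <- NA

    ## destination choice -----------------------------------------------
    midSeason <- as.numeric(dts$sep15 - dts$may1)
    ind$destX <- ind$hrX; ind$destY <- ind$hrY; ind$clamped <- FALSE
    for (i in which(!ind$resident)) {
      dM <- ind$distanceKm[i] * 1000
      theta <- (seq_len(24) - 1) / 24 * 2 * pi + runif(1, 0, 2 * pi / 24)
      dmax <- vapply(theta, function(th)
        maxFeasibleDistance(ind$hrX[i], ind$hrY[i], th, L, margin), 0)
      feas <- which(dmax >= dM)
      if (!length(feas)) {
        dM <- 0.95 * max(dmax)
        ind$clamped[i] <- TRUE
        ind$distanceKm[i] <- dM / 1000
        warning(sprintf("%s: drawn displacement infeasible; clamped to %.1f km",
                        ind$individual_id[i], dM / 1000), call. = FALSE)
        feas <- which(dmax >= dM)
      }
      cx <- ind$hrX[i] + dM * cos(theta[feas])
      cy <- ind$hrY[i] + dM * sin(theta[feas])
      cs <- .bufferStatsCpp(static, cube@x0, cube@y0, cube@cellSize, cx, cy, 500)
      depDayI <- as.numeric(ind$departureDate[i] - dts$may1)
      warmDelta <- config@seasonalWarmingDegC *
        ((depDayI + midSeason) / 2 - depDayI / 2) / midSeason
      mism <- sqrt((cs[, "median"] - (ind$breedMedian[i] - warmDelta))^2 +
                   ((cs[, "min"] - cs[, "median"]) - ind$availability[i])^2)
      w <- exp(-config@betaTracking * mism)
      pick <- sample.int(length(feas), 1, prob = w / sum(w))
      ind$destX[i] <- cx[pick]; ind$destY[i] <- cy[pick]
    }

    ## fix streams ------------------------------------------------------
    oneYear <- function(i, yearShiftDays = 0, jitterSd = 0) {
      bb <- breedXY[[i]]
      tsB <- as.POSIXct(bb[, 3], tz = "UTC", origin = "1970-01-01")
      t2 <- seq(tsB[length(tsB)] + dt, tEnd, by = dt)
      spd2 <- numeric(length(t2))
      if (ind$resident[i]) {
        xy2 <- ouTrack(length(t2), ind$hrX[i], ind$hrY[i])
      } else {
        depT <- tsB[length(tsB)] + 1
        trav <- t2 < depT + 86400
        xy2 <- matrix(NA_real_, length(t2), 2)
        if (any(trav)) {
          f <- as.numeric(t2[trav] - depT, units = "secs") / 86400
          xy2[trav, 1] <- ind$hrX[i] + f * (ind$destX[i] - ind$hrX[i])
          xy2[trav, 2] <- ind$hrY[i] + f * (ind$destY[i] - ind$hrY[i])
          spd2[trav] <- runif(sum(trav), 8, 15)
        }
        xy2[!trav, ] <- ouTrack(sum(!trav), ind$destX[i], ind$destY[i])
      }
      tsq <- c(tsB, t2)
      xy <- rbind(bb[, 1:2, drop = FALSE], xy2)
      spd <- c(numeric(length(tsB)), spd2)
      flight <- spd == 0 & runif(length(spd)) < config@flightFixProb
      spd[flight] <- runif(sum(flight), 5, 15)
      if (jitterSd > 0) xy <- xy + rnorm(2 * nrow(xy), 0, jitterSd)
      data.frame(individual_id = ind$individual_id[i],
                 population = ind$population[i],
                 timestamp = tsq - yearShiftDays * 86400,
                 x = xy[, 1], y = xy[, 2], speed_ms = spd)
    }
    fixes <- do.call(rbind, lapply(seq_len(n), oneYear))
    nMulti <- ceiling(config@multiYearFraction * n)
    if (nMulti > 0) {
      prev <- do.call(rbind, lapply(seq_len(nMulti), function(i)
        oneYear(i, yearShiftDays = 365, jitterSd = 40)))
      fixes <- rbind(prev, fixes)
    }
    fixes <- fixes[order(fixes$individual_id, fixes$timestamp), ]
    rownames(fixes) <- NULL
    attr(fixes, "truth") <- ind
    fixes
  })
}

#' Generate a complete synthetic world
#'
#' Landscape, NDVI series and tracks from one config; deterministic given
#' `config@seed`.
#'
#' @param config A [SyntheticWorldConfig-class].
#' @return List with elements `cube`, `ndvi`, `fixes` and `truth` (the
#'   per-individual generating table).
#' @export
simulateWorld <- function(config) {
  cube <- generateLandscape(config)
  ndvi <- generateNDVI(config)
  fixes <- generateTracks(config, cube)
  list(cube = cube, ndvi = ndvi, fixes = fixes, truth = attr(fixes, "truth"))
}

#' Write or read a tracking table
#'
#' CSV with columns `individual_id`, `population`, `timestamp` (ISO-8601
#' UTC), `x`, `y`, `speed_ms`. `readFixes()` also accepts files with
#' other column names through `columnMap` (ours = theirs), e.g. Movebank
#' exports.
#'
#' @param fixes Fix table as produced by [generateTracks()].
#' @param path File path.
#' @return `writeFixesCSV()`: `path` invisibly; `readFixes()`: the fix
#'   table with `timestamp` parsed as `POSIXct` UTC.
#' @export
writeFixesCSV <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname writeFixesCSV
#' @param columnMap Optional named character vector mapping the package's
#'   column names to the file's column names.
#' @export
readFixes <- function(path, columnMap = NULL) {
  dt <- data.table::fread(path, data.table = FALSE)
  if (!is.null(columnMap))
    for (ours in names(columnMap))
      if (columnMap[[ours]] %in% names(dt))
        names(dt)[names(dt) == columnMap[[ours]]] <- ours
  need <- c("individual_id", "population", "timestamp", "x", "y")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("fix table lacks columns: ", paste(miss, collapse = ", "))
  dt$timestamp <- as.POSIXct(dt$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                            "%Y-%m-%d %H:%M:%OS"))
  dt
}
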