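#' @include AllClasses.R
NULL

#' Materialise one hourly temperature slice
#'
#' @param cube A [TemperatureCube-class].
#' @param hour Either an integer index into the hour axis or a `POSIXct`
#'   matched to the nearest hour.
#' @return Numeric matrix `[ix, iy]` of temperatures (degC) at that hour.
#' @export
setGeneric("tempSlice", function(cube, hour) standardGeneric("tempSlice"))

#' @rdname tempSlice
setMethod("tempSlice", "TemperatureCube", function(cube, hour) {
  i <- matchHour(cube, hour)
  if (is.na(i)) stop("hour outside the cube's time axis")
  cube@staticField + cube@hourOffset[i]
})

#' Hour axis of a temperature cube
#' @param cube A [TemperatureCube-class].
#' @return `POSIXct` vector of slice timestamps (UTC).
#' @export
setGeneric("cubeHours", function(cube) standardGeneric("cubeHours"))

#' @rdname cubeHours
setMethod("cubeHours", "TemperatureCube", function(cube) cube@hours)

#' Ground-truth refugia patch mask of a synthetic cube
#' @param cube A [TemperatureCube-class].
#' @return Logical matrix `[ix, iy]`; TRUE inside a refugia patch.
#' @export
setGeneric("patchMask", function(cube) standardGeneric("patchMask"))

#' @rdname patchMask
setMethod("patchMask", "TemperatureCube", function(cube) cube@patchMask)

#' Area of a kernel niche region
#' @param region A [NicheRegion-class].
#' @return Area in squared grid units (PC units^2 or m^2).
#' @export
setGeneric("nicheArea", function(region) standardGeneric("nicheArea"))

#' @rdname nicheArea
setMethod("nicheArea", "NicheRegion", function(region) region@area)

#' Centroid of a kernel niche region
#' @param region A [NicheRegion-class].
#' @return Numeric `(x, y)`: the area-weighted centroid of the region.
#' @export
setGeneric("nicheCentroid", function(region) standardGeneric("nicheCentroid"))

#' @rdname nicheCentroid
setMethod("nicheCentroid", "NicheRegion", function(region) region@centroid)

#' Number of retained principal axes
#' @param model A [NicheModel-class].
#' @return Integer count of axes retained under the cumulative-variance rule.
#' @export
setGeneric("retainedAxes", function(model) standardGeneric("retainedAxes"))

#' @rdname retainedAxes
setMethod("retainedAxes", "NicheModel", function(model) model@retained)

#' Per-axis variance fractions
#' @param model A [NicheModel-class].
#' @return Numeric vector of variance fractions, non-increasing.
#' @export
setGeneric("axisVariance", function(model) standardGeneric("axisVariance"))

#' @rdname axisVariance
setMethod("axisVariance", "NicheModel", function(model) model@varFrac)

setMethod("show", "SyntheticWorldConfig", function(object) {
  cat("SyntheticWorldConfig\n")
  cat(sprintf("  %d populations, %s individuals, year %d, seed %d\n",
              object@nPopulations,
              paste(object@individualsPerPopulation, collapse = "/"),
              as.integer(object@year), as.integer(object@seed)))
  cat(sprintf("  landscape %.0f m @ %.0f m cells; patch density %s /km^2; cooling %.1f degC\n",
              object@landscapeSize, object@cellSize,
              paste(object@refugiaPatchDensity, collapse = "/"),
              object@refugiaCoolingDegC))
  cat(sprintf("  beta(refugia->ln distance) = %.2f; beta(tracking) = %.2f\n",
              object@betaRefugiaDistance, object@betaTracking))
})

setMethod("show", "TemperatureCube", function(object) {
  d <- dim(object@staticField)
  cat("TemperatureCube\n")
  cat(sprintf("  grid %d x %d @ %.0f m, origin (%.0f, %.0f)\n",
              d[1], d[2], object@cellSize, object@x0, object@y0))
  cat(sprintf("  %d hourly slices, %s .. %s UTC\n", length(object@hours),
              format(min(object@hours)), format(max(object@hours))))
  cat(sprintf("  refugia patch cells: %d (%.1f%%)\n", sum(object@patchMask),
              100 * mean(object@patchMask)))
})

setMethod("show", "NDVISeries", function(object) {
  d <- dim(object@values)
  cat("NDVISeries\n")
  cat(sprintf("  grid %d x %d @ %.0f m; %d composites (8-day), %s .. %s\n",
              d[1], d[2], object@cellSize, d[3],
              format(min(object@periodStarts)), format(max(object@periodStarts))))
})

setMethod("show", "NicheModel", function(object) {
  cat("NicheModel (standardised PCA of microclimate variables)\n")
  cat(sprintf("  axis variance: %s\n",
              paste(sprintf("%.1f%%", 100 * object@varFrac), collapse = " ")))
  cat(sprintf("  retained axes: %d (cumulative > %.0f%%)\n",
              object@retained, 100 * object@threshold))
})

setMethod("show", "NicheRegion", function(object) {
  lab <- paste(unlist(object@meta[c("level", "season", "year")]), collapse = " / ")
  cat(sprintf("NicheRegion [%s space]%s\n", object@space,
              if (nzchar(lab)) paste0(" ", lab) else ""))
  cat(sprintf("  %.1f%% kernel region: area %.4g, centroid (%.3f, %.3f)\n",
              100 * object@mass, object@area,
              object@centroid[1], object@centroid[2]))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  speedTol %.2f m/s; daylight %d-%d h (breeding), %d-%d h (post)\n",
              object@speedTol, object@breedingWindow[1], object@breedingWindow[2],
              object@postWindow[1], object@postWindow[2]))
  cat(sprintf("  departure rule: %d days away; buffer %.0f m; kernels %.1f%%/%.0f%%\n",
              as.integer(object@minAwayDays), object@bufferRadius,
              100 * object@nicheMass, 100 * object@udMass))
  cat(sprintf("  seed %d; outDir '%s'\n", as.integer(object@seed), object@outDir))
})

## Nearest-hour matching of timestamps to the cube axis; NA when more than
## half an hour outside the axis.
matchHour <- function(cube, hour) {
  if (is.numeric(hour)) {
    i <- as.integer(hour)
    i[i < 1L | i > length(cube@hours)] <- NA_integer_
    return(i)
  }
  h <- as.numeric(difftime(hour, cube@hours[1], units = "hours"))
  i <- as.integer(round(h)) + 1L
  i[i < 1L | i > length(cube@hours)] <- NA_integer_
  i
}
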