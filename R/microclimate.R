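## Buffer temperature statistics and refugia metrics per fix, and the
## pre-departure NDVI covariate per individual.

#' Names of the eight microclimate niche variables
#' @return Character vector in canonical order.
#' @export
nicheVariables <- function() {
  c("point_temp", "buffer_mean", "buffer_median", "buffer_max",
    "buffer_min", "buffer_sd", "refugia_use", "refugia_availability")
}

#' Buffer temperature statistics and refugia metrics
#'
#' For each fix, temperature statistics (mean, median, maximum, minimum,
#' standard deviation) over all grid cells whose centres lie within
#' `radiusM` of the fix, at the cube hour nearest the fix timestamp,
#' plus the temperature of the cell containing the fix and the two
#' refugia metrics:
#' `refugia_use = point_temp - buffer_median` and
#' `refugia_availability = buffer_min - buffer_median` (both more
#' negative where cool refugia are used/available; availability can never
#' be positive). The median uses midpoint interpolation on even cell
#' counts and the standard deviation the n-1 denominator.
#'
#' Fixes whose buffer has under `minCoverage` of its cells inside the
#' grid, whose timestamp misses the hour axis, or whose own cell is
#' outside the grid are flagged invalid (`valid = FALSE`, statistics NA).
#'
#' @param fixes Fix table with `timestamp`, `x`, `y`.
#' @param cube A [TemperatureCube-class].
#' @param radiusM Buffer radius, metres (default 500).
#' @param minCoverage Minimum fraction of buffer cells inside the grid
#'   (default 0.5).
#' @return `fixes` with the eight variables of [nicheVariables()] plus
#'   `valid` appended.
#' @export
bufferStats <- function(fixes, cube, radiusM = 500, minCoverage = 0.5) {
  stopifnot(is(cube, "TemperatureCube"))
  n <- nrow(fixes)
  hi <- matchHour(cube, fixes$timestamp)
  raw <- .bufferStatsCpp(cube@staticField, cube@x0, cube@y0, cube@cellSize,
                         fixes$x, fixes$y, radiusM)
  off <- ifelse(is.na(hi), NA_real_, cube@hourOffset[hi])
  out <- fixes
  out$point_temp <- raw[, "point"] + off
  out$buffer_mean <- raw[, "mean"] + off
  out$buffer_median <- raw[, "median"] + off
  out$buffer_max <- raw[, "max"] + off
  out$buffer_min <- raw[, "min"] + off
  out$buffer_sd <- raw[, "sd"]
  out$refugia_use <- raw[, "point"] - raw[, "median"]
  out$refugia_availability <- raw[, "min"] - raw[, "median"]
  out$valid <- !is.na(hi) & !is.na(raw[, "point"]) &
    raw[, "coverage"] >= minCoverage
  bad <- !out$valid
  if (any(bad))
    out[bad, nicheVariables()] <- NA_real_
  out
}

#' Pre-departure NDVI covariate
#'
#' Mean NDVI over the 8 days before the reference date (the departure
#' date for migrants, the end of the breeding season, Jul 15, for
#' residents), averaged spatially over the individual's breeding area.
#' Composites partially overlapping the window are weighted by the number
#' of days of overlap. With no overlapping composite the value is `NA`
#' (such individuals are dropped from the distance model with a logged
#' reason).
#'
#' @param ndvi An [NDVISeries-class].
#' @param breedingRegion Geographic [NicheRegion-class] delimiting the
#'   breeding area (its member cells select the NDVI cells averaged; if
#'   none overlap, the NDVI cell containing the region centroid is used).
#' @param refDate Reference `Date` (departure or breeding-season end).
#' @param windowDays Averaging window length, days (default 8).
#' @return Scalar mean NDVI, or `NA` if no composite overlaps the window.
#' @export
ndviPreDeparture <- function(ndvi, breedingRegion, refDate, windowDays = 8) {
  stopifnot(is(ndvi, "NDVISeries"), inherits(refDate, "Date"))
  win0 <- refDate - windowDays
  win1 <- refDate                                  # window is [win0, win1)
  starts <- ndvi@periodStarts
  ends <- starts + 8
  ovl <- pmin(as.numeric(win1 - starts), as.numeric(ends - win0), 8, windowDays)
  ovl <- pmax(ovl, 0)
  if (all(ovl == 0)) return(NA_real_)

  nx <- dim(ndvi@values)[1]; ny <- dim(ndvi@values)[2]
  cx <- ndvi@x0 + (seq_len(nx) - 0.5) * ndvi@cellSize
  cy <- ndvi@y0 + (seq_len(ny) - 0.5) * ndvi@cellSize
  grid <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  inside <- containsPoints(breedingRegion, grid)
  if (!any(inside)) {
    ctr <- nicheCentroid(breedingRegion)
    ix <- min(nx, max(1L, as.integer(floor((ctr[1] - ndvi@x0) / ndvi@cellSize)) + 1L))
    iy <- min(ny, max(1L, as.integer(floor((ctr[2] - ndvi@y0) / ndvi@cellSize)) + 1L))
    sel <- matrix(FALSE, nx, ny); sel[ix, iy] <- TRUE
  } else {
    sel <- matrix(inside, nx, ny)
  }
  vals <- vapply(which(ovl > 0), function(k) mean(ndvi@values[, , k][sel]), 0)
  sum(vals * ovl[ovl > 0]) / sum(ovl)
}
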