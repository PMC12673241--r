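## Fix-level filters, season assignment and individual-inclusion rules.

#' Filter GPS fixes (null velocity, daylight windows)
#'
#' Retains fixes on the ground (speed at most `speedTol`, default exactly
#' 0) and, where a `season` column is present, daylight fixes: local hour
#' 06-17 in the breeding season and 07-20 in post-breeding. Duplicate
#' timestamps within an individual are dropped first (keeping the first
#' record), so retained timestamps are strictly increasing per
#' individual. Every removed fix is accounted for in the `exclusions`
#' attribute with a named reason, and removal counts per rule are in the
#' `log` attribute; the filter is idempotent.
#'
#' If the table has no `speed_ms` column, step speeds are computed from
#' consecutive displacements per individual, with a warning.
#'
#' @param fixes Fix table (`individual_id`, `timestamp`, `x`, `y`,
#'   optionally `speed_ms` and `season`).
#' @param speedTol Null-velocity tolerance in m/s (default 0).
#' @param tzOffset Local time = UTC + `tzOffset` hours (default 1).
#' @param breedingWindow,postWindow Inclusive local-hour windows.
#' @return Filtered fix table with attributes `exclusions` (removed rows
#'   plus `reason`) and `log` (counts removed per rule).
#' @export
filterFixes <- function(fixes, speedTol = 0, tzOffset = 1,
                        breedingWindow = c(6, 17), postWindow = c(7, 20)) {
  if (nrow(fixes) == 0) {
    attr(fixes, "exclusions") <- cbind(fixes[0, ], reason = character())
    attr(fixes, "log") <- c(duplicate_timestamp = 0L, nonzero_speed = 0L,
                            outside_daylight = 0L)
    return(fixes)
  }
  ord <- order(fixes$individual_id, fixes$timestamp)
  fixes <- fixes[ord, , drop = FALSE]
  reason <- rep(NA_character_, nrow(fixes))

  dup <- duplicated(fixes[, c("individual_id", "timestamp")])
  reason[dup] <- "duplicate_timestamp"

  if (is.null(fixes$speed_ms)) {
    warning("no speed_ms column; deriving step speeds from displacements")
    spl <- split(seq_len(nrow(fixes)), fixes$individual_id)
    fixes$speed_ms <- 0
    for (ii in spl) {
      if (length(ii) < 2) next
      d <- sqrt(diff(fixes$x[ii])^2 + diff(fixes$y[ii])^2)
      dt <- pmax(as.numeric(diff(fixes$timestamp[ii]), units = "secs"), 1)
      fixes$speed_ms[ii] <- c(0, d / dt)
    }
  }
  bad <- is.na(reason) & fixes$speed_ms > speedTol
  reason[bad] <- "nonzero_speed"

  if (!is.null(fixes$season)) {
    hr <- localHour(fixes$timestamp, tzOffset)
    inWin <- rep(TRUE, nrow(fixes))
    b <- !is.na(fixes$season) & fixes$season == "breeding"
    p <- !is.na(fixes$season) & fixes$season == "post_breeding"
    inWin[b] <- hr[b] >= breedingWindow[1] & hr[b] <= breedingWindow[2]
    inWin[p] <- hr[p] >= postWindow[1] & hr[p] <= postWindow[2]
    bad <- is.na(reason) & !inWin
    reason[bad] <- "outside_daylight"
  }

  keep <- is.na(reason)
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  excl <- cbind(fixes[!keep, , drop = FALSE], reason = reason[!keep])
  attr(out, "exclusions") <- excl
  attr(out, "log") <- c(
    duplicate_timestamp = sum(reason == "duplicate_timestamp", na.rm = TRUE),
    nonzero_speed = sum(reason == "nonzero_speed", na.rm = TRUE),
    outside_daylight = sum(reason == "outside_daylight", na.rm = TRUE))
  out
}

## Minimum distance (m) from points to a geographic niche region.
distToRegion <- function(region, pts) {
  idx <- which(region@mask, arr.ind = TRUE)
  cx <- region@xgrid[idx[, 1]]
  cy <- region@ygrid[idx[, 2]]
  d2 <- outer(pts[, 1], cx, "-")^2 + outer(pts[, 2], cy, "-")^2
  sqrt(apply(d2, 1, min))
}

#' Detect post-breeding departure for one individual-year
#'
#' The breeding area is the 90% kernel region of the individual's May
#' fixes, buffered by `bufferM` (default 1 km). The departure date is the
#' first date after which the daily fix centroid stays outside that
#' buffered area for at least `minAwayDays` consecutive days; a return
#' within the window rejects the candidate. Individuals that never
#' qualify are residents, with the post-breeding window fixed at
#' Jul 15 - Sep 15. If tracking ends less than `minAwayDays` after a
#' candidate with no observed return, the individual is flagged
#' `indeterminate`.
#'
#' @param fixes Speed-filtered fixes of one individual covering one season
#'   (one calendar year).
#' @param minAwayDays Consecutive days away defining departure (default 30).
#' @param udMass Kernel mass of the breeding area (default 0.90).
#' @param bufferM Buffer around the breeding area, metres (default 1000).
#' @param minRegionFixes Minimum May fixes needed to define the breeding
#'   area (default 5).
#' @param gridsize Kernel grid for the breeding area.
#' @return List with `assignment` (one-row data.frame: `individual_id`,
#'   `year`, `status`, `departure_date`, `post_start`, `post_end`,
#'   `capture_date`) and `breedingRegion` (a geographic
#'   [NicheRegion-class], or `NULL` when indeterminate).
#' @export
detectDeparture <- function(fixes, minAwayDays = 30, udMass = 0.90,
                            bufferM = 1000, minRegionFixes = 5,
                            gridsize = c(200, 200)) {
  stopifnot(length(unique(fixes$individual_id)) == 1)
  id <- fixes$individual_id[1]
  dates <- as.Date(fixes$timestamp, tz = "UTC")
  year <- as.integer(format(max(dates), "%Y"))
  dts <- seasonDates(year)
  capture <- min(dates)
  base <- data.frame(individual_id = id, year = year, status = "indeterminate",
                     departure_date = as.Date(NA), post_start = as.Date(NA),
                     post_end = as.Date(NA), capture_date = capture,
                     stringsAsFactors = FALSE)
  mayIdx <- dates >= dts$may1 & dates < dts$may1 + 31
  if (sum(mayIdx) < minRegionFixes)
    return(list(assignment = base, breedingRegion = NULL))
  region <- kernelRegion(cbind(fixes$x[mayIdx], fixes$y[mayIdx]),
                         mass = udMass, gridsize = gridsize, bwMin = 30,
                         space = "geo",
                         meta = list(level = "individual", season = "breeding",
                                     year = year, individual_id = id))

  keep <- dates >= dts$may1
  cent <- stats::aggregate(cbind(x, y) ~ date,
                           data = data.frame(date = dates[keep],
                                             x = fixes$x[keep],
                                             y = fixes$y[keep]),
                           FUN = mean)
  cent <- cent[order(cent$date), ]
  cent$outside <- distToRegion(region, cbind(cent$x, cent$y)) > bufferM
  lastDate <- max(cent$date)

  departure <- as.Date(NA)
  status <- "resident"
  i <- 1L
  while (i <= nrow(cent)) {
    if (!cent$outside[i]) { i <- i + 1L; next }
    cand <- cent$date[i]
    win <- cent$date >= cand & cent$date < cand + minAwayDays
    if (any(!cent$outside[win])) {
      ## brief return: resume scanning after the first inside day
      i <- which(win & !cent$outside)[1] + 1L
      next
    }
    if (as.numeric(lastDate - cand) < minAwayDays - 1) {
      status <- "indeterminate"
      break
    }
    departure <- cand
    status <- "migrant"
    break
  }
  base$status <- status
  if (status == "migrant") {
    base$departure_date <- departure
    base$post_start <- departure
    base$post_end <- dts$sep15
  } else if (status == "resident") {
    base$post_start <- dts$jul15
    base$post_end <- dts$sep15
  }
  list(assignment = base, breedingRegion = region)
}

#' Season assignments for all individual-years
#'
#' Runs [detectDeparture()] per individual and calendar year.
#'
#' @param fixes Speed-filtered fix table (all individuals).
#' @param ... Passed to [detectDeparture()].
#' @return List with `assignments` (data.frame, one row per
#'   individual-year) and `breedingRegions` (named list keyed
#'   `"id.year"`).
#' @export
seasonAssignments <- function(fixes, ...) {
  yr <- format(as.Date(fixes$timestamp, tz = "UTC"), "%Y")
  key <- paste(fixes$individual_id, yr, sep = ".")
  parts <- split(seq_len(nrow(fixes)), key)
  res <- lapply(parts, function(ii) detectDeparture(fixes[ii, , drop = FALSE], ...))
  assignments <- do.call(rbind, lapply(res, `[[`, "assignment"))
  rownames(assignments) <- NULL
  regions <- lapply(res, `[[`, "breedingRegion")
  names(regions) <- names(parts)
  list(assignments = assignments, breedingRegions = regions)
}

#' Apply individual-inclusion and last-year rules
#'
#' Excludes individual-years captured on or after May 1, with fewer than
#' 7 tracked days before departure, or with an indeterminate departure;
#' for individuals tracked in several years, keeps only the most recent
#' year that survives the other rules.
#'
#' @param assignments Assignment table from [seasonAssignments()].
#' @param minPreDepartureDays Minimum tracked days before departure
#'   (default 7).
#' @return The table with `included` (logical) and `exclusion_reason`.
#' @export
applyInclusionRules <- function(assignments, minPreDepartureDays = 7) {
  a <- assignments
  a$included <- TRUE
  a$exclusion_reason <- NA_character_
  for (i in seq_len(nrow(a))) {
    may1 <- seasonDates(a$year[i])$may1
    if (a$status[i] == "indeterminate") {
      a$included[i] <- FALSE; a$exclusion_reason[i] <- "indeterminate_departure"
    } else if (a$capture_date[i] >= may1) {
      a$included[i] <- FALSE; a$exclusion_reason[i] <- "captured_after_may1"
    } else if (a$status[i] == "migrant" &&
               as.numeric(a$departure_date[i] - a$capture_date[i]) <
                 minPreDepartureDays) {
      a$included[i] <- FALSE; a$exclusion_reason[i] <- "lt7days_predeparture"
    }
  }
  for (id in unique(a$individual_id)) {
    ii <- which(a$individual_id == id & a$included)
    if (length(ii) > 1) {
      drop <- ii[a$year[ii] != max(a$year[ii])]
      a$included[drop] <- FALSE
      a$exclusion_reason[drop] <- "not_last_year"
    }
  }
  a
}

#' Label fixes with their season
#'
#' Breeding runs from May 1 to the departure date (migrants) or to Jul 15
#' (residents); post-breeding from departure (or Jul 15) to Sep 15.
#' Fixes outside these windows, or belonging to excluded individual-years,
#' are labelled `excluded`.
#'
#' @param fixes Fix table.
#' @param assignments Assignment table from [applyInclusionRules()].
#' @return `fixes` with a `season` factor column
#'   (`breeding`/`post_breeding`/`excluded`).
#' @export
assignSeasons <- function(fixes, assignments) {
  dates <- as.Date(fixes$timestamp, tz = "UTC")
  yr <- as.integer(format(dates, "%Y"))
  key <- paste(fixes$individual_id, yr, sep = ".")
  akey <- paste(assignments$individual_id, assignments$year, sep = ".")
  m <- match(key, akey)
  season <- rep("excluded", nrow(fixes))
  ok <- !is.na(m) & assignments$included[m] %in% TRUE
  for (j in unique(m[ok])) {
    rows <- which(ok & m == j)
    a <- assignments[j, ]
    dts <- seasonDates(a$year)
    bEnd <- if (a$status == "migrant") a$departure_date else dts$jul15
    d <- dates[rows]
    season[rows][d >= dts$may1 & d < bEnd] <- "breeding"
    season[rows][d >= a$post_start & d <= a$post_end] <- "post_breeding"
  }
  fixes$season <- season
  fixes
}
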