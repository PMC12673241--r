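## Daily utilization distributions, breeding centroids and the summed
## post-breeding migration distance.

#' Daily utilization-distribution centroids for one individual
#'
#' For every date with at least `minFixes` fixes, fits the 90% bivariate
#' normal kernel region of that day's relocations (normal-reference
#' bandwidth, highest-density-region threshold — the same kernel
#' definition as the niche space, in projected metres) and records its
#' mass-weighted centroid. Because a day holds at most a few dozen
#' fixes, the kernel density is evaluated exactly on the grid rather
#' than by binned FFT. Days with fewer fixes are skipped and listed in
#' the `skipped` attribute.
#'
#' @param fixes Filtered fixes of one individual (with `season` labels).
#' @param udMass Kernel mass (default 0.90).
#' @param minFixes Minimum fixes per day (default 5).
#' @param gridsize Kernel grid per day (default 64 x 64; daily ranges
#'   span a few hundred metres, giving better than 10 m resolution).
#' @param bwMin Bandwidth floor in metres (default 30, one raster cell).
#' @return data.frame `individual_id`, `date`, `season`, `x`, `y`,
#'   `n_fixes` (one row per retained day) with skipped days in
#'   `attr(, "skipped")`.
#' @export
dailyUD <- function(fixes, udMass = 0.90, minFixes = 5,
                    gridsize = c(64, 64), bwMin = 30) {
  stopifnot(length(unique(fixes$individual_id)) == 1)
  date <- as.Date(fixes$timestamp, tz = "UTC")
  parts <- split(seq_len(nrow(fixes)), date)
  keep <- vapply(parts, length, 0L) >= minFixes
  skipped <- names(parts)[!keep]
  parts <- parts[keep]
  ctr <- vapply(parts, function(ii) {
    h <- kernelBandwidth(cbind(fixes$x[ii], fixes$y[ii]), bwMin = bwMin)
    .kdeHdrCentroidCpp(fixes$x[ii], fixes$y[ii], h[1], h[2],
                       as.integer(gridsize[1]), as.integer(gridsize[2]),
                       udMass)
  }, numeric(3))
  out <- data.frame(
    individual_id = rep(fixes$individual_id[1], length(parts)),
    date = as.Date(names(parts)),
    season = if (!is.null(fixes$season))
      vapply(parts, function(ii) fixes$season[ii][1], "") else NA_character_,
    x = ctr[1, ], y = ctr[2, ],
    n_fixes = vapply(parts, length, 0L))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Post-breeding migration distance of one individual
#'
#' The mean breeding centroid is the mean of the breeding-season daily
#' centroids. Consecutive post-breeding daily centroids within
#' `collapseRadiusKm` of the running centroid of the current area are
#' merged into one post-breeding area (an individual can use several
#' areas in sequence). The total distance is the Euclidean distance from
#' the mean breeding centroid to the first area plus the distances
#' between consecutive areas; `ln_distance` applies the natural log after
#' flooring the total at `distanceFloorKm` so residents stay finite.
#'
#' Summing over merged areas rather than every daily centroid keeps the
#' distance independent of tracking duration; set
#' `collapseRadiusKm = 0` to obtain the literal per-day sum.
#'
#' @param daily Daily centroid table from [dailyUD()] (one individual),
#'   with `season` labels.
#' @param collapseRadiusKm Area-merge radius, km (default 5).
#' @param distanceFloorKm Floor before the log, km (default 0.5).
#' @return One-row data.frame: breeding centroid, number of post-breeding
#'   areas, `total_distance_km`, `ln_distance`; `NULL` if either season
#'   lacks days.
#' @export
migrationDistance <- function(daily, collapseRadiusKm = 5,
                              distanceFloorKm = 0.5) {
  b <- daily[daily$season %in% "breeding", , drop = FALSE]
  p <- daily[daily$season %in% "post_breeding", , drop = FALSE]
  if (nrow(b) == 0 || nrow(p) == 0) return(NULL)
  bc <- c(mean(b$x), mean(b$y))
  p <- p[order(p$date), ]

  areas <- list()
  cur <- NULL
  for (i in seq_len(nrow(p))) {
    pt <- c(p$x[i], p$y[i])
    if (is.null(cur)) { cur <- list(sum = pt, n = 1L); next }
    ctr <- cur$sum / cur$n
    if (sqrt(sum((pt - ctr)^2)) / 1000 <= collapseRadiusKm) {
      cur$sum <- cur$sum + pt; cur$n <- cur$n + 1L
    } else {
      areas[[length(areas) + 1L]] <- cur$sum / cur$n
      cur <- list(sum = pt, n = 1L)
    }
  }
  areas[[length(areas) + 1L]] <- cur$sum / cur$n

  total <- sqrt(sum((areas[[1]] - bc)^2))
  if (length(areas) > 1)
    for (i in seq_len(length(areas) - 1))
      total <- total + sqrt(sum((areas[[i + 1]] - areas[[i]])^2))
  totalKm <- total / 1000
  data.frame(individual_id = daily$individual_id[1],
             breeding_x = bc[1], breeding_y = bc[2],
             n_post_areas = length(areas),
             n_breeding_days = nrow(b), n_post_days = nrow(p),
             total_distance_km = totalKm,
             ln_distance = log(max(totalKm, distanceFloorKm)))
}
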