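## Shared fixtures and independent oracles, built in code at test time.

## Brute-force buffer statistics: explicit loop over every grid cell,
## testing cell-centre-in-circle membership, with stats::median/sd.
## Independent of the package's compiled path.
bruteBufferStats <- function(field, x0, y0, cell, fx, fy, radius) {
  nx <- nrow(field); ny <- ncol(field)
  vals <- c()
  total <- 0L
  for (ix in floor((fx - radius - x0) / cell):ceiling((fx + radius - x0) / cell)) {
    for (iy in floor((fy - radius - y0) / cell):ceiling((fy + radius - y0) / cell)) {
      cx <- x0 + (ix + 0.5) * cell
      cy <- y0 + (iy + 0.5) * cell
      if ((cx - fx)^2 + (cy - fy)^2 <= radius^2) {
        total <- total + 1L
        if (ix >= 0 && ix < nx && iy >= 0 && iy < ny)
          vals <- c(vals, field[ix + 1, iy + 1])
      }
    }
  }
  pix <- floor((fx - x0) / cell) + 1
  piy <- floor((fy - y0) / cell) + 1
  pt <- if (pix >= 1 && pix <= nx && piy >= 1 && piy <= ny)
    field[pix, piy] else NA_real_
  if (length(vals) == 0)
    return(c(point = pt, mean = NA, median = NA, max = NA, min = NA,
             sd = NA, coverage = 0, n_cells = 0))
  c(point = pt, mean = mean(vals), median = stats::median(vals),
    max = max(vals), min = min(vals),
    sd = if (length(vals) > 1) stats::sd(vals) else 0,
    coverage = length(vals) / total, n_cells = length(vals))
}

## Hand-built temperature cube over an arbitrary static field.
makeCube <- function(static, offset = 0, x0 = 0, y0 = 0, cell = 30,
                     year = 2018, nHours = NULL,
                     mask = matrix(FALSE, nrow(static), ncol(static))) {
  t0 <- as.POSIXct(sprintf("%d-05-01 00:00:00", year), tz = "UTC")
  if (is.null(nHours)) nHours <- 24L
  hours <- seq(t0, by = 3600, length.out = nHours)
  off <- rep_len(offset, nHours)
  new("TemperatureCube", x0 = x0, y0 = y0, cellSize = cell,
      staticField = static, hourOffset = off, hours = hours,
      patchMask = mask, meta = list())
}

## Hand-built NDVI series from per-period constant values (plus optional
## spatial field).
makeNDVI <- function(periodValues, start = as.Date("2018-05-01"),
                     n = 8, cell = 250) {
  vals <- array(rep(periodValues, each = n * n),
                dim = c(n, n, length(periodValues)))
  new("NDVISeries", x0 = 0, y0 = 0, cellSize = cell,
      periodStarts = seq(start, by = 8, length.out = length(periodValues)),
      values = vals)
}

## Square region mask in an arbitrary coordinate window (for analytic
## overlap geometry). Cell centres on a fine grid spanning [lo, hi].
squareRegion <- function(xlim, ylim, lo = -1, hi = 2, n = 600,
                         space = "pc") {
  g <- seq(lo + (hi - lo) / (2 * n), hi - (hi - lo) / (2 * n), length.out = n)
  mask <- outer(g >= xlim[1] & g <= xlim[2], g >= ylim[1] & g <= ylim[2], "&")
  regionFromMask(g, g, mask, space = space)
}

## Small synthetic world used across tests (cheap but full-featured).
testWorldConfig <- function(seed = 42, ...) {
  args <- list(individualsPerPopulation = c(3, 4, 4, 3, 5),
               landscapeSize = 6000, fixIntervalMinutes = 120, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(syntheticWorldConfig, args)
}

## Environment table of iid standard-normal niche variables (for PCA
## contracts that need full-rank isotropic input).
isotropicEnv <- function(n, seed = 1) {
  withr::with_seed(seed, {
    env <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    names(env) <- nicheVariables()
    env
  })
}
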