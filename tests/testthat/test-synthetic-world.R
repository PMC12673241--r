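test_that("identical config and seed give bit-identical worlds", {
  cfg <- testWorldConfig(seed = 5)
  w1 <- simulateWorld(cfg)
  w2 <- simulateWorld(cfg)
  expect_identical(w1$cube@staticField, w2$cube@staticField)
  expect_identical(w1$cube@patchMask, w2$cube@patchMask)
  expect_identical(w1$ndvi@values, w2$ndvi@values)
  expect_identical(w1$fixes, w2$fixes)
})

test_that("temperature cube honours its invariants", {
  cube <- generateLandscape(testWorldConfig(seed = 3))
  expect_true(all(is.finite(cube@staticField)))
  d <- as.numeric(diff(cubeHours(cube)), units = "hours")
  expect_true(all(abs(d - 1) < 1e-9))
  # within-patch cells are cooler than matrix cells by the configured
  # cooling on average (noise cancels in the mean)
  msk <- patchMask(cube)
  expect_gt(sum(msk), 0)
  gap <- mean(cube@staticField[!msk]) - mean(cube@staticField[msk])
  expect_equal(gap, 4, tolerance = 0.15)
})

test_that("a zero-density, noise-free landscape is flat with zero availability", {
  cfg <- testWorldConfig(seed = 2, refugiaPatchDensity = 0, noiseSd = 0,
                         latGradientDegCPerKm = 0)
  cube <- generateLandscape(cfg)
  expect_equal(sum(patchMask(cube)), 0)
  expect_equal(stats::sd(cube@staticField), 0)
  st <- bufferStats(data.frame(timestamp = cubeHours(cube)[10],
                               x = 3000, y = 3000), cube)
  expect_equal(st$refugia_availability, 0)
  expect_equal(st$refugia_use, 0)
})

test_that("patch cooling shows up exactly as min-minus-median in a clean world", {
  cfg <- testWorldConfig(seed = 9, refugiaCoolingDegC = 4, noiseSd = 0,
                         latGradientDegCPerKm = 0)
  cube <- generateLandscape(cfg)
  msk <- patchMask(cube)
  # pick a probe whose 500 m buffer contains >=1 patch cell but <50% patch
  idx <- which(msk, arr.ind = TRUE)
  probe <- NULL
  for (k in seq_len(nrow(idx))) {
    px <- (idx[k, 1] - 0.5) * 30; py <- (idx[k, 2] - 0.5) * 30
    if (px < 600 || py < 600 || px > 5400 || py > 5400) next
    st <- bufferStats(data.frame(timestamp = cubeHours(cube)[1],
                                 x = px, y = py), cube)
    probe <- st; break
  }
  expect_false(is.null(probe))
  expect_equal(probe$refugia_availability, -4)
})

test_that("excessive patch density on a tiny landscape is rejected", {
  cfg <- testWorldConfig(seed = 1, landscapeSize = 1200,
                         refugiaPatchDensity = 5000)
  expect_error(generateLandscape(cfg), "too small")
})

test_that("refugia availability shifts monotonically with patch density", {
  dens <- c(0.5, 2, 6)
  meanAvail <- vapply(dens, function(dd) {
    cfg <- testWorldConfig(seed = 77, refugiaPatchDensity = dd)
    cube <- generateLandscape(cfg)
    pts <- withr::with_seed(7, data.frame(
      timestamp = cubeHours(cube)[12],
      x = runif(150, 600, 5400), y = runif(150, 600, 5400)))
    mean(bufferStats(pts, cube)$refugia_availability)
  }, 0)
  expect_true(all(diff(meanAvail) < 0))
})

test_that("NDVI series is valid and declines from May to July", {
  ndvi <- generateNDVI(testWorldConfig(seed = 4))
  expect_true(all(ndvi@values >= -1 & ndvi@values <= 1))
  expect_true(all(as.numeric(diff(ndvi@periodStarts)) == 8))
  early <- mean(ndvi@values[, , 1])
  july <- mean(ndvi@values[, , 9])     # early July composite
  expect_gt(early, july + 0.2)
})

test_that("tracks carry the advertised structure and ground truth", {
  cfg <- testWorldConfig(seed = 21)
  cube <- generateLandscape(cfg)
  fx <- generateTracks(cfg, cube)
  tr <- attr(fx, "truth")
  expect_setequal(names(fx)[1:6],
                  c("individual_id", "population", "timestamp", "x", "y",
                    "speed_ms"))
  expect_equal(nrow(tr), sum(cfg@individualsPerPopulation))
  # refugia availability metric is never positive
  expect_true(all(tr$availability <= 0))
  # flight fixes exist so the null-velocity filter has work to do
  expect_gt(sum(fx$speed_ms > 5), 0)
  # fixes cover night hours too, so the daylight filter has work to do
  hrs <- as.integer(format(fx$timestamp, "%H"))
  expect_gt(sum(hrs < 5 | hrs > 21), 0)
})

test_that("a resident individual stays inside its breeding range", {
  cfg <- testWorldConfig(seed = 31, residentThresholdKm = 100)  # force residency
  cube <- generateLandscape(cfg)
  fx <- generateTracks(cfg, cube)
  tr <- attr(fx, "truth")
  expect_true(all(tr$resident))
  one <- fx[fx$individual_id == tr$individual_id[1] & fx$speed_ms == 0, ]
  dmax <- max(sqrt((one$x - tr$hrX[1])^2 + (one$y - tr$hrY[1])^2))
  expect_lt(dmax, 1500)     # a few home-range SDs
})

test_that("null world has no availability-distance slope; betas propagate", {
  cfg0 <- testWorldConfig(seed = 61, betaRefugiaDistance = 0,
                          individualsPerPopulation = 30)
  cube0 <- generateLandscape(cfg0)
  tr0 <- attr(generateTracks(cfg0, cube0), "truth")
  s0 <- coef(summary(lm(log(distanceKm) ~ zAvailability, tr0)))
  expect_gt(s0[2, 4], 0.01)            # no detectable slope

  cfgB <- testWorldConfig(seed = 62, betaRefugiaDistance = -0.6,
                          individualsPerPopulation = 30)
  cubeB <- generateLandscape(cfgB)
  trB <- attr(generateTracks(cfgB, cubeB), "truth")
  sB <- coef(summary(lm(log(distanceKm) ~ zAvailability,
                        trB[!trB$clamped, ])))
  expect_lt(sB[2, 1], -0.3)
  expect_lt(abs(sB[2, 1] + 0.6), 3 * sB[2, 2])
})

test_that("fixes CSV round-trips including column aliasing", {
  cfg <- testWorldConfig(seed = 8, individualsPerPopulation = 1)
  w <- simulateWorld(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFixesCSV(w$fixes, path)
  rd <- readFixes(path)
  expect_equal(nrow(rd), nrow(w$fixes))
  expect_equal(rd$x, w$fixes$x)
  expect_s3_class(rd$timestamp, "POSIXct")
  # Movebank-style aliases via columnMap
  dt <- data.table::fread(path)
  data.table::setnames(dt, c("individual_id", "x", "y"),
                       c("individual-local-identifier", "utm-easting",
                         "utm-northing"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, path2)
  rd2 <- readFixes(path2, columnMap = c(
    individual_id = "individual-local-identifier",
    x = "utm-easting", y = "utm-northing"))
  expect_equal(rd2$x, rd$x)
})
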