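test_that("PCA loadings are orthonormal with diagonal score covariance", {
  env <- isotropicEnv(3000, seed = 11)
  # induce correlation so the axes are non-trivial
  env$buffer_mean <- env$point_temp * 0.8 + env$buffer_mean * 0.2
  env$buffer_min <- env$buffer_median * 0.6 + env$refugia_availability * 0.4
  m <- fitNichePCA(env)
  L <- m@loadings
  expect_equal(t(L) %*% L, diag(8), tolerance = 1e-8, ignore_attr = TRUE)
  S <- nicheScores(m, env)
  C <- stats::cov(S)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-8)
  expect_equal(unname(sort(diag(C), decreasing = TRUE)),
               sort(m@varFrac * sum(diag(C)), decreasing = TRUE),
               tolerance = 1e-8)
})

test_that("isotropic input spreads variance evenly across all eight axes", {
  env <- isotropicEnv(1e5, seed = 2)
  m <- fitNichePCA(env)
  expect_equal(axisVariance(m), rep(1 / 8, 8), tolerance = 0.02)
})

test_that("retention keeps the smallest axis count passing 70%", {
  expect_equal(retainAxisCount(c(0.6478, 0.2074, rep(0.1448 / 6, 6))), 2L)
  expect_equal(retainAxisCount(c(0.71, rep(0.29 / 7, 7))), 1L)
  expect_equal(retainAxisCount(c(0.30, 0.25, 0.20, rep(0.0625, 4), 0)), 3L)
  # an end-to-end check: two dominant latent factors retain two axes
  env <- isotropicEnv(4000, seed = 3)
  f1 <- rnorm(4000); f2 <- rnorm(4000)
  for (v in c("point_temp", "buffer_mean", "buffer_median", "buffer_max"))
    env[[v]] <- f1 + 0.25 * rnorm(4000)
  for (v in c("refugia_availability", "refugia_use", "buffer_sd"))
    env[[v]] <- f2 + 0.25 * rnorm(4000)
  m <- fitNichePCA(env)
  expect_equal(retainedAxes(m), 2L)
})

test_that("axis signs follow temperature (PC1) and availability (PC2)", {
  cfg <- testWorldConfig(seed = 13)
  w <- simulateWorld(cfg)
  sp <- filterFixes(w$fixes)
  env <- bufferStats(sp[seq(1, nrow(sp), by = 7), ], w$cube)
  m <- fitNichePCA(env[env$valid, ])
  tempVars <- c("point_temp", "buffer_mean", "buffer_median",
                "buffer_max", "buffer_min")
  expect_gt(sum(m@loadings[tempVars, 1]), 0)
  expect_gt(m@loadings["refugia_availability", 2], 0)
})

test_that("degenerate inputs are rejected or rank-reduced", {
  env <- isotropicEnv(100, seed = 5)
  env$buffer_sd <- 1
  expect_error(fitNichePCA(env), "buffer_sd")
  # duplicated variables: rank deficiency caps the retained axes
  env2 <- isotropicEnv(500, seed = 6)
  env2$buffer_mean <- env2$point_temp
  env2$buffer_median <- env2$point_temp
  env2$buffer_max <- env2$point_temp
  env2$buffer_min <- env2$point_temp
  env2$refugia_use <- env2$refugia_availability
  env2$buffer_sd <- env2$refugia_availability
  m2 <- fitNichePCA(env2)
  expect_lte(retainedAxes(m2), 2L)
  expect_error(fitNichePCA(env2[1:5, ]), "at least")
})

test_that("kernel regions are deterministic and cover their nominal mass", {
  pts <- withr::with_seed(8, cbind(rnorm(2e4), rnorm(2e4)))
  r1 <- kernelRegion(pts, mass = 0.995)
  r2 <- kernelRegion(pts, mass = 0.995)
  expect_identical(r1@mask, r2@mask)
  expect_equal(r1@centroid, r2@centroid)
  cover <- mean(containsPoints(r1, pts))
  expect_lt(abs(cover - 0.995), 0.004)
  r90 <- kernelRegion(pts, mass = 0.90)
  expect_lt(abs(mean(containsPoints(r90, pts)) - 0.90), 0.01)
  expect_lt(nicheArea(r90), nicheArea(r1))
})

test_that("well-separated clusters yield a disconnected region", {
  pts <- withr::with_seed(9, rbind(cbind(rnorm(500), rnorm(500)),
                                   cbind(rnorm(500) + 30, rnorm(500))))
  r <- kernelRegion(pts, mass = 0.95)
  # some x-column strictly between the lobes holds no region cells
  midCols <- r@xgrid > 12 & r@xgrid < 18
  expect_true(any(rowSums(r@mask[midCols, , drop = FALSE]) == 0))
  expect_true(any(r@mask[r@xgrid < 10, ]) && any(r@mask[r@xgrid > 20, ]))
})

test_that("niche area is invariant under translation of the scores", {
  pts <- withr::with_seed(10, cbind(rnorm(3000, sd = 1.3), rnorm(3000)))
  a0 <- nicheArea(kernelRegion(pts, mass = 0.995))
  a1 <- nicheArea(kernelRegion(sweep(pts, 2, c(25, -14), "+"), mass = 0.995))
  expect_lt(abs(a1 - a0) / a0, 0.01)
})

test_that("overlap algebra: identity, disjunction, half shift", {
  A <- squareRegion(c(0, 1), c(0, 1))
  expect_equal(overlapPct(A, A), 100)
  B <- squareRegion(c(5, 6) - 4, c(0, 1))      # shifted out of A entirely
  expect_equal(overlapPct(B, A), 0)
  C <- squareRegion(c(0.5, 1.5), c(0, 1))
  expect_lt(abs(overlapPct(C, A) - 50), 1)
  expect_lt(abs(overlapPct(A, C) - 50), 1)
  # overlap is directional: reference is the denominator
  D <- squareRegion(c(0, 2), c(0, 1))
  expect_equal(overlapPct(D, A), 100)
  expect_lt(abs(overlapPct(A, D) - 50), 1)
})

test_that("regions from different niche models refuse to overlap", {
  e1 <- isotropicEnv(600, seed = 21)
  e2 <- isotropicEnv(600, seed = 22)
  m1 <- fitNichePCA(e1); m2 <- fitNichePCA(e2)
  r1 <- kernelNiche(nicheScores(m1, e1), model = m1)
  r2 <- kernelNiche(nicheScores(m2, e2), model = m2)
  expect_error(overlapPct(r1, r2), "different niche models")
})

test_that("overlap grows monotonically as the subject dilates", {
  A <- squareRegion(c(0.2, 0.8), c(0.2, 0.8))
  sizes <- c(0.3, 0.5, 0.7, 1.0)
  ov <- vapply(sizes, function(s)
    overlapPct(squareRegion(c(0.5 - s, 0.5 + s), c(0.5 - s, 0.5 + s)), A), 0)
  expect_true(all(diff(ov) >= 0))
  expect_equal(ov[4], 100)
})

test_that("seasonal dissimilarity is a centroid distance", {
  # identical seasonal score sets give zero
  pts <- withr::with_seed(30, cbind(rnorm(500), rnorm(500)))
  rA <- kernelNiche(pts, minPoints = 10)
  expect_equal(seasonalDissimilarity(rA, rA)$dissimilarity, 0)
  # 3-4-5 triangle via two unit squares centred at (0,0) and (3,4)
  sq1 <- squareRegion(c(-0.5, 0.5), c(-0.5, 0.5), lo = -2, hi = 6, n = 800)
  sq2 <- squareRegion(c(2.5, 3.5), c(3.5, 4.5), lo = -2, hi = 6, n = 800)
  expect_equal(seasonalDissimilarity(sq1, sq2)$dissimilarity, 5,
               tolerance = 0.01)
  # randomising season labels on pooled scores gives ~zero dissimilarity
  pool <- withr::with_seed(31, cbind(rnorm(2000, 2), rnorm(2000, -1)))
  d <- withr::with_seed(32, replicate(20, {
    pick <- sample(nrow(pool), nrow(pool) / 2)
    seasonalDissimilarity(kernelNiche(pool[pick, ], minPoints = 10),
                          kernelNiche(pool[-pick, ], minPoints = 10))$dissimilarity
  }))
  expect_lt(stats::median(d), 0.1)
})

test_that("too few score points is an explicit error for niche building", {
  expect_error(kernelNiche(cbind(rnorm(10), rnorm(10)), minPoints = 30),
               "at least")
})
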