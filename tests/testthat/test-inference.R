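## Synthetic per-individual tables with known coefficients.
mkTable <- function(n = 40, nPop = 5, b1 = 0, b2 = 0, bN = 0, sd = 0.3,
                    popSd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    pop <- rep(sprintf("pop%d", seq_len(nPop)), length.out = n)
    u <- rnorm(nPop, 0, popSd)[as.integer(factor(pop))]
    pc1 <- rnorm(n); pc2 <- rnorm(n); nd <- runif(n, 0.2, 0.5)
    data.frame(individual_id = sprintf("I%02d", seq_len(n)), population = pop,
               pc1_centroid = pc1, pc2_centroid = pc2,
               ndvi_pre_departure = nd,
               ln_distance = 1 + b1 * scale(pc1)[, 1] + b2 * scale(pc2)[, 1] +
                 bN * nd + u + rnorm(n, 0, sd))
  })
}

test_that("known coefficients are recovered; OLS fallback is exact", {
  # single population: exact OLS on a noise-free response
  tab <- mkTable(n = 30, nPop = 1, b1 = 0.7, b2 = -0.9, bN = 2, sd = 0,
                 popSd = 0)
  expect_warning(fit <- fitDistanceModel(tab), "single population")
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["pc1_scaled"]), 0.7, tolerance = 1e-8)
  expect_equal(unname(est["pc2_scaled"]), -0.9, tolerance = 1e-8)
  expect_equal(unname(est["ndvi_pre_departure"]), 2, tolerance = 1e-8)

  # five populations, small noise: mixed model close to truth
  tab5 <- mkTable(n = 60, nPop = 5, b2 = -0.6, sd = 0.05, seed = 4)
  fit5 <- fitDistanceModel(tab5)
  est5 <- setNames(fit5$fixed$estimate, fit5$fixed$term)
  expect_lt(abs(est5["pc2_scaled"] + 0.6), 0.05)
  expect_true(all(fit5$fixed$se > 0))
  expect_true(all(fit5$fixed$p > 0 & fit5$fixed$p <= 1))
  expect_equal(fit5$n_individuals, 60)
})

test_that("covariate scaling is recorded and invertible", {
  tab <- mkTable(n = 50, nPop = 1, b2 = -0.5, sd = 0, popSd = 0, seed = 9)
  tab$pc2_centroid <- tab$pc2_centroid * 7 + 3       # far from z-scale
  tab$ln_distance <- 1 - 0.5 * scale(tab$pc2_centroid)[, 1] +
    2 * tab$ndvi_pre_departure + 0.7 * scale(tab$pc1_centroid)[, 1]
  suppressWarnings(fit <- fitDistanceModel(tab))
  s <- fit$scaling
  raw <- stats::lm(ln_distance ~ pc1_centroid + pc2_centroid +
                     ndvi_pre_departure, tab)
  sc2 <- fit$fixed$estimate[fit$fixed$term == "pc2_scaled"]
  expect_equal(coef(raw)[["pc2_centroid"]] * s$sd[s$var == "pc2_centroid"],
               sc2, tolerance = 1e-10)
})

test_that("dissimilarity model scales its covariates and keeps signs", {
  withr::with_seed(21, {
    n <- 50
    tab <- data.frame(
      individual_id = sprintf("I%02d", 1:n),
      population = rep(sprintf("pop%d", 1:5), each = 10),
      overlap_breeding_pct = runif(n, 30, 100),
      pc1_centroid = rnorm(n), pc2_centroid = rnorm(n),
      ln_distance = rnorm(n))
    tab$dissimilarity <- 2 - 0.4 * scale(tab$ln_distance)[, 1] + rnorm(n, 0, 0.1)
  })
  fit <- fitDissimilarityModel(tab)
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_lt(abs(est["ln_distance_scaled"] + 0.4), 0.1)
  expect_equal(sort(fit$scaling$var),
               sort(c("overlap_breeding_pct", "pc1_centroid", "pc2_centroid",
                      "ln_distance")))
})

test_that("permuting the response leaves all terms non-significant on average", {
  tab <- mkTable(n = 46, nPop = 5, b2 = -0.6, sd = 0.3, seed = 33)
  ps <- withr::with_seed(34, replicate(30, {
    tb <- tab
    tb$ln_distance <- sample(tb$ln_distance)
    f <- suppressMessages(fitDistanceModel(tb))
    f$fixed$p[f$fixed$term == "pc2_scaled"]
  }))
  expect_gt(mean(ps > 0.05), 0.8)          # ~5% nominal rejections
  expect_gt(min(ps), 0)
})

test_that("adding the random intercept never lowers the ML log-likelihood", {
  tab <- mkTable(n = 60, nPop = 5, b2 = -0.5, sd = 0.2, popSd = 0.5, seed = 41)
  ml0 <- stats::logLik(stats::lm(
    ln_distance ~ scale(pc1_centroid) + scale(pc2_centroid) +
      ndvi_pre_departure, tab))
  ml1 <- stats::logLik(lme4::lmer(
    ln_distance ~ scale(pc1_centroid) + scale(pc2_centroid) +
      ndvi_pre_departure + (1 | population), tab, REML = FALSE))
  expect_gte(as.numeric(ml1), as.numeric(ml0) - 1e-6)
})

test_that("subsampling enumerates small populations and caps large ones", {
  withr::with_seed(50, {
    mkScores <- function(n) lapply(setNames(seq_len(n), paste0("i", seq_len(n))),
                                   function(i) cbind(rnorm(60), rnorm(60)))
    ref <- kernelNiche(cbind(rnorm(4000), rnorm(4000)), minPoints = 10)
    s6 <- mkScores(6)
    r6 <- subsampleRobustness(s6, ref, k = 5, seed = 7, gridsize = c(120, 120))
    expect_equal(r6$n_combinations, choose(6, 5))
    expect_true(all(r6$overlaps >= 0 & r6$overlaps <= 100))

    s9 <- mkScores(9)
    r9 <- subsampleRobustness(s9, ref, k = 5, maxCombinations = 50, seed = 7,
                              gridsize = c(120, 120))
    expect_equal(r9$n_combinations, 50)
    # seeded: same seed, same draws
    r9b <- subsampleRobustness(s9, ref, k = 5, maxCombinations = 50, seed = 7,
                               gridsize = c(120, 120))
    expect_identical(r9$overlaps, r9b$overlaps)
    expect_error(subsampleRobustness(mkScores(5), ref, k = 5), "more than")
  })
})
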