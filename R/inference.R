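## The two linear mixed-effects models and the 5-individual subsampling
## robustness procedure.

scaleRecord <- function(x) {
  c(center = mean(x), sd = sd(x))
}

fitMixed <- function(modelId, response, terms, tab) {
  tab <- tab[stats::complete.cases(tab[, c(response, terms, "population")]), ]
  nPop <- length(unique(tab$population))
  form <- stats::reformulate(c(terms, if (nPop >= 2) "(1 | population)"),
                             response = response)
  if (nPop < 2) {
    warning(sprintf("%s: single population; random intercept unidentifiable, ",
                    modelId), "falling back to ordinary least squares")
    fit <- stats::lm(form, data = tab)
    cf <- summary(fit)$coefficients
    fixed <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                        df = fit$df.residual, p = cf[, 4], row.names = NULL)
    reSd <- NA_real_
    singular <- NA
  } else {
    fit <- lmerTest::lmer(form, data = tab, REML = TRUE)
    cf <- summary(fit)$coefficients
    fixed <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"], df = cf[, "df"],
                        p = cf[, "Pr(>|t|)"], row.names = NULL)
    vc <- as.data.frame(lme4::VarCorr(fit))
    reSd <- vc$sdcor[vc$grp == "population"][1]
    singular <- lme4::isSingular(fit)
  }
  structure(list(model_id = modelId, fixed = fixed,
                 random_intercept_sd = reSd, n_individuals = nrow(tab),
                 singular = singular, fit = fit),
            class = "ModelFit")
}

#' @export
print.ModelFit <- function(x, ...) {
  cat(sprintf("Linear mixed model '%s' (n = %d individuals)\n",
              x$model_id, x$n_individuals))
  f <- x$fixed
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-28s est %8.3f  SE %6.3f  p %s\n", f$term[i],
                f$estimate[i], f$se[i], format.pval(f$p[i], digits = 3)))
  cat(sprintf("  random intercept (population) SD: %.3f%s\n",
              x$random_intercept_sd,
              if (isTRUE(x$singular)) "  [singular fit]" else ""))
  if (!is.null(x$scaling)) {
    cat("  covariate scaling (z-scores):\n")
    s <- x$scaling
    for (i in seq_len(nrow(s)))
      cat(sprintf("    %-26s center %8.3f  sd %6.3f\n",
                  s$var[i], s$center[i], s$sd[i]))
  }
  invisible(x)
}

#' Model 1: breeding microclimate vs distance travelled
#'
#' Linear mixed-effects model (REML, random intercept by population) of
#' log distance travelled on the scaled PC1 (temperature) and PC2
#' (refugia availability) coordinates of the individual's breeding niche
#' centroid and the mean NDVI of the 8 days before departure. p-values
#' use Satterthwaite degrees of freedom. With a single population the
#' random intercept is unidentifiable and an ordinary least-squares fit
#' is returned with a warning.
#'
#' @param tab One row per individual: `ln_distance`, `pc1_centroid`,
#'   `pc2_centroid`, `ndvi_pre_departure`, `population`. Rows with
#'   missing values are dropped.
#' @return A `ModelFit` list: `fixed` (term/estimate/se/df/p),
#'   `random_intercept_sd`, `n_individuals`, `singular`, `scaling`
#'   (the z-score constants, so unscaled coefficients are recoverable as
#'   `estimate / sd`), and the underlying `fit`.
#' @export
fitDistanceModel <- function(tab) {
  need <- c("ln_distance", "pc1_centroid", "pc2_centroid",
            "ndvi_pre_departure", "population")
  stopifnot(all(need %in% names(tab)))
  tab <- tab[stats::complete.cases(tab[, need]), ]
  s1 <- scaleRecord(tab$pc1_centroid); s2 <- scaleRecord(tab$pc2_centroid)
  tab$pc1_scaled <- (tab$pc1_centroid - s1["center"]) / s1["sd"]
  tab$pc2_scaled <- (tab$pc2_centroid - s2["center"]) / s2["sd"]
  out <- fitMixed("distance_model", "ln_distance",
                  c("pc1_scaled", "pc2_scaled", "ndvi_pre_departure"), tab)
  out$scaling <- data.frame(var = c("pc1_centroid", "pc2_centroid"),
                            center = c(s1["center"], s2["center"]),
                            sd = c(s1["sd"], s2["sd"]), row.names = NULL)
  out
}

#' Model 2: niche use and distance vs seasonal niche dissimilarity
#'
#' Linear mixed-effects model (REML, random intercept by population) of
#' the seasonal niche dissimilarity (centroid distance in PC units) on
#' the individual's breeding-niche overlap with its population's breeding
#' niche, the scaled PC1/PC2 breeding-centroid coordinates, and the log
#' distance travelled. All four covariates are z-scaled (recorded in
#' `scaling`); the distance coefficient is the headline term.
#'
#' @param tab One row per individual: `dissimilarity`,
#'   `overlap_breeding_pct`, `pc1_centroid`, `pc2_centroid`,
#'   `ln_distance`, `population`.
#' @return A `ModelFit` list; see [fitDistanceModel()].
#' @export
fitDissimilarityModel <- function(tab) {
  need <- c("dissimilarity", "overlap_breeding_pct", "pc1_centroid",
            "pc2_centroid", "ln_distance", "population")
  stopifnot(all(need %in% names(tab)))
  tab <- tab[stats::complete.cases(tab[, need]), ]
  covs <- c("overlap_breeding_pct", "pc1_centroid", "pc2_centroid",
            "ln_distance")
  sc <- lapply(tab[covs], scaleRecord)
  for (v in covs)
    tab[[paste0(v, "_scaled")]] <- (tab[[v]] - sc[[v]]["center"]) / sc[[v]]["sd"]
  out <- fitMixed("dissimilarity_model", "dissimilarity",
                  paste0(covs, "_scaled"), tab)
  out$scaling <- data.frame(var = covs,
                            center = vapply(sc, `[[`, 0, "center"),
                            sd = vapply(sc, `[[`, 0, "sd"), row.names = NULL)
  out
}

#' Subsampling robustness of a population's seasonal niche
#'
#' Rebuilds the population seasonal niche from every subset of `k`
#' individuals (all subsets when there are at most `maxCombinations`;
#' otherwise `maxCombinations` distinct subsets sampled without
#' replacement under `seed`) and records each subset niche's overlap with
#' a fixed reference niche (normally the species-level niche of the same
#' season). Comparing the spread of subset overlaps with the full-data
#' overlap shows whether `k` individuals already represent the
#' population.
#'
#' @param scoresByIndividual Named list of PC score matrices, one per
#'   individual of the population-season.
#' @param reference Reference [NicheRegion-class].
#' @param k Individuals per subset (default 5).
#' @param maxCombinations Cap on subsets (default 10000).
#' @param seed RNG seed for subset sampling.
#' @param mass Kernel mass (default 0.995).
#' @param gridsize Kernel grid for subset niches (default 200 x 200;
#'   overlap is measured on the reference grid, so the subset grid only
#'   sets membership resolution).
#' @param model Optional [NicheModel-class] fingerprint stamp.
#' @return A `SubsampleOverlap` list: `overlaps` (one per subset),
#'   `n_combinations`, `full_overlap`, `k`, `n_individuals`.
#' @export
subsampleRobustness <- function(scoresByIndividual, reference, k = 5,
                                maxCombinations = 10000, seed = 1,
                                mass = 0.995, gridsize = c(200, 200),
                                model = NULL) {
  n <- length(scoresByIndividual)
  if (n <= k)
    stop(sprintf("population has %d individuals; need more than k = %d", n, k))
  nAll <- choose(n, k)
  subsets <- if (nAll <= maxCombinations) {
    asplit(combn(n, k), 2)
  } else {
    withSeed(seed, {
      seen <- new.env(hash = TRUE)
      out <- vector("list", maxCombinations)
      got <- 0L
      while (got < maxCombinations) {
        s <- sort(sample.int(n, k))
        key <- paste(s, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- s
      }
      out
    })
  }
  pooled <- do.call(rbind, scoresByIndividual)
  full <- kernelNiche(pooled, mass = mass, model = model,
                      gridsize = gridsize, minPoints = 1)
  fullOverlap <- overlapPct(full, reference)
  overlaps <- vapply(subsets, function(s) {
    reg <- kernelNiche(do.call(rbind, scoresByIndividual[s]), mass = mass,
                       model = model, gridsize = gridsize, minPoints = 1)
    overlapPct(reg, reference)
  }, 0)
  structure(list(overlaps = overlaps, n_combinations = length(subsets),
                 full_overlap = fullOverlap, k = k, n_individuals = n),
            class = "SubsampleOverlap")
}

#' @export
print.SubsampleOverlap <- function(x, ...) {
  cat(sprintf("Subsample robustness: %d subsets of %d from %d individuals\n",
              x$n_combinations, x$k, x$n_individuals))
  q <- stats::quantile(x$overlaps, c(0, 0.25, 0.5, 0.75, 1))
  cat(sprintf("  subset overlap %%: min %.1f / median %.1f / max %.1f\n",
              q[1], q[3], q[5]))
  cat(sprintf("  full-data overlap %%: %.1f\n", x$full_overlap))
  invisible(x)
}
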