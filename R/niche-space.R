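## Environmental-space niche: standardised PCA of the eight microclimate
## variables, kernel niche regions in PC1-PC2, overlaps and the seasonal
## centroid dissimilarity.

#' Fit the environmental-space PCA
#'
#' Standardises the eight microclimate variables (mean 0, sd 1) over all
#' complete records pooled across seasons, individuals and years, and
#' eigen-decomposes the resulting correlation structure. Axis signs are
#' oriented so that PC1 increases with the five temperature variables and
#' PC2 increases with the refugia-availability loading; the retained axis
#' count is the smallest number of axes whose cumulative variance
#' fraction exceeds `threshold`.
#'
#' @param env Environment table containing the [nicheVariables()] columns
#'   (rows with `valid == FALSE` or NAs are dropped).
#' @param threshold Cumulative-variance retention threshold (default 0.70).
#' @param minRecords Minimum complete records required (default 8).
#' @return A [NicheModel-class].
#' @export
fitNichePCA <- function(env, threshold = 0.70, minRecords = 8) {
  vars <- nicheVariables()
  miss <- setdiff(vars, names(env))
  if (length(miss))
    stop("environment table lacks variables: ", paste(miss, collapse = ", "))
  X <- as.matrix(env[, vars])
  if (!is.null(env$valid)) X <- X[env$valid %in% TRUE, , drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < minRecords)
    stop(sprintf("need at least %d complete records, got %d", minRecords, nrow(X)))
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(vars[sds == 0], collapse = ", "))
  pr <- prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pr$sdev^2
  varFrac <- eig / sum(eig)
  load <- pr$rotation
  tempVars <- c("point_temp", "buffer_mean", "buffer_median",
                "buffer_max", "buffer_min")
  if (sum(load[tempVars, 1]) < 0) load[, 1] <- -load[, 1]
  if (ncol(load) >= 2 && load["refugia_availability", 2] < 0)
    load[, 2] <- -load[, 2]
  nz <- sum(eig > max(eig) * 1e-9)            # rank: axes with nonzero variance
  retained <- min(retainAxisCount(varFrac, threshold), nz)
  new("NicheModel",
      center = pr$center, scale = pr$scale, loadings = load,
      varFrac = varFrac, retained = as.integer(retained),
      threshold = threshold,
      id = paste0("pca-", substr(paste(
        format(sum(abs(load)) * 1e6, digits = 12),
        format(sum(pr$center) * 1e3, digits = 12), sep = "-"), 1, 40)))
}

#' Axis retention under the cumulative-variance rule
#'
#' The number of leading axes to keep: the smallest count whose
#' cumulative variance fraction exceeds `threshold` (e.g. fractions
#' `(0.6478, 0.2074, ...)` keep two axes under the default 0.70 rule,
#' since 64.78% < 70% but 85.52% > 70%).
#'
#' @param varFrac Non-increasing per-axis variance fractions.
#' @param threshold Cumulative-variance threshold (default 0.70).
#' @return Integer axis count.
#' @export
retainAxisCount <- function(varFrac, threshold = 0.70) {
  as.integer(which(cumsum(varFrac) > threshold)[1])
}

#' Project records into niche space
#'
#' Applies the model's standardisation and loadings; downstream niche
#' regions use the first two principal components.
#'
#' @param model A [NicheModel-class].
#' @param env Environment table with the [nicheVariables()] columns.
#' @return Matrix of scores (`PC1`, `PC2`, ...), one row per record; rows
#'   with missing variables give NA scores.
#' @export
nicheScores <- function(model, env) {
  vars <- nicheVariables()
  X <- as.matrix(env[, vars])
  S <- scale(X, center = model@center, scale = model@scale) %*% model@loadings
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  S
}

#' Kernel niche region in PC1-PC2 space
#'
#' The realized microclimatic niche of one analysis level (species,
#' population or individual) in one season and year: the 99.5% bivariate
#' normal kernel region of the level's PC scores (the high mass level
#' trims outlying scores).
#'
#' @param scores Score matrix (uses columns 1-2) for one level/season/year.
#' @param mass Kernel mass (default 0.995).
#' @param minPoints Minimum score points; fewer raises an error so the
#'   caller can skip the level with a logged reason (default 30).
#' @param model Optional [NicheModel-class] whose fingerprint stamps the
#'   region so regions from different models cannot be overlapped.
#' @param meta Labels (level, season, year).
#' @param gridsize Kernel evaluation grid (default 400 x 400).
#' @return A [NicheRegion-class].
#' @export
kernelNiche <- function(scores, mass = 0.995, minPoints = 30, model = NULL,
                        meta = list(), gridsize = c(400, 400)) {
  kernelRegion(as.matrix(scores)[, 1:2, drop = FALSE], mass = mass,
               gridsize = gridsize, space = "pc",
               modelId = if (is.null(model)) NA_character_ else model@id,
               meta = meta, minPoints = minPoints)
}

#' Seasonal niche dissimilarity of one individual
#'
#' Euclidean distance in PC units between the centroids of the breeding
#' and post-breeding niche regions; zero means identical mean seasonal
#' conditions.
#'
#' @param breeding,postBreeding [NicheRegion-class] objects for the same
#'   individual and year.
#' @return One-row data.frame with the two centroids and `dissimilarity`.
#' @export
seasonalDissimilarity <- function(breeding, postBreeding) {
  if (!is.na(breeding@modelId) && !is.na(postBreeding@modelId) &&
      breeding@modelId != postBreeding@modelId)
    stop("seasonal regions come from different niche models")
  b <- nicheCentroid(breeding); p <- nicheCentroid(postBreeding)
  data.frame(breeding_pc1 = b[1], breeding_pc2 = b[2],
             post_pc1 = p[1], post_pc2 = p[2],
             dissimilarity = sqrt(sum((b - p)^2)))
}
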