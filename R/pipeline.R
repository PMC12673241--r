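## End-to-end orchestration: synthetic world -> ingest -> microclimate ->
## niche space -> movement -> inference, from a single seeded config.

#' Create a pipeline configuration
#'
#' All knobs default to the analysis' standard values; the synthetic
#' world block defaults to [syntheticWorldConfig()]. One master `seed`
#' derives per-stage child seeds (see [deriveSeed()]) so any stage can be
#' re-run in isolation reproducibly.
#'
#' @param world A [SyntheticWorldConfig-class].
#' @param speedTol,tzOffset,breedingWindow,postWindow See
#'   [PipelineConfig-class].
#' @param minAwayDays,bufferRadius,nicheMass,udMass,varianceThreshold
#'   See [PipelineConfig-class].
#' @param collapseRadiusKm,distanceFloorKm,minFixesPerDay,minNichePoints
#'   See [PipelineConfig-class].
#' @param subsampleK,maxCombinations,nicheGrid,udGrid See
#'   [PipelineConfig-class].
#' @param runRobustness,seed,outDir See [PipelineConfig-class].
#' @return A validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(world = syntheticWorldConfig(),
                           speedTol = 0, tzOffset = 1,
                           breedingWindow = c(6, 17), postWindow = c(7, 20),
                           minAwayDays = 30, bufferRadius = 500,
                           nicheMass = 0.995, udMass = 0.90,
                           varianceThreshold = 0.70,
                           collapseRadiusKm = 5, distanceFloorKm = 0.5,
                           minFixesPerDay = 5, minNichePoints = 30,
                           subsampleK = 5, maxCombinations = 10000,
                           nicheGrid = c(400, 400), udGrid = c(64, 64),
                           runRobustness = TRUE, seed = 1, outDir = "") {
  new("PipelineConfig", world = world, speedTol = speedTol,
      tzOffset = tzOffset, breedingWindow = breedingWindow,
      postWindow = postWindow, minAwayDays = minAwayDays,
      bufferRadius = bufferRadius, nicheMass = nicheMass, udMass = udMass,
      varianceThreshold = varianceThreshold,
      collapseRadiusKm = collapseRadiusKm, distanceFloorKm = distanceFloorKm,
      minFixesPerDay = minFixesPerDay, minNichePoints = minNichePoints,
      subsampleK = subsampleK, maxCombinations = maxCombinations,
      nicheGrid = nicheGrid, udGrid = udGrid, runRobustness = runRobustness,
      seed = seed, outDir = outDir)
}

slotsToList <- function(obj) {
  nm <- methods::slotNames(class(obj))
  out <- lapply(nm, function(s) {
    v <- slot(obj, s)
    if (is(v, "SyntheticWorldConfig"))
      slotsToList(v)
    else if (is.numeric(v)) sprintf("%.17g", v)   # lossless double round-trip
    else v
  })
  names(out) <- nm
  out
}

#' Write / read a pipeline configuration as YAML
#'
#' Numeric values are serialised with 17 significant digits so the
#' config round-trips losslessly.
#'
#' @param config A [PipelineConfig-class].
#' @param path YAML file path.
#' @return `writePipelineConfig()`: `path` invisibly;
#'   `readPipelineConfig()`: the [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(slotsToList(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  num <- function(x) as.numeric(x)
  w <- lst$world
  world <- do.call(syntheticWorldConfig, lapply(w, num))
  args <- lst[setdiff(names(lst), c("world", "outDir", "runRobustness"))]
  args <- lapply(args, num)
  args$runRobustness <- isTRUE(lst$runRobustness %||% TRUE)
  args$world <- world
  args$outDir <- lst$outDir %||% ""
  do.call(pipelineConfig, args)
}

writeTable <- function(x, outDir, name) {
  if (nzchar(outDir)) data.table::fwrite(x, file.path(outDir, name))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Simulates the synthetic world, applies the fix filters and season
#' rules, attaches the microclimate variables, builds the PCA niche with
#' kernel regions and overlaps at species, population and individual
#' level, computes daily utilization distributions and migration
#' distances, fits both mixed models, and runs the subsampling
#' robustness check for every population with more than `subsampleK`
#' included individuals. With a non-empty `outDir` all tables are
#' written as CSV, niche contours as GeoJSON, model summaries as text,
#' and a JSON manifest records the package version, seed and config; a
#' fixed seed yields byte-identical outputs across runs.
#'
#' @param config A [PipelineConfig-class].
#' @return Invisible list with all intermediate and final products
#'   (world, assignments, env table, niche model, regions, overlap and
#'   dissimilarity tables, movement summary, the two `ModelFit`s, and
#'   the robustness distributions).
#' @export
runPipeline <- function(config) {
  validObject(config)
  outDir <- config@outDir
  if (nzchar(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  ## --- synthetic world ------------------------------------------------
  wcfg <- config@world
  wcfg@seed <- deriveSeed(config@seed, "world")
  message("stage simulate: generating synthetic world (seed ", wcfg@seed, ")")
  world <- simulateWorld(wcfg)
  writeTable(within(world$fixes,
                    timestamp <- format(timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                        tz = "UTC")),
             outDir, "fixes_raw.csv")

  ## --- ingest ---------------------------------------------------------
  message("stage ingest: null-velocity filter, departure rule, seasons")
  sp <- filterFixes(world$fixes, speedTol = config@speedTol,
                    tzOffset = config@tzOffset,
                    breedingWindow = config@breedingWindow,
                    postWindow = config@postWindow)
  sa <- seasonAssignments(sp, minAwayDays = config@minAwayDays,
                          udMass = config@udMass)
  assignments <- applyInclusionRules(sa$assignments)
  labelled <- assignSeasons(sp, assignments)
  filt <- filterFixes(labelled, speedTol = config@speedTol,
                      tzOffset = config@tzOffset,
                      breedingWindow = config@breedingWindow,
                      postWindow = config@postWindow)
  retained <- filt[filt$season != "excluded", , drop = FALSE]
  writeTable(assignments, outDir, "season_assignments.csv")
  excl <- rbind(attr(sp, "exclusions"),
                attr(filt, "exclusions")[, names(attr(sp, "exclusions"))])
  excl$timestamp <- format(excl$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  writeTable(excl, outDir, "fix_exclusions.csv")

  ## --- microclimate ---------------------------------------------------
  message("stage envjoin: buffer statistics for ", nrow(retained), " fixes")
  env <- bufferStats(retained, world$cube, radiusM = config@bufferRadius)
  envValid <- env[env$valid, , drop = FALSE]
  out <- within(envValid,
                timestamp <- format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  writeTable(out, outDir, "env_table.csv")

  ## --- niche space ----------------------------------------------------
  message("stage niche: PCA and kernel niche regions")
  model <- fitNichePCA(envValid, threshold = config@varianceThreshold)
  sc <- nicheScores(model, envValid)
  envValid$PC1 <- sc[, 1]; envValid$PC2 <- sc[, 2]
  writeTable(data.frame(variable = rownames(model@loadings),
                        model@loadings[, 1:2],
                        center = model@center, scale = model@scale),
             outDir, "niche_model_loadings.csv")
  writeTable(data.frame(axis = seq_along(model@varFrac),
                        var_frac = model@varFrac,
                        cum_var = cumsum(model@varFrac),
                        retained = seq_along(model@varFrac) <= model@retained),
             outDir, "niche_model_variance.csv")

  seasons <- c("breeding", "post_breeding")
  scoreMat <- function(idx) cbind(envValid$PC1[idx], envValid$PC2[idx])
  nicheFor <- function(idx, level, season, extra = list()) {
    kernelNiche(scoreMat(idx), mass = config@nicheMass, model = model,
                minPoints = config@minNichePoints,
                gridsize = config@nicheGrid,
                meta = c(list(level = level, season = season), extra))
  }
  speciesAll <- nicheFor(seq_len(nrow(envValid)), "species", "all")
  speciesSeason <- lapply(setNames(seasons, seasons), function(s)
    nicheFor(which(envValid$season == s), "species", s))

  pops <- sort(unique(envValid$population))
  popSeason <- list(); popOverlap <- list()
  for (p in pops) for (s in seasons) {
    idx <- which(envValid$population == p & envValid$season == s)
    key <- paste(p, s, sep = ".")
    popSeason[[key]] <- tryCatch(
      nicheFor(idx, "population", s, list(population = p)),
      error = function(e) NULL)
    if (!is.null(popSeason[[key]]))
      popOverlap[[key]] <- data.frame(
        population = p, season = s, n_fixes = length(idx),
        overlap_with_species_pct = overlapPct(popSeason[[key]],
                                              speciesSeason[[s]]))
  }
  popOverlap <- do.call(rbind, popOverlap)
  rownames(popOverlap) <- NULL
  writeTable(popOverlap, outDir, "overlap_population.csv")

  speciesOverlap <- data.frame(
    comparison = c("breeding_vs_overall", "post_breeding_vs_overall",
                   "post_vs_breeding", "breeding_vs_post"),
    overlap_pct = c(overlapPct(speciesSeason$breeding, speciesAll),
                    overlapPct(speciesSeason$post_breeding, speciesAll),
                    overlapPct(speciesSeason$post_breeding,
                               speciesSeason$breeding),
                    overlapPct(speciesSeason$breeding,
                               speciesSeason$post_breeding)))
  writeTable(speciesOverlap, outDir, "overlap_species.csv")

  inclIds <- assignments$individual_id[assignments$included]
  indNiche <- list(); indRows <- list(); nicheSkips <- list()
  for (id in inclIds) {
    for (s in seasons) {
      idx <- which(envValid$individual_id == id & envValid$season == s)
      key <- paste(id, s, sep = ".")
      indNiche[[key]] <- tryCatch(
        nicheFor(idx, "individual", s, list(individual_id = id)),
        error = function(e) {
          nicheSkips[[key]] <<- data.frame(individual_id = id, season = s,
                                           n_fixes = length(idx))
          NULL
        })
    }
    bN <- indNiche[[paste(id, "breeding", sep = ".")]]
    pN <- indNiche[[paste(id, "post_breeding", sep = ".")]]
    if (is.null(bN)) next
    p <- envValid$population[envValid$individual_id == id][1]
    popB <- popSeason[[paste(p, "breeding", sep = ".")]]
    row <- data.frame(
      individual_id = id, population = p,
      pc1_centroid = nicheCentroid(bN)[1], pc2_centroid = nicheCentroid(bN)[2],
      overlap_breeding_pct = if (!is.null(popB)) overlapPct(bN, popB) else NA,
      dissimilarity = NA_real_)
    if (!is.null(pN))
      row$dissimilarity <- seasonalDissimilarity(bN, pN)$dissimilarity
    indRows[[id]] <- row
  }
  indTab <- do.call(rbind, indRows)
  rownames(indTab) <- NULL
  if (length(nicheSkips)) {
    skips <- do.call(rbind, nicheSkips)
    message("stage niche: skipped ", nrow(skips),
            " individual-season niches (fewer than ", config@minNichePoints,
            " points)")
    writeTable(skips, outDir, "niche_skips.csv")
  }

  ## --- NDVI covariate -------------------------------------------------
  aInc <- assignments[assignments$included, , drop = FALSE]
  ndviCov <- do.call(rbind, lapply(seq_len(nrow(aInc)), function(i) {
    a <- aInc[i, ]
    ref <- if (a$status == "migrant") a$departure_date
           else seasonDates(a$year)$jul15
    reg <- sa$breedingRegions[[paste(a$individual_id, a$year, sep = ".")]]
    v <- if (is.null(reg)) NA_real_
         else ndviPreDeparture(world$ndvi, reg, ref)
    data.frame(individual_id = a$individual_id,
               ndvi_pre_departure = v)
  }))
  writeTable(ndviCov, outDir, "ndvi_pre_departure.csv")

  ## --- movement -------------------------------------------------------
  message("stage movement: daily utilization distributions")
  mv <- list(); dailyAll <- list()
  for (i in seq_len(nrow(aInc))) {
    a <- aInc[i, ]
    ff <- retained[retained$individual_id == a$individual_id &
                   format(retained$timestamp, "%Y") == a$year, , drop = FALSE]
    if (nrow(ff) == 0) next
    daily <- dailyUD(ff, udMass = config@udMass,
                     minFixes = config@minFixesPerDay,
                     gridsize = config@udGrid)
    dailyAll[[a$individual_id]] <- daily
    m <- migrationDistance(daily, collapseRadiusKm = config@collapseRadiusKm,
                           distanceFloorKm = config@distanceFloorKm)
    if (!is.null(m)) mv[[a$individual_id]] <- m
  }
  movement <- do.call(rbind, mv)
  rownames(movement) <- NULL
  writeTable(do.call(rbind, dailyAll), outDir, "daily_centroids.csv")
  writeTable(movement, outDir, "movement_summary.csv")

  ## --- inference ------------------------------------------------------
  message("stage models: mixed-effects fits")
  tab <- merge(merge(movement[, c("individual_id", "total_distance_km",
                                  "ln_distance")],
                     cbind(indTab), by = "individual_id"),
               ndviCov, by = "individual_id")
  writeTable(tab, outDir, "model_table.csv")
  distModel <- if (nrow(tab) >= 8) fitDistanceModel(tab) else NULL
  dissModel <- if (sum(!is.na(tab$dissimilarity)) >= 8)
    fitDissimilarityModel(tab) else NULL
  if (nzchar(outDir)) {
    if (!is.null(distModel)) {
      writeTable(distModel$fixed, outDir, "model_distance.csv")
      writeLines(utils::capture.output(print(distModel)),
                 file.path(outDir, "model_distance.txt"))
    }
    if (!is.null(dissModel)) {
      writeTable(dissModel$fixed, outDir, "model_dissimilarity.csv")
      writeLines(utils::capture.output(print(dissModel)),
                 file.path(outDir, "model_dissimilarity.txt"))
    }
  }

  ## --- subsampling robustness -----------------------------------------
  robustness <- list()
  if (config@runRobustness) for (p in pops) for (s in seasons) {
    ids <- unique(envValid$individual_id[envValid$population == p &
                                         envValid$individual_id %in% inclIds])
    if (length(ids) <= config@subsampleK) next
    sByI <- lapply(setNames(ids, ids), function(id) {
      idx <- which(envValid$individual_id == id & envValid$season == s)
      scoreMat(idx)
    })
    sByI <- sByI[vapply(sByI, nrow, 0L) > 0]
    if (length(sByI) <= config@subsampleK) next
    message("stage robustness: ", p, " ", s, " (", length(sByI),
            " individuals)")
    robustness[[paste(p, s, sep = ".")]] <- subsampleRobustness(
      sByI, speciesSeason[[s]], k = config@subsampleK,
      maxCombinations = config@maxCombinations,
      seed = deriveSeed(config@seed, paste0("robustness-", p, "-", s)),
      mass = config@nicheMass, model = model)
  }
  if (length(robustness)) {
    robTab <- do.call(rbind, lapply(names(robustness), function(k) {
      r <- robustness[[k]]
      ps <- strsplit(k, ".", fixed = TRUE)[[1]]
      data.frame(population = ps[1], season = ps[2],
                 subset = seq_along(r$overlaps), overlap_pct = r$overlaps,
                 full_overlap_pct = r$full_overlap)
    }))
    writeTable(robTab, outDir, "subsample_robustness.csv")
  }

  ## --- manifest & geometry --------------------------------------------
  if (nzchar(outDir)) {
    writeRegionsGeoJSON(c(list(species_all = speciesAll), speciesSeason,
                          Filter(Negate(is.null), popSeason)),
                        file.path(outDir, "niche_regions.geojson"))
    ## the recorded config describes the analysis, not the output location
    cfgRec <- config
    cfgRec@outDir <- ""
    cfgY <- yaml::as.yaml(slotsToList(cfgRec))
    h <- 0; for (k in utf8ToInt(cfgY)) h <- (h * 131 + k) %% 1e9
    jsonlite::write_json(
      list(package = "refugiaTrack",
           version = as.character(utils::packageVersion("refugiaTrack")),
           seed = config@seed, config_hash = h,
           n_fixes_raw = nrow(world$fixes), n_fixes_retained = nrow(retained),
           n_individuals_included = length(inclIds)),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    writePipelineConfig(cfgRec, file.path(outDir, "config.yaml"))
  }

  invisible(list(
    config = config, world = world, assignments = assignments,
    retainedFixes = retained, env = envValid, nicheModel = model,
    speciesAll = speciesAll, speciesSeason = speciesSeason,
    popSeason = popSeason, indNiche = indNiche,
    popOverlap = popOverlap, speciesOverlap = speciesOverlap,
    individualTable = indTab, ndvi = ndviCov, movement = movement,
    modelTable = tab, distModel = distModel, dissModel = dissModel,
    robustness = robustness))
}
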