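## End-to-end orchestration: simulate -> quantify -> axons -> classify ->
## fit -> report. Everything is deterministic given (config, seed); each
## stage derives its own sub-seed from the run seed.

.stageSeeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  list(dendrites = base * 2L + 11L, axons = base * 2L + 23L,
       l5 = base * 2L + 37L, distance = base * 2L + 41L,
       boot = base * 2L + 53L)
}

#' Run the full analysis pipeline on synthetic annotations
#'
#' Generates dendrite annotations (main-bifurcation cohorts for L2 and
#' deep-layer dendrites plus an L5tt tuft cohort), axon output tables and
#' L5 feature tables under the given configuration; then computes
#' per-cell-type synapse densities and inhibitory fractions, the distal
#' tuft composition, axonal innervation profiles with the conditional
#' matrix and bootstrap specificity test, L5 subtype clustering with
#' thick-tuftedness regressions, and the exponential distance-model fit.
#' Optionally writes every table as tab-separated text.
#'
#' @param config generator configuration, see [generatorConfig()].
#' @param outDir optional output directory for TSV tables.
#' @param seed run seed; all stage seeds derive from it.
#' @param nPerGroup dendrites per main-bifurcation cohort.
#' @param nTuftCells L5tt cells for the tuft cohort.
#' @param nBoot bootstrap resamples for the specificity test.
#' @return list with `manifest` (seeds and cohort sizes), `densities`
#'   (per-group summaries), `tuft` (per-branch distal composition),
#'   `axons` (profiles, conditional matrix, specificity test, region
#'   consistency), `l5` (clustering, PC1 fits), `distance` (exponential
#'   fit), and `tables` (named list of flat `data.frame`s; written to
#'   `outDir` when given).
#' @export
runPipeline <- function(config = generatorConfig(), outDir = NULL,
                        seed = 1, nPerGroup = 41, nTuftCells = 8,
                        nBoot = 2000) {
  seeds <- .stageSeeds(seed)

  ## --- simulate + quantify dendrites -------------------------------
  gen <- generateDendrites(config,
    nPerCelltype = c(L2 = nPerGroup, DL = nPerGroup, L5tt = nTuftCells),
    seed = seeds$dendrites)
  ads <- extractDendrites(gen$annotation)
  ct <- vapply(ads, cellType, character(1))
  densities <- lapply(split(ads[ct %in% c("L2", "DL")],
                            ct[ct %in% c("L2", "DL")]), function(grp) {
    summarizeDensities(lapply(grp, densityResult, window = c(-10, 10)))
  })
  tuft <- distalTuftResults(ads[ct == "L5tt"],
                            distalLength = config$geometry$distalLength)

  ## --- axons --------------------------------------------------------
  axGen <- generateAxons(config, seed = seeds$axons)
  profiles <- innervationProfile(axGen$table)
  condMat <- conditionalMatrix(profiles)
  cats <- targetCategories()
  spec <- bootstrapSpecificityTest(
    profiles[profiles$seedType == "L2", cats],
    profiles[profiles$seedType == "DL", cats],
    nBoot = nBoot, seed = seeds$boot)
  regions <- regionConsistency(profiles)
  multiplicity <- multiplicityStats(axGen$table)

  ## --- L5 subtype models -------------------------------------------
  l5 <- generateL5Features(config, seed = seeds$l5)
  cluster <- suppressWarnings(clusterL5(l5$features))
  tt <- thickTuftedness(l5$features)
  eFit <- fitLinear(tt$scores, l5$eDensity)
  fracObs <- l5$iDensity / (l5$iDensity + l5$eDensity)
  ## at n = 18 a noisy draw can put a pole of the fitted fraction inside
  ## the data range; the fit is then rejected by its guard and reported
  ## as unavailable rather than aborting the run
  fracFit <- tryCatch(fitLinearFraction(tt$scores, fracObs),
                      error = function(e) conditionMessage(e))
  predE <- predictFractionFromDensities(tt$scores, l5$eDensity,
                                        l5$iDensity, mode = "E_only")

  ## --- distance model ----------------------------------------------
  dd <- generateDistanceSamples(config, seed = seeds$distance)
  dFit <- fitExponential(dd$distance, dd$fraction)

  tables <- list(
    density_summary = do.call(rbind, lapply(names(densities), function(g)
      cbind(group = g, densities[[g]]$summary))),
    tuft_branches = tuft,
    conditional_matrix = condMat$matrix,
    conditional_restricted = condMat$restricted,
    specificity_test = spec,
    region_cv = regions$cv,
    l5_cells = cbind(l5$features, label = cluster$labels,
                     pc1 = tt$scores, eDensity = l5$eDensity,
                     iDensity = l5$iDensity),
    distance_fit = data.frame(param = names(dFit$params),
                              value = unname(dFit$params),
                              rSquared = dFit$rSquared, n = dFit$n))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      utils::write.table(tables[[nm]],
                         file.path(outDir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }

  list(
    manifest = list(seed = seed, stageSeeds = seeds,
                    nPerGroup = nPerGroup, nTuftCells = nTuftCells,
                    nBoot = nBoot, nTrees = nTrees(gen$annotation),
                    nAxons = nrow(axGen$truth)),
    densities = densities, tuft = tuft,
    axons = list(profiles = profiles, conditional = condMat,
                 specificity = spec, regions = regions,
                 multiplicity = multiplicity),
    l5 = list(cluster = cluster, thickTuftedness = tt, eFit = eFit,
              fractionFit = fracFit, predictedFraction = predE,
              truthLabels = l5$labels),
    distance = list(fit = dFit, data = dd),
    tables = tables)
}
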