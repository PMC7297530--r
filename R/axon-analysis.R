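## Axon-level identity calibration, target-preference profiles, multiplicity
## and specificity statistics. Axon data are tabular: one row per output
## synapse (the seed synapse is never part of the table).

#' The eight subcellular target categories
#'
#' Layer 2 or deep-layer apical dendrite, shaft of other dendrites,
#' single- or double-innervated spine (neck targeting included with the
#' double class), layer 2 cell body, axon initial segment, or glia.
#'
#' @export
targetCategories <- function() {
  c("L2_AD", "DL_AD", "other_shaft", "single_spine", "double_spine",
    "soma", "AIS", "glia")
}

#' Validate an axon output-synapse table
#'
#' The table has one row per output synapse with columns `axon`,
#' `seedType` (AD type of the seed synapse), `seedLocation` (`"shaft"` or
#' `"spine"`), `region`, `layerContext` (`"L1"` or `"L2"`), `category`
#' (one of [targetCategories()]), `adId` (identity of the targeted apical
#' dendrite, `NA` for non-AD targets) and `singleSpine` (logical: the
#' output sits on a single-innervated spine). The seed synapse itself is
#' excluded from the table.
#'
#' @param tab a `data.frame`.
#' @return The validated table (invisibly usable), with `category` as
#'   character.
#' @export
axonTable <- function(tab) {
  need <- c("axon", "seedType", "seedLocation", "region", "layerContext",
            "category", "adId", "singleSpine")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("axon table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$category), targetCategories())
  if (length(bad))
    stop("unknown target categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tab$category <- as.character(tab$category)
  tab
}

#' Per-axon fraction of outputs onto single-innervated spines
#'
#' @param tab an axon table (see [axonTable()]).
#' @return `data.frame` with `axon`, `seedType`, `seedLocation`,
#'   `layerContext`, `region`, `nSynapses`, `spineFraction`.
#' @export
spineFraction <- function(tab) {
  tab <- axonTable(tab)
  sp <- split(tab, tab$axon)
  out <- do.call(rbind, lapply(sp, function(d) {
    if (!nrow(d)) stop("axon with zero outputs", call. = FALSE)
    data.frame(axon = d$axon[1], seedType = d$seedType[1],
               seedLocation = d$seedLocation[1],
               layerContext = d$layerContext[1], region = d$region[1],
               nSynapses = nrow(d),
               spineFraction = mean(d$singleSpine))
  }))
  rownames(out) <- NULL
  out
}

#' Classify axons as excitatory or putative inhibitory
#'
#' A strict majority of output synapses onto single-innervated spines
#' (fraction above the 50% threshold) makes an axon excitatory; at or
#' below the threshold it is putative inhibitory.
#'
#' @param f numeric vector of single-innervated-spine fractions in
#'   `[0, 1]`.
#' @param threshold classification threshold.
#' @return character vector `"excitatory"` / `"putative_inhibitory"`.
#' @examples
#' classifyAxon(c(0.9, 0.5, 0.1))
#' @export
classifyAxon <- function(f, threshold = 0.5) {
  stopifnot(all(f >= 0 & f <= 1))
  ifelse(f > threshold, "excitatory", "putative_inhibitory")
}

#' Fraction of excitatory axons per seeded structure
#'
#' For each (seed AD type, seed location, layer context) cell: the
#' fraction of seed synapses whose presynaptic axon is classified
#' excitatory by [classifyAxon()]. Cells with no axons are absent from the
#' result (missing, not zero).
#'
#' @param tab an axon table.
#' @param threshold spine-fraction classification threshold.
#' @return `data.frame` with `seedType`, `seedLocation`, `layerContext`,
#'   `nAxons`, `excFraction`.
#' @export
excitatoryFractionPerStructure <- function(tab, threshold = 0.5) {
  sf <- spineFraction(tab)
  sf$class <- classifyAxon(sf$spineFraction, threshold)
  agg <- stats::aggregate(class ~ seedType + seedLocation + layerContext,
    data = sf, FUN = function(v) mean(v == "excitatory"))
  n <- stats::aggregate(axon ~ seedType + seedLocation + layerContext,
    data = sf, FUN = length)
  out <- merge(agg, n)
  names(out)[names(out) == "class"] <- "excFraction"
  names(out)[names(out) == "axon"] <- "nAxons"
  out[, c("seedType", "seedLocation", "layerContext", "nAxons",
          "excFraction")]
}

#' Correct a density result for misidentified shaft synapses
#'
#' A fraction `fExcShaft` of shaft synapses on the structure originates
#' from excitatory (spine-preferring) axons; that mass is moved from the
#' putative-inhibitory to the excitatory count and all densities and the
#' inhibitory fraction are recomputed. Double-innervated spines keep one
#' excitatory and one inhibitory component and are untouched.
#'
#' @param raw an uncorrected `"DensityResult"`.
#' @param fExcShaft fraction in `[0, 1]` of shaft synapses that are
#'   excitatory.
#' @return The corrected `"DensityResult"` (`corrected = TRUE`).
#' @export
correctDensity <- function(raw, fExcShaft) {
  stopifnot(inherits(raw, "DensityResult"),
            fExcShaft >= 0, fExcShaft <= 1)
  if (isTRUE(raw$corrected))
    stop("density result is already corrected", call. = FALSE)
  moved <- raw$nShaft * fExcShaft
  out <- raw
  out$nInh <- raw$nInh - moved
  out$nExc <- raw$nExc + moved
  out$nShaft <- raw$nShaft - moved
  L <- raw$shaftLength
  out$densExcLen <- out$nExc / L
  out$densInhLen <- out$nInh / L
  out$densShaftLen <- out$nShaft / L
  out$densExcArea <- out$nExc / raw$surfaceArea
  out$densInhArea <- out$nInh / raw$surfaceArea
  out$inhFraction <- if (out$nExc + out$nInh > 0)
    out$nInh / (out$nExc + out$nInh) else NA_real_
  out$corrected <- TRUE
  out
}

#' Accuracy of predicting axon class from seed-synapse location
#'
#' The location-implied class (shaft seed implies putative inhibitory,
#' spine seed implies excitatory) is compared with the axon's class from
#' its output spine fraction.
#'
#' @param tab an axon table.
#' @param by grouping columns (default seed AD type and location).
#' @param threshold classification threshold.
#' @return `data.frame` with the grouping columns, `nAxons` and
#'   `accuracy`.
#' @export
predictionAccuracy <- function(tab, by = c("seedType", "seedLocation"),
                               threshold = 0.5) {
  sf <- spineFraction(tab)
  sf$class <- classifyAxon(sf$spineFraction, threshold)
  sf$implied <- ifelse(sf$seedLocation == "shaft", "putative_inhibitory",
                       "excitatory")
  sf$match <- sf$class == sf$implied
  agg <- stats::aggregate(sf["match"], by = sf[by], FUN = mean)
  n <- stats::aggregate(list(nAxons = sf$axon), by = sf[by], FUN = length)
  out <- merge(n, agg)
  names(out)[names(out) == "match"] <- "accuracy"
  out
}

#' Per-axon fractional innervation of the eight target categories
#'
#' The number of output synapses on each target category divided by the
#' axon's total output count (seed synapse excluded by construction).
#'
#' @param tab an axon table.
#' @return `data.frame` with `axon`, `seedType`, `region`, `nSynapses` and
#'   one fraction column per category (fractions sum to 1 per axon).
#' @export
innervationProfile <- function(tab) {
  tab <- axonTable(tab)
  cats <- targetCategories()
  sp <- split(tab, tab$axon)
  out <- do.call(rbind, lapply(sp, function(d) {
    if (!nrow(d)) stop("axon with zero outputs", call. = FALSE)
    fr <- as.numeric(table(factor(d$category, levels = cats))) / nrow(d)
    row <- data.frame(axon = d$axon[1], seedType = d$seedType[1],
                      region = d$region[1], nSynapses = nrow(d))
    row[cats] <- as.list(fr)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Conditional AD-innervation matrix by seed type
#'
#' For each seed group: the mean of per-axon fractions of output synapses
#' on L2 and deep-layer apical dendrites, the mean overall AD-targeting
#' fraction, and the AD-restricted renormalization (per-axon fraction of
#' AD synapses on each AD type, averaged over axons with at least one AD
#' synapse). The ratio-of-means variant of the restricted fractions is
#' reported alongside the per-axon mean, since the two differ in general.
#'
#' @param profiles output of [innervationProfile()].
#' @return list with `matrix` (`data.frame`: `seedType`, `n`, `L2_AD`,
#'   `DL_AD`, `adFraction`), `restricted` (per-axon means with `nADAxons`)
#'   and `restrictedPooled` (ratio-of-means variant).
#' @export
conditionalMatrix <- function(profiles) {
  sp <- split(profiles, profiles$seedType)
  rows <- lapply(sp, function(d) {
    ad <- d$L2_AD + d$DL_AD
    keep <- ad > 0
    data.frame(
      seedType = d$seedType[1], n = nrow(d),
      L2_AD = mean(d$L2_AD), DL_AD = mean(d$DL_AD),
      adFraction = mean(ad),
      nADAxons = sum(keep),
      restrL2 = if (any(keep)) mean(d$L2_AD[keep] / ad[keep]) else
        NA_real_,
      restrDL = if (any(keep)) mean(d$DL_AD[keep] / ad[keep]) else
        NA_real_,
      pooledRestrL2 = if (any(keep)) mean(d$L2_AD) / mean(ad) else
        NA_real_,
      pooledRestrDL = if (any(keep)) mean(d$DL_AD) / mean(ad) else
        NA_real_)
  })
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  list(matrix = all[, c("seedType", "n", "L2_AD", "DL_AD", "adFraction")],
       restricted = all[, c("seedType", "nADAxons", "restrL2", "restrDL")],
       restrictedPooled = all[, c("seedType", "nADAxons", "pooledRestrL2",
                                  "pooledRestrDL")])
}

#' Multiplicity of AD innervation per axon
#'
#' For each axon, the mean number of synapses per distinct targeted apical
#' dendrite (of the queried type, or any AD). Axons with no qualifying AD
#' target are excluded (averages are not defined on empty sets). Also
#' reports the connection-level fraction of monosynaptic (single-synapse)
#' connections.
#'
#' @param tab an axon table with `adId` set on AD-target rows.
#' @param adType restrict to `"L2_AD"` or `"DL_AD"` targets, or `NULL` for
#'   all AD targets.
#' @return list with `perSeed` (`data.frame`: `seedType`, `nAxons`,
#'   `meanSynapsesPerTarget`, `sem`, `monoFraction`, `nConnections`) and
#'   `overall` (same statistics pooled over seed groups).
#' @export
multiplicityStats <- function(tab, adType = NULL) {
  tab <- axonTable(tab)
  ad <- tab[tab$category %in% (adType %||% c("L2_AD", "DL_AD")) &
            !is.na(tab$adId), , drop = FALSE]
  if (!nrow(ad))
    return(list(perSeed = NULL, overall = NULL))
  conn <- stats::aggregate(list(nSyn = ad$axon),
    by = list(axon = ad$axon, seedType = ad$seedType, adId = ad$adId),
    FUN = length)
  perAxon <- stats::aggregate(list(meanPerTarget = conn$nSyn),
    by = list(axon = conn$axon, seedType = conn$seedType), FUN = mean)
  stat <- function(d, c2) {
    data.frame(nAxons = nrow(d),
               meanSynapsesPerTarget = mean(d$meanPerTarget),
               sem = stats::sd(d$meanPerTarget) / sqrt(nrow(d)),
               monoFraction = mean(c2$nSyn == 1),
               nConnections = nrow(c2))
  }
  perSeed <- do.call(rbind, lapply(split(perAxon, perAxon$seedType),
    function(d) cbind(seedType = d$seedType[1],
                      stat(d, conn[conn$seedType == d$seedType[1], ]))))
  rownames(perSeed) <- NULL
  list(perSeed = perSeed, overall = stat(perAxon, conn))
}

#' Binarized AD-type preference (multiple innervations ignored)
#'
#' Each distinct targeted apical dendrite counts once; per axon the
#' fractions of distinct-AD targets of each type are computed and averaged
#' per seed group. Axons with no distinct AD target are excluded.
#'
#' @param tab an axon table.
#' @return `data.frame` with `seedType`, `nAxons`, `L2_AD`, `DL_AD` (mean
#'   fractions of distinct AD targets).
#' @export
binarizedPreference <- function(tab) {
  tab <- axonTable(tab)
  ad <- tab[tab$category %in% c("L2_AD", "DL_AD") & !is.na(tab$adId), ,
            drop = FALSE]
  if (!nrow(ad)) return(NULL)
  distinct <- unique(ad[, c("axon", "seedType", "adId", "category")])
  perAxon <- do.call(rbind, lapply(split(distinct, distinct$axon),
    function(d) data.frame(seedType = d$seedType[1],
                           fL2 = mean(d$category == "L2_AD"),
                           fDL = mean(d$category == "DL_AD"))))
  out <- do.call(rbind, lapply(split(perAxon, perAxon$seedType),
    function(d) data.frame(seedType = d$seedType[1], nAxons = nrow(d),
                           L2_AD = mean(d$fL2), DL_AD = mean(d$fDL))))
  rownames(out) <- NULL
  out
}

#' Bootstrap test for axonal target specificity
#'
#' Tests, per target category, whether the mean fractional innervation
#' differs between two axon groups. The two groups' per-axon fraction
#' vectors are concatenated and bootstrap resamples of the original group
#' sizes are drawn from the pooled sample; the p-value is the fraction of
#' resampled mean differences at least as extreme (two-sided, in absolute
#' value) as the observed mean difference. Significance uses a Bonferroni
#' threshold of `alpha / nComparisons`. The `pPlus` column adds the
#' observed statistic to the null set (the +1 convention); both
#' conventions are reported.
#'
#' @param groupA,groupB numeric matrices or data.frames, axons in rows and
#'   target categories in columns (same columns).
#' @param nBoot number of bootstrap resamples.
#' @param alpha family significance level.
#' @param nComparisons Bonferroni correction factor.
#' @param seed RNG seed.
#' @return `data.frame` with `category`, `meanA`, `meanB`, `diff`, `p`,
#'   `pPlus`, `significant`.
#' @export
bootstrapSpecificityTest <- function(groupA, groupB, nBoot = 10000,
                                     alpha = 0.05, nComparisons = 8,
                                     seed = 1) {
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  stopifnot(ncol(A) == ncol(B), nrow(A) > 0, nrow(B) > 0)
  nA <- nrow(A); nB <- nrow(B)
  obs <- colMeans(A) - colMeans(B)
  pool <- rbind(A, B)
  n <- nA + nB
  if (!is.null(seed)) set.seed(seed)
  ## resampled axon indices are shared across categories: the resampling
  ## unit is the axon, not the single fraction
  IA <- matrix(sample.int(n, nA * nBoot, replace = TRUE), nBoot)
  IB <- matrix(sample.int(n, nB * nBoot, replace = TRUE), nBoot)
  extreme <- vapply(seq_len(ncol(A)), function(j) {
    pj <- pool[, j]
    d <- rowMeans(matrix(pj[IA], nBoot)) -
      rowMeans(matrix(pj[IB], nBoot))
    sum(abs(d) >= abs(obs[j]))
  }, numeric(1))
  p <- extreme / nBoot
  data.frame(category = colnames(A) %||% paste0("V", seq_len(ncol(A))),
             meanA = colMeans(A), meanB = colMeans(B), diff = obs,
             p = p, pPlus = (extreme + 1) / (nBoot + 1),
             significant = p < alpha / nComparisons,
             row.names = NULL)
}

#' Cross-region consistency of innervation preference
#'
#' Per seed group and target category: the coefficient of variation of the
#' per-region mean fractional innervations (SD of region means divided by
#' their mean, in percent). An omnibus multivariate location test (Wilks'
#' lambda MANOVA of the six retained categories on region; axon initial
#' segment and glia are excluded as near-empty categories that make the
#' covariance singular) is followed, only on rejection, by per-category
#' one-way ANOVAs at a Bonferroni-corrected level.
#'
#' @param profiles output of [innervationProfile()] with a `region`
#'   column; must span at least two regions.
#' @param alpha family significance level for the omnibus test.
#' @return list with `cv` (`data.frame`: `seedType`, `category`, `cv`),
#'   `omnibus` (`data.frame`: `seedType`, `statistic`, `p`, `applicable`)
#'   and `followUp` (per-category ANOVA p-values with Bonferroni flags,
#'   only for seed groups where the omnibus test rejected).
#' @export
regionConsistency <- function(profiles, alpha = 0.05) {
  stopifnot(length(unique(profiles$region)) >= 2)
  cats <- targetCategories()
  retained <- setdiff(cats, c("AIS", "glia"))
  cv <- do.call(rbind, lapply(split(profiles, profiles$seedType),
    function(d) {
      do.call(rbind, lapply(cats, function(cc) {
        rm <- tapply(d[[cc]], d$region, mean)
        data.frame(seedType = d$seedType[1], category = cc,
                   cv = if (mean(rm) > 0)
                     stats::sd(rm) / mean(rm) * 100 else NA_real_)
      }))
    }))
  rownames(cv) <- NULL
  omnibus <- NULL; followUp <- NULL
  for (st in unique(profiles$seedType)) {
    d <- profiles[profiles$seedType == st, , drop = FALSE]
    Y <- as.matrix(d[, retained])
    fit <- tryCatch({
      mv <- stats::manova(Y ~ factor(d$region))
      sm <- summary(mv, test = "Wilks")$stats
      if (is.null(sm) || !nrow(sm) || is.na(sm[1, "Wilks"]))
        stop("test not applicable")
      list(stat = unname(sm[1, "Wilks"]), p = unname(sm[1, "Pr(>F)"]),
           ok = TRUE)
    }, error = function(e) list(stat = NA_real_, p = NA_real_,
                                ok = FALSE))
    omnibus <- rbind(omnibus, data.frame(
      seedType = st, statistic = fit$stat, p = fit$p,
      applicable = fit$ok))
    if (fit$ok && !is.na(fit$p) && fit$p < alpha) {
      fu <- do.call(rbind, lapply(retained, function(cc) {
        a <- stats::anova(stats::aov(d[[cc]] ~ factor(d$region)))
        data.frame(seedType = st, category = cc,
                   p = a[["Pr(>F)"]][1],
                   significant = a[["Pr(>F)"]][1] <
                     alpha / length(retained))
      }))
      followUp <- rbind(followUp, fu)
    }
  }
  list(cv = cv, omnibus = omnibus, followUp = followUp)
}
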