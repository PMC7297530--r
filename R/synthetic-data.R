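## Synthetic annotation generator. Emits NML-backed skeleton annotations of
## apical dendrites with Poisson synapse placement, tabular axon output
## data with tunable AD-type selectivity, two-cluster L5 feature vectors,
## and noisy samples of the distance model -- each with ground truth.

#' Default generator configuration
#'
#' All defaults define the emulated study conditions: per-cell-type synapse
#' rates at the main bifurcation and at the distal tuft (synapses per um of
#' shaft path), the exponential distance model of the inhibitory fraction
#' along the trunk, axon-population parameters (AD-targeting probability,
#' type selectivity, per-target multiplicity, non-AD category mix), the
#' two-cluster L5 morphological feature model, double-spine and spine-neck
#' innervation rates, and skeleton geometry (node spacing, trunk lengths,
#' tuft branch lengths). See the methods vignette for the provenance and
#' calibration of every value.
#'
#' @return nested list of generator parameters.
#' @export
generatorConfig <- function() {
  ct <- c("L2", "L2MN", "L3", "L5tt", "L5st", "DL")
  list(
    dataset = list(name = "synthetic", voxelSize = c(11.24, 11.24, 28),
                   piaOffset = 0, depthAxis = 3L, cuttingAxis = 3L,
                   thicknessCorrection = 1),
    geometry = list(
      nodeSpacing = 1,
      mbDepth = c(mean = 100, sd = 10),
      somaDistance = list(L2 = c(40, 10), L2MN = c(50, 12),
                          L3 = c(150, 20), L5tt = c(320, 30),
                          L5st = c(300, 30)),
      dlTrunkBelow = 60,
      tuftLength = c(L2 = 60, L2MN = 60, L3 = 60, L5tt = 80, L5st = 50,
                     DL = 60),
      distalLength = 30,
      branchAngleDeg = 30,
      trunkDiameter = c(L2 = 2.16, L2MN = 2.16, L3 = 1.9, L5tt = 2.4,
                        L5st = 1.6, DL = 1.77),
      spineNeckLength = 1, spineHeadLength = 0.5,
      obliqueAngleDeg = 75),
    rates = list(
      mb = data.frame(celltype = ct,
                      shaft = c(0.42, 0.42, 0.05, 0.07, 0.41, 0.22),
                      spine = c(0.84, 0.84, 2.00, 1.90, 1.00, 2.16)),
      distal = data.frame(celltype = ct,
                          shaft = c(0.08, 0.08, 0.09, 0.23, 0.26, 0.23),
                          spine = c(1.79, 1.79, 1.76, 1.00, 0.66, 1.00)),
      doubleSpine = c(L2 = 0.064, L2MN = 0.064, L3 = 0.04, L5tt = 0.04,
                      L5st = 0.04, DL = 0.035),
      neckPerSpine = 0.02,
      excShaftMix = c(L2 = 0.01, L2MN = 0.01, L3 = 0.02, L5tt = 0.02,
                      L5st = 0.60, DL = 0.02)),
    distanceModel = c(a = 1.57, b = -0.047, c = 0.1),
    distanceNoiseSd = 0.12,
    distanceRange = c(10, 330),
    nDistancePoints = 81,
    axons = list(
      pAD = 0.203, selectivity = 0.548,
      synapsesPerAxon = c(mean = 30, min = 6),
      multiplicity = c(`1` = 0.77, `2` = 0.16, `3` = 0.05, `4` = 0.02),
      nonADMix = c(other_shaft = 0.568, single_spine = 0.12,
                   double_spine = 0.10, soma = 0.20, AIS = 0.01,
                   glia = 0.002),
      excSpineFraction = 0.92, adPoolSize = 60,
      seedGroups = data.frame(
        seedType = rep(c("L2", "DL"), each = 4),
        seedLocation = "shaft", layerContext = "L2",
        region = rep(c("S1", "V2", "PPC", "ACC"), 2),
        n = c(21, 20, 21, 30, 19, 20, 20, 32), excMix = 0),
      identityMix = data.frame(
        seedType = c("L2", "DL", "L5st", "L5st"),
        layerContext = c("L2", "L2", "L1", "L2"),
        shaftExcFraction = c(0.01, 0.02, 0.44, 0.60))),
    l5 = list(
      nTT = 7, nST = 11,
      ttMean = c(somaEquivDiameter = 17, bifurcationDepth = 115,
                 nOblique = 6, trunkDiameter = 2.4),
      ttSd = c(1, 10, 1.2, 0.25),
      stMean = c(somaEquivDiameter = 13, bifurcationDepth = 85,
                 nOblique = 3, trunkDiameter = 1.6),
      stSd = c(1, 10, 1, 0.2),
      eModel = c(slope = 0.44, intercept = 1.4), eNoiseSd = 0.25,
      fracModel = c(a = 0.043, b = 0.13, c = 0.58, d = 1.40),
      iNoiseSd = 0.04))
}

## straight chain of nodes from `origin` along unit `direction`. Node arc
## positions are the regular grid plus `extraArcs` (synapse event
## positions inserted exactly, so no event is displaced by rounding).
## When attachId is given the chain omits its arc-0 node and connects its
## first node to that id instead.
.makeChain <- function(origin, direction, length, spacing, idStart,
                       attachId = NULL, extraArcs = numeric()) {
  nSeg <- max(1L, round(length / spacing))
  arc <- sort(unique(c(seq(0, length, length.out = nSeg + 1),
                       extraArcs)))
  if (!is.null(attachId)) arc <- arc[arc > 0]
  ids <- idStart + seq_along(arc) - 1L
  nodes <- data.frame(id = ids,
                      x = origin[1] + arc * direction[1],
                      y = origin[2] + arc * direction[2],
                      z = origin[3] + arc * direction[3],
                      arc = arc)
  if (is.null(attachId)) {
    edges <- if (length(ids) > 1) cbind(ids[-length(ids)], ids[-1]) else
      matrix(integer(), ncol = 2)
  } else {
    edges <- cbind(c(attachId, ids[-length(ids)]), ids)
  }
  list(nodes = nodes, edges = edges)
}

.distShare <- function(d, dm) {
  pmin(0.9, pmax(0.02, dm["c"] + dm["a"] * exp(dm["b"] * d)))
}

## sample synapses on one path compartment; returns event table
## kind: "shaft" or "spine"
.sampleEvents <- function(lo, hi, shaftRate, spineRate) {
  L <- hi - lo
  if (L <= 0) return(data.frame(arc = numeric(), kind = character()))
  nS <- stats::rpois(1, shaftRate * L)
  nP <- stats::rpois(1, spineRate * L)
  data.frame(arc = stats::runif(nS + nP, lo, hi),
             kind = rep(c("shaft", "spine"), c(nS, nP)))
}

## one synthetic cell: returns a SkeletonTree in canonical um coordinates
## (z = depth below pia) plus a truth row
.generateCell <- function(celltype, cfg, cellIndex) {
  g <- cfg$geometry
  r <- cfg$rates
  mbR <- r$mb[r$mb$celltype == celltype, ]
  diR <- r$distal[r$distal$celltype == celltype, ]
  midShaft <- (mbR$shaft + diR$shaft) / 2
  midSpine <- (mbR$spine + diR$spine) / 2
  pDouble <- r$doubleSpine[[celltype]]
  pNeck <- r$neckPerSpine
  zMB <- stats::rnorm(1, g$mbDepth["mean"], g$mbDepth["sd"])
  mbPos <- c(cellIndex * 50, 0, zMB)
  hasSoma <- celltype != "DL"

  ## sample all synapse events per path first; their arcs become exact
  ## node positions so window clipping and event counting agree
  if (hasSoma) {
    dm <- g$somaDistance[[celltype]]
    dMB <- max(15, stats::rnorm(1, dm[1], dm[2]))
    trunkLen <- dMB
  } else {
    dMB <- NA_real_
    trunkLen <- g$dlTrunkBelow
  }
  tl <- g$tuftLength[[celltype]]
  distalLo <- max(10, tl - g$distalLength)

  trunkEvents <- if (hasSoma) {
    ev <- .sampleEvents(max(0, trunkLen - 10), trunkLen,
                        mbR$shaft, mbR$spine)
    if (trunkLen > 10) {
      ## below the window: total rate fixed at the MB total, inhibitory
      ## share following the exponential distance model
      tot <- mbR$shaft + mbR$spine
      n <- stats::rpois(1, tot * (trunkLen - 10))
      if (n > 0) {
        a <- stats::runif(n, 0, trunkLen - 10)
        sh <- .distShare(a, cfg$distanceModel)  # arc == distance to soma
        ev <- rbind(ev, data.frame(
          arc = a, kind = ifelse(stats::runif(n) < sh, "shaft",
                                 "spine")))
      }
    }
    ev
  } else {
    .sampleEvents(0, trunkLen, mbR$shaft, mbR$spine)
  }
  branchEvents <- lapply(1:2, function(i) {
    ev <- rbind(.sampleEvents(0, min(10, tl), mbR$shaft, mbR$spine),
                .sampleEvents(distalLo, tl, diR$shaft, diR$spine))
    if (distalLo > 10)
      ev <- rbind(ev, .sampleEvents(10, distalLo, midShaft, midSpine))
    ev
  })

  if (hasSoma) {
    phi <- if (celltype == "L2MN") g$obliqueAngleDeg else 0
    phi <- phi * pi / 180
    dirDown <- c(sin(phi), 0, cos(phi))
    somaPos <- mbPos + dMB * dirDown
    trunk <- .makeChain(somaPos, -dirDown, trunkLen, g$nodeSpacing, 1L,
                        extraArcs = trunkEvents$arc)
  } else {
    bottom <- mbPos + c(0, 0, trunkLen)
    trunk <- .makeChain(bottom, c(0, 0, -1), trunkLen, g$nodeSpacing,
                        1L, extraArcs = trunkEvents$arc)
  }
  mbId <- trunk$nodes$id[nrow(trunk$nodes)]
  nextId <- mbId + 1L
  ang <- g$branchAngleDeg * pi / 180
  paths <- list(trunk = trunk)
  for (i in 1:2) {
    dir <- c(c(-1, 1)[i] * sin(ang), 0, -cos(ang))
    br <- .makeChain(mbPos, dir, tl, g$nodeSpacing, nextId,
                     attachId = mbId, extraArcs = branchEvents[[i]]$arc)
    nextId <- max(br$nodes$id) + 1L
    paths[[c("branchA", "branchB")[i]]] <- br
  }

  comments <- list()
  addComment <- function(id, txt) {
    key <- as.character(id)
    comments[[key]] <<- c(comments[[key]], txt)
  }
  if (hasSoma) addComment(trunk$nodes$id[1], "soma")
  addComment(mbId, "main bifurcation")

  spineNodes <- list(); spineEdges <- list()
  placeOn <- function(path, events) {
    if (!nrow(events)) return(invisible())
    idx <- match(events$arc, path$nodes$arc)   # exact: arcs are nodes
    for (k in seq_len(nrow(events))) {
      nid <- path$nodes$id[idx[k]]
      if (events$kind[k] == "shaft") {
        addComment(nid, "synapse shaft")
      } else {
        base <- unlist(path$nodes[idx[k], c("x", "y", "z")])
        th <- stats::runif(1, 0, 2 * pi)
        off <- c(cos(th), sin(th), 0)
        neckId <- nextId; headId <- nextId + 1L
        nextId <<- nextId + 2L
        np <- base + g$spineNeckLength * off
        hp <- base + (g$spineNeckLength + g$spineHeadLength) * off
        spineNodes[[length(spineNodes) + 1L]] <<- data.frame(
          id = c(neckId, headId),
          x = c(np[1], hp[1]), y = c(np[2], hp[2]), z = c(np[3], hp[3]),
          arc = NA_real_)
        spineEdges[[length(spineEdges) + 1L]] <<- rbind(c(nid, neckId),
                                                        c(neckId, headId))
        addComment(neckId, "spine neck")
        addComment(headId, "synapse spine_primary")
        if (stats::runif(1) < pDouble)
          addComment(headId, "synapse spine_secondary")
        if (stats::runif(1) < pNeck)
          addComment(neckId, "synapse spine_neck")
      }
    }
  }
  placeOn(paths$trunk, trunkEvents)
  placeOn(paths$branchA, branchEvents[[1]])
  placeOn(paths$branchB, branchEvents[[2]])

  allNodes <- rbind(do.call(rbind, lapply(paths, `[[`, "nodes")),
                    if (length(spineNodes)) do.call(rbind, spineNodes))
  allEdges <- rbind(do.call(rbind, lapply(paths, `[[`, "edges")),
                    if (length(spineEdges)) do.call(rbind, spineEdges))
  allNodes$arc <- NULL
  ## shaft nodes carry the trunk radius (nm); spine nodes none
  shaftIds <- unlist(lapply(paths, function(p) p$nodes$id))
  allNodes$radius <- ifelse(allNodes$id %in% shaftIds,
                            g$trunkDiameter[[celltype]] / 2 * 1000,
                            NA_real_)
  allNodes$comment <- vapply(as.character(allNodes$id), function(k)
    if (!is.null(comments[[k]]))
      paste(comments[[k]], collapse = "; ") else NA_character_,
    character(1))
  tree <- SkeletonTree(sprintf("ad_%s_%03d", celltype, cellIndex),
                       allNodes, allEdges)
  truth <- data.frame(name = tree@name, celltype = celltype,
                      mbDepth = zMB, somaDistance = dMB,
                      shaftRateMB = mbR$shaft, spineRateMB = mbR$spine,
                      shaftRateDistal = diR$shaft,
                      spineRateDistal = diR$spine,
                      doubleSpineRate = pDouble)
  list(tree = tree, truth = truth)
}

#' Generate synthetic apical-dendrite annotations
#'
#' Builds per-cell skeletons (trunk, Y-shaped main bifurcation, two tuft
#' branches, spines as short labelled side branches) and places synapses
#' by independent Poisson processes along arc length at compartment- and
#' cell-type-specific rates. The inhibitory share along the trunk follows
#' the exponential distance model. Landmarks and synapse classes are
#' encoded in node comments, so the emitted [AnnotationSet-class] is fully
#' self-describing and round-trips through [writeNML()] / [parseNML()].
#'
#' The annotation set is in voxel coordinates (canonical frame: the depth
#' axis is `z`); [extractDendrites()] returns the analysis-ready
#' micrometre representation.
#'
#' @param config generator configuration, see [generatorConfig()].
#' @param nPerCelltype named integer vector, cells per type (names from
#'   `L2`, `L2MN`, `L3`, `L5tt`, `L5st`, `DL`).
#' @param seed optional RNG seed (fixed seed gives byte-identical NML).
#' @return list with `annotation` (an [AnnotationSet-class], voxel units)
#'   and `truth` (`data.frame` of per-cell ground truth).
#' @export
generateDendrites <- function(config = generatorConfig(),
                              nPerCelltype = c(L2 = 5, DL = 5),
                              seed = NULL) {
  if (any(nPerCelltype < 0) || is.null(names(nPerCelltype)))
    stop("invalid config: nPerCelltype must be a named non-negative vector",
         call. = FALSE)
  bad <- setdiff(names(nPerCelltype), config$rates$mb$celltype)
  if (length(bad))
    stop("invalid config: unknown cell types ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cells <- list()
  idx <- 0
  for (ct in names(nPerCelltype)) {
    for (i in seq_len(nPerCelltype[[ct]])) {
      idx <- idx + 1
      cells[[idx]] <- .generateCell(ct, config, idx)
    }
  }
  trees <- lapply(cells, function(cl) {
    tr <- cl$tree
    vs <- config$dataset$voxelSize
    tr@nodes$x <- tr@nodes$x * 1000 / vs[1]
    tr@nodes$y <- tr@nodes$y * 1000 / vs[2]
    tr@nodes$z <- tr@nodes$z * 1000 / vs[3]
    tr
  })
  meta <- do.call(DatasetMeta, config$dataset)
  list(annotation = AnnotationSet(trees, meta, unit = "voxel"),
       truth = do.call(rbind, lapply(cells, `[[`, "truth")))
}

#' Extract analysis-ready dendrite annotations
#'
#' Converts an annotation set to physical units (micrometres; the depth
#' axis becomes `z` = depth below pia, pia offset applied), decodes the
#' comment conventions (cell type from the tree name `ad_<type>_<i>`,
#' `"soma"` / `"main bifurcation"` landmarks, `"spine neck"` labels,
#' `"synapse <class>"` entries, multiple entries separated by `";"`) and
#' returns one [DendriteAnnotation-class] per tree with the default
#' within-10-um main-bifurcation analysis window.
#'
#' @param aset an [AnnotationSet-class] (voxel or nm units).
#' @return list of [DendriteAnnotation-class] objects.
#' @export
extractDendrites <- function(aset) {
  if (aset@unit == "voxel") aset <- toPhysical(aset)
  m <- aset@meta
  lapply(aset@trees, function(tr) {
    nd <- tr@nodes
    nd$x <- nd$x / 1000; nd$y <- nd$y / 1000; nd$z <- nd$z / 1000
    if (m@depthAxis != 3) {          # canonicalize: depth on z
      ax <- c("x", "y", "z")
      tmp <- nd[[ax[m@depthAxis]]]
      nd[[ax[m@depthAxis]]] <- nd$z
      nd$z <- tmp
    }
    nd$z <- nd$z + m@piaOffset
    nd$radius <- nd$radius / 1000    # nm -> um
    ct <- sub("^ad_([A-Za-z0-9]+)_.*$", "\\1", tr@name)
    if (!(ct %in% .celltypes)) ct <- "unknown"
    parts <- strsplit(ifelse(is.na(nd$comment), "", nd$comment), ";")
    parts <- lapply(parts, trimws)
    has <- function(tag) vapply(parts, function(p) tag %in% p, logical(1))
    soma <- nd$id[has("soma")]
    mb <- nd$id[has("main bifurcation")]
    neckSeeds <- nd$id[has("spine neck")]
    tree <- SkeletonTree(tr@name, nd, tr@edges, tr@groupLabel)
    spn <- if (length(neckSeeds))
      .spineSubtreeNodes(tree, neckSeeds) else integer()
    syn <- do.call(rbind, lapply(seq_along(parts), function(i) {
      sy <- grep("^synapse ", parts[[i]], value = TRUE)
      if (!length(sy)) return(NULL)
      data.frame(node = nd$id[i], onto = sub("^synapse ", "", sy))
    }))
    if (is.null(syn))
      syn <- data.frame(node = integer(), onto = character())
    syn <- cbind(id = seq_len(nrow(syn)), syn)
    DendriteAnnotation(tree, celltype = ct,
                       somaNode = if (length(soma)) soma[1] else
                         NA_integer_,
                       mainBifurcationNode = if (length(mb)) mb[1] else
                         NA_integer_,
                       spineNeckNodes = spn, synapses = syn,
                       analysisWindow = c(-10, 10))
  })
}

#' Generate a synthetic axon output table
#'
#' Per axon: the number of output synapses is Poisson (truncated below);
#' each synapse targets an apical dendrite with probability `pAD`. AD
#' synapses are organized into connections with multiplicities from the
#' configured distribution; each connection targets an AD of the axon's
#' own seed type with probability `(1 + s) / 2` (selectivity `s = 0` is
#' indiscriminate, `s = 1` fully selective). Non-AD synapses draw a
#' category from the configured mix. Groups with `excMix > 0` plant
#' excitatory (spine-preferring) axons among the shaft-seeded population
#' for identity-calibration experiments.
#'
#' @param config generator configuration.
#' @param seedGroups `data.frame` describing the seed cohorts (columns
#'   `seedType`, `seedLocation`, `layerContext`, `region`, `n`, optional
#'   `excMix`); defaults to `config$axons$seedGroups`.
#' @param seed optional RNG seed.
#' @return list with `table` (an [axonTable()]-valid `data.frame`, one row
#'   per output synapse) and `truth` (`data.frame` per axon with the true
#'   class), plus the planted `selectivity` and `pAD`.
#' @export
generateAxons <- function(config = generatorConfig(), seedGroups = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- config$axons
  sg <- seedGroups %||% ax$seedGroups
  if (is.null(sg$excMix)) sg$excMix <- 0
  if (any(sg$n <= 0))
    stop("invalid config: group sizes must be positive", call. = FALSE)
  rows <- list(); truth <- list(); aid <- 0
  for (gi in seq_len(nrow(sg))) {
    for (k in seq_len(sg$n[gi])) {
      aid <- aid + 1
      axid <- sprintf("ax%04d", aid)
      trueClass <- if (stats::runif(1) < sg$excMix[gi]) "excitatory" else
        "putative_inhibitory"
      nSyn <- max(ax$synapsesPerAxon["min"],
                  stats::rpois(1, ax$synapsesPerAxon["mean"]))
      if (trueClass == "excitatory") {
        sp <- stats::runif(nSyn) < ax$excSpineFraction
        cat <- ifelse(sp, "single_spine", "other_shaft")
        adId <- rep(NA_character_, nSyn)
      } else {
        nAD <- stats::rbinom(1, nSyn, ax$pAD)
        cat <- character(); adId <- character()
        if (nAD > 0) {
          mult <- integer()
          while (sum(mult) < nAD)
            mult <- c(mult, sample(as.integer(names(ax$multiplicity)), 1,
                                   prob = ax$multiplicity))
          over <- sum(mult) - nAD
          if (over > 0) mult[length(mult)] <- mult[length(mult)] - over
          mult <- mult[mult > 0]
          own <- if (sg$seedType[gi] == "L2") "L2_AD" else "DL_AD"
          other <- setdiff(c("L2_AD", "DL_AD"), own)
          ctype <- ifelse(stats::runif(length(mult)) <
                            (1 + ax$selectivity) / 2, own, other)
          adPick <- character(length(mult))
          for (tt in unique(ctype)) {
            i <- which(ctype == tt)
            pool <- paste0(sg$region[gi], "_", tt, "_",
                           seq_len(ax$adPoolSize))
            adPick[i] <- sample(pool, length(i), replace = FALSE)
          }
          cat <- rep(ctype, mult)
          adId <- rep(adPick, mult)
        }
        nOther <- nSyn - nAD
        oc <- sample(names(ax$nonADMix), nOther, replace = TRUE,
                     prob = ax$nonADMix)
        cat <- c(cat, oc)
        adId <- c(adId, rep(NA_character_, nOther))
      }
      rows[[aid]] <- data.frame(
        axon = axid, seedType = sg$seedType[gi],
        seedLocation = sg$seedLocation[gi],
        region = sg$region[gi], layerContext = sg$layerContext[gi],
        category = cat, adId = adId,
        singleSpine = cat == "single_spine")
      truth[[aid]] <- data.frame(axon = axid, trueClass = trueClass,
                                 seedType = sg$seedType[gi],
                                 seedLocation = sg$seedLocation[gi],
                                 layerContext = sg$layerContext[gi],
                                 region = sg$region[gi], nSynapses = nSyn)
    }
  }
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth),
       selectivity = ax$selectivity, pAD = ax$pAD)
}

#' Seed groups for the identity-calibration experiment
#'
#' Builds shaft-seeded groups with the configured per-structure excitatory
#' mixing rates (`config$axons$identityMix`).
#'
#' @param config generator configuration.
#' @param nPerGroup axons per group.
#' @return `data.frame` usable as `seedGroups` in [generateAxons()].
#' @export
identitySeedGroups <- function(config = generatorConfig(),
                               nPerGroup = 40) {
  im <- config$axons$identityMix
  data.frame(seedType = im$seedType, seedLocation = "shaft",
             layerContext = im$layerContext, region = "S1",
             n = nPerGroup, excMix = im$shaftExcFraction)
}

#' Generate the two-cluster L5 morphological feature table
#'
#' Samples the four features from the configured thick-tufted and
#' slender-tufted Gaussian clusters, derives the thick-tuftedness score
#' (PC1) and generates per-cell excitatory and putative-inhibitory
#' synapse densities from the configured linear and linear-fraction
#' models with additive noise.
#'
#' @param config generator configuration.
#' @param seed optional RNG seed.
#' @return list with `features` (`data.frame`), `labels` (true subtype),
#'   `scores` (PC1), `eDensity`, `iDensity`.
#' @export
generateL5Features <- function(config = generatorConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  l5 <- config$l5
  n <- l5$nTT + l5$nST
  labels <- rep(c("L5tt", "L5st"), c(l5$nTT, l5$nST))
  draw <- function(m, s, k)
    vapply(1:4, function(j) stats::rnorm(k, m[j], s[j]),
           numeric(k))
  X <- rbind(draw(l5$ttMean, l5$ttSd, l5$nTT),
             draw(l5$stMean, l5$stSd, l5$nST))
  colnames(X) <- .l5FeatureNames
  X[, "nOblique"] <- pmax(0, round(X[, "nOblique"]))
  X[, "somaEquivDiameter"] <- pmax(5, X[, "somaEquivDiameter"])
  X[, "trunkDiameter"] <- pmax(0.5, X[, "trunkDiameter"])
  features <- as.data.frame(X)
  x <- thickTuftedness(features)$scores
  eTrue <- l5$eModel["slope"] * x + l5$eModel["intercept"]
  eDensity <- pmax(0.05, eTrue + stats::rnorm(n, 0, l5$eNoiseSd))
  fm <- l5$fracModel
  fTrue <- pmin(0.95, pmax(0.02,
    (fm["a"] * x + fm["b"]) / (fm["c"] * x + fm["d"])))
  iDensity <- pmax(0.02, eTrue * fTrue / (1 - fTrue) +
                     stats::rnorm(n, 0, l5$iNoiseSd))
  list(features = features, labels = labels, scores = x,
       eDensity = unname(eDensity), iDensity = unname(iDensity))
}

#' Sample noisy observations of the exponential distance model
#'
#' Draws distances uniformly over the configured range and evaluates the
#' inhibitory-fraction distance model with additive Gaussian noise.
#'
#' @param config generator configuration.
#' @param n number of points.
#' @param seed optional RNG seed.
#' @return `data.frame` with `distance` (um) and `fraction`.
#' @export
generateDistanceSamples <- function(config = generatorConfig(),
                                    n = config$nDistancePoints,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dm <- config$distanceModel
  x <- stats::runif(n, config$distanceRange[1], config$distanceRange[2])
  y <- dm["c"] + dm["a"] * exp(dm["b"] * x) +
    stats::rnorm(n, 0, config$distanceNoiseSd)
  data.frame(distance = x, fraction = unname(y))
}
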