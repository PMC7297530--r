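## Synapse classification, densities, inhibitory fractions, and profiles
## along path distance and cortical depth.

#' Classify input synapses by structural target
#'
#' Synapses on the dendritic shaft, on spine necks, and secondary
#' innervations of an already-innervated spine are putative inhibitory;
#' primary spine innervations are excitatory.
#'
#' @param onto character vector of structural categories (`"shaft"`,
#'   `"spine_primary"`, `"spine_secondary"`, `"spine_neck"`).
#' @return character vector, `"excitatory"` or `"putative_inhibitory"`.
#' @examples
#' classifySynapse(c("shaft", "spine_primary", "spine_secondary"))
#' @export
classifySynapse <- function(onto) {
  bad <- setdiff(unique(onto), .ontoLevels)
  if (length(bad))
    stop("unknown synapse category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ifelse(onto == "spine_primary", "excitatory", "putative_inhibitory")
}

#' Synapse densities and inhibitory fraction of one dendrite
#'
#' Counts classified synapses (optionally restricted to a path-distance
#' window around a landmark), divides by the spine-pruned shaft path length
#' of the window (and, when diameter information is available, by the
#' corresponding surface area), and reports the putative-inhibitory
#' fraction plus spine statistics.
#'
#' @param ad a [DendriteAnnotation-class] (micrometre units).
#' @param window optional numeric length-2 arc interval; `c(-10, 10)`
#'   means within 10 um of the landmark (see [shaftPathLength()]).
#' @param ref `"bifurcation"` (default) or `"soma"`.
#' @return An object of class `"DensityResult"`: a list with counts
#'   (`nExc`, `nInh` and per-category `nShaft`, `nSpinePrimary`,
#'   `nSpineSecondary`, `nSpineNeck`), `shaftLength` (um), `surfaceArea`
#'   (um^2 or `NA`), length and area densities (`densExcLen`,
#'   `densInhLen`, `densShaftLen`, `densExcArea`, `densInhArea`),
#'   `inhFraction`, `spineDensity` (primary spine synapses per um),
#'   `multiSpineFraction` (innervated spines carrying two or more
#'   synapses), and `corrected = FALSE`.
#' @seealso [correctDensity()] for axon-identity correction.
#' @export
densityResult <- function(ad, window = NULL, ref = "bifurcation") {
  syn <- ad@synapses
  if (!is.null(window) && nrow(syn)) {
    d <- arcDistances(ad, ref)
    arc <- d[as.character(syn$node)]
    w <- if (min(window) < 0) c(0, max(abs(window))) else sort(window)
    syn <- syn[!is.na(arc) & arc >= w[1] & arc <= w[2], , drop = FALSE]
  }
  L <- shaftPathLength(ad, window, ref)
  if (L <= 0)
    stop("undefined density: zero shaft path length in window",
         call. = FALSE)
  cls <- if (nrow(syn)) classifySynapse(syn$onto) else character()
  nExc <- sum(cls == "excitatory")
  nInh <- sum(cls == "putative_inhibitory")
  area <- tryCatch(surfaceArea(L, averageDiameter(ad)),
                   error = function(e) NA_real_)
  ## spine multiplicity: group spine-head synapses by node
  spineSyn <- syn[syn$onto %in% c("spine_primary", "spine_secondary"), ,
                  drop = FALSE]
  innervated <- unique(spineSyn$node[spineSyn$onto == "spine_primary"])
  perSpine <- table(factor(spineSyn$node, levels = innervated))
  multi <- if (length(innervated))
    sum(perSpine >= 2) / length(innervated) else NA_real_
  res <- list(
    nExc = nExc, nInh = nInh,
    nShaft = sum(syn$onto == "shaft"),
    nSpinePrimary = sum(syn$onto == "spine_primary"),
    nSpineSecondary = sum(syn$onto == "spine_secondary"),
    nSpineNeck = sum(syn$onto == "spine_neck"),
    shaftLength = L, surfaceArea = area,
    densExcLen = nExc / L, densInhLen = nInh / L,
    densShaftLen = sum(syn$onto == "shaft") / L,
    densSpineLen = sum(syn$onto == "spine_primary") / L,
    densExcArea = nExc / area, densInhArea = nInh / area,
    inhFraction = if (nExc + nInh > 0) nInh / (nExc + nInh) else NA_real_,
    spineDensity = sum(syn$onto == "spine_primary") / L,
    multiSpineFraction = multi,
    corrected = FALSE,
    celltype = ad@celltype)
  class(res) <- "DensityResult"
  res
}

#' @export
print.DensityResult <- function(x, ...) {
  cat(sprintf(
    "DensityResult [%s%s]: %d exc + %d inh on %.2f um shaft (i/(i+e) = %.3f)\n",
    x$celltype, if (x$corrected) ", corrected" else "",
    x$nExc, x$nInh, x$shaftLength,
    if (is.na(x$inhFraction)) NaN else x$inhFraction))
  invisible(x)
}

#' Summarize density results per dendrite and pooled
#'
#' Per-dendrite statistics are means (with SEM) over dendrites; pooled
#' statistics sum counts and lengths first and then divide. The two need
#' not agree (mean of ratios vs ratio of means) and both are labelled.
#'
#' @param results list of `"DensityResult"` objects.
#' @return list with `perDendrite` (`data.frame` of per-dendrite values
#'   plus `mean` and `sem` attributes in `summary`), `summary`
#'   (`data.frame`: statistic, mean, sem, n) and `pooled` (list with
#'   pooled densities and fraction).
#' @export
summarizeDensities <- function(results) {
  stopifnot(length(results) > 0)
  grab <- function(f) vapply(results, function(r) r[[f]], numeric(1))
  per <- data.frame(
    nExc = grab("nExc"), nInh = grab("nInh"),
    shaftLength = grab("shaftLength"),
    densExcLen = grab("densExcLen"), densInhLen = grab("densInhLen"),
    densShaftLen = grab("densShaftLen"),
    densSpineLen = grab("densSpineLen"),
    inhFraction = grab("inhFraction"),
    multiSpineFraction = grab("multiSpineFraction"))
  sem <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  summ <- data.frame(
    statistic = names(per),
    mean = vapply(per, mean, numeric(1), na.rm = TRUE),
    sem = vapply(per, sem, numeric(1)),
    n = vapply(per, function(v) sum(!is.na(v)), numeric(1)),
    row.names = NULL)
  totInh <- sum(per$nInh); totExc <- sum(per$nExc)
  totLen <- sum(per$shaftLength)
  pooled <- list(densInhLen = totInh / totLen,
                 densExcLen = totExc / totLen,
                 inhFraction = totInh / (totInh + totExc),
                 pathLength = totLen, n = length(results))
  list(perDendrite = per, summary = summ, pooled = pooled)
}

#' Inhibitory fraction profile along path distance to soma
#'
#' Bins synapses (pooled over the given dendrites) by path distance to the
#' soma into half-open `[lo, hi)` bins, then merges any bin with fewer than
#' `minCount` synapses into its immediate proximal neighbour (or distal
#' neighbour when there is none), and reports the per-bin putative
#' inhibitory fraction.
#'
#' @param ads a [DendriteAnnotation-class] or list of them (soma landmark
#'   required).
#' @param bin bin width, micrometres.
#' @param minCount minimum synapse count per reported bin.
#' @return `data.frame` with `binStart`, `binEnd`, `nExc`, `nInh`,
#'   `inhFraction`, `mergedFrom` (indices of the original bins pooled into
#'   each reported bin). Zero rows if there are no synapses.
#' @export
distanceProfile <- function(ads, bin = 10, minCount = 4) {
  if (is(ads, "DendriteAnnotation")) ads <- list(ads)
  pts <- do.call(rbind, lapply(ads, function(ad) {
    syn <- ad@synapses
    if (!nrow(syn)) return(NULL)
    d <- arcDistances(ad, "soma")
    data.frame(arc = as.numeric(d[as.character(syn$node)]),
               cls = classifySynapse(syn$onto))
  }))
  if (is.null(pts) || !nrow(pts))
    return(data.frame(binStart = numeric(), binEnd = numeric(),
                      nExc = integer(), nInh = integer(),
                      inhFraction = numeric(), mergedFrom = character()))
  hi <- ceiling(max(pts$arc) / bin) * bin
  if (hi == 0) hi <- bin
  breaks <- seq(0, hi, by = bin)
  idx <- findInterval(pts$arc, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  nInh <- tabulate(idx[pts$cls == "putative_inhibitory"], nb)
  nExc <- tabulate(idx[pts$cls == "excitatory"], nb)
  ## drop leading/trailing empty bins outside the data range
  merged <- mergeBins(nExc + nInh, minCount)
  out <- do.call(rbind, lapply(merged, function(grp) {
    data.frame(binStart = breaks[min(grp)], binEnd = breaks[max(grp) + 1],
               nExc = sum(nExc[grp]), nInh = sum(nInh[grp]),
               mergedFrom = paste(grp, collapse = ","))
  }))
  out$inhFraction <- ifelse(out$nExc + out$nInh > 0,
                            out$nInh / (out$nExc + out$nInh), NA_real_)
  out[, c("binStart", "binEnd", "nExc", "nInh", "inhFraction",
          "mergedFrom")]
}

#' Merge deficient bins into neighbours
#'
#' Scans bins from proximal to distal; any bin whose total is below
#' `minCount` is merged into its immediate proximal neighbour when one
#' exists, else into its distal neighbour, repeating until every reported
#' bin reaches the minimum (or a single bin remains).
#'
#' @param counts integer vector of per-bin totals.
#' @param minCount minimum total per reported bin.
#' @return list of integer vectors: the original bin indices pooled into
#'   each reported bin, in order.
#' @export
mergeBins <- function(counts, minCount = 4) {
  groups <- as.list(seq_along(counts))
  total <- function(g) sum(counts[g])
  repeat {
    if (length(groups) <= 1) break
    tots <- vapply(groups, total, numeric(1))
    bad <- which(tots < minCount)
    if (!length(bad)) break
    i <- bad[1]
    if (i > 1) {
      groups[[i - 1]] <- c(groups[[i - 1]], groups[[i]])
      groups[[i]] <- NULL
    } else {
      groups[[2]] <- c(groups[[1]], groups[[2]])
      groups[[1]] <- NULL
    }
  }
  lapply(groups, sort)
}

#' Pooled inhibitory fraction and densities per cortical depth slab
#'
#' Partitions dendrites into virtual tangential sections of `slab`
#' micrometres of cortical depth (the canonical depth axis is `z`, i.e.
#' depth below pia as produced by [extractDendrites()]), pools synapse
#' counts and spine-pruned path lengths across all dendritic segments per
#' slab, and attaches a percentile bootstrap confidence interval obtained
#' by resampling dendrites.
#'
#' @param ads list of [DendriteAnnotation-class] objects whose `z`
#'   coordinate is depth below pia in micrometres.
#' @param slab slab thickness, micrometres.
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return `data.frame` with one row per slab holding pooled counts, path
#'   length, densities, `inhFraction` and its bootstrap interval
#'   (`fracLo`, `fracHi`). Slabs with zero path length are omitted.
#' @export
corticalDepthProfile <- function(ads, slab = 100, nBoot = 10000,
                                 seed = 1, conf = 0.95) {
  stopifnot(length(ads) > 0)
  allZ <- unlist(lapply(ads, function(ad) ad@tree@nodes$z))
  lo <- floor(min(allZ) / slab) * slab
  hi <- ceiling(max(allZ) / slab) * slab
  if (hi == lo) hi <- lo + slab
  breaks <- seq(lo, hi, by = slab)
  nb <- length(breaks) - 1
  ## per dendrite x slab: counts and path length
  perDend <- lapply(ads, function(ad) {
    pt <- .prunedTree(ad)
    lens <- .edgeLengths(pt@nodes, pt@edges)
    i <- match(pt@edges[, 1], pt@nodes$id)
    j <- match(pt@edges[, 2], pt@nodes$id)
    z1 <- pt@nodes$z[i]; z2 <- pt@nodes$z[j]
    zmin <- pmin(z1, z2); zmax <- pmax(z1, z2); span <- zmax - zmin
    pathLen <- vapply(seq_len(nb), function(k) {
      ov <- pmax(0, pmin(zmax, breaks[k + 1]) - pmax(zmin, breaks[k]))
      w <- ifelse(span > 0, ov / span,
                  as.numeric(zmin >= breaks[k] & zmin < breaks[k + 1]))
      sum(lens * w)
    }, numeric(1))
    syn <- ad@synapses
    if (nrow(syn)) {
      zsyn <- ad@tree@nodes$z[match(syn$node, ad@tree@nodes$id)]
      sidx <- findInterval(zsyn, breaks, rightmost.closed = TRUE)
      cls <- classifySynapse(syn$onto)
      nInh <- tabulate(sidx[cls == "putative_inhibitory"], nb)
      nExc <- tabulate(sidx[cls == "excitatory"], nb)
    } else nInh <- nExc <- rep(0L, nb)
    list(len = pathLen, nInh = nInh, nExc = nExc)
  })
  lenM <- do.call(rbind, lapply(perDend, `[[`, "len"))
  inhM <- do.call(rbind, lapply(perDend, `[[`, "nInh"))
  excM <- do.call(rbind, lapply(perDend, `[[`, "nExc"))
  pooled <- function(rows) {
    li <- colSums(inhM[rows, , drop = FALSE])
    le <- colSums(excM[rows, , drop = FALSE])
    ll <- colSums(lenM[rows, , drop = FALSE])
    ifelse(li + le > 0, li / (li + le), NA_real_)
  }
  obs <- pooled(seq_along(ads))
  n <- length(ads)
  if (!is.null(seed)) set.seed(seed)
  bootF <- matrix(NA_real_, nBoot, nb)
  for (b in seq_len(nBoot))
    bootF[b, ] <- pooled(sample.int(n, n, replace = TRUE))
  a <- (1 - conf) / 2
  ci <- apply(bootF, 2, stats::quantile, probs = c(a, 1 - a),
              na.rm = TRUE, names = FALSE)
  out <- data.frame(
    slabStart = utils::head(breaks, -1), slabEnd = breaks[-1],
    nInh = colSums(inhM), nExc = colSums(excM),
    pathLength = colSums(lenM),
    densInhLen = colSums(inhM) / colSums(lenM),
    densExcLen = colSums(excM) / colSums(lenM),
    inhFraction = obs, fracLo = ci[1, ], fracHi = ci[2, ])
  out[out$pathLength > 0, , drop = FALSE]
}

#' Tuft branch decomposition of an apical dendrite
#'
#' Removes the main bifurcation from the spine-pruned skeleton; the
#' component containing the soma (or, without a soma, the deepest node) is
#' the trunk side, every other component is a tuft branch.
#'
#' @param ad a [DendriteAnnotation-class] with the main bifurcation set.
#' @return list of integer node-id vectors, one per tuft branch.
#' @export
tuftBranches <- function(ad) {
  if (is.na(ad@mainBifurcationNode))
    stop("main bifurcation landmark is not set", call. = FALSE)
  pt <- .prunedTree(ad)
  g <- .treeGraph(pt)
  g2 <- igraph::delete_vertices(g, as.character(ad@mainBifurcationNode))
  comp <- igraph::components(g2)
  anchor <- if (!is.na(ad@somaNode)) as.character(ad@somaNode) else
    as.character(pt@nodes$id[which.max(pt@nodes$z)])
  trunkComp <- comp$membership[anchor]
  keep <- setdiff(seq_len(comp$no), trunkComp)
  lapply(keep, function(k)
    as.integer(names(comp$membership)[comp$membership == k]))
}

#' Per-branch synaptic composition of the distal tuft
#'
#' For each tuft branch the distal compartment is the terminal
#' `distalLength` micrometres of arc distance from the main bifurcation;
#' synapse counts (spine synapses inherit their attachment arc) and the
#' clipped shaft path length give per-branch densities and the putative
#' inhibitory fraction.
#'
#' @param ads a [DendriteAnnotation-class] or list of them.
#' @param distalLength length of the distal compartment, micrometres.
#' @return `data.frame` with one row per tuft branch: `dendrite`,
#'   `celltype`, `branch`, `nExc`, `nInh`, `pathLength`, `inhFraction`.
#' @export
distalTuftResults <- function(ads, distalLength = 30) {
  if (is(ads, "DendriteAnnotation")) ads <- list(ads)
  out <- do.call(rbind, lapply(ads, function(ad) {
    branches <- tuftBranches(ad)
    if (!length(branches)) return(NULL)
    arc <- arcDistances(ad, "bifurcation")
    pt <- .prunedTree(ad)
    lens <- .edgeLengths(pt@nodes, pt@edges)
    syn <- ad@synapses
    synArc <- if (nrow(syn)) arc[as.character(syn$node)] else numeric()
    ## spine synapse nodes are outside the pruned tree; assign them to the
    ## branch of their attachment by propagating membership over edges
    member <- rep(NA_integer_, nrow(ad@tree@nodes))
    names(member) <- as.character(ad@tree@nodes$id)
    for (k in seq_along(branches))
      member[as.character(branches[[k]])] <- k
    eg <- ad@tree@edges
    repeat {
      m1 <- member[as.character(eg[, 1])]
      m2 <- member[as.character(eg[, 2])]
      sp1 <- !(as.character(eg[, 1]) %in% as.character(pt@nodes$id))
      sp2 <- !(as.character(eg[, 2]) %in% as.character(pt@nodes$id))
      f1 <- is.na(m1) & !is.na(m2) & sp1
      f2 <- is.na(m2) & !is.na(m1) & sp2
      if (!any(f1) && !any(f2)) break
      member[as.character(eg[f1, 1])] <- m2[f1]
      member[as.character(eg[f2, 2])] <- m1[f2]
    }
    do.call(rbind, lapply(seq_along(branches), function(k) {
      ids <- branches[[k]]
      brLen <- max(arc[as.character(ids)])
      lo <- max(0, brLen - distalLength)
      inBranchEdge <- pt@edges[, 1] %in% ids & pt@edges[, 2] %in% ids
      du <- arc[as.character(pt@edges[, 1])]
      dv <- arc[as.character(pt@edges[, 2])]
      ## along a tree edge |du - dv| equals the edge length, so the arc
      ## overlap is the clipped path length directly
      ov <- pmax(0, pmin(pmax(du, dv), brLen) - pmax(pmin(du, dv), lo))
      pl <- sum(ov[inBranchEdge])
      if (nrow(syn)) {
        inWin <- member[as.character(syn$node)] == k &
          !is.na(member[as.character(syn$node)]) &
          synArc >= lo & synArc <= brLen + 1e-9
        cls <- classifySynapse(syn$onto[which(inWin)])
      } else cls <- character()
      nE <- sum(cls == "excitatory"); nI <- sum(cls == "putative_inhibitory")
      data.frame(dendrite = ad@tree@name, celltype = ad@celltype,
                 branch = k, nExc = nE, nInh = nI, pathLength = pl,
                 inhFraction = if (nE + nI > 0) nI / (nE + nI) else
                   NA_real_)
    }))
  }))
  rownames(out) <- NULL
  out
}
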