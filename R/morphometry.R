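## Geometric measurements on dendrite annotations. All inputs are
## DendriteAnnotation objects with micrometre coordinates; outputs are um
## (lengths), um^2 (areas).

.edgeLengths <- function(nodes, edges) {
  if (!nrow(edges)) return(numeric())
  i <- match(edges[, 1], nodes$id)
  j <- match(edges[, 2], nodes$id)
  sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2 +
       (nodes$z[i] - nodes$z[j])^2)
}

.treeGraph <- function(tree) {
  g <- igraph::graph_from_edgelist(
    cbind(as.character(tree@edges[, 1]), as.character(tree@edges[, 2])),
    directed = FALSE)
  iso <- setdiff(as.character(tree@nodes$id), igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  igraph::E(g)$weight <- .edgeLengths(tree@nodes, tree@edges)
  g
}

#' Node ids belonging to spine-neck branches
#'
#' Labelled spine-neck nodes (the `spineNeckNodes` slot, or node comments
#' containing "spine neck") take precedence. If none are labelled, a
#' geometric fallback marks terminal branches shorter than 3 um whose tip
#' carries a synapse-tagged comment.
#'
#' @param ad a [DendriteAnnotation-class].
#' @return integer node ids (possibly empty).
#' @export
spineNodes <- function(ad) {
  if (length(ad@spineNeckNodes)) return(ad@spineNeckNodes)
  nd <- ad@tree@nodes
  lab <- nd$id[!is.na(nd$comment) & grepl("spine neck", nd$comment,
                                          fixed = TRUE)]
  if (length(lab)) {
    ## extend labels over whole terminal branch beyond the labelled node
    return(.spineSubtreeNodes(ad@tree, lab))
  }
  ## geometric fallback: short synapse-bearing terminal branches
  g <- .treeGraph(ad@tree)
  deg <- igraph::degree(g)
  leaves <- as.integer(names(deg)[deg == 1])
  synLeaves <- intersect(leaves, nd$id[!is.na(nd$comment) &
                                       grepl("synapse", nd$comment)])
  if (!length(synLeaves)) return(integer())
  found <- integer()
  for (lf in synLeaves) {
    path <- lf
    len <- 0
    cur <- as.character(lf)
    repeat {
      nb <- setdiff(names(igraph::neighbors(g, cur)), as.character(path))
      if (length(nb) != 1) break
      w <- igraph::E(g, P = c(cur, nb[1]))$weight
      len <- len + w
      if (deg[nb[1]] >= 3 || len >= 3) break
      path <- c(path, as.integer(nb[1]))
      cur <- nb[1]
    }
    if (len < 3) found <- c(found, path)
  }
  sort(unique(found))
}

.spineSubtreeNodes <- function(tree, seedIds) {
  ## the spine subtree is everything that disconnects from the main shaft
  ## when labelled neck nodes are removed: remove them, call the largest
  ## remaining component (by total edge length) the shaft, and return all
  ## other nodes plus the necks themselves
  g <- .treeGraph(tree)
  g2 <- igraph::delete_vertices(g, as.character(seedIds))
  comp <- igraph::components(g2)
  if (comp$no <= 1)
    return(sort(as.integer(seedIds)))
  compLen <- vapply(seq_len(comp$no), function(k) {
    vs <- names(comp$membership)[comp$membership == k]
    sub <- igraph::induced_subgraph(g2, vs)
    sum(igraph::E(sub)$weight) + length(vs) * 1e-9
  }, numeric(1))
  shaft <- which.max(compLen)
  off <- names(comp$membership)[comp$membership != shaft]
  sort(unique(as.integer(c(seedIds, off))))
}

.prunedTree <- function(ad) {
  sp <- spineNodes(ad)
  tr <- ad@tree
  if (!length(sp)) return(tr)
  keepNodes <- tr@nodes[!(tr@nodes$id %in% sp), , drop = FALSE]
  keepEdges <- tr@edges[!(tr@edges[, 1] %in% sp) &
                        !(tr@edges[, 2] %in% sp), , drop = FALSE]
  SkeletonTree(tr@name, keepNodes, keepEdges, tr@groupLabel)
}

#' Arc distances from a reference node along the (pruned) skeleton
#'
#' Path distance in micrometres from the reference node to every node of
#' the spine-pruned skeleton. Spine-neck nodes get the arc position of
#' their attachment node (their synapses are assigned to the shaft
#' position where the spine branches off).
#'
#' @param ad a [DendriteAnnotation-class].
#' @param ref `"soma"`, `"bifurcation"` or a node id.
#' @return named numeric vector, names = node ids of the full tree.
#' @export
arcDistances <- function(ad, ref = c("soma", "bifurcation")) {
  if (is.character(ref)) {
    ref <- match.arg(ref)
    refNode <- if (ref == "soma") ad@somaNode else ad@mainBifurcationNode
    if (is.na(refNode))
      stop("reference landmark '", ref, "' is not set", call. = FALSE)
  } else refNode <- as.integer(ref)
  pt <- .prunedTree(ad)
  g <- .treeGraph(pt)
  d <- igraph::distances(g, v = as.character(refNode))[1, ]
  shaft <- stats::setNames(as.numeric(d), names(d))
  ## spine nodes inherit the arc position of their shaft attachment: the
  ## attachment value propagates outwards over the spine branch
  sp <- setdiff(ad@tree@nodes$id, pt@nodes$id)
  if (length(sp)) {
    spd <- stats::setNames(rep(NA_real_, length(sp)), as.character(sp))
    arcs <- c(shaft, spd)
    eg <- ad@tree@edges
    repeat {
      a1 <- arcs[as.character(eg[, 1])]
      a2 <- arcs[as.character(eg[, 2])]
      fill1 <- is.na(a1) & !is.na(a2)
      fill2 <- is.na(a2) & !is.na(a1)
      if (!any(fill1) && !any(fill2)) break
      arcs[as.character(eg[fill1, 1])] <- a2[fill1]
      arcs[as.character(eg[fill2, 2])] <- a1[fill2]
    }
    shaft <- arcs
  }
  shaft
}

#' Shaft path length of a dendrite
#'
#' Removes spine-neck branches from the skeleton and sums the Euclidean
#' lengths of the remaining edges. With a window, only the portion of each
#' edge whose arc distance from the reference landmark falls inside the
#' (closed) interval is counted; negative window bounds are interpreted as
#' unsigned distance (so `c(-10, 10)` measures within 10 um of the
#' landmark).
#'
#' @param ad a [DendriteAnnotation-class] (micrometre units).
#' @param window optional numeric length-2 arc-distance interval.
#' @param ref landmark for window distances: `"bifurcation"` (default) or
#'   `"soma"`.
#' @return Path length in micrometres. Zero (with a warning) if the window
#'   excludes the whole dendrite.
#' @export
shaftPathLength <- function(ad, window = NULL, ref = "bifurcation") {
  pt <- .prunedTree(ad)
  if (is.null(window))
    return(sum(.edgeLengths(pt@nodes, pt@edges)))
  w <- sort(c(max(0, min(window)), max(window)))
  if (min(window) < 0) w <- c(0, max(abs(window)))
  d <- arcDistances(ad, ref)
  lens <- .edgeLengths(pt@nodes, pt@edges)
  du <- d[as.character(pt@edges[, 1])]
  dv <- d[as.character(pt@edges[, 2])]
  lo <- pmin(du, dv)
  hi <- pmax(du, dv)
  ## arc distance varies linearly along a tree edge
  overlap <- pmax(0, pmin(hi, w[2]) - pmax(lo, w[1]))
  ## guard: edges crossing the reference (hi - lo < len) are split at 0
  tot <- sum(overlap)
  if (tot == 0)
    warning("window excludes all of the dendrite; returning 0")
  tot
}

#' Average dendritic diameter
#'
#' Mean of diameter samples taken every ~`spacing` micrometres along the
#' dendritic path. Explicit diameter samples take precedence over node
#' radii; with radii, nodes are subsampled at the requested arc spacing.
#'
#' @param ad a [DendriteAnnotation-class].
#' @param spacing sampling interval along the arc, micrometres.
#' @return Mean diameter in micrometres.
#' @export
averageDiameter <- function(ad, spacing = 2.5) {
  ds <- ad@diameterSamples
  if (nrow(ds) > 0)
    return(mean(ds$diameter))
  nd <- ad@tree@nodes
  if (all(is.na(nd$radius)))
    stop("measurement missing: no diameter samples and no node radii",
         call. = FALSE)
  ref <- if (!is.na(ad@somaNode)) "soma" else "bifurcation"
  d <- arcDistances(ad, ref)
  withR <- nd[!is.na(nd$radius), ]
  arc <- d[as.character(withR$id)]
  ord <- order(arc)
  arc <- arc[ord]; rad <- withR$radius[ord]
  picked <- logical(length(arc))
  last <- -Inf
  for (i in seq_along(arc)) {
    if (arc[i] - last >= spacing - 1e-9) {
      picked[i] <- TRUE
      last <- arc[i]
    }
  }
  mean(2 * rad[picked])
}

#' Dendritic surface area from the open-cylinder model
#'
#' `pi * pathLength * averageDiameter`.
#'
#' @param pathLength shaft path length, micrometres.
#' @param avgDiameter average diameter, micrometres.
#' @return Surface area in square micrometres.
#' @examples
#' surfaceArea(10, 2) # 62.83 um^2
#' @export
surfaceArea <- function(pathLength, avgDiameter) {
  if (any(pathLength <= 0) || any(avgDiameter <= 0))
    stop("pathLength and avgDiameter must be positive", call. = FALSE)
  pi * pathLength * avgDiameter
}

#' Equivalent-volume sphere diameter of an ellipsoidal soma
#'
#' Diameter of the sphere whose volume matches the ellipsoid with the given
#' axis diameters: the geometric mean `(a b c)^(1/3)`.
#'
#' @param axisDiameters numeric length-3, micrometres.
#' @return Diameter in micrometres.
#' @examples
#' equivalentSphereDiameter(c(8, 8, 27)) # 12
#' @export
equivalentSphereDiameter <- function(axisDiameters) {
  if (length(axisDiameters) != 3 || any(axisDiameters <= 0))
    stop("axisDiameters must be 3 positive values", call. = FALSE)
  prod(axisDiameters)^(1 / 3)
}

#' Equal-area circle diameter of an elliptical cross-section
#'
#' @param major,minor full ellipse axes, micrometres.
#' @return `sqrt(major * minor)`.
#' @export
ellipseEquivalentDiameter <- function(major, minor) {
  if (any(major <= 0) || any(minor <= 0))
    stop("axes must be positive", call. = FALSE)
  sqrt(major * minor)
}

#' Trunk diameter at a given path distance from the soma
#'
#' Looks up the diameter sample nearest to the requested arc position. If
#' samples carry ellipse axes (`major`, `minor` columns) the equal-area
#' circle diameter is used. If the trunk is shorter than the requested
#' distance, the most distal available sample is used with a warning.
#'
#' @param ad a [DendriteAnnotation-class] whose `diameterSamples` have an
#'   `arc` column (distance from soma, micrometres).
#' @param distanceFromSoma target arc position, micrometres.
#' @return Diameter in micrometres.
#' @export
trunkDiameterAt <- function(ad, distanceFromSoma = 50) {
  ds <- ad@diameterSamples
  if (!nrow(ds))
    stop("measurement missing: no diameter samples", call. = FALSE)
  diam <- if (all(c("major", "minor") %in% names(ds)))
    ellipseEquivalentDiameter(ds$major, ds$minor) else ds$diameter
  if (max(ds$arc) < distanceFromSoma) {
    warning("trunk shorter than ", distanceFromSoma,
            " um; using most distal sample")
    return(diam[which.max(ds$arc)])
  }
  diam[which.min(abs(ds$arc - distanceFromSoma))]
}

#' Synaptic interface area from annotated ellipse axes
#'
#' `pi * (major/2) * (minor/2)` for the two annotated full axes of the
#' synaptic contact.
#'
#' @param major,minor full axes, micrometres.
#' @return Area in square micrometres.
#' @examples
#' synapseInterfaceArea(2, 1) # ~1.571
#' @export
synapseInterfaceArea <- function(major, minor) {
  if (any(major <= 0) || any(minor <= 0))
    stop("axes must be positive", call. = FALSE)
  pi * (major / 2) * (minor / 2)
}

#' Detect the main bifurcation of an apical dendrite
#'
#' An annotated bifurcation (node comment containing "main bifurcation", or
#' the `mainBifurcationNode` slot) is authoritative. Otherwise the most
#' proximal node with two or more daughter branches whose two largest
#' daughter subtrees have total path lengths within `similarityTol`
#' (relative to the larger) is returned -- the "Y" of two similar daughter
#' branches.
#'
#' @param ad a [DendriteAnnotation-class]; rooted at the soma if set, else
#'   at the lowest-id leaf.
#' @param similarityTol relative length tolerance between the two largest
#'   daughter subtrees.
#' @return Node id of the main bifurcation.
#' @export
detectMainBifurcation <- function(ad, similarityTol = 0.5) {
  if (!is.na(ad@mainBifurcationNode))
    return(ad@mainBifurcationNode)
  nd <- ad@tree@nodes
  tagged <- nd$id[!is.na(nd$comment) &
                  grepl("main bifurcation", nd$comment, fixed = TRUE)]
  if (length(tagged))
    return(tagged[1])
  pt <- .prunedTree(ad)
  g <- .treeGraph(pt)
  deg <- igraph::degree(g)
  root <- if (!is.na(ad@somaNode)) ad@somaNode else
    min(as.integer(names(deg)[deg == 1]))
  d <- igraph::distances(g, v = as.character(root))[1, ]
  cand <- as.integer(names(deg)[deg >= 3])
  cand <- cand[cand != root]
  cand <- cand[order(d[as.character(cand)])]
  for (b in cand) {
    ## daughter subtrees: components after removing b, excluding the one
    ## containing the root
    g2 <- igraph::delete_vertices(g, as.character(b))
    comp <- igraph::components(g2)
    rootComp <- comp$membership[as.character(root)]
    subLens <- vapply(setdiff(seq_len(comp$no), rootComp), function(k) {
      vs <- names(comp$membership)[comp$membership == k]
      sub <- igraph::induced_subgraph(g2, vs)
      ## include the connecting edge from b to this component
      nb <- names(igraph::neighbors(g, as.character(b)))
      joint <- intersect(nb, vs)
      stub <- sum(vapply(joint, function(v)
        igraph::E(g, P = c(as.character(b), v))$weight, numeric(1)))
      sum(igraph::E(sub)$weight) + stub
    }, numeric(1))
    if (length(subLens) < 2) next
    sl <- sort(subLens, decreasing = TRUE)[1:2]
    if ((sl[1] - sl[2]) / sl[1] <= similarityTol)
      return(b)
  }
  stop("detection failed: no qualifying main bifurcation", call. = FALSE)
}

#' Path distance from soma to main bifurcation
#'
#' Arc length of the unique tree path between the two landmarks, spine
#' necks excluded.
#'
#' @param ad a [DendriteAnnotation-class] with both landmarks set.
#' @return Distance in micrometres.
#' @export
somaToBifurcationDistance <- function(ad) {
  if (is.na(ad@somaNode) || is.na(ad@mainBifurcationNode))
    stop("soma and main bifurcation landmarks must both be set",
         call. = FALSE)
  d <- arcDistances(ad, "soma")
  as.numeric(d[as.character(ad@mainBifurcationNode)])
}

#' Depth profiles of main bifurcations and axonal paths
#'
#' Builds (i) a histogram (default 20-um bins, normalized to a density) and
#' kernel density estimate (default 25-um bandwidth) of main-bifurcation
#' depths below pia, and (ii) the fraction of axonal path length per
#' tangential cortical slice, averaged across datasets. Nodes marking
#' synapse locations (comments containing "synapse") are removed from the
#' axon skeletons before path measurement.
#'
#' @param bifurcationDepths numeric vector of main-bifurcation depths below
#'   pia, micrometres.
#' @param axonSets list of [AnnotationSet-class] objects in physical units
#'   (one per dataset) holding axon skeletons.
#' @param bin histogram/slice width, micrometres.
#' @param kdeBandwidth kernel bandwidth (SD), micrometres.
#' @return list with `bifHist` (`data.frame`: `binStart`, `binEnd`,
#'   `count`, `density`), `bifDensity` (a [stats::density()] object or
#'   `NULL`), and `axonProfile` (`data.frame`: `binStart`, `binEnd`,
#'   `fraction`; per-dataset fractions each sum to 1 before averaging).
#' @export
landmarkDepthProfiles <- function(bifurcationDepths = numeric(),
                                  axonSets = list(), bin = 20,
                                  kdeBandwidth = 25) {
  bifHist <- NULL
  bifDensity <- NULL
  if (length(bifurcationDepths)) {
    lo <- floor(min(bifurcationDepths) / bin) * bin
    hi <- ceiling(max(bifurcationDepths) / bin) * bin
    if (hi == lo) hi <- lo + bin
    breaks <- seq(lo, hi, by = bin)
    h <- hist(bifurcationDepths, breaks = breaks, plot = FALSE,
              right = FALSE)
    bifHist <- data.frame(binStart = utils::head(breaks, -1),
                          binEnd = breaks[-1], count = h$counts,
                          density = h$density)
    if (length(bifurcationDepths) >= 2)
      bifDensity <- stats::density(bifurcationDepths, bw = kdeBandwidth)
  }
  axonProfile <- NULL
  if (length(axonSets)) {
    perDataset <- lapply(axonSets, function(aset) {
      stopifnot(is(aset, "AnnotationSet"))
      if (aset@unit != "nm") aset <- toPhysical(aset)
      m <- aset@meta
      axCol <- c("x", "y", "z")[m@depthAxis]
      segs <- do.call(rbind, lapply(aset@trees, function(tr) {
        keep <- tr@nodes$id[is.na(tr@nodes$comment) |
                            !grepl("synapse", tr@nodes$comment)]
        nd <- tr@nodes[tr@nodes$id %in% keep, , drop = FALSE]
        eg <- tr@edges[tr@edges[, 1] %in% keep &
                       tr@edges[, 2] %in% keep, , drop = FALSE]
        if (!nrow(eg)) return(NULL)
        i <- match(eg[, 1], nd$id); j <- match(eg[, 2], nd$id)
        data.frame(len = .edgeLengths(nd, eg) / 1000,
                   d1 = depthBelowPia(nd[[axCol]][i], m),
                   d2 = depthBelowPia(nd[[axCol]][j], m))
      }))
      segs
    })
    allD <- unlist(lapply(perDataset, function(s)
      if (is.null(s)) numeric() else c(s$d1, s$d2)))
    lo <- floor(min(allD) / bin) * bin
    hi <- ceiling(max(allD) / bin) * bin
    if (hi == lo) hi <- lo + bin
    breaks <- seq(lo, hi, by = bin)
    fracs <- vapply(perDataset, function(s) {
      perSlice <- vapply(seq_len(length(breaks) - 1), function(k) {
        slo <- breaks[k]; shi <- breaks[k + 1]
        dmin <- pmin(s$d1, s$d2); dmax <- pmax(s$d1, s$d2)
        span <- dmax - dmin
        ov <- pmax(0, pmin(dmax, shi) - pmax(dmin, slo))
        ## vertical extent-weighted share; depth-constant edges assigned
        ## wholly to their slice
        w <- ifelse(span > 0, ov / span,
                    as.numeric(dmin >= slo & dmin < shi))
        sum(s$len * w)
      }, numeric(1))
      perSlice / sum(perSlice)
    }, numeric(length(breaks) - 1))
    axonProfile <- data.frame(binStart = utils::head(breaks, -1),
                              binEnd = breaks[-1],
                              fraction = rowMeans(as.matrix(fracs)))
  }
  list(bifHist = bifHist, bifDensity = bifDensity,
       axonProfile = axonProfile)
}
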