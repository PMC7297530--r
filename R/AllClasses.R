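#' @import methods
NULL

## Central containers for skeleton annotations. Positions are voxel-indexed
## (0-based, corner-anchored) until toPhysical() is applied; all downstream
## geometry is done in physical units.

#' Dataset metadata for an annotated EM volume
#'
#' Holds the per-dataset constants needed to place skeleton annotations in
#' physical cortical space: the nominal voxel size, the depth of the
#' dataset's top face below the pial surface, which axis points towards
#' increasing cortical depth, and the section-thickness correction applied
#' along the cutting axis (a value of 1.49 compensates compressed sections
#' in datasets where nominal and actual cutting thickness differ).
#'
#' @slot name dataset name (e.g. `"S1"`).
#' @slot voxelSize numeric length-3, nm per voxel along x/y/z.
#' @slot piaOffset depth of the dataset origin below pia, in micrometres.
#' @slot depthAxis axis index (1--3) whose positive direction is increasing
#'   cortical depth.
#' @slot cuttingAxis axis index (1--3) of the sectioning direction.
#' @slot thicknessCorrection dimensionless factor applied to coordinates
#'   along the cutting axis when converting to physical units.
#'
#' @seealso [DatasetMeta()], [toPhysical()]
#' @export
setClass("DatasetMeta",
  slots = c(
    name = "character",
    voxelSize = "numeric",
    piaOffset = "numeric",
    depthAxis = "integer",
    cuttingAxis = "integer",
    thicknessCorrection = "numeric"
  ),
  prototype = prototype(
    name = "unnamed",
    voxelSize = c(1, 1, 1),
    piaOffset = 0,
    depthAxis = 3L,
    cuttingAxis = 3L,
    thicknessCorrection = 1
  )
)

setValidity("DatasetMeta", function(object) {
  msg <- character()
  if (length(object@voxelSize) != 3 || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive finite values (nm)")
  if (length(object@piaOffset) != 1 || is.na(object@piaOffset) ||
      object@piaOffset < 0)
    msg <- c(msg, "piaOffset must be a single non-negative value (um)")
  if (!(object@depthAxis %in% 1:3))
    msg <- c(msg, "depthAxis must be 1, 2 or 3")
  if (!(object@cuttingAxis %in% 1:3))
    msg <- c(msg, "cuttingAxis must be 1, 2 or 3")
  if (length(object@thicknessCorrection) != 1 ||
      !is.finite(object@thicknessCorrection) ||
      object@thicknessCorrection <= 0)
    msg <- c(msg, "thicknessCorrection must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Construct dataset metadata
#'
#' @param name dataset name.
#' @param voxelSize numeric length-3, nm per voxel along x/y/z.
#' @param piaOffset depth of the dataset top face below pia (micrometres).
#' @param depthAxis axis of increasing cortical depth (1--3).
#' @param cuttingAxis sectioning axis (1--3).
#' @param thicknessCorrection factor applied along the cutting axis.
#' @return A [DatasetMeta-class] object.
#' @examples
#' DatasetMeta("S1", voxelSize = c(11.24, 11.24, 28), piaOffset = 125)
#' @export
DatasetMeta <- function(name = "unnamed", voxelSize = c(1, 1, 1),
                        piaOffset = 0, depthAxis = 3L, cuttingAxis = 3L,
                        thicknessCorrection = 1) {
  new("DatasetMeta", name = as.character(name),
      voxelSize = as.numeric(voxelSize), piaOffset = as.numeric(piaOffset),
      depthAxis = as.integer(depthAxis), cuttingAxis = as.integer(cuttingAxis),
      thicknessCorrection = as.numeric(thicknessCorrection))
}

#' Skeleton tree (nodes + edges)
#'
#' A single annotated neurite: a node table with positions, optional radii
#' and per-node comment strings, and an undirected edge list. Multiple
#' connected components are tolerated at parse time (raw annotations often
#' contain stray nodes); operations that need connectivity check for it.
#'
#' @slot name tree name, unique within an [AnnotationSet-class].
#' @slot nodes `data.frame` with columns `id`, `x`, `y`, `z`, `radius`,
#'   `comment` (`NA` where absent).
#' @slot edges two-column integer matrix of node ids (unordered pairs).
#' @slot groupLabel optional grouping label.
#' @export
setClass("SkeletonTree",
  slots = c(
    name = "character",
    nodes = "data.frame",
    edges = "matrix",
    groupLabel = "character"
  ),
  prototype = prototype(name = "tree", groupLabel = NA_character_)
)

setValidity("SkeletonTree", function(object) {
  msg <- character()
  nd <- object@nodes
  need <- c("id", "x", "y", "z", "radius", "comment")
  if (!all(need %in% names(nd)))
    msg <- c(msg, paste("nodes must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(nd$id))
      msg <- c(msg, "node ids must be unique within a tree")
    e <- object@edges
    if (ncol(e) != 2)
      msg <- c(msg, "edges must be a two-column matrix")
    else if (nrow(e)) {
      if (any(e[, 1] == e[, 2]))
        msg <- c(msg, "self-edges are not allowed")
      missing <- setdiff(c(e), nd$id)
      if (length(missing))
        msg <- c(msg, paste("edge endpoints missing from nodes:",
                            paste(missing, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a skeleton tree
#'
#' @param name tree name.
#' @param nodes `data.frame` with at least `id`, `x`, `y`, `z`; `radius` and
#'   `comment` are added as `NA` if missing.
#' @param edges two-column matrix (or data.frame) of node-id pairs; may have
#'   zero rows.
#' @param groupLabel optional label.
#' @return A [SkeletonTree-class].
#' @export
SkeletonTree <- function(name, nodes, edges = matrix(integer(), ncol = 2),
                         groupLabel = NA_character_) {
  nodes <- as.data.frame(nodes)
  if (is.null(nodes$radius)) nodes$radius <- NA_real_
  if (is.null(nodes$comment)) nodes$comment <- NA_character_
  nodes$id <- as.integer(nodes$id)
  nodes$comment <- as.character(nodes$comment)
  edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(integer(), ncol = 2)
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("source", "target")
  canon <- c("id", "x", "y", "z", "radius", "comment")
  extras <- setdiff(names(nodes), canon)
  new("SkeletonTree", name = as.character(name),
      nodes = nodes[, c(canon, extras), drop = FALSE],
      edges = edges, groupLabel = as.character(groupLabel))
}

#' A parsed annotation file: dataset metadata plus skeleton trees
#'
#' @slot meta a [DatasetMeta-class].
#' @slot trees list of [SkeletonTree-class]; tree names are unique.
#' @slot unit `"voxel"` (as parsed) or `"nm"` (after [toPhysical()]).
#' @export
setClass("AnnotationSet",
  slots = c(meta = "DatasetMeta", trees = "list", unit = "character"),
  prototype = prototype(unit = "voxel")
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (!all(vapply(object@trees, is, logical(1), class2 = "SkeletonTree")))
    msg <- c(msg, "trees must all be SkeletonTree objects")
  else {
    nm <- vapply(object@trees, function(t) t@name, character(1))
    if (anyDuplicated(nm))
      msg <- c(msg, "tree names must be unique")
  }
  if (!(object@unit %in% c("voxel", "nm")))
    msg <- c(msg, "unit must be 'voxel' or 'nm'")
  if (length(msg)) msg else TRUE
})

#' Construct an annotation set
#'
#' @param trees list of [SkeletonTree-class] objects.
#' @param meta a [DatasetMeta-class].
#' @param unit coordinate unit, `"voxel"` or `"nm"`.
#' @return An [AnnotationSet-class].
#' @export
AnnotationSet <- function(trees = list(), meta = DatasetMeta(),
                          unit = "voxel") {
  new("AnnotationSet", meta = meta, trees = trees, unit = unit)
}

#' One apical dendrite ready for analysis
#'
#' Positions in the embedded tree are in micrometres. Synapses are rows of a
#' record table; each synapse sits on a tree node and carries its structural
#' target class (`shaft`, `spine_primary`, `spine_secondary`, `spine_neck`).
#'
#' @slot tree [SkeletonTree-class] in micrometre coordinates.
#' @slot celltype one of `"L2"`, `"L2MN"`, `"L3"`, `"L5tt"`, `"L5st"`,
#'   `"DL"`, `"unknown"`.
#' @slot somaNode node id of the soma, `NA` if the soma is outside the
#'   volume (deep-layer dendrites).
#' @slot mainBifurcationNode node id of the main bifurcation, `NA` if unset.
#' @slot spineNeckNodes integer vector of node ids on spine-neck branches.
#' @slot synapses `data.frame` with columns `id`, `node`, `onto`,
#'   `sizeMajor`, `sizeMinor`, `presynAxon`.
#' @slot diameterSamples `data.frame` with columns `arc` (micrometres along
#'   the path) and `diameter` (micrometres).
#' @slot analysisWindow numeric length-2 path-distance interval (micrometres
#'   around the main bifurcation) or length-0 if unset.
#' @export
setClass("DendriteAnnotation",
  slots = c(
    tree = "SkeletonTree",
    celltype = "character",
    somaNode = "integer",
    mainBifurcationNode = "integer",
    spineNeckNodes = "integer",
    synapses = "data.frame",
    diameterSamples = "data.frame",
    analysisWindow = "numeric"
  )
)

.celltypes <- c("L2", "L2MN", "L3", "L5tt", "L5st", "DL", "unknown")
.ontoLevels <- c("shaft", "spine_primary", "spine_secondary", "spine_neck")

setValidity("DendriteAnnotation", function(object) {
  msg <- character()
  if (!(object@celltype %in% .celltypes))
    msg <- c(msg, paste("celltype must be one of:",
                        paste(.celltypes, collapse = ", ")))
  syn <- object@synapses
  need <- c("id", "node", "onto")
  if (!all(need %in% names(syn)))
    msg <- c(msg, "synapses must have columns id, node, onto")
  else if (nrow(syn)) {
    if (!all(syn$onto %in% .ontoLevels))
      msg <- c(msg, paste("synapse onto must be one of:",
                          paste(.ontoLevels, collapse = ", ")))
    if (!all(syn$node %in% object@tree@nodes$id))
      msg <- c(msg, "synapse nodes must exist in the tree")
  }
  ds <- object@diameterSamples
  if (nrow(ds) && any(ds$diameter <= 0, na.rm = TRUE))
    msg <- c(msg, "diameter samples must be positive")
  if (length(object@analysisWindow) %in% c(0, 2) == FALSE)
    msg <- c(msg, "analysisWindow must be length 0 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct a dendrite annotation
#'
#' @param tree [SkeletonTree-class] with micrometre coordinates.
#' @param celltype cell-type label (see [DendriteAnnotation-class]).
#' @param somaNode,mainBifurcationNode landmark node ids (`NA` allowed).
#' @param spineNeckNodes integer node ids on spine-neck branches.
#' @param synapses synapse record table; missing optional columns are added.
#' @param diameterSamples `data.frame(arc, diameter)` in micrometres.
#' @param analysisWindow numeric length-2 interval of path distance around
#'   the main bifurcation, or `NULL`.
#' @return A [DendriteAnnotation-class].
#' @export
DendriteAnnotation <- function(tree, celltype = "unknown",
                               somaNode = NA_integer_,
                               mainBifurcationNode = NA_integer_,
                               spineNeckNodes = integer(),
                               synapses = NULL,
                               diameterSamples = NULL,
                               analysisWindow = NULL) {
  if (is.null(synapses))
    synapses <- data.frame(id = integer(), node = integer(),
                           onto = character())
  synapses <- as.data.frame(synapses)
  nr <- nrow(synapses)
  if (is.null(synapses$sizeMajor)) synapses$sizeMajor <- rep(NA_real_, nr)
  if (is.null(synapses$sizeMinor)) synapses$sizeMinor <- rep(NA_real_, nr)
  if (is.null(synapses$presynAxon))
    synapses$presynAxon <- rep(NA_integer_, nr)
  if (is.null(diameterSamples))
    diameterSamples <- data.frame(arc = numeric(), diameter = numeric())
  new("DendriteAnnotation", tree = tree, celltype = celltype,
      somaNode = as.integer(somaNode),
      mainBifurcationNode = as.integer(mainBifurcationNode),
      spineNeckNodes = as.integer(spineNeckNodes),
      synapses = synapses,
      diameterSamples = as.data.frame(diameterSamples),
      analysisWindow = as.numeric(analysisWindow %||% numeric()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- accessors -----------------------------------------------------------

#' @describeIn AnnotationSet-class number of trees
#' @param x an `AnnotationSet`.
#' @export
nTrees <- function(x) length(x@trees)

#' Extract the tree list from an annotation set
#' @param x an [AnnotationSet-class].
#' @return list of [SkeletonTree-class].
#' @export
skeletonTrees <- function(x) x@trees

#' Dataset metadata accessor
#' @param x an [AnnotationSet-class].
#' @export
datasetMeta <- function(x) x@meta

#' Node table accessor
#' @param x a [SkeletonTree-class] or [DendriteAnnotation-class].
#' @export
nodeTable <- function(x) {
  if (is(x, "DendriteAnnotation")) x@tree@nodes else x@nodes
}

#' Edge matrix accessor
#' @param x a [SkeletonTree-class] or [DendriteAnnotation-class].
#' @export
edgeMatrix <- function(x) {
  if (is(x, "DendriteAnnotation")) x@tree@edges else x@edges
}

#' Synapse record accessor
#' @param x a [DendriteAnnotation-class].
#' @export
synapseRecords <- function(x) x@synapses

#' Cell-type accessor
#' @param x a [DendriteAnnotation-class].
#' @export
cellType <- function(x) x@celltype

## ---- show methods --------------------------------------------------------

setMethod("show", "DatasetMeta", function(object) {
  cat("DatasetMeta '", object@name, "': voxel ",
      paste(object@voxelSize, collapse = " x "),
      " nm, pia offset ", object@piaOffset, " um, depth axis ",
      object@depthAxis, ", thickness correction ",
      object@thicknessCorrection, "\n", sep = "")
})

setMethod("show", "SkeletonTree", function(object) {
  cat("SkeletonTree '", object@name, "': ", nrow(object@nodes), " nodes, ",
      nrow(object@edges), " edges\n", sep = "")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet (", object@unit, "): ", length(object@trees),
      " trees, dataset '", object@meta@name, "'\n", sep = "")
})

setMethod("show", "DendriteAnnotation", function(object) {
  cat("DendriteAnnotation [", object@celltype, "]: ",
      nrow(object@tree@nodes), " nodes, ", nrow(object@synapses),
      " synapses", sep = "")
  if (!is.na(object@mainBifurcationNode))
    cat(", main bifurcation at node", object@mainBifurcationNode)
  cat("\n")
})
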