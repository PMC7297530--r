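#' Read a webKnossos-style NML skeleton annotation
#'
#' Parses the XML skeleton dialect exported by webKnossos: `<thing>` (or
#' `<tree>`) elements holding `<node>` and `<edge>` children, with per-node
#' comments given either inline as a `comment` attribute or in a trailing
#' `<comments>` block (both forms are mapped onto the node's `comment`
#' field). A `<scale>` element inside `<parameters>`, when present, supplies
#' the voxel size. Unknown node attributes are retained verbatim as extra
#' columns of the node table and written back by [writeNML()].
#'
#' Coordinates are voxel-indexed as stored in the file; convert with
#' [toPhysical()] before any geometric measurement.
#'
#' @param x path to an NML file, or a single character string containing the
#'   document.
#' @param meta optional [DatasetMeta-class] overriding anything found in the
#'   file's `<parameters>` block.
#' @return An [AnnotationSet-class] with `unit == "voxel"`.
#' @examples
#' nml <- '<things><thing id="1" name="t"><nodes>
#'   <node id="1" x="0" y="0" z="0"/><node id="2" x="10" y="0" z="0"/>
#'   </nodes><edges><edge source="1" target="2"/></edges></thing></things>'
#' aset <- parseNML(nml)
#' nTrees(aset)
#' @export
parseNML <- function(x, meta = NULL) {
  doc <- tryCatch(
    xml2::read_xml(if (length(x) == 1 && !grepl("<", x, fixed = TRUE))
      x else paste(x, collapse = "\n")),
    error = function(e) stop("NML parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(meta)) {
    sc <- xml2::xml_find_first(doc, ".//parameters/scale")
    exp <- xml2::xml_find_first(doc, ".//parameters/experiment")
    meta <- DatasetMeta(
      name = if (!inherits(exp, "xml_missing"))
        xml2::xml_attr(exp, "name") %||na% "unnamed" else "unnamed",
      voxelSize = if (!inherits(sc, "xml_missing"))
        as.numeric(c(xml2::xml_attr(sc, "x"), xml2::xml_attr(sc, "y"),
                     xml2::xml_attr(sc, "z"))) else c(1, 1, 1))
  }

  ## comments block: node id -> content
  cmts <- xml2::xml_find_all(doc, ".//comments/comment")
  cmtMap <- if (length(cmts)) {
    stats::setNames(xml2::xml_attr(cmts, "content"),
                    xml2::xml_attr(cmts, "node"))
  } else character()

  things <- xml2::xml_find_all(doc, "./thing | ./tree")
  trees <- lapply(things, function(th) {
    nm <- xml2::xml_attr(th, "name")
    if (is.na(nm)) nm <- paste0("tree_", xml2::xml_attr(th, "id"))
    ndEls <- xml2::xml_find_all(th, ".//node")
    nodes <- .parseNodes(ndEls, cmtMap)
    egEls <- xml2::xml_find_all(th, ".//edge")
    edges <- if (length(egEls)) {
      cbind(as.integer(xml2::xml_attr(egEls, "source")),
            as.integer(xml2::xml_attr(egEls, "target")))
    } else matrix(integer(), ncol = 2)
    bad <- setdiff(c(edges), nodes$id)
    if (length(bad))
      stop("NML structural error in tree '", nm,
           "': edges reference missing node ids ",
           paste(bad, collapse = ", "), call. = FALSE)
    SkeletonTree(name = nm, nodes = nodes, edges = edges,
                 groupLabel = xml2::xml_attr(th, "groupId"))
  })
  AnnotationSet(trees = trees, meta = meta, unit = "voxel")
}

`%||na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

.parseNodes <- function(ndEls, cmtMap) {
  if (!length(ndEls))
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric(),
                      comment = character()))
  attrList <- lapply(ndEls, xml2::xml_attrs)
  allAttrs <- unique(unlist(lapply(attrList, names)))
  cols <- lapply(allAttrs, function(a)
    vapply(attrList, function(v) if (a %in% names(v)) v[[a]] else
      NA_character_, character(1)))
  names(cols) <- allAttrs
  nodes <- data.frame(
    id = as.integer(cols$id),
    x = as.numeric(cols$x), y = as.numeric(cols$y), z = as.numeric(cols$z),
    radius = if (!is.null(cols$radius)) as.numeric(cols$radius) else
      NA_real_,
    comment = if (!is.null(cols$comment)) cols$comment else NA_character_,
    stringsAsFactors = FALSE)
  if (length(cmtMap)) {
    hit <- match(as.character(nodes$id), names(cmtMap))
    nodes$comment <- ifelse(!is.na(hit), unname(cmtMap[hit]), nodes$comment)
  }
  extras <- setdiff(allAttrs, c("id", "x", "y", "z", "radius", "comment"))
  for (a in extras) nodes[[a]] <- cols[[a]]
  nodes
}

#' Write an annotation set as an NML document
#'
#' Produces a canonical NML serialization (nodes ordered by node id, trees
#' in list order) that reparses to an equal annotation set. Node comments
#' are emitted inline as `comment` attributes: node ids are only unique
#' within a tree here, so a global `<comments>` block would be ambiguous.
#'
#' @param aset an [AnnotationSet-class].
#' @param file optional output path; if `NULL` the document is returned as a
#'   character string.
#' @return The NML document as a single string (invisibly, when `file` is
#'   given).
#' @seealso [parseNML()]
#' @export
writeNML <- function(aset, file = NULL) {
  stopifnot(is(aset, "AnnotationSet"))
  m <- aset@meta
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  num <- function(v) formatC(v, format = "g", digits = 15)
  out <- c("<things>",
           "  <parameters>",
           sprintf('    <experiment name="%s"/>', esc(m@name)),
           sprintf('    <scale x="%s" y="%s" z="%s"/>',
                   num(m@voxelSize[1]), num(m@voxelSize[2]),
                   num(m@voxelSize[3])),
           "  </parameters>")
  extraSkip <- c("id", "x", "y", "z", "radius", "comment")
  for (i in seq_along(aset@trees)) {
    tr <- aset@trees[[i]]
    nd <- tr@nodes[order(tr@nodes$id), , drop = FALSE]
    out <- c(out, sprintf('  <thing id="%d" name="%s">', i, esc(tr@name)),
             "    <nodes>")
    extras <- setdiff(names(nd), extraSkip)
    for (j in seq_len(nrow(nd))) {
      at <- sprintf('id="%d" x="%s" y="%s" z="%s"', nd$id[j],
                    num(nd$x[j]), num(nd$y[j]), num(nd$z[j]))
      if (!is.na(nd$radius[j]))
        at <- paste0(at, sprintf(' radius="%s"', num(nd$radius[j])))
      if (!is.na(nd$comment[j]))
        at <- paste0(at, sprintf(' comment="%s"', esc(nd$comment[j])))
      for (a in extras) if (!is.na(nd[[a]][j]))
        at <- paste0(at, sprintf(' %s="%s"', a, esc(nd[[a]][j])))
      out <- c(out, paste0("      <node ", at, "/>"))
    }
    out <- c(out, "    </nodes>", "    <edges>")
    eg <- tr@edges
    if (nrow(eg)) {
      ord <- order(eg[, 1], eg[, 2])
      out <- c(out, sprintf('      <edge source="%d" target="%d"/>',
                            eg[ord, 1], eg[ord, 2]))
    }
    out <- c(out, "    </edges>", "  </thing>")
  }
  out <- c(out, "</things>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Convert an annotation set from voxel to physical coordinates
#'
#' Multiplies each coordinate by the voxel size along its axis (nm per
#' voxel); the cutting-axis coordinate is additionally multiplied by the
#' section-thickness correction factor. After conversion, depth below pia is
#' available via [depthBelowPia()].
#'
#' @param aset an [AnnotationSet-class] with `unit == "voxel"`.
#' @return The annotation set with node positions in nm (`unit == "nm"`).
#' @examples
#' tr <- SkeletonTree("t", data.frame(id = 1L, x = 10, y = 0, z = 0))
#' aset <- AnnotationSet(list(tr),
#'   DatasetMeta(voxelSize = c(11.24, 11.24, 28)))
#' nodeTable(skeletonTrees(toPhysical(aset))[[1]])$x  # 112.4 nm
#' @export
toPhysical <- function(aset) {
  stopifnot(is(aset, "AnnotationSet"))
  if (aset@unit == "nm")
    return(aset)
  m <- aset@meta
  if (length(m@voxelSize) != 3 || any(is.na(m@voxelSize)))
    stop("configuration error: voxel size is not set", call. = FALSE)
  sc <- m@voxelSize
  sc[m@cuttingAxis] <- sc[m@cuttingAxis] * m@thicknessCorrection
  aset@trees <- lapply(aset@trees, function(tr) {
    tr@nodes$x <- tr@nodes$x * sc[1]
    tr@nodes$y <- tr@nodes$y * sc[2]
    tr@nodes$z <- tr@nodes$z * sc[3]
    tr
  })
  aset@unit <- "nm"
  aset
}

#' Cortical depth below pia for physical positions
#'
#' @param depthCoord nm coordinate(s) along the dataset's depth axis (i.e.
#'   after [toPhysical()]).
#' @param meta the [DatasetMeta-class] supplying the pia offset.
#' @return Depth below pia in micrometres.
#' @export
depthBelowPia <- function(depthCoord, meta) {
  meta@piaOffset + depthCoord / 1000
}

#' Compare two annotation sets on nodes, edges, comments and names
#'
#' Order-insensitive structural equality: trees are matched by name, nodes
#' by id, edges as unordered pairs.
#'
#' @param a,b [AnnotationSet-class] objects.
#' @param tol numeric tolerance for coordinates.
#' @return `TRUE` or a character description of the first difference.
#' @export
annotationsEqual <- function(a, b, tol = 1e-9) {
  nmA <- vapply(a@trees, function(t) t@name, character(1))
  nmB <- vapply(b@trees, function(t) t@name, character(1))
  if (!setequal(nmA, nmB))
    return("tree names differ")
  for (nm in nmA) {
    ta <- a@trees[[match(nm, nmA)]]
    tb <- b@trees[[match(nm, nmB)]]
    na <- ta@nodes[order(ta@nodes$id), c("id", "x", "y", "z", "comment")]
    nb <- tb@nodes[order(tb@nodes$id), c("id", "x", "y", "z", "comment")]
    if (nrow(na) != nrow(nb) || !all(na$id == nb$id))
      return(paste0("node ids differ in tree '", nm, "'"))
    if (max(abs(as.matrix(na[, c("x", "y", "z")]) -
                as.matrix(nb[, c("x", "y", "z")])), 0) > tol)
      return(paste0("node positions differ in tree '", nm, "'"))
    ca <- ifelse(is.na(na$comment), "", na$comment)
    cb <- ifelse(is.na(nb$comment), "", nb$comment)
    if (!all(ca == cb))
      return(paste0("comments differ in tree '", nm, "'"))
    ea <- .canonEdges(ta@edges)
    eb <- .canonEdges(tb@edges)
    if (!identical(ea, eb))
      return(paste0("edges differ in tree '", nm, "'"))
  }
  TRUE
}

.canonEdges <- function(e) {
  if (!nrow(e)) return(matrix(integer(), ncol = 2))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}
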