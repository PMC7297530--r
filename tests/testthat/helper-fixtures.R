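# Fixtures built in code: tiny hand-made skeletons with known geometry.

# straight chain along `direction` with `n` nodes spaced `spacing` um apart
chainTree <- function(n, spacing = 1, direction = c(1, 0, 0),
                      origin = c(0, 0, 0), name = "chain",
                      idStart = 1L) {
  arc <- (seq_len(n) - 1) * spacing
  nodes <- data.frame(id = idStart + seq_len(n) - 1L,
                      x = origin[1] + arc * direction[1],
                      y = origin[2] + arc * direction[2],
                      z = origin[3] + arc * direction[3])
  edges <- if (n > 1) cbind(nodes$id[-n], nodes$id[-1]) else
    matrix(integer(), ncol = 2)
  SkeletonTree(name, nodes, edges)
}

# merge a second tree into the first, connecting attachFrom -> attachTo
joinTrees <- function(t1, t2, attachFrom, attachTo) {
  SkeletonTree(t1@name, rbind(t1@nodes, t2@nodes),
               rbind(t1@edges, t2@edges,
                     cbind(attachFrom, attachTo)))
}

# Y-shaped dendrite: vertical trunk (soma at deep end) splitting at the
# bifurcation into two straight daughters; returns a DendriteAnnotation
# with landmarks set. All lengths um.
yDendrite <- function(trunkLen = 30, daughterLen = 20, spacing = 1,
                      celltype = "L2", daughter2Len = daughterLen) {
  trunk <- chainTree(trunkLen / spacing + 1, spacing,
                     direction = c(0, 0, -1),
                     origin = c(0, 0, 100 + trunkLen), name = "y")
  mbId <- trunk@nodes$id[nrow(trunk@nodes)]
  mbPos <- unlist(trunk@nodes[nrow(trunk@nodes), c("x", "y", "z")])
  nextId <- mbId + 1L
  ang <- 30 * pi / 180
  mk <- function(len, sgn, id0) {
    d <- c(sgn * sin(ang), 0, -cos(ang))
    n <- max(1, round(len / spacing))
    arc <- seq_len(n) * spacing
    nodes <- data.frame(id = id0 + seq_len(n) - 1L,
                        x = mbPos[1] + arc * d[1],
                        y = mbPos[2] + arc * d[2],
                        z = mbPos[3] + arc * d[3])
    list(nodes = nodes, edges = cbind(c(mbId, nodes$id[-n]), nodes$id))
  }
  b1 <- mk(daughterLen, -1, nextId)
  nextId <- max(b1$nodes$id) + 1L
  b2 <- mk(daughter2Len, 1, nextId)
  keep <- c("id", "x", "y", "z")
  tree <- SkeletonTree("y", rbind(trunk@nodes[keep], b1$nodes[keep],
                                  b2$nodes[keep]),
                       rbind(trunk@edges, b1$edges, b2$edges))
  DendriteAnnotation(tree, celltype = celltype,
                     somaNode = trunk@nodes$id[1],
                     mainBifurcationNode = mbId)
}

# attach a labelled 2-node spine (neck + head) at the given shaft node;
# head carries the given synapse comments
addSpine <- function(ad, atNode, headSynapses = "spine_primary",
                     neckSynapse = FALSE) {
  tr <- ad@tree
  base <- unname(unlist(tr@nodes[match(atNode, tr@nodes$id),
                                 c("x", "y", "z")]))
  id0 <- max(tr@nodes$id) + 1L
  nodes <- data.frame(id = c(id0, id0 + 1L),
                      x = base[1] + c(1, 1.5), y = base[2], z = base[3])
  tree <- SkeletonTree(tr@name, rbind(tr@nodes[names(nodes)], nodes),
                       rbind(tr@edges, cbind(c(atNode, id0),
                                             c(id0, id0 + 1L))))
  syn <- ad@synapses
  for (s in headSynapses)
    syn <- rbind(syn, data.frame(id = nrow(syn) + 1L, node = id0 + 1L,
                                 onto = s, sizeMajor = NA_real_,
                                 sizeMinor = NA_real_,
                                 presynAxon = NA_integer_))
  if (neckSynapse)
    syn <- rbind(syn, data.frame(id = nrow(syn) + 1L, node = id0,
                                 onto = "spine_neck", sizeMajor = NA_real_,
                                 sizeMinor = NA_real_,
                                 presynAxon = NA_integer_))
  DendriteAnnotation(tree, celltype = ad@celltype, somaNode = ad@somaNode,
                     mainBifurcationNode = ad@mainBifurcationNode,
                     spineNeckNodes = c(ad@spineNeckNodes, id0, id0 + 1L),
                     synapses = syn,
                     diameterSamples = ad@diameterSamples,
                     analysisWindow = if (length(ad@analysisWindow))
                       ad@analysisWindow else NULL)
}

# add shaft synapse records on existing nodes
addShaftSynapses <- function(ad, atNodes) {
  syn <- ad@synapses
  for (nd in atNodes)
    syn <- rbind(syn, data.frame(id = nrow(syn) + 1L, node = nd,
                                 onto = "shaft", sizeMajor = NA_real_,
                                 sizeMinor = NA_real_,
                                 presynAxon = NA_integer_))
  initialize(ad, synapses = syn)
}

# random tree for property tests: spanning tree over random points
randomTree <- function(n = 50, name = "rand") {
  pos <- matrix(runif(3 * n, 0, 100), ncol = 3)
  # random spanning tree: connect each node to a random earlier node
  parents <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
  edges <- cbind(parents, 2:n)
  comments <- ifelse(runif(n) < 0.2,
                     paste0("c", sample(100, n, replace = TRUE)),
                     NA_character_)
  SkeletonTree(name, data.frame(id = 1:n, x = pos[, 1], y = pos[, 2],
                                z = pos[, 3], comment = comments),
               edges)
}

# independent oracle: total length as plain sum over the edge list
bruteForceLength <- function(tree, excludeIds = integer()) {
  nd <- tree@nodes
  keep <- !(tree@edges[, 1] %in% excludeIds) &
    !(tree@edges[, 2] %in% excludeIds)
  e <- tree@edges[keep, , drop = FALSE]
  if (!nrow(e)) return(0)
  i <- match(e[, 1], nd$id); j <- match(e[, 2], nd$id)
  sum(sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 +
           (nd$z[i] - nd$z[j])^2))
}

# independent oracle for the bin-merge rule: literal recursive rewrite
oracleMergeBins <- function(counts, minCount) {
  groups <- as.list(seq_along(counts))
  repeat {
    tots <- vapply(groups, function(g) sum(counts[g]), numeric(1))
    bad <- which(tots < minCount)
    if (!length(bad) || length(groups) == 1) return(groups)
    i <- bad[1]
    j <- if (i > 1) i - 1 else i + 1
    groups[[j]] <- sort(c(groups[[j]], groups[[i]]))
    groups[[i]] <- NULL
  }
}
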