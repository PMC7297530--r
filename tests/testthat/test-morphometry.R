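test_that("shaft path length sums Euclidean edge lengths", {
  tr <- chainTree(3, spacing = 1)
  ad <- DendriteAnnotation(tr)
  expect_equal(shaftPathLength(ad), 2)
})

test_that("spine-neck branches are pruned before measuring", {
  ad <- DendriteAnnotation(chainTree(3, spacing = 1), somaNode = 1L)
  ad <- addSpine(ad, atNode = 2L)                 # adds 1.5 um of branch
  expect_equal(shaftPathLength(ad), 2)
})

test_that("path length matches a brute-force edge-walk oracle", {
  set.seed(21)
  for (rep in 1:10) {
    tr <- randomTree(40)
    ad <- DendriteAnnotation(tr)
    expect_equal(shaftPathLength(ad), bruteForceLength(tr))
  }
})

test_that("windowed path length is additive over a partition", {
  ad <- yDendrite(trunkLen = 30, daughterLen = 20)
  whole <- shaftPathLength(ad)
  parts <- c(shaftPathLength(ad, c(0, 10)),
             shaftPathLength(ad, c(10, 20)),
             shaftPathLength(ad, c(20, 30)))
  expect_equal(sum(parts), whole)
  # the +-10 um window covers 10 um of trunk plus 10 um of each daughter
  expect_equal(shaftPathLength(ad, c(-10, 10)), 30)
})

test_that("an empty window yields zero with a warning", {
  ad <- yDendrite(trunkLen = 20, daughterLen = 10)
  expect_warning(L <- shaftPathLength(ad, c(500, 600)), "excludes")
  expect_equal(L, 0)
})

test_that("average diameter is the mean of samples", {
  ad <- DendriteAnnotation(chainTree(3), diameterSamples =
    data.frame(arc = c(0, 2.5, 5), diameter = c(1, 2, 3)))
  expect_equal(averageDiameter(ad), 2)
  ad2 <- DendriteAnnotation(chainTree(3), diameterSamples =
    data.frame(arc = 0:1, diameter = c(2, 2)))
  expect_equal(averageDiameter(ad2), 2)
})

test_that("a linear taper measured at 2.5 um spacing averages mid-taper", {
  arc <- seq(0, 30, by = 2.5)
  ad <- DendriteAnnotation(chainTree(31), diameterSamples =
    data.frame(arc = arc, diameter = 2 - arc / 30))
  # closed form: mean of linear taper 2.0 -> 1.0 is 1.5
  expect_lt(abs(averageDiameter(ad) - 1.5), 2.5 / 30 / 2 + 1e-9)
})

test_that("node radii stand in when no diameter samples exist", {
  nd <- data.frame(id = 1:11, x = 0:10, y = 0, z = 0, radius = 1.1)
  tr <- SkeletonTree("t", nd, cbind(1:10, 2:11))
  ad <- DendriteAnnotation(tr, somaNode = 1L)
  expect_equal(averageDiameter(ad), 2.2)
  adNone <- DendriteAnnotation(chainTree(3))
  expect_error(averageDiameter(adNone), "measurement missing")
})

test_that("surface area follows the open-cylinder formula", {
  expect_equal(surfaceArea(10, 2), 20 * pi)
  expect_equal(surfaceArea(1, 1 / pi), 1)
  expect_error(surfaceArea(-1, 2), "positive")
  # linear in each argument
  expect_equal(surfaceArea(7, 3), 7 * surfaceArea(1, 3))
  expect_equal(surfaceArea(7, 3), 3 * surfaceArea(7, 1))
})

test_that("open-cylinder area matches a triangulated mesh oracle", {
  L <- 20; d <- 1.6
  # triangulate the cylinder into strips and sum triangle areas
  nTheta <- 400; nZ <- 200
  th <- seq(0, 2 * pi, length.out = nTheta + 1)
  zz <- seq(0, L, length.out = nZ + 1)
  r <- d / 2
  triArea <- function(a, b, c) {
    ab <- b - a; ac <- c - a
    cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
            ab[3] * ac[1] - ab[1] * ac[3],
            ab[1] * ac[2] - ab[2] * ac[1])
    sqrt(sum(cr^2)) / 2
  }
  # per rectangular panel: two triangles; panels are congruent
  a <- c(r * cos(th[1]), r * sin(th[1]), zz[1])
  b <- c(r * cos(th[2]), r * sin(th[2]), zz[1])
  cc <- c(r * cos(th[1]), r * sin(th[1]), zz[2])
  dd <- c(r * cos(th[2]), r * sin(th[2]), zz[2])
  mesh <- (triArea(a, b, cc) + triArea(b, dd, cc)) * nTheta * nZ
  expect_lt(abs(mesh - surfaceArea(L, d)) / surfaceArea(L, d), 0.01)
})

test_that("equivalent sphere diameter is the geometric mean of axes", {
  expect_equal(equivalentSphereDiameter(c(10, 10, 10)), 10)
  expect_equal(equivalentSphereDiameter(c(8, 8, 27)), 12)
  # oracle: match ellipsoid volume pi*a*b*c/6 directly
  ax <- c(7.3, 11.1, 9.2)
  vol <- pi * prod(ax) / 6
  dSphere <- (6 * vol / pi)^(1 / 3)
  expect_equal(equivalentSphereDiameter(ax), dSphere)
  # permutation invariant
  expect_equal(equivalentSphereDiameter(ax),
               equivalentSphereDiameter(rev(ax)))
  expect_error(equivalentSphereDiameter(c(-1, 2, 3)), "positive")
})

test_that("trunk diameter uses the equal-area circle of the ellipse", {
  expect_equal(ellipseEquivalentDiameter(2, 2), 2)
  expect_equal(ellipseEquivalentDiameter(2, 0.5), 1)
  ad <- DendriteAnnotation(chainTree(3), diameterSamples =
    data.frame(arc = c(10, 50, 90), major = c(3, 2, 1),
               minor = c(3, 0.5, 1)))
  expect_equal(trunkDiameterAt(ad, 50), 1)
  expect_warning(d <- trunkDiameterAt(ad, 200), "distal")
  expect_equal(d, 1)
})

test_that("synapse interface area is an ellipse from full axes", {
  expect_equal(synapseInterfaceArea(2, 1), pi * 0.5)
  expect_equal(synapseInterfaceArea(2 / sqrt(pi), 2 / sqrt(pi)), 1)
  # circle case equals pi r^2
  expect_equal(synapseInterfaceArea(3, 3), pi * 1.5^2)
  expect_error(synapseInterfaceArea(0, 1), "positive")
})

test_that("main bifurcation detection honours annotations and symmetry", {
  ad <- yDendrite(trunkLen = 30, daughterLen = 20)
  ad2 <- initialize(ad, mainBifurcationNode = NA_integer_)
  expect_equal(detectMainBifurcation(ad2), 31L)   # symmetric Y
  expect_equal(detectMainBifurcation(ad), ad@mainBifurcationNode)
})

test_that("strongly asymmetric daughters fail detection at tol 0.5", {
  ad <- yDendrite(trunkLen = 30, daughterLen = 20, daughter2Len = 2)
  ad <- initialize(ad, mainBifurcationNode = NA_integer_)
  expect_error(detectMainBifurcation(ad, similarityTol = 0.5),
               "detection failed")
})

test_that("soma-to-bifurcation distance is the trunk arc length", {
  ad <- yDendrite(trunkLen = 100, daughterLen = 20)
  expect_equal(somaToBifurcationDistance(ad), 100)
  # spine necks on the trunk do not contribute
  ad2 <- addSpine(ad, atNode = 50L)
  expect_equal(somaToBifurcationDistance(ad2), 100)
  # oracle: path distance on the weighted graph, walked independently
  set.seed(5)
  tr <- randomTree(30)
  ad3 <- DendriteAnnotation(tr, somaNode = 1L,
                            mainBifurcationNode = 30L)
  g <- igraph::graph_from_edgelist(apply(tr@edges, 2, as.character),
                                   directed = FALSE)
  nd <- tr@nodes
  w <- sqrt((nd$x[tr@edges[, 1]] - nd$x[tr@edges[, 2]])^2 +
            (nd$y[tr@edges[, 1]] - nd$y[tr@edges[, 2]])^2 +
            (nd$z[tr@edges[, 1]] - nd$z[tr@edges[, 2]])^2)
  oracle <- igraph::distances(g, "1", "30", weights = w)[1, 1]
  expect_equal(somaToBifurcationDistance(ad3), oracle)
})

test_that("length measurements are invariant under rigid rotation", {
  set.seed(9)
  tr <- randomTree(30)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- tr
  xyz <- as.matrix(tr@nodes[, c("x", "y", "z")]) %*% t(R)
  rot@nodes$x <- xyz[, 1]; rot@nodes$y <- xyz[, 2]; rot@nodes$z <- xyz[, 3]
  expect_equal(shaftPathLength(DendriteAnnotation(rot)),
               shaftPathLength(DendriteAnnotation(tr)))
})

test_that("bifurcation depth histograms and axon slices behave", {
  # all bifurcations at one depth: single occupied bin
  p <- landmarkDepthProfiles(bifurcationDepths = rep(105, 8))
  expect_equal(sum(p$bifHist$count > 0), 1)
  expect_equal(sum(p$bifHist$count), 8)

  # one straight vertical axon spanning 40 um: two slices at 0.5 each
  ax <- chainTree(41, spacing = 1, direction = c(0, 0, 1),
                  origin = c(0, 0, 100), name = "axon")
  aset <- AnnotationSet(list(ax), DatasetMeta(), unit = "voxel")
  aset@meta@voxelSize <- c(1000, 1000, 1000)  # um-per-voxel scaling
  p2 <- landmarkDepthProfiles(axonSets = list(aset))
  expect_equal(nrow(p2$axonProfile), 2)
  expect_equal(p2$axonProfile$fraction, c(0.5, 0.5))
  expect_equal(sum(p2$axonProfile$fraction), 1)

  # a uniform vertical mat of axons gives a flat profile
  mat <- lapply(1:30, function(i)
    chainTree(101, 1, c(0, 0, 1), origin = c(i * 10, 0, 0),
              name = paste0("ax", i)))
  aset3 <- AnnotationSet(mat, DatasetMeta(voxelSize = c(1000, 1000, 1000)))
  p3 <- landmarkDepthProfiles(axonSets = list(aset3))
  expect_equal(nrow(p3$axonProfile), 5)
  expect_true(all(abs(p3$axonProfile$fraction - 0.2) < 1e-9))
})

test_that("synapse-marking nodes are dropped from axon path profiles", {
  nd <- data.frame(id = 1:3, x = 0, y = 0, z = c(0, 10000, 500000),
                   comment = c(NA, NA, "synapse"))
  ax <- SkeletonTree("a", nd, cbind(1:2, 2:3))
  aset <- AnnotationSet(list(ax), DatasetMeta())
  p <- landmarkDepthProfiles(axonSets = list(aset))
  # only the 10-um edge (node 1-2) remains; it spans one 20-um slice
  expect_equal(sum(p$axonProfile$fraction), 1)
  expect_lte(max(p$axonProfile$binEnd), 20)
})
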