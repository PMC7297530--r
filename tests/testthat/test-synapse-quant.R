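test_that("structural categories map to synapse classes", {
  expect_equal(classifySynapse("shaft"), "putative_inhibitory")
  expect_equal(classifySynapse("spine_primary"), "excitatory")
  expect_equal(classifySynapse("spine_secondary"), "putative_inhibitory")
  expect_equal(classifySynapse("spine_neck"), "putative_inhibitory")
  expect_error(classifySynapse("axosomatic"), "unknown")
})

test_that("densities and fractions follow counts over shaft length", {
  # 10 shaft synapses on a 20-um chain
  ad <- DendriteAnnotation(chainTree(21), somaNode = 1L)
  ad <- addShaftSynapses(ad, atNodes = 2:11)
  r <- densityResult(ad)
  expect_equal(r$densInhLen, 0.5)
  expect_equal(r$inhFraction, 1)
  expect_equal(r$nExc, 0)

  # 1 shaft + 3 primary-spine synapses: inhibitory fraction 1/4
  ad2 <- DendriteAnnotation(chainTree(21), somaNode = 1L)
  ad2 <- addShaftSynapses(ad2, atNodes = 5L)
  for (nd in c(8L, 12L, 16L)) ad2 <- addSpine(ad2, nd)
  r2 <- densityResult(ad2)
  expect_equal(r2$inhFraction, 0.25)
  expect_equal(r2$shaftLength, 20)
  expect_equal(r2$spineDensity, 3 / 20)
})

test_that("double-innervated spines count one excitatory one inhibitory", {
  ad <- DendriteAnnotation(chainTree(21), somaNode = 1L)
  ad <- addSpine(ad, 5L, headSynapses = c("spine_primary",
                                          "spine_secondary"))
  ad <- addSpine(ad, 10L)
  r <- densityResult(ad)
  expect_equal(r$nExc, 2)
  expect_equal(r$nInh, 1)
  expect_equal(r$multiSpineFraction, 0.5)
})

test_that("spine-neck synapses stay out of the innervated-spine rate", {
  ad <- DendriteAnnotation(chainTree(21), somaNode = 1L)
  ad <- addSpine(ad, 5L, neckSynapse = TRUE)
  ad <- addSpine(ad, 10L)
  r <- densityResult(ad)
  expect_equal(r$nSpineNeck, 1)
  expect_equal(r$multiSpineFraction, 0)   # necks don't make spines "multi"
})

test_that("windowed density results combine over a window partition", {
  set.seed(31)
  ad <- yDendrite(trunkLen = 40, daughterLen = 30)
  ad <- addShaftSynapses(ad, sample(nodeTable(ad)$id, 25))
  whole <- densityResult(ad, window = c(0, 30))
  a <- densityResult(ad, window = c(0, 15))
  b <- densityResult(ad, window = c(15, 30))
  expect_equal(a$nInh + b$nInh, whole$nInh)
  expect_equal(a$shaftLength + b$shaftLength, whole$shaftLength)
  # count-weighted combination reproduces the pooled fraction
  expect_equal((a$densInhLen * a$shaftLength +
                b$densInhLen * b$shaftLength) / whole$shaftLength,
               whole$densInhLen)
})

test_that("Poisson placement recovers the generating rates", {
  set.seed(77)
  # 100 dendrites at inh 0.42 / exc 0.84 per um over a 30-um window
  res <- lapply(1:100, function(i) {
    ad <- DendriteAnnotation(chainTree(31), somaNode = 1L)
    nI <- rpois(1, 0.42 * 30); nE <- rpois(1, 0.84 * 30)
    ad <- addShaftSynapses(ad, sample(2:30, nI, replace = TRUE))
    for (k in seq_len(nE))
      ad <- addSpine(ad, sample(2:30, 1))
    densityResult(ad)
  })
  s <- summarizeDensities(res)$summary
  mInh <- s$mean[s$statistic == "densInhLen"]
  sInh <- s$sem[s$statistic == "densInhLen"]
  mExc <- s$mean[s$statistic == "densExcLen"]
  sExc <- s$sem[s$statistic == "densExcLen"]
  expect_lt(abs(mInh - 0.42), 3 * sInh)
  expect_lt(abs(mExc - 0.84), 3 * sExc)
})

test_that("pooled and per-dendrite statistics are both exposed", {
  # ratio of means vs mean of ratios: pooling counts need not equal the
  # mean of per-dendrite fractions
  mk <- function(nI, nE) {
    ad <- DendriteAnnotation(chainTree(21), somaNode = 1L)
    ad <- addShaftSynapses(ad, rep(5L, nI))
    if (nE > 0) for (k in seq_len(nE)) ad <- addSpine(ad, 10L)
    densityResult(ad)
  }
  res <- list(mk(1, 9), mk(9, 1))
  s <- summarizeDensities(res)
  expect_equal(s$pooled$inhFraction, 0.5)
  expect_equal(mean(s$perDendrite$inhFraction), 0.5)
  res2 <- list(mk(1, 9), mk(5, 5))
  s2 <- summarizeDensities(res2)
  expect_equal(s2$pooled$inhFraction, 6 / 20)
  expect_equal(mean(s2$perDendrite$inhFraction), (0.1 + 0.5) / 2)
})

test_that("deficient distance bins merge proximally first", {
  # oracle re-implements the merge rule literally
  cases <- list(c(5, 6, 7), c(5, 2, 6), c(1, 1, 10), c(0, 5, 6),
                c(4, 3, 3, 4), c(2, 2), c(10), c(3))
  for (counts in cases) {
    expect_identical(mergeBins(counts, 4), oracleMergeBins(counts, 4))
  }
  # the spec'd worked example: [5, 2, 6] -> [7, 6]
  m <- mergeBins(c(5, 2, 6), 4)
  expect_equal(lapply(m, function(g) sum(c(5, 2, 6)[g])), list(7, 6))
  # exhaustive scan over small random vectors
  set.seed(13)
  for (rep in 1:50) {
    counts <- rpois(sample(2:6, 1), 3)
    expect_identical(mergeBins(counts, 4), oracleMergeBins(counts, 4))
  }
})

test_that("distance profiles bin by path distance to soma", {
  ad <- DendriteAnnotation(chainTree(31), somaNode = 1L)
  # 5 inh at 2-6 um, 6 exc at 12-17, 7 inh at 22-28: no merges
  ad <- addShaftSynapses(ad, c(3:7, 23:29))
  for (nd in 13:18) ad <- addSpine(ad, nd)
  p <- distanceProfile(ad, bin = 10, minCount = 4)
  expect_equal(nrow(p), 3)
  expect_equal(p$inhFraction, c(1, 0, 1))
  expect_equal(p$nExc, c(0, 6, 0))

  # all synapses in one bin: single-bin profile at the global fraction
  ad2 <- DendriteAnnotation(chainTree(31), somaNode = 1L)
  ad2 <- addShaftSynapses(ad2, c(3L, 4L))
  for (nd in 5:8) ad2 <- addSpine(ad2, nd)
  p2 <- distanceProfile(ad2, bin = 10, minCount = 4)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$inhFraction, 2 / 6)

  # no synapses: empty profile
  expect_equal(nrow(distanceProfile(
    DendriteAnnotation(chainTree(5), somaNode = 1L))), 0)
})

test_that("trunk profile of generated L2 cells follows the distance model", {
  set.seed(91)
  gen <- generateDendrites(generatorConfig(), c(L2 = 25), seed = 91)
  ads <- extractDendrites(gen$annotation)
  p <- distanceProfile(ads, bin = 10, minCount = 20)
  mid <- (p$binStart + p$binEnd) / 2
  model <- pmin(0.9, pmax(0.02, 0.1 + 1.57 * exp(-0.047 * mid)))
  # pooled over 25 cells the binned fractions track the model closely
  keep <- p$binEnd <= 30    # proximal trunk, before window effects
  expect_lt(max(abs(p$inhFraction[keep] - model[keep])), 0.12)
})

test_that("depth-slab pooling and bootstrap intervals behave", {
  # one dendrite entirely inside one slab: fraction exact, CI degenerate
  ad <- DendriteAnnotation(chainTree(21, direction = c(1, 0, 0),
                                     origin = c(0, 0, 150)),
                           somaNode = 1L)
  ad <- addShaftSynapses(ad, 3:7)
  for (nd in 10:14) ad <- addSpine(ad, nd)
  p <- corticalDepthProfile(list(ad), nBoot = 200, seed = 4)
  expect_equal(nrow(p), 1)
  expect_equal(p$slabStart, 100)
  expect_equal(p$inhFraction, 0.5)
  expect_equal(p$fracLo, 0.5)
  expect_equal(p$fracHi, 0.5)

  # two identical dendrites: zero-width interval
  p2 <- corticalDepthProfile(list(ad, ad), nBoot = 200, seed = 4)
  expect_equal(p2$fracHi - p2$fracLo, 0)

  # dendrite spanning two slabs: path length splits by depth extent
  adv <- DendriteAnnotation(chainTree(41, direction = c(0, 0, 1),
                                      origin = c(0, 0, 80)),
                            somaNode = 1L)
  p3 <- corticalDepthProfile(list(adv), nBoot = 50, seed = 1)
  expect_equal(p3$pathLength, c(20, 20))
})

test_that("bootstrap intervals cover the generating fraction", {
  set.seed(55)
  hits <- replicate(120, {
    ads <- lapply(1:12, function(i) {
      ad <- DendriteAnnotation(chainTree(31, origin = c(0, 0, 120)),
                               somaNode = 1L)
      nI <- rpois(1, 0.3 * 30); nE <- rpois(1, 0.7 * 30)
      ad <- addShaftSynapses(ad, sample(2:30, nI, replace = TRUE))
      syn <- ad@synapses
      for (k in seq_len(nE))
        syn <- rbind(syn, data.frame(id = nrow(syn) + 1, node = 15L,
                                     onto = "spine_primary",
                                     sizeMajor = NA_real_,
                                     sizeMinor = NA_real_,
                                     presynAxon = NA_integer_))
      initialize(ad, synapses = syn)
    })
    p <- corticalDepthProfile(ads, nBoot = 300, seed = NULL)
    p$fracLo[1] <= 0.3 && 0.3 <= p$fracHi[1]
  })
  # nominal 95% coverage; binomial tolerance at 120 replicates
  expect_gt(mean(hits), 0.95 - 3 * sqrt(0.95 * 0.05 / 120))
})

test_that("tuft branches decompose at the main bifurcation", {
  ad <- yDendrite(trunkLen = 30, daughterLen = 25)
  br <- tuftBranches(ad)
  expect_length(br, 2)
  expect_equal(sort(vapply(br, length, integer(1))), c(25, 25))
})

test_that("distal tuft composition is measured per branch", {
  ad <- yDendrite(trunkLen = 30, daughterLen = 40)
  br <- tuftBranches(ad)
  # put 2 shaft synapses in the distal window of branch 1, 6 spines too
  arc <- arcDistances(ad, "bifurcation")
  distal1 <- br[[1]][arc[as.character(br[[1]])] > 12]
  ad <- addShaftSynapses(ad, distal1[1:2])
  for (nd in distal1[1:6]) ad <- addSpine(ad, nd)
  r <- distalTuftResults(ad, distalLength = 30)
  expect_equal(nrow(r), 2)
  expect_equal(r$nInh[1], 2)
  expect_equal(r$nExc[1], 6)
  expect_equal(r$inhFraction[1], 0.25)
  expect_equal(r$nExc[2] + r$nInh[2], 0)
  expect_equal(r$pathLength, c(30, 30))
})
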