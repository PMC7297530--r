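# small hand-made axon table builder
axRows <- function(axon, categories, seedType = "L2",
                   seedLocation = "shaft", region = "S1",
                   layerContext = "L2", adId = NA_character_,
                   singleSpine = NULL) {
  data.frame(axon = axon, seedType = seedType,
             seedLocation = seedLocation, region = region,
             layerContext = layerContext, category = categories,
             adId = adId,
             singleSpine = singleSpine %||%
               (categories == "single_spine"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("spine fraction counts single-innervated-spine outputs", {
  tab <- axRows("a1", c(rep("single_spine", 9), "other_shaft"))
  expect_equal(spineFraction(tab)$spineFraction, 0.9)
  tab2 <- axRows("a2", rep("other_shaft", 7))
  expect_equal(spineFraction(tab2)$spineFraction, 0)
  # brute force on randomized output lists
  set.seed(2)
  for (rep in 1:10) {
    cats <- sample(targetCategories(), 20, replace = TRUE)
    tab3 <- axRows("a", cats)
    expect_equal(spineFraction(tab3)$spineFraction,
                 sum(cats == "single_spine") / 20)
  }
})

test_that("axon classification needs a strict spine majority", {
  expect_equal(classifyAxon(0.9), "excitatory")
  expect_equal(classifyAxon(0.1), "putative_inhibitory")
  expect_equal(classifyAxon(0.5), "putative_inhibitory")  # boundary
  expect_equal(classifyAxon(0.5 + 1e-9), "excitatory")
})

test_that("per-structure excitatory fractions aggregate over seeds", {
  tab <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      axRows(paste0("e", i), rep("single_spine", 10)))),
    do.call(rbind, lapply(1:2, function(i)
      axRows(paste0("i", i), rep("other_shaft", 10)))))
  out <- excitatoryFractionPerStructure(tab)
  expect_equal(out$excFraction, 0.6)
  expect_equal(out$nAxons, 5)

  # all spine-seeded axons excitatory
  tabS <- axRows("s1", rep("single_spine", 8), seedLocation = "spine")
  outS <- excitatoryFractionPerStructure(tabS)
  expect_equal(outS$excFraction, 1)
})

test_that("generator mixing is recovered within binomial error", {
  set.seed(8)
  sg <- data.frame(seedType = "L5st", seedLocation = "shaft",
                   layerContext = "L2", region = "S1", n = 200,
                   excMix = 0.6)
  ax <- generateAxons(seedGroups = sg, seed = 8)
  out <- excitatoryFractionPerStructure(ax$table)
  se <- sqrt(0.6 * 0.4 / 200)
  expect_lt(abs(out$excFraction - 0.6), 3 * se)
  # classification agrees with the planted truth
  sf <- spineFraction(ax$table)
  cls <- classifyAxon(sf$spineFraction)
  truth <- ax$truth$trueClass[match(sf$axon, ax$truth$axon)]
  expect_gt(mean(cls == truth), 0.98)
})

test_that("identity correction moves shaft mass to the excitatory side", {
  ad <- DendriteAnnotation(chainTree(21), somaNode = 1L)
  ad <- addShaftSynapses(ad, rep(5L, 10))
  raw <- densityResult(ad)
  same <- correctDensity(raw, 0)
  expect_equal(same$nInh, raw$nInh)
  expect_equal(same$inhFraction, raw$inhFraction)
  expect_true(same$corrected)

  corr <- correctDensity(raw, 0.6)
  expect_equal(corr$nInh, 4)
  expect_equal(corr$nExc, 6)
  expect_equal(corr$inhFraction, 0.4)
  expect_error(correctDensity(corr, 0.1), "already corrected")
})

test_that("corrected fractions match per-synapse reclassification", {
  # Monte-Carlo oracle: reassign each shaft synapse excitatory with
  # probability f and compare expected fractions
  set.seed(14)
  f <- 0.44
  nShaft <- 40; nSpine <- 60
  sims <- replicate(2000, {
    reassigned <- rbinom(1, nShaft, f)
    (nShaft - reassigned) / (nShaft + nSpine)
  })
  ad <- DendriteAnnotation(chainTree(21), somaNode = 1L)
  ad <- addShaftSynapses(ad, rep(5L, nShaft))
  syn <- ad@synapses
  syn <- rbind(syn, data.frame(id = nrow(syn) + seq_len(nSpine),
                               node = 10L, onto = "spine_primary",
                               sizeMajor = NA_real_, sizeMinor = NA_real_,
                               presynAxon = NA_integer_))
  ad <- initialize(ad, synapses = syn)
  corr <- correctDensity(densityResult(ad), f)
  expect_lt(abs(corr$inhFraction - mean(sims)),
            3 * sd(sims) / sqrt(2000))
})

test_that("prediction accuracy reflects seed-location agreement", {
  tab <- rbind(axRows("i1", rep("other_shaft", 10)),
               axRows("i2", rep("other_shaft", 10)))
  out <- predictionAccuracy(tab)
  expect_equal(out$accuracy, 1)

  # half the shaft-seeded axons behave excitatory
  tab2 <- rbind(axRows("i1", rep("other_shaft", 10)),
                axRows("e1", rep("single_spine", 10)))
  out2 <- predictionAccuracy(tab2)
  expect_equal(out2$accuracy, 0.5)
})

test_that("innervation profiles are fraction vectors summing to one", {
  tab <- axRows("a1", c(rep("L2_AD", 2), rep("glia", 8)))
  pr <- innervationProfile(tab)
  expect_equal(pr$L2_AD, 0.2)
  expect_equal(pr$glia, 0.8)
  set.seed(4)
  for (rep in 1:10) {
    tab <- axRows("a", sample(targetCategories(), 15, replace = TRUE))
    pr <- innervationProfile(tab)
    expect_equal(sum(pr[targetCategories()]), 1)
  }
})

test_that("conditional matrix averages per-axon fractions", {
  tab <- axRows("a1", c("L2_AD", rep("DL_AD", 3), rep("soma", 6)),
                adId = c("x", "y", "y", "y", rep(NA, 6)))
  cm <- conditionalMatrix(innervationProfile(tab))
  expect_equal(cm$matrix$L2_AD, 0.1)
  expect_equal(cm$matrix$DL_AD, 0.3)
  expect_equal(cm$restricted$restrL2, 0.25)
  expect_equal(cm$restricted$restrDL, 0.75)
  # identical axons: mean equals the individual
  tab2 <- rbind(tab, transform(axRows("a2",
    c("L2_AD", rep("DL_AD", 3), rep("soma", 6)),
    adId = c("x", "y", "y", "y", rep(NA, 6)))))
  cm2 <- conditionalMatrix(innervationProfile(tab2))
  expect_equal(cm2$matrix$L2_AD, 0.1)
})

test_that("multiplicity statistics group synapses by distinct AD", {
  tab <- axRows("a1", c("L2_AD", "L2_AD", "DL_AD"),
                adId = c("a", "a", "b"))
  m <- multiplicityStats(tab)
  expect_equal(m$overall$meanSynapsesPerTarget, 1.5)
  expect_equal(m$overall$monoFraction, 0.5)
  expect_equal(m$overall$nConnections, 2)

  tab2 <- axRows("a1", rep("L2_AD", 3), adId = c("a", "b", "c"))
  m2 <- multiplicityStats(tab2)
  expect_equal(m2$overall$meanSynapsesPerTarget, 1)
  expect_equal(m2$overall$monoFraction, 1)

  # brute-force group-by oracle on random assignments
  set.seed(6)
  for (rep in 1:10) {
    ids <- sample(letters[1:5], 12, replace = TRUE)
    tab3 <- axRows("a1", rep("L2_AD", 12), adId = ids)
    m3 <- multiplicityStats(tab3)
    expect_equal(m3$overall$meanSynapsesPerTarget,
                 mean(as.numeric(table(ids))))
    expect_equal(m3$overall$monoFraction,
                 mean(table(ids) == 1))
  }
})

test_that("binarized preference counts each distinct AD once", {
  tab <- axRows("a1", c("L2_AD", "L2_AD", "DL_AD"),
                adId = c("a", "a", "b"))
  b <- binarizedPreference(tab)
  expect_equal(b$L2_AD, 0.5)
  expect_equal(b$DL_AD, 0.5)
  tab2 <- axRows("a1", rep("L2_AD", 4), adId = "a")
  b2 <- binarizedPreference(tab2)
  expect_equal(b2$L2_AD, 1)
  expect_equal(b2$DL_AD, 0)
})

test_that("binarized preference equals the conditional matrix when all
           connections are monosynaptic", {
  set.seed(12)
  sg <- data.frame(seedType = c("L2", "DL"), seedLocation = "shaft",
                   layerContext = "L2", region = "S1", n = 30, excMix = 0)
  cfg <- generatorConfig()
  cfg$axons$multiplicity <- c(`1` = 1)   # force monosynaptic connections
  ax <- generateAxons(cfg, seedGroups = sg, seed = 12)
  adOnly <- ax$table[ax$table$category %in% c("L2_AD", "DL_AD"), ]
  bp <- binarizedPreference(ax$table)
  cm <- conditionalMatrix(innervationProfile(adOnly))
  for (st in c("L2", "DL")) {
    expect_equal(bp$L2_AD[bp$seedType == st],
                 cm$restricted$restrL2[cm$restricted$seedType == st],
                 tolerance = 1e-12)
  }
})

test_that("bootstrap specificity p-values behave at the extremes", {
  set.seed(3)
  A <- matrix(runif(80), 10)
  colnames(A) <- targetCategories()
  out <- bootstrapSpecificityTest(A, A, nBoot = 500, seed = 3)
  expect_true(all(out$p > 0.5))
  expect_false(any(out$significant))

  # disjoint supports with large separation
  B <- A + 5
  out2 <- bootstrapSpecificityTest(A, B, nBoot = 500, seed = 3)
  expect_true(all(out2$p == 0))
  expect_true(all(out2$pPlus <= 1 / 500 + 1e-12))
  expect_true(all(out2$significant))
})

test_that("bootstrap test is invariant to relabelling and common scaling", {
  set.seed(5)
  A <- matrix(runif(64), 8); B <- matrix(runif(64), 8)
  colnames(A) <- colnames(B) <- targetCategories()
  out <- bootstrapSpecificityTest(A, B, nBoot = 400, seed = 9)
  perm <- sample(8)
  out2 <- bootstrapSpecificityTest(A[, perm], B[, perm], nBoot = 400,
                                   seed = 9)
  expect_equal(out$p[perm], out2$p)
  out3 <- bootstrapSpecificityTest(2 * A, 2 * B, nBoot = 400, seed = 9)
  expect_equal(out$p, out3$p)
})

test_that("selectivity separates seed groups; s = 0 does not", {
  set.seed(10)
  cfg <- generatorConfig()
  sg <- data.frame(seedType = c("L2", "DL"), seedLocation = "shaft",
                   layerContext = "L2", region = "S1", n = 45, excMix = 0)
  ax1 <- generateAxons(cfg, sg, seed = 10)
  pr1 <- innervationProfile(ax1$table)
  t1 <- bootstrapSpecificityTest(
    pr1[pr1$seedType == "L2", targetCategories()],
    pr1[pr1$seedType == "DL", targetCategories()], nBoot = 1000,
    seed = 2)
  expect_true(all(t1$significant[t1$category %in% c("L2_AD", "DL_AD")]))

  cfg$axons$selectivity <- 0
  ax0 <- generateAxons(cfg, sg, seed = 11)
  pr0 <- innervationProfile(ax0$table)
  t0 <- bootstrapSpecificityTest(
    pr0[pr0$seedType == "L2", targetCategories()],
    pr0[pr0$seedType == "DL", targetCategories()], nBoot = 1000,
    seed = 2)
  expect_false(any(t0$significant))
})

test_that("AD-restricted selectivity increases monotonically in s", {
  set.seed(20)
  cfg <- generatorConfig()
  sg <- data.frame(seedType = "L2", seedLocation = "shaft",
                   layerContext = "L2", region = "S1", n = 60, excMix = 0)
  fr <- vapply(c(0, 0.5, 1), function(s) {
    cfg$axons$selectivity <- s
    ax <- generateAxons(cfg, sg, seed = 20 + round(s * 10))
    cm <- conditionalMatrix(innervationProfile(ax$table))
    cm$restricted$restrL2
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_equal(fr[3], 1)   # fully selective: only own-type ADs
})

test_that("region CVs follow the definition and the omnibus test runs", {
  # identical region means: CV 0
  set.seed(30)
  base <- axRows("a", sample(targetCategories(), 12, replace = TRUE))
  tabs <- do.call(rbind, lapply(c("S1", "V2", "PPC", "ACC"), function(rg)
    do.call(rbind, lapply(1:3, function(i)
      transform(base, axon = paste0(rg, i), region = rg)))))
  rc <- regionConsistency(innervationProfile(tabs))
  expect_true(all(rc$cv$cv[!is.na(rc$cv$cv)] < 1e-9))

  # direct arithmetic oracle on region means {1,1,1,3}
  m <- c(1, 1, 1, 3)
  prof <- do.call(rbind, lapply(seq_along(m), function(k) {
    p <- innervationProfile(axRows(paste0("x", k), c("L2_AD", "soma"),
                                   region = c("S1", "V2", "PPC",
                                              "ACC")[k]))
    p$L2_AD <- m[k]
    p
  }))
  rc2 <- regionConsistency(prof)
  cvL2 <- rc2$cv$cv[rc2$cv$category == "L2_AD"]
  expect_equal(cvL2, sd(m) / mean(m) * 100)
})

test_that("the omnibus test rejects near the nominal rate under the null", {
  set.seed(41)
  ps <- replicate(120, {
    prof <- do.call(rbind, lapply(c("S1", "V2", "PPC", "ACC"),
      function(rg) {
        n <- 10
        X <- t(rmultinom(n, 25, prob = c(.2, .15, .3, .1, .15, .06,
                                         .03, .01))) / 25
        colnames(X) <- targetCategories()
        cbind(data.frame(axon = paste0(rg, 1:n), seedType = "L2",
                         region = rg, nSynapses = 25), as.data.frame(X))
      }))
    rc <- regionConsistency(prof)
    rc$omnibus$p
  })
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})
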