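test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig(nGenes = 40, nAnimals = 3, seed = 42)
  s1 <- simulateCounts(cfg)
  s2 <- simulateCounts(cfg)
  expect_identical(counts(s1$experiment), counts(s2$experiment))
  expect_identical(s1$truth, s2$truth)

  a1 <- simulateAnnotation(100, 10, c(5, 20), seed = 7)
  a2 <- simulateAnnotation(100, 10, c(5, 20), seed = 7)
  expect_identical(geneSets(a1), geneSets(a2))

  c1 <- simulateCellIntensities(200, senescentFraction = 0.4, seed = 5)
  c2 <- simulateCellIntensities(200, senescentFraction = 0.4, seed = 5)
  expect_identical(c1, c2)
})

test_that("a null configuration plants no effects and yields a valid design", {
  cfg <- simConfig(nGenes = 300, nAnimals = 6, seed = 2)
  sim <- simulateCounts(cfg)
  expect_true(all(sim$truth$fc_E == 1))
  expect_true(all(sim$truth$fc_U == 1))
  expect_true(all(sim$truth$fc_EU == 1))
  m <- counts(sim$experiment)
  expect_true(all(m >= 0) && all(m == round(m)))
  # each animal contributes exactly one sample per arm
  tab <- table(animalIds(sim$experiment), treatments(sim$experiment))
  expect_true(all(tab == 1))
  # group means differ only by sampling noise: mean log-ratio near zero
  fm <- fpmValues(fpm(sim$experiment))
  trt <- treatments(sim$experiment)
  lr <- log2(rowMeans(fm[, trt == "EU"]) / rowMeans(fm[, trt == "control"]))
  expect_lt(abs(mean(lr)), 0.1)
})

test_that("configuration errors are caught", {
  expect_error(simConfig(treatments = character(0)), "empty")
  expect_error(simConfig(treatments = c("E", "U")), "control")
  expect_error(simConfig(dispersion = 0), "positive")
  expect_error(simConfig(nGenes = 10,
    effects = data.frame(gene = 1, condition = "E", fc = 0.5)),
    "\\(-1, 1\\)")
})

test_that("NB mean-variance law holds across replicate samples", {
  # no block effect, fixed library size: counts are iid NB per gene
  cfg <- simConfig(nGenes = 200, nAnimals = 100,
                   treatments = "control", algebra = list(),
                   animalSd = 0, librarySizeRange = c(2e7, 2e7), seed = 3)
  sim <- simulateCounts(cfg)
  m <- counts(sim$experiment)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  ratio <- v / (mu + 0.1 * mu^2)
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.2)
})

test_that("additive planting converges to the additivity expectation", {
  # 30 planted genes among null filler, 200 animals: the mean measured
  # combined FC tracks the mean per-replicate expectation (MC tolerance)
  eff <- rbind(data.frame(gene = 1:30, condition = "E", fc = 2),
               data.frame(gene = 1:30, condition = "U", fc = 3))
  modes <- rep("none", 300); modes[1:30] <- "additive"
  cfg <- simConfig(nGenes = 300, nAnimals = 200, effects = eff,
                   synergyMode = modes, seed = 9)
  sim <- simulateCounts(cfg)
  expect_equal(unique(sim$truth$fc_EU[1:30]), expectedFC(2, 3))
  fm <- fpm(sim$experiment)
  tab <- buildSynergyTable(fm, sim$experiment, "EU", c("E", "U"),
                           genes = sprintf("gene%05d", 1:30))
  # the two means agree up to the small O(dispersion) ratio bias shared
  # by measured and expected FCs
  expect_lt(abs(mean(tab$meanMeasured) - mean(tab$meanExpected)), 0.3)
  expect_lt(abs(mean(tab$meanMeasured) - 4), 0.6)
})

test_that("annotation generator honours degenerate settings", {
  empty <- simulateAnnotation(50, 0, c(5, 10), seed = 1)
  expect_equal(length(empty), 0L)
  expect_equal(length(annotationDomain(empty)), 50L)

  whole <- simulateAnnotation(20, 3, c(20, 20), seed = 1)
  expect_true(all(vapply(geneSets(whole), function(g)
    setequal(g, annotationDomain(whole)), TRUE)))

  expect_error(simulateAnnotation(10, 2, c(5, 11)), "exceed")
})

test_that("cell-intensity mixture respects the planted senescent fraction", {
  none <- simulateCellIntensities(2000, senescentFraction = 0, seed = 4)
  p <- suppressWarnings(ks.test(none$green[none$condition == "control"],
                                none$green[none$condition == "treated"]))
  expect_gt(p$p.value, 1e-3)

  all <- simulateCellIntensities(2000, senescentFraction = 1, seed = 4)
  expect_lt(abs(mean(all$green[all$condition == "treated"]) - 20), 0.5)

  expect_error(simulateCellIntensities(10, senescentFraction = 1.2), "0, 1")
  expect_error(simulateCellIntensities(10, controlSd = 0), "positive")

  mix <- simulateCellIntensities(10000, senescentFraction = 0.3, seed = 6)
  cross <- gaussianCrossing(10, 2, 20, 2)
  frac <- mean(mix$green[mix$condition == "treated"] > cross)
  expect_lt(abs(frac - 0.3), 0.02)
})
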