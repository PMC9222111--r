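eps <- 1e-12  # pseudocount small enough to recover the pure ratios

test_that("symmetric FC follows its definition and is anti-symmetric", {
  expect_equal(symmetricFC(10, 5, eps), 2)
  expect_equal(symmetricFC(5, 10, eps), -2)
  expect_equal(symmetricFC(7, 7, eps), 1)
  expect_equal(symmetricFC(7, 7, 3), 1)  # identity ratio for any pseudocount

  set.seed(1)
  a <- runif(500, 0.1, 100); b <- runif(500, 0.1, 100)
  fc <- symmetricFC(a, b, eps)
  expect_true(all(abs(fc) >= 1))
  # reciprocal ratios map to the negated value (off the ratio-1 fixed point)
  off <- abs(a - b) > 1e-9
  expect_equal(symmetricFC(b, a, eps)[off], -fc[off], tolerance = 1e-6)

  expect_error(symmetricFC(-1, 5), "non-negative")
  expect_error(symmetricFC(1, 5, pseudocount = 0), "positive")
})

test_that("the additivity expectation follows the sign rule", {
  expect_equal(expectedFC(2, 3), 4)
  expect_equal(expectedFC(-2, -2), -3)
  expect_equal(expectedFC(-2, 3), 2)
  set.seed(2)
  x <- runif(300, 1, 50)
  expect_equal(expectedFC(rep(1, 300), x), x)   # neutral partner
  y <- runif(300, 1, 50) * sample(c(-1, 1), 300, TRUE)
  expect_equal(expectedFC(x, y), expectedFC(y, x))  # symmetric
  expect_error(expectedFC(0.5, 2), ">= 1")
})

test_that("paired synergy test classifies direction and degenerate input", {
  same <- c(2, 3, 4, 2.5, 3.5, 3)
  res <- quantSynergyTest(same, same)
  expect_equal(res$p, 1)
  expect_equal(res$direction, "none")

  set.seed(3)
  expected <- c(2, 2.2, 1.8, 2.1, 1.9, 2)
  measured <- expected + 2 + rnorm(6, 0, 0.05)
  res2 <- quantSynergyTest(measured, expected)
  expect_lt(res2$p, 0.05)
  expect_equal(res2$direction, "stimulatory")

  # sign disagreement forces the inhibitory call even with larger mean
  res3 <- quantSynergyTest(measured, -expected)
  expect_lt(res3$p, 0.05)
  expect_equal(res3$direction, "inhibitory")

  expect_equal(quantSynergyTest(c(1, 2), c(1, 3))$direction, "untestable")
})

test_that("exclusive intersections partition the union of DEG sets", {
  tab <- intersectDegSets(list(A = c("a", "b"), B = c("b", "c")))
  sig <- setNames(tab$genes, tab$signature)
  expect_equal(sig[["A"]], "a")
  expect_equal(sig[["A&B"]], "b")
  expect_equal(sig[["B"]], "c")

  disj <- intersectDegSets(list(A = c("a", "b"), B = c("c")))
  expect_true(all(disj$degree == 1))

  set.seed(4)
  pool <- sprintf("g%03d", 1:120)
  sets <- list(E = sample(pool, 50), U = sample(pool, 50),
               EU = sample(pool, 50))
  tab3 <- intersectDegSets(sets)
  memb <- attr(tab3, "membership")
  # brute-force per-gene membership lookup
  for (g in unique(unlist(sets))) {
    expSig <- paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
                    collapse = "&")
    cell <- memb[[expSig]]
    expect_true(g %in% cell)
  }
  expect_equal(sum(tab3$n_genes), length(unique(unlist(sets))))
  expect_equal(anyDuplicated(unlist(memb)), 0L)

  expect_error(intersectDegSets(list(A = "a")), "at least 2")
  expect_error(intersectDegSets(setNames(list("a", "b"), c("A", "A"))),
               "unique")
})

test_that("qualitative labels encode stimulation and inhibition patterns", {
  algebra <- list(EU = c("E", "U"))
  allSets <- c("E", "U", "EU")
  expect_equal(classifyQualitative("EU", algebra, allSets), "stimulation")
  expect_equal(classifyQualitative("U", algebra, allSets), "inhibition")
  expect_equal(classifyQualitative(c("E", "EU"), algebra, allSets), "none")
  expect_error(classifyQualitative("XY", algebra, allSets), "unknown")
})

test_that("KS shift test matches the brute-force ECDF oracle", {
  x <- c(0.2, 1.4, -0.5, 2.2, 0.9, 1.1, 0.1, 0.6)
  y <- c(1.2, 2.4, 0.5, 3.1, 1.9, 2.1, 1.1, 1.6)
  res <- ksShiftTest(x, y, splitBySign = FALSE)
  expect_equal(res$D, bruteKS(x, y))

  same <- rep(c(-2, -1.5, -3, 2, 1.5, 3), 2)
  res2 <- ksShiftTest(same, same)
  expect_true(all(res2$D == 0))
  expect_true(all(res2$p == 1))

  set.seed(6)
  big <- ksShiftTest(rnorm(200), rnorm(200, 1), splitBySign = FALSE)
  expect_lt(big$p, 0.05)

  expect_error(ksShiftTest(numeric(0), numeric(0)), "empty")
})

test_that("targeted screen flags amplified combined responses only", {
  planted <- function(fcE, fcU, fcEU, seed = 10) {
    eff <- rbind(
      data.frame(gene = 1, condition = "E", fc = fcE),
      data.frame(gene = 1, condition = "U", fc = fcU),
      data.frame(gene = 1, condition = "EU", fc = fcEU))
    cfg <- simConfig(nGenes = 100, nAnimals = 6, effects = eff,
                     dispersion = 0.01, seed = seed)
    sim <- simulateCounts(cfg)
    fm <- fpm(sim$experiment)
    targetedPairwiseScreen(list(`24h` = fm), list(`24h` = sim$experiment),
                           "EU", c("E", "U"),
                           eligibleGenes = "gene00001")
  }
  # strong combined response over both singles
  hit <- planted(2, 2, 8)
  expect_equal(hit$gene, "gene00001")
  expect_equal(hit$direction, "up")
  # additive gene with singles (2, 3): combined 4 beats both singles, so
  # the screen alone cannot certify synergy
  add <- planted(2, 3, 4)
  expect_equal(add$gene, "gene00001")
  # identical FPM in all conditions -> empty
  null <- planted(1, 1, 1)
  expect_equal(nrow(null), 0L)
  # exclusion list removes genes from the screen
  excl <- targetedPairwiseScreen(list(), list(), "EU", c("E", "U"),
                                 eligibleGenes = "g1", excludeGenes = "g1")
  expect_equal(nrow(excl), 0L)
})

test_that("synergy table flags expectations leaving the symmetric scale", {
  # opposite-sign singles can push the printed formula into (-1, 1)
  eff <- rbind(data.frame(gene = 1, condition = "E", fc = 2),
               data.frame(gene = 1, condition = "U", fc = -2.05))
  cfg <- simConfig(nGenes = 50, nAnimals = 6, effects = eff,
                   dispersion = 0.01, seed = 2)
  sim <- simulateCounts(cfg)
  tab <- buildSynergyTable(fpm(sim$experiment), sim$experiment, "EU",
                           c("E", "U"), genes = "gene00001")
  expect_true(tab$expected_out_of_range)
})
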