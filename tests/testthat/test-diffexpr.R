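test_that("TMM factors are neutral under scaling and react to composition", {
  set.seed(1)
  base <- matrix(rnbinom(400, mu = 100, size = 10), 200, 2,
                 dimnames = list(sprintf("g%03d", 1:200), c("s1", "s2")))
  base[, 2] <- base[, 1]
  expect_equal(unname(tmmFactors(base)), c(1, 1), tolerance = 1e-8)

  doubled <- base
  doubled[, 2] <- 2L * base[, 1]
  f <- tmmFactors(doubled)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-6)

  # one gene takes ~50% of column 2's reads: factor for s2 < 1
  comp <- base
  comp[1, 2] <- sum(base[, 2])
  f2 <- tmmFactors(comp)
  expect_lt(f2[["s2"]], 1)

  expect_error(tmmFactors(cbind(s1 = c(1L, 2L), s2 = c(0L, 0L))), "s2")
})

test_that("TMM matches the longhand doubly-trimmed recipe on a toy matrix", {
  set.seed(42)
  toy <- matrix(rnbinom(40, mu = 200, size = 5) + 1L, 10, 4,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  toy[1, 2] <- 3000L  # composition shift
  expect_equal(unname(tmmFactors(toy)), unname(bruteTMM(toy)),
               tolerance = 1e-6)
})

test_that("FPM follows its definition and matches the reference CPM", {
  m <- matrix(c(500L, 999500L, 1000L, 999000L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ce <- makeToyExperiment(m, c("control", "E"), 1)
  f1 <- fpm(ce, factors = c(1, 1))
  expect_equal(fpmValues(f1)["g1", "s1"], 500)
  # doubling a count at fixed library size doubles its FPM
  expect_equal(fpmValues(f1)["g1", "s2"], 2 * fpmValues(f1)["g1", "s1"])
  # a factor of 2 halves every FPM in that sample
  f2 <- fpm(ce, factors = c(1, 2))
  expect_equal(fpmValues(f2)[, "s2"], fpmValues(f1)[, "s2"] / 2)

  set.seed(3)
  big <- matrix(rnbinom(2000, mu = 50, size = 5), 500, 4,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:4)))
  ce2 <- makeToyExperiment(big, c("control", "E"), 2)
  fac <- tmmFactors(ce2)
  ours <- fpmValues(fpm(ce2, fac))
  dge <- edgeR::DGEList(big)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  expect_equal(ours, edgeR::cpm(dge, normalized.lib.sizes = TRUE),
               tolerance = 1e-10)
})

test_that("expression filter applies the smallest-group CPM rule exactly", {
  # 6 samples in two groups of 3, all library sizes equal: the CPM cutoff
  # corresponds to exactly 10 counts
  L <- 1e6L
  m <- rbind(
    atBoundary = c(10L, 10L, 10L, 0L, 0L, 0L),   # 3 samples at cutoff
    oneFewer   = c(10L, 10L, 0L, 0L, 0L, 0L),    # 2 samples at cutoff
    zero       = rep(0L, 6),
    high       = rep(1000L, 6))
  m <- rbind(m, filler = as.integer(L - colSums(m)))
  colnames(m) <- sprintf("s%d", 1:6)
  stopifnot(all(colSums(m) == L))
  ce <- makeToyExperiment(m, c("control", "E"), 3)
  kept <- filterExpressed(ce)
  expect_true("atBoundary" %in% kept)
  expect_false("oneFewer" %in% kept)
  expect_false("zero" %in% kept)
  expect_true("high" %in% kept)
})

test_that("copied treatment columns give zero coefficients and p near 1", {
  set.seed(8)
  half <- matrix(rnbinom(120, mu = 200, size = 10), 40, 3)
  m <- matrix(0L, 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  m[, c(1, 3, 5)] <- half
  m[, c(2, 4, 6)] <- half  # treatment arm identical per animal
  ce <- makeToyExperiment(m, c("control", "E"), 3)
  # the degenerate fixture triggers edgeR's zero-variance offset warning
  res <- suppressWarnings(
    deTest(ce, "E", method = "edgeR", testedGenes = rownames(m)))
  expect_true(all(abs(res$log2FC) < 1e-8))
  expect_true(all(res$pvalue > 0.999))
})

test_that("raw p-values are near-uniform under the planted null", {
  fracs <- vapply(1:2, function(seed) {
    cfg <- simConfig(nGenes = 1000, nAnimals = 6,
                     treatments = c("control", "E"), algebra = list(),
                     seed = seed)
    sim <- simulateCounts(cfg)
    res <- deTest(sim$experiment, "E", method = "edgeR")
    mean(res$pvalue < 0.05, na.rm = TRUE)
  }, 1)
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.08)
})

test_that("consensus rule requires both FDRs, the FPM floor and direction A", {
  m <- matrix(0L, 3, 6, dimnames = list(c("gA", "gB", "gC"),
                                        sprintf("s%d", 1:6)))
  # FPM scale: library sizes equal, factor 1 => FPM = count/L*1e6
  L <- 1e6L
  m["gA", ] <- c(0L, 10L, 0L, 8L, 0L, 12L)        # control mean 0, E mean 10
  m["gB", ] <- c(5L, 3L, 4L, 3L, 5L, 3L)          # means below 5 FPM
  m["gC", ] <- c(6L, 30L, 6L, 28L, 6L, 32L)       # control mean 6 FPM
  filler <- as.integer(L - colSums(m))
  m <- rbind(m, filler = filler)
  ce <- makeToyExperiment(m, c("control", "E"), 3)
  fm <- fpm(ce, factors = rep(1, 6))
  mk <- function(fdrs, lfc = c(1, 1, 1, 0)) {
    r <- data.frame(gene = rownames(m), log2FC = lfc,
                    pvalue = fdrs, fdr = fdrs, tested = TRUE)
    attr(r, "contrast") <- "E"; attr(r, "control") <- "control"
    r
  }
  # gA: FDR_B too high -> excluded even though FPM passes
  degs <- consensusDeg(mk(c(0.01, 0.01, 0.01, 1)),
                       mk(c(0.20, 0.01, 0.01, 1)), fm, ce)
  expect_false("gA" %in% degs$gene)
  expect_true("gC" %in% degs$gene)
  # gB: both FDRs pass but group means stay under 5 FPM
  expect_false("gB" %in% degs$gene)
  # gC passes via its control-group mean of 6 FPM
  degs2 <- consensusDeg(mk(c(1, 1, 0.01, 1)), mk(c(1, 1, 0.01, 1)), fm, ce)
  expect_equal(degs2$gene, "gC")
  expect_equal(degs2$direction, "up")
  # contrast mismatch is an error
  other <- mk(c(1, 1, 1, 1)); attr(other, "contrast") <- "U"
  expect_error(consensusDeg(mk(rep(1, 4)), other, fm, ce), "contrast")
})

test_that("row clustering centers, scales and merges like the oracle", {
  set.seed(5)
  x <- matrix(runif(24, 1, 100), 4, 6,
              dimnames = list(sprintf("r%d", 1:4), NULL))
  cl <- clusterRows(x)
  expect_equal(unname(rowMeans(cl$scaled)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(cl$scaled, 1, sd)), rep(1, 4), tolerance = 1e-12)
  oracle <- bruteCompleteLinkage(dist(cl$scaled))
  expect_equal(unname(cl$hclust$height), oracle$heights, tolerance = 1e-12)
  expect_equal(hclustMerges(cl$hclust), oracle$merges)

  # identical rows merge first at height zero
  y <- rbind(a = c(1, 5, 9), b = c(1, 5, 9), c = c(9, 1, 2), d = c(0, 9, 1))
  cly <- clusterRows(y, logTransform = FALSE)
  expect_equal(cly$hclust$height[1], 0)
  expect_equal(hclustMerges(cly$hclust)[[1]], c(1, 2))

  expect_error(clusterRows(rbind(rep(1, 4), rep(2, 4))), "constant")
})
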