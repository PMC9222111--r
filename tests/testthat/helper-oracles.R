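# Independent brute-force oracles used to cross-check the analytical
# routines. These deliberately avoid the code paths they validate.

# two-sample KS statistic: largest ECDF gap over all observed points
bruteKS <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 1)))
}

# upper-tail hypergeometric p by exhaustive enumeration of all draws of
# size q from a domain of size N containing a term of size m
bruteHyperP <- function(N, m, q, k) {
  draws <- combn(N, q)
  term <- seq_len(m)
  hits <- apply(draws, 2L, function(d) sum(d %in% term))
  mean(hits >= k)
}

# exact two-sided paired Wilcoxon signed-rank p by enumerating all 2^n
# sign assignments (tie-free, non-zero differences assumed)
bruteWilcoxP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  p <- 2 * min(mean(W >= V), mean(W <= V))
  min(p, 1)
}

# complete-linkage agglomeration by direct search; returns the sequence of
# merge heights and the member sets merged at each step
bruteCompleteLinkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    merges <- c(merges, list(merged))
    clusters[[best[2]]] <- merged
    clusters[[best[3]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# member sets merged at each step of an hclust tree
hclustMerges <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1L)
  members <- function(k) if (k < 0) -k else sets[[k]]
  for (i in seq_len(n - 1L))
    sets[[i]] <- sort(c(members(hc$merge[i, 1]), members(hc$merge[i, 2])))
  sets
}

# published TMM recipe, written out longhand: doubly trimmed weighted mean
# of M-values against a reference column chosen by upper-quartile proximity
bruteTMM <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2L, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j] / lib[j]
    refv <- counts[, ref] / lib[ref]
    fin <- obs > 0 & refv > 0
    M <- log2(obs[fin] / refv[fin])
    A <- (log2(obs[fin]) + log2(refv[fin])) / 2
    w <- (lib[j] - counts[fin, j]) / (lib[j] * counts[fin, j]) +
      (lib[ref] - counts[fin, ref]) / (lib[ref] * counts[fin, ref])
    n <- length(M)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL &
      rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, 1)
  f / exp(mean(log(f)))
}

# small CountExperiment with a paired two-or-more-arm design
makeToyExperiment <- function(counts, treatmentsPerAnimal, nAnimals,
                              timepoint = "24h") {
  nArm <- length(treatmentsPerAnimal)
  stopifnot(ncol(counts) == nArm * nAnimals)
  sheet <- data.frame(
    sample = colnames(counts),
    animal = rep(sprintf("a%02d", seq_len(nAnimals)), each = nArm),
    treatment = rep(treatmentsPerAnimal, nAnimals),
    timepoint = timepoint, batch = timepoint)
  CountExperiment(counts, sheet)
}
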