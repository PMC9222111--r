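#' Hypergeometric over-representation analysis with the E statistic
#'
#' For every term of the annotation, tests whether the query gene set
#' contains more term members than expected under uniform sampling from the
#' effective domain: the raw p-value is the upper-tail hypergeometric
#' probability of observing at least \code{k} term genes in a query of size
#' \code{q} given term size \code{m} and domain size \code{N}. The effect
#' size is \code{E = (k/q) / (m/N)}. Benjamini-Hochberg adjustment is
#' applied across all tested terms. Query genes outside the domain are
#' dropped with a message; an empty query after filtering is an error.
#'
#' @param query character vector of gene ids.
#' @param annotation an \linkS4class{AnnotationSet}.
#' @return data.frame with columns \code{term}, \code{description},
#'   \code{k}, \code{q}, \code{m}, \code{N}, \code{E}, \code{pvalue},
#'   \code{p_adj}, ordered by increasing raw p.
#' @export
hypergeomEnrich <- function(query, annotation) {
    domain <- annotationDomain(annotation)
    query <- unique(as.character(query))
    outside <- setdiff(query, domain)
    if (length(outside))
        message(length(outside), " query gene(s) outside the domain dropped")
    query <- intersect(query, domain)
    if (length(query) == 0L)
        stop("query is empty after domain filtering")
    terms <- geneSets(annotation)
    q <- length(query)
    N <- length(domain)
    k <- vapply(terms, function(g) sum(g %in% query), 1L)
    m <- vapply(terms, length, 1L)
    pvalue <- phyper(k - 1L, m, N - m, q, lower.tail = FALSE)
    out <- data.frame(term = names(terms),
                      description = unname(termDescriptions(annotation)),
                      k = unname(k), q = q, m = unname(m), N = N,
                      E = unname((k / q) / (m / N)),
                      pvalue = unname(pvalue),
                      row.names = NULL, stringsAsFactors = FALSE)
    out$p_adj <- p.adjust(out$pvalue, method = "BH")
    out[order(out$pvalue, out$term), , drop = FALSE]
}

#' Filter enrichment rows on adjusted p and effect size
#'
#' Keeps rows with adjusted p-value at most \code{pMax} and enrichment E of
#' at least \code{eMin}; both boundaries are inclusive.
#'
#' @param rows output of \code{\link{hypergeomEnrich}}.
#' @param pMax adjusted-p threshold, default 0.001.
#' @param eMin minimal E, default 3.
#' @return the retained rows.
#' @export
filterEnriched <- function(rows, pMax = 0.001, eMin = 3) {
    rows[rows$p_adj <= pMax & rows$E >= eMin, , drop = FALSE]
}

#' Random-set calibration of the enrichment significance threshold
#'
#' Repeatedly draws uniform random gene sets (without replacement) from the
#' effective domain, runs the over-representation analysis on each, and
#' records the minimal adjusted p-value per run. The distribution of these
#' minima shows how often a given adjusted-p threshold is breached by
#' chance for query sets of each size, which is what justifies a stringent
#' threshold (0.001 rather than 0.05) for real queries.
#'
#' @param annotation an \linkS4class{AnnotationSet}.
#' @param setSizes integer vector of query-set sizes to calibrate
#'   (typically the observed intersection sizes).
#' @param nRuns number of simulation runs per size, default 100.
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame of class \code{"CalibrationResult"} with columns
#'   \code{size}, \code{run}, \code{min_adj_p}; attributes \code{nRuns},
#'   \code{seed}. See \code{\link{summarizeCalibration}}.
#' @export
calibrateThreshold <- function(annotation, setSizes, nRuns = 100, seed = 1L) {
    if (nRuns < 1L) stop("nRuns must be >= 1")
    domain <- annotationDomain(annotation)
    if (any(setSizes > length(domain)))
        stop("set sizes cannot exceed the domain size")
    if (length(annotation) == 0L)
        stop("annotation has no terms")
    set.seed(seed)
    rows <- vector("list", length(setSizes) * nRuns)
    i <- 0L
    for (size in setSizes) {
        for (run in seq_len(nRuns)) {
            g <- sample(domain, size)
            enr <- hypergeomEnrich(g, annotation)
            i <- i + 1L
            rows[[i]] <- data.frame(size = size, run = run,
                                    min_adj_p = min(enr$p_adj))
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "nRuns") <- nRuns
    attr(out, "seed") <- seed
    class(out) <- c("CalibrationResult", class(out))
    out
}

#' Fraction of calibration runs breaching candidate thresholds
#'
#' @param calibration output of \code{\link{calibrateThreshold}}.
#' @param thresholds candidate adjusted-p thresholds.
#' @return data.frame with columns \code{size}, \code{threshold},
#'   \code{fraction} (share of runs whose minimal adjusted p fell below the
#'   threshold).
#' @export
summarizeCalibration <- function(calibration,
                                 thresholds = c(0.05, 0.01, 0.001)) {
    out <- expand.grid(size = unique(calibration$size),
                       threshold = thresholds)
    out$fraction <- mapply(function(s, t)
        mean(calibration$min_adj_p[calibration$size == s] < t),
        out$size, out$threshold)
    out[order(out$size, -out$threshold), , drop = FALSE]
}
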