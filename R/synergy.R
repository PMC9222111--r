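#' Symmetric fold change of two FPM values
#'
#' The per-replicate ratio \code{(treated + c) / (control + c)} mapped onto
#' the symmetric scale: ratios >= 1 are returned as-is, ratios < 1 as
#' \code{-1/ratio}, so +r means r-fold up-regulation and -r means r-fold
#' down-regulation and no value falls inside (-1, 1). A ratio of exactly 1
#' maps to +1. The pseudocount guards against zero denominators in single
#' replicates.
#'
#' @param fpmTreated,fpmControl non-negative FPM values (vectorized).
#' @param pseudocount positive value added to numerator and denominator;
#'   default 0.5.
#' @return symmetric fold change(s).
#' @examples
#' symmetricFC(10, 5, pseudocount = 1e-9)  #  2
#' symmetricFC(5, 10, pseudocount = 1e-9)  # -2
#' @export
symmetricFC <- function(fpmTreated, fpmControl, pseudocount = 0.5) {
    if (pseudocount <= 0) stop("pseudocount must be positive")
    if (any(fpmTreated < 0) || any(fpmControl < 0))
        stop("FPM values must be non-negative")
    r <- (fpmTreated + pseudocount) / (fpmControl + pseudocount)
    ifelse(r >= 1, r, -1 / r)
}

#' Additivity expectation for a combined treatment
#'
#' The symmetric fold change a combined treatment should show if the two
#' single-treatment effects simply add:
#' \code{fc1 + fc2 - 1} when both are positive, \code{fc1 + fc2 + 1} when at
#' least one is negative. A neutral partner (+1) leaves the expectation
#' unchanged; the operation is symmetric in its arguments. Note the formula
#' can produce values inside (-1, 1) for opposite-sign inputs (e.g.
#' \code{expectedFC(1, -2) == 0}); such values are returned as printed and
#' flagged downstream rather than remapped.
#'
#' @param fc1,fc2 symmetric fold changes (|x| >= 1), vectorized.
#' @return the expected combined symmetric fold change.
#' @examples
#' expectedFC(2, 3)    #  4
#' expectedFC(-2, -2)  # -3
#' expectedFC(-2, 3)   #  2
#' @export
expectedFC <- function(fc1, fc2) {
    if (any(abs(fc1) < 1) || any(abs(fc2) < 1))
        stop("inputs must be valid symmetric fold changes (|x| >= 1)")
    ifelse(fc1 > 0 & fc2 > 0, fc1 + fc2 - 1, fc1 + fc2 + 1)
}

#' Paired test for quantitative synergy
#'
#' Two-sided paired t-test of the per-replicate measured combined fold
#' changes against the per-replicate additivity expectations. When p falls
#' below \code{alpha} the response is classified as stimulatory
#' (mean measured above mean expected) or inhibitory (mean measured below
#' mean expected, or measured and expected means of different signs — the
#' sign disagreement forces the inhibitory call). Identical vectors (all
#' differences zero) are declared p = 1 with no call; a perfectly constant
#' non-zero shift is declared p = 0.
#'
#' @param measured,expected per-replicate symmetric FC vectors of equal
#'   length; pairs with NA in either member are dropped.
#' @param alpha significance level, default 0.05.
#' @return list with \code{p}, \code{direction} (\code{"stimulatory"},
#'   \code{"inhibitory"}, \code{"none"} or \code{"untestable"}),
#'   \code{meanMeasured}, \code{meanExpected}, \code{n}.
#' @export
quantSynergyTest <- function(measured, expected, alpha = 0.05) {
    stopifnot(length(measured) == length(expected))
    ok <- !is.na(measured) & !is.na(expected)
    m <- measured[ok]; e <- expected[ok]
    n <- length(m)
    if (n < 3L)
        return(list(p = NA_real_, direction = "untestable",
                    meanMeasured = NA_real_, meanExpected = NA_real_, n = n))
    d <- m - e
    if (all(d == 0)) {
        p <- 1
    } else if (sd(d) == 0) {
        p <- 0
    } else {
        p <- t.test(m, e, paired = TRUE)$p.value
    }
    mm <- mean(m); me <- mean(e)
    direction <- "none"
    if (p < alpha) {
        direction <- if (sign(mm) != sign(me)) "inhibitory"
                     else if (mm > me) "stimulatory" else "inhibitory"
    }
    list(p = p, direction = direction, meanMeasured = mm, meanExpected = me,
         n = n)
}

#' Exclusive intersections of DEG sets
#'
#' Partitions the union of the supplied gene sets into the exclusive cells
#' of their Venn diagram (one cell per observed membership signature, empty
#' cells omitted), the tabular equivalent of an UpSet plot. When
#' \code{algebra} is supplied each cell additionally receives a qualitative
#' synergy label via \code{\link{classifyQualitative}}.
#'
#' @param sets named list of character vectors (or data.frames with a
#'   \code{gene} column, e.g. \code{\link{consensusDeg}} output).
#' @param algebra optional named list decomposing combined condition labels
#'   into their single constituents.
#' @return data.frame with columns \code{id}, \code{signature} (labels
#'   joined by \code{"&"}), \code{degree}, \code{n_genes}, \code{genes}
#'   (ids joined by \code{";"}) and, when algebra is given, \code{label};
#'   attribute \code{membership} holds the gene lists.
#' @export
intersectDegSets <- function(sets, algebra = NULL) {
    if (length(sets) < 2L) stop("need at least 2 sets")
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
        stop("sets must have unique labels")
    sets <- lapply(sets, function(s) {
        if (is.data.frame(s)) unique(as.character(s$gene))
        else unique(as.character(s))
    })
    universe <- unique(unlist(sets, use.names = FALSE))
    memb <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
    if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L)
    sig <- apply(memb, 1L, function(row)
        paste(names(sets)[row], collapse = "&"))
    groups <- split(universe, sig)
    # partition check: every input gene lands in exactly one cell
    stopifnot(sum(lengths(groups)) == length(universe))
    ord <- order(-lengths(groups), names(groups))
    groups <- groups[ord]
    out <- data.frame(
        id = sprintf("i%d", seq_along(groups)),
        signature = names(groups),
        degree = vapply(strsplit(names(groups), "&", fixed = TRUE),
                        length, 1L),
        n_genes = unname(lengths(groups)),
        genes = vapply(groups, paste, "", collapse = ";"),
        row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(algebra))
        out$label <- vapply(strsplit(out$signature, "&", fixed = TRUE),
                            classifyQualitative, "", algebra = algebra,
                            allSets = names(sets))
    attr(out, "membership") <- groups
    out
}

#' Qualitative synergy label of a membership signature
#'
#' Given the set of contrasts under which a gene (or intersection cell) is
#' regulated, classifies the pattern: \code{"stimulation"} when it is
#' regulated under a combined condition but under none of that condition's
#' single constituents; \code{"inhibition"} when it is regulated under a
#' single condition but not under a compared combined condition containing
#' it (the added stimulus blocks the effect); \code{"none"} otherwise.
#' Stimulation takes precedence when both patterns apply.
#'
#' @param signature character vector of contrast labels containing the gene.
#' @param algebra named list decomposing combined labels into singles, e.g.
#'   \code{list(EU = c("E", "U"))}.
#' @param allSets labels of all compared DEG sets; a constituent or combined
#'   condition that was not compared cannot support a call.
#' @return one of \code{"stimulation"}, \code{"inhibition"}, \code{"none"}.
#' @export
classifyQualitative <- function(signature, algebra, allSets) {
    known <- union(allSets, union(names(algebra), unlist(algebra)))
    bad <- setdiff(signature, known)
    if (length(bad))
        stop("unknown contrast label(s): ", paste(bad, collapse = ", "))
    combos <- intersect(names(algebra), allSets)
    for (c in intersect(signature, combos)) {
        parts <- algebra[[c]]
        if (all(parts %in% allSets) && !any(parts %in% signature))
            return("stimulation")
    }
    singles <- setdiff(signature, names(algebra))
    for (s in singles) {
        for (c in combos) {
            if (s %in% algebra[[c]] && !(c %in% signature))
                return("inhibition")
        }
    }
    "none"
}

#' Distribution-shift test between single and combined fold changes
#'
#' Two-sample Kolmogorov-Smirnov test comparing the log2 fold changes of one
#' gene set under a single condition versus a combined condition, with down-
#' and up-regulated genes tested separately. The exact null distribution is
#' used when both stratum sizes are at most 25, the asymptotic one
#' otherwise. Strata with fewer than 5 genes are skipped with a message.
#'
#' @param fcSingle,fcCombined parallel numeric vectors of log2 fold changes
#'   for the same genes under the two contrasts.
#' @param splitBySign test down- and up-regulated genes separately
#'   (default TRUE); the strata are defined by \code{direction} or, when
#'   absent, by the sign of \code{fcSingle}.
#' @param direction optional per-gene \code{"up"}/\code{"down"} labels.
#' @return data.frame with columns \code{sign}, \code{n}, \code{D}, \code{p}.
#' @export
ksShiftTest <- function(fcSingle, fcCombined, splitBySign = TRUE,
                        direction = NULL) {
    if (length(fcSingle) == 0L || length(fcCombined) == 0L)
        stop("empty input")
    if (splitBySign) {
        # sign-stratified use compares the same genes under two contrasts
        stopifnot(length(fcSingle) == length(fcCombined))
        if (is.null(direction))
            direction <- ifelse(fcSingle >= 0, "up", "down")
        strata <- split(seq_along(fcSingle), direction)
        pairs <- lapply(strata, function(idx)
            list(x = fcSingle[idx], y = fcCombined[idx]))
    } else {
        pairs <- list(all = list(x = fcSingle, y = fcCombined))
    }
    rows <- lapply(names(pairs), function(s) {
        x <- pairs[[s]]$x; y <- pairs[[s]]$y
        if (length(x) < 5L || length(y) < 5L) {
            message("stratum '", s, "' skipped (fewer than 5 genes)")
            return(NULL)
        }
        exact <- length(x) <= 25L && length(y) <= 25L
        kt <- suppressWarnings(ks.test(x, y, exact = exact))
        data.frame(sign = s, n = length(x), D = unname(kt$statistic),
                   p = kt$p.value, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# per-gene per-animal FPM for one condition, columns ordered by animal
.fpmByAnimal <- function(fpmMat, experiment, condition, animals) {
    vals <- fpmValues(fpmMat)
    sel <- which(treatments(experiment) == condition)
    a <- animalIds(experiment)[sel]
    out <- matrix(NA_real_, nrow(vals), length(animals),
                  dimnames = list(rownames(vals), animals))
    hit <- a %in% animals
    out[, a[hit]] <- vals[, sel[hit], drop = FALSE]
    out
}

#' Per-gene measured and expected fold changes with the paired synergy test
#'
#' For every gene, computes per-replicate (per-animal) symmetric fold
#' changes of each single condition and of the combined condition against
#' the same animal's control sample, derives the per-replicate additivity
#' expectation, and applies \code{\link{quantSynergyTest}}. Animals missing
#' any required condition are dropped listwise. Expectations falling inside
#' (-1, 1) — possible for opposite-sign singles — are kept as computed and
#' flagged. Raw p-values carry the synergy calls; a Benjamini-Hochberg
#' column is provided alongside as a safety rail.
#'
#' @param fpmMat \linkS4class{FpmMatrix} for the experiment.
#' @param experiment a \linkS4class{CountExperiment} (single timepoint).
#' @param combined label of the combined condition.
#' @param singles labels of its single constituents.
#' @param genes genes to test (e.g. the union of the relevant DEG sets);
#'   default all genes in \code{fpmMat}.
#' @param control control label, default \code{"control"}.
#' @param pseudocount passed to \code{\link{symmetricFC}}.
#' @param alpha significance level for the direction call.
#' @return data.frame with one row per gene: \code{gene}, \code{n},
#'   \code{meanMeasured}, \code{meanExpected}, \code{p}, \code{p_adj},
#'   \code{direction}, \code{expected_out_of_range}, and the per-replicate
#'   vectors serialized as \code{";"}-joined strings (\code{measured},
#'   \code{expected}).
#' @export
buildSynergyTable <- function(fpmMat, experiment, combined, singles,
                              genes = NULL, control = "control",
                              pseudocount = 0.5, alpha = 0.05) {
    if (is.null(genes)) genes <- rownames(fpmValues(fpmMat))
    animals <- unique(animalIds(experiment))
    ctl <- .fpmByAnimal(fpmMat, experiment, control, animals)[genes, ,
                                                              drop = FALSE]
    comb <- .fpmByAnimal(fpmMat, experiment, combined, animals)[genes, ,
                                                                drop = FALSE]
    sing <- lapply(singles, function(s)
        .fpmByAnimal(fpmMat, experiment, s, animals)[genes, , drop = FALSE])
    measured <- symmetricFC(comb, ctl, pseudocount)
    singleFc <- lapply(sing, function(x) symmetricFC(x, ctl, pseudocount))
    # reduce left over constituents with the raw formula: intermediate
    # values may leave the symmetric-FC codomain and are flagged, not fixed
    expected <- Reduce(function(a, b)
        ifelse(a > 0 & b > 0, a + b - 1, a + b + 1),
        singleFc[-1], singleFc[[1]])
    rows <- lapply(seq_along(genes), function(i) {
        res <- quantSynergyTest(measured[i, ], expected[i, ], alpha = alpha)
        data.frame(gene = genes[i], n = res$n,
                   meanMeasured = res$meanMeasured,
                   meanExpected = res$meanExpected, p = res$p,
                   direction = res$direction,
                   expected_out_of_range =
                       any(abs(expected[i, ]) < 1, na.rm = TRUE),
                   measured = paste(signif(measured[i, ], 6),
                                    collapse = ";"),
                   expected = paste(signif(expected[i, ], 6),
                                    collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p, method = "BH")
    out <- out[, c("gene", "n", "meanMeasured", "meanExpected", "p",
                   "p_adj", "direction", "expected_out_of_range",
                   "measured", "expected")]
    attr(out, "combined") <- combined
    attr(out, "singles") <- singles
    out
}

#' Targeted pairwise screen for amplified combined responses
#'
#' Paired t-tests on normalized FPM values compare each single condition
#' against the combined one, per timepoint. A gene passes when, for at
#' least one timepoint, every single-vs-combined comparison rejects at
#' \code{alpha}. Only genes that are consensus DEG for at least one of the
#' compared contrasts enter the screen, and genes belonging to clear
#' qualitative-synergism intersections are excluded. Direction is the sign
#' of the combined-vs-control mean FPM change at the first passing
#' timepoint.
#'
#' @param fpmList named list (one element per timepoint) of
#'   \linkS4class{FpmMatrix} objects.
#' @param experiments named list of matching \linkS4class{CountExperiment}
#'   objects.
#' @param combined label of the combined condition.
#' @param singles labels of its single constituents.
#' @param eligibleGenes genes eligible for the screen (consensus DEG of the
#'   compared contrasts).
#' @param excludeGenes genes to drop (clear qualitative synergism).
#' @param control control label.
#' @param alpha per-test significance level, default 0.05.
#' @return data.frame with columns \code{gene}, \code{timepoint} (first
#'   passing), \code{direction}, and the per-single p-values at that
#'   timepoint (\code{p_<single>}).
#' @export
targetedPairwiseScreen <- function(fpmList, experiments, combined, singles,
                                   eligibleGenes,
                                   excludeGenes = character(),
                                   control = "control", alpha = 0.05) {
    stopifnot(identical(names(fpmList), names(experiments)))
    genes <- setdiff(eligibleGenes, excludeGenes)
    if (length(genes) == 0L)
        return(data.frame(gene = character(), timepoint = character(),
                          direction = character(), stringsAsFactors = FALSE))
    hits <- list()
    for (tp in names(fpmList)) {
        ex <- experiments[[tp]]
        fm <- fpmList[[tp]]
        present <- intersect(genes, rownames(fpmValues(fm)))
        if (length(present) == 0L) next
        missing <- setdiff(c(combined, singles, control),
                           unique(treatments(ex)))
        if (length(missing))
            stop("condition(s) absent at timepoint ", tp, ": ",
                 paste(missing, collapse = ", "))
        animals <- unique(animalIds(ex))
        comb <- .fpmByAnimal(fm, ex, combined, animals)[present, ,
                                                        drop = FALSE]
        ctl <- .fpmByAnimal(fm, ex, control, animals)[present, ,
                                                      drop = FALSE]
        pvals <- sapply(singles, function(s) {
            sv <- .fpmByAnimal(fm, ex, s, animals)[present, , drop = FALSE]
            vapply(seq_len(nrow(sv)), function(i) {
                ok <- !is.na(sv[i, ]) & !is.na(comb[i, ])
                if (sum(ok) < 3L) return(NA_real_)
                d <- comb[i, ok] - sv[i, ok]
                if (all(d == 0)) return(1)
                if (sd(d) == 0) return(0)
                t.test(comb[i, ok], sv[i, ok], paired = TRUE)$p.value
            }, 1)
        })
        pvals <- matrix(pvals, nrow = length(present),
                        dimnames = list(present, singles))
        pass <- rowSums(pvals < alpha, na.rm = TRUE) == length(singles) &
            !apply(is.na(pvals), 1L, any)
        if (any(pass)) {
            dirn <- rowMeans(comb - ctl, na.rm = TRUE)[pass]
            tab <- data.frame(gene = present[pass], timepoint = tp,
                              direction = ifelse(dirn >= 0, "up", "down"),
                              stringsAsFactors = FALSE)
            for (s in singles)
                tab[[paste0("p_", s)]] <- pvals[pass, s]
            hits[[tp]] <- tab
        }
    }
    if (length(hits) == 0L)
        return(data.frame(gene = character(), timepoint = character(),
                          direction = character(), stringsAsFactors = FALSE))
    all <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
    # keep the first passing timepoint per gene
    all[!duplicated(all$gene), , drop = FALSE]
}
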