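#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors (30% trimming on M-values, 5% on
#' A-values, reference column chosen by upper-quartile proximity to the mean
#' upper quartile), renormalized so their geometric mean is 1. Composition
#' shifts (one gene absorbing a large share of a column) yield factors
#' departing from 1, whereas pure library-size scaling does not.
#'
#' @param experiment a \linkS4class{CountExperiment} (or count matrix).
#' @return named numeric vector of positive per-sample factors.
#' @export
tmmFactors <- function(experiment) {
    m <- if (is(experiment, "CountExperiment")) counts(experiment)
         else as.matrix(experiment)
    if (ncol(m) < 2L) stop("TMM needs at least 2 samples")
    zero <- colSums(m) == 0
    if (any(zero))
        stop("sample(s) with zero total count: ",
             paste(colnames(m)[zero], collapse = ", "))
    f <- edgeR::calcNormFactors(m, method = "TMM")
    names(f) <- colnames(m)
    f
}

#' Fragments per million
#'
#' \code{FPM[g, s] = count[g, s] / (librarySize[s] * factor[s]) * 1e6} with
#' library sizes taken as column sums of the raw counts.
#'
#' @param experiment a \linkS4class{CountExperiment}.
#' @param factors per-sample normalization factors; defaults to
#'   \code{\link{tmmFactors}}.
#' @return An \linkS4class{FpmMatrix}.
#' @export
fpm <- function(experiment, factors = NULL) {
    m <- counts(experiment)
    if (is.null(factors)) factors <- tmmFactors(experiment)
    if (any(factors <= 0)) stop("normalization factors must be positive")
    libSize <- colSums(m)
    vals <- t(t(m) / (libSize * factors)) * 1e6
    new("FpmMatrix", fpm = vals,
        libSizes = setNames(as.numeric(libSize), colnames(m)),
        normFactors = setNames(as.numeric(factors), colnames(m)))
}

#' Expression filter for the statistical analysis
#'
#' Keeps genes whose counts-per-million exceed the threshold implied by 10
#' counts in the median library, in at least as many samples as the smallest
#' treatment group. This is the explicit form of the count-based
#' independent filter applied before testing.
#'
#' @param experiment a \linkS4class{CountExperiment}.
#' @param minCount count level (in the median library) defining the CPM
#'   threshold; default 10.
#' @return character vector of gene ids passing the filter.
#' @export
filterExpressed <- function(experiment, minCount = 10) {
    m <- counts(experiment)
    groups <- paste(treatments(experiment), timepoints(experiment))
    libSize <- colSums(m)
    cutoff <- minCount / median(libSize) * 1e6
    cpm <- t(t(m) / libSize) * 1e6
    minGroup <- min(table(groups))
    rownames(m)[rowSums(cpm >= cutoff) >= minGroup]
}

.checkContrast <- function(experiment, condition, control) {
    trt <- treatments(experiment)
    if (!condition %in% trt) stop("condition '", condition, "' not present")
    if (!control %in% trt) stop("control '", control, "' not present")
    byAnimal <- table(animalIds(experiment)[trt %in% c(condition, control)],
                      trt[trt %in% c(condition, control)])
    complete <- sum(rowSums(byAnimal > 0) == 2L)
    if (complete < 3L)
        stop("need >= 3 animals with both '", condition, "' and '",
             control, "'")
    invisible(TRUE)
}

#' Blocked negative-binomial differential expression
#'
#' Fits a per-gene NB log-linear model with animal (block) and treatment
#' terms on all samples of the experiment and tests the coefficient of
#' \code{condition} against \code{control}. Two independent procedures are
#' available: \code{"edgeR"} (TMM offsets, Cox-Reid tagwise dispersion,
#' likelihood-ratio test) and \code{"DESeq2"} (median-of-ratios size
#' factors, trended dispersion shrinkage, Wald test). Benjamini-Hochberg
#' FDR is computed over the tested genes. Genes outside \code{testedGenes}
#' (or removed by DESeq2's independent filtering / outlier handling) are
#' returned with \code{tested = FALSE} and NA statistics.
#'
#' @param experiment a \linkS4class{CountExperiment}; should contain a
#'   single timepoint (analyses per timepoint are run separately).
#' @param condition treatment label to test.
#' @param control reference label, default \code{"control"}.
#' @param method \code{"edgeR"} or \code{"DESeq2"}.
#' @param testedGenes genes entering the statistical analysis; defaults to
#'   \code{\link{filterExpressed}}.
#' @return data.frame with columns \code{gene}, \code{log2FC}, \code{pvalue},
#'   \code{fdr}, \code{tested}; attributes \code{contrast}, \code{control},
#'   \code{method}.
#' @export
deTest <- function(experiment, condition, control = "control",
                   method = c("edgeR", "DESeq2"), testedGenes = NULL) {
    method <- match.arg(method)
    .checkContrast(experiment, condition, control)
    if (length(unique(timepoints(experiment))) > 1L)
        stop("experiment spans multiple timepoints; analyze them separately")
    if (is.null(testedGenes)) testedGenes <- filterExpressed(experiment)
    m <- counts(experiment)
    keep <- rownames(m) %in% testedGenes
    sub <- m[keep, , drop = FALSE]
    animal <- factor(animalIds(experiment))
    treatment <- relevel(factor(treatments(experiment)), ref = control)
    out <- data.frame(gene = rownames(m), log2FC = NA_real_,
                      pvalue = NA_real_, fdr = NA_real_, tested = FALSE,
                      stringsAsFactors = FALSE)

    if (method == "edgeR") {
        design <- model.matrix(~ animal + treatment)
        y <- edgeR::DGEList(counts = sub)
        y <- edgeR::calcNormFactors(y, method = "TMM")
        y <- edgeR::estimateDisp(y, design)
        fit <- edgeR::glmFit(y, design)
        lrt <- edgeR::glmLRT(fit,
            coef = paste0("treatment", condition))
        tab <- lrt$table
        out$log2FC[keep] <- tab$logFC
        out$pvalue[keep] <- tab$PValue
        out$fdr[keep] <- p.adjust(tab$PValue, method = "BH")
        out$tested[keep] <- TRUE
    } else {
        cd <- data.frame(animal = animal, treatment = treatment)
        dds <- DESeq2::DESeqDataSetFromMatrix(sub, colData = cd,
            design = ~ animal + treatment)
        dds <- DESeq2::DESeq(dds, quiet = TRUE)
        res <- DESeq2::results(dds,
            contrast = c("treatment", condition, control), alpha = 0.05)
        out$log2FC[keep] <- res$log2FoldChange
        out$pvalue[keep] <- res$pvalue
        out$fdr[keep] <- res$padj
        # NA padj = removed by independent filtering or outlier flagging
        out$tested[keep] <- !is.na(res$padj)
    }
    attr(out, "contrast") <- condition
    attr(out, "control") <- control
    attr(out, "method") <- method
    out
}

# mean FPM over the samples of one treatment group
.groupMeanFpm <- function(fpmMat, experiment, condition) {
    vals <- fpmValues(fpmMat)
    sel <- treatments(experiment) == condition
    if (!any(sel)) stop("no samples for condition '", condition, "'")
    rowMeans(vals[, sel, drop = FALSE])
}

#' Consensus differentially expressed genes
#'
#' A gene is a consensus DEG for a contrast when it is tested by both
#' procedures, has FDR below \code{fdrMax} in both, and its mean FPM is at
#' least \code{fpmMin} in at least one of the two contrast groups. The
#' reported direction is the sign of the method-A (first result) log2
#' fold change.
#'
#' @param resA,resB \code{\link{deTest}} results for the same contrast from
#'   the two methods.
#' @param fpmMat \linkS4class{FpmMatrix} over the same samples.
#' @param experiment the \linkS4class{CountExperiment} the results came from.
#' @param fdrMax FDR threshold, default 0.05.
#' @param fpmMin group-mean FPM threshold, default 5.
#' @param full if TRUE, return all tested genes with a \code{consensus}
#'   flag column instead of only the members.
#' @return data.frame with columns \code{gene}, \code{direction}
#'   (\code{"up"}/\code{"down"}), \code{log2FC_A}, \code{fdr_A},
#'   \code{log2FC_B}, \code{fdr_B}, \code{meanFpmTreated},
#'   \code{meanFpmControl} (and \code{consensus} when \code{full});
#'   attribute \code{contrast}.
#' @export
consensusDeg <- function(resA, resB, fpmMat, experiment,
                         fdrMax = 0.05, fpmMin = 5, full = FALSE) {
    if (!identical(attr(resA, "contrast"), attr(resB, "contrast")) ||
        !identical(attr(resA, "control"), attr(resB, "control")))
        stop("results come from different contrasts")
    condition <- attr(resA, "contrast")
    control <- attr(resA, "control")
    stopifnot(identical(resA$gene, resB$gene))
    meanTrt <- .groupMeanFpm(fpmMat, experiment, condition)[resA$gene]
    meanCtl <- .groupMeanFpm(fpmMat, experiment, control)[resA$gene]
    tab <- data.frame(gene = resA$gene,
        direction = ifelse(resA$log2FC >= 0, "up", "down"),
        log2FC_A = resA$log2FC, fdr_A = resA$fdr,
        log2FC_B = resB$log2FC, fdr_B = resB$fdr,
        meanFpmTreated = meanTrt, meanFpmControl = meanCtl,
        row.names = NULL, stringsAsFactors = FALSE)
    member <- resA$tested & resB$tested &
        !is.na(resA$fdr) & resA$fdr < fdrMax &
        !is.na(resB$fdr) & resB$fdr < fdrMax &
        pmax(meanTrt, meanCtl) >= fpmMin
    if (full) {
        tab$consensus <- member
        tab <- tab[resA$tested | resB$tested, , drop = FALSE]
    } else {
        tab <- tab[member, , drop = FALSE]
    }
    attr(tab, "contrast") <- condition
    attr(tab, "control") <- control
    tab
}

#' Cluster expression rows for heatmap display
#'
#' Rows are log-transformed (\code{log2(x + 1)}), centered and scaled
#' (per-row mean 0, SD 1), then clustered by complete-linkage agglomeration
#' on Euclidean distances. Constant rows (zero SD) are dropped with a
#' message; an all-constant input is an error.
#'
#' @param mat an \linkS4class{FpmMatrix} or numeric matrix (genes x samples).
#' @param logTransform apply \code{log2(x + 1)} first (default TRUE).
#' @return list with the \code{hclust} object, the row \code{order}, and
#'   the \code{scaled} matrix that was clustered.
#' @export
clusterRows <- function(mat, logTransform = TRUE) {
    x <- if (is(mat, "FpmMatrix")) fpmValues(mat) else as.matrix(mat)
    if (nrow(x) < 2L) stop("need at least 2 rows to cluster")
    if (logTransform) x <- log2(x + 1)
    sds <- apply(x, 1L, sd)
    if (all(sds == 0)) stop("all rows are constant")
    if (any(sds == 0)) {
        message(sum(sds == 0), " constant row(s) dropped before clustering")
        x <- x[sds > 0, , drop = FALSE]
    }
    scaled <- t(scale(t(x)))
    hc <- hclust(dist(scaled, method = "euclidean"), method = "complete")
    list(hclust = hc, order = hc$order, scaled = scaled)
}
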