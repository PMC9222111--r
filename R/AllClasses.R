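#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' CountExperiment: integer counts plus the blocked factorial sample sheet
#'
#' A \linkS4class{SummarizedExperiment} carrying one \code{"counts"} assay of
#' non-negative integers and a sample sheet (\code{colData}) describing the
#' blocked factorial design: one column each for \code{animal} (the block),
#' \code{treatment} (condition label, e.g. \code{"control"}, \code{"E"},
#' \code{"EU"}), \code{timepoint} and \code{batch}.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

.validCountExperiment <- function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (anyNA(m))
            msg <- c(msg, "counts contain NA")
        else {
            if (any(m < 0))
                msg <- c(msg, "counts must be non-negative")
            if (any(m != round(m)))
                msg <- c(msg, "counts must be integers")
        }
    }
    needed <- c("animal", "treatment", "timepoint", "batch")
    missing <- setdiff(needed, colnames(colData(object)))
    if (length(missing))
        msg <- c(msg, paste0("sample sheet lacks column(s): ",
                             paste(missing, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (is.null(msg)) TRUE else msg
}
setValidity("CountExperiment", .validCountExperiment)

#' Construct a CountExperiment
#'
#' @param counts gene x sample matrix of non-negative integer counts with
#'   gene ids as rownames and sample ids as colnames.
#' @param sampleSheet data.frame with one row per sample and columns
#'   \code{sample} (or rownames), \code{animal}, \code{treatment},
#'   \code{timepoint}, \code{batch}. Order may differ from the matrix; rows
#'   are matched by sample id and every matrix sample must be present
#'   exactly once.
#'
#' @return A validated \code{CountExperiment}.
#' @examples
#' m <- matrix(0:3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' sheet <- data.frame(sample = c("s1", "s2"), animal = c("a1", "a1"),
#'                     treatment = c("control", "E"),
#'                     timepoint = "24h", batch = "b1")
#' CountExperiment(m, sheet)
#' @export
CountExperiment <- function(counts, sampleSheet) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene ids as rownames and sample ids as colnames")
    sampleSheet <- as.data.frame(sampleSheet)
    ids <- if ("sample" %in% colnames(sampleSheet)) {
        as.character(sampleSheet$sample)
    } else rownames(sampleSheet)
    if (anyDuplicated(ids))
        stop("duplicate sample ids in sample sheet: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    absent <- setdiff(colnames(counts), ids)
    if (length(absent))
        stop("sample sheet is missing matrix sample(s): ",
             paste(absent, collapse = ", "))
    extra <- setdiff(ids, colnames(counts))
    if (length(extra))
        stop("sample sheet lists unknown sample(s): ",
             paste(extra, collapse = ", "))
    sampleSheet <- sampleSheet[match(colnames(counts), ids), , drop = FALSE]
    cd <- DataFrame(
        animal = as.character(sampleSheet$animal),
        treatment = as.character(sampleSheet$treatment),
        timepoint = as.character(sampleSheet$timepoint),
        batch = as.character(sampleSheet$batch),
        row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("CountExperiment", se)
}

#' FpmMatrix: normalized expression in fragments per million
#'
#' Expression values normalized to fragments per million (FPM):
#' \code{count / (librarySize * normFactor) * 1e6}. Carries the per-sample
#' library sizes and normalization factors used.
#'
#' @slot fpm gene x sample numeric matrix, all values >= 0.
#' @slot libSizes per-sample library sizes (column sums of raw counts).
#' @slot normFactors per-sample normalization factors (e.g. TMM).
#' @export
setClass("FpmMatrix",
    representation(fpm = "matrix", libSizes = "numeric",
                   normFactors = "numeric"))

setValidity("FpmMatrix", function(object) {
    msg <- NULL
    if (any(object@fpm < 0)) msg <- c(msg, "FPM values must be >= 0")
    if (length(object@libSizes) != ncol(object@fpm))
        msg <- c(msg, "libSizes length != number of samples")
    if (length(object@normFactors) != ncol(object@fpm))
        msg <- c(msg, "normFactors length != number of samples")
    if (any(object@normFactors <= 0)) msg <- c(msg, "normFactors must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' AnnotationSet: gene-set annotation over an effective domain
#'
#' Named gene sets (terms) over an effective domain of annotatable gene ids.
#' Every term is a non-empty subset of the domain. The domain is the universe
#' used as the "effective domain size" in enrichment statistics.
#'
#' @slot terms named list of character vectors (gene ids per term).
#' @slot descriptions named character vector, parallel to \code{terms}.
#' @slot domain character vector of all annotatable gene ids.
#' @export
setClass("AnnotationSet",
    representation(terms = "list", descriptions = "character",
                   domain = "character"))

setValidity("AnnotationSet", function(object) {
    msg <- NULL
    if (length(object@terms) &&
        (is.null(names(object@terms)) || anyDuplicated(names(object@terms))))
        msg <- c(msg, "terms must be uniquely named")
    if (length(object@terms) != length(object@descriptions))
        msg <- c(msg, "descriptions length != number of terms")
    if (anyDuplicated(object@domain))
        msg <- c(msg, "duplicate gene ids in domain")
    if (any(vapply(object@terms, length, 1L) == 0L))
        msg <- c(msg, "empty term(s) present")
    stray <- vapply(object@terms,
                    function(g) length(setdiff(g, object@domain)) > 0L, TRUE)
    if (any(stray))
        msg <- c(msg, paste0("term(s) with genes outside domain: ",
                             paste(names(object@terms)[stray], collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Construct an AnnotationSet
#'
#' @param terms named list of character vectors of gene ids.
#' @param domain character vector of all annotatable gene ids.
#' @param descriptions optional named character vector of term descriptions.
#' @return An \code{AnnotationSet}.
#' @export
AnnotationSet <- function(terms, domain, descriptions = NULL) {
    terms <- lapply(terms, function(g) unique(as.character(g)))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(terms)), names(terms))
    new("AnnotationSet", terms = terms,
        descriptions = descriptions[names(terms)],
        domain = unique(as.character(domain)))
}
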