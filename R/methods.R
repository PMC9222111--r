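#' @importFrom BiocGenerics counts
NULL

#' Accessors for CountExperiment, FpmMatrix and AnnotationSet
#'
#' @param object,x a \code{CountExperiment}, \code{FpmMatrix} or
#'   \code{AnnotationSet}.
#' @return \code{counts} returns the integer count matrix; \code{sampleSheet}
#'   the sample sheet as a data.frame; \code{animalIds}, \code{treatments}
#'   and \code{timepoints} the per-sample design columns; \code{fpmValues}
#'   the FPM matrix; \code{libSizes} and \code{normFactors} the per-sample
#'   scaling quantities; \code{geneSets}, \code{termDescriptions} and
#'   \code{annotationDomain} the annotation content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("counts", "CountExperiment", function(object)
    assay(object, "counts"))

#' @rdname accessors
#' @export
sampleSheet <- function(object) {
    stopifnot(is(object, "CountExperiment"))
    cd <- colData(object)
    data.frame(sample = rownames(cd), animal = cd$animal,
               treatment = cd$treatment, timepoint = cd$timepoint,
               batch = cd$batch, row.names = NULL)
}

#' @rdname accessors
#' @export
animalIds <- function(object) colData(object)$animal

#' @rdname accessors
#' @export
treatments <- function(object) colData(object)$treatment

#' @rdname accessors
#' @export
timepoints <- function(object) colData(object)$timepoint

#' @rdname accessors
#' @export
fpmValues <- function(object) {
    stopifnot(is(object, "FpmMatrix"))
    object@fpm
}

#' @rdname accessors
#' @export
libSizes <- function(object) {
    stopifnot(is(object, "FpmMatrix"))
    object@libSizes
}

#' @rdname accessors
#' @export
normFactors <- function(object) {
    stopifnot(is(object, "FpmMatrix"))
    object@normFactors
}

#' @rdname accessors
#' @export
geneSets <- function(object) {
    stopifnot(is(object, "AnnotationSet"))
    object@terms
}

#' @rdname accessors
#' @export
termDescriptions <- function(object) {
    stopifnot(is(object, "AnnotationSet"))
    object@descriptions
}

#' @rdname accessors
#' @export
annotationDomain <- function(object) {
    stopifnot(is(object, "AnnotationSet"))
    object@domain
}

#' @rdname accessors
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@terms))

setMethod("show", "CountExperiment", function(object) {
    cat("CountExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  treatments:",
        paste(sort(unique(treatments(object))), collapse = ", "), "\n")
    cat("  animals:", length(unique(animalIds(object))),
        " timepoints:", paste(sort(unique(timepoints(object))),
                              collapse = ", "), "\n")
})

setMethod("show", "FpmMatrix", function(object) {
    cat("FpmMatrix:", nrow(object@fpm), "genes x", ncol(object@fpm),
        "samples\n")
    cat("  library sizes:", paste(format(range(object@libSizes),
        big.mark = ","), collapse = " - "), "\n")
    cat("  norm factors:", paste(format(range(object@normFactors),
        digits = 3), collapse = " - "), "\n")
})

setMethod("show", "AnnotationSet", function(object) {
    sizes <- vapply(object@terms, length, 1L)
    cat("AnnotationSet:", length(object@terms), "terms over a domain of",
        length(object@domain), "genes\n")
    if (length(sizes))
        cat("  term sizes:", min(sizes), "-", max(sizes), "\n")
})
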