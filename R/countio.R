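#' Read a count matrix and its sample sheet
#'
#' Reads a tab-separated gene x sample count table (first column gene ids,
#' header row sample ids) plus a sample-sheet TSV with columns
#' \code{sample}, \code{animal}, \code{treatment}, \code{timepoint},
#' \code{batch}, and returns a validated \linkS4class{CountExperiment}.
#' Row and column order are preserved. Malformed cells are rejected with an
#' error naming the offending gene and sample; a sheet/matrix sample
#' mismatch is a reconciliation error listing the missing ids.
#'
#' @param path path to the counts TSV.
#' @param sheetPath path to the sample-sheet TSV.
#' @return A \code{CountExperiment}.
#' @seealso [writeCounts()]
#' @export
readCounts <- function(path, sheetPath) {
    if (!file.exists(path)) stop("counts file not found: ", path)
    if (!file.exists(sheetPath)) stop("sample sheet not found: ", sheetPath)
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- genes
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop("malformed count (non-integer or negative) for gene '",
             genes[bad[1, 1]], "' in sample '", colnames(m)[bad[1, 2]], "'")
    storage.mode(m) <- "integer"
    sheet <- read.delim(sheetPath, stringsAsFactors = FALSE)
    needed <- c("sample", "animal", "treatment", "timepoint", "batch")
    missing <- setdiff(needed, colnames(sheet))
    if (length(missing))
        stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
    CountExperiment(m, sheet)
}

#' Write a CountExperiment as counts + sample-sheet TSVs
#'
#' @param object a \linkS4class{CountExperiment}.
#' @param path,sheetPath output paths for the counts and sheet TSVs.
#' @return invisibly, the two paths.
#' @export
writeCounts <- function(object, path, sheetPath) {
    m <- counts(object)
    tab <- data.frame(gene = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sampleSheet(object), sheetPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(path, sheetPath))
}

#' Read gene sets in GMT format
#'
#' Each line is \code{term<TAB>description<TAB>gene1<TAB>gene2...}. Genes
#' outside \code{domain} are dropped (a message reports how many) and terms
#' emptied by that filtering are removed. Duplicate genes within a line are
#' deduplicated (set semantics).
#'
#' @param path path to the GMT file.
#' @param domain character vector of annotatable gene ids (the effective
#'   domain of enrichment statistics).
#' @return An \linkS4class{AnnotationSet}.
#' @export
readGmt <- function(path, domain) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(fields, length, 1L) < 3L)
    if (length(short))
        stop("malformed GMT line ", short[1], ": fewer than 3 fields")
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicate term id(s) in GMT: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    descr <- vapply(fields, `[[`, "", 2L)
    terms <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
    names(terms) <- ids
    dropped <- sum(vapply(terms, function(g) sum(!g %in% domain), 1L))
    if (dropped > 0L)
        message(dropped, " gene entr", if (dropped == 1L) "y" else "ies",
                " outside the domain dropped while reading GMT")
    terms <- lapply(terms, function(g) g[g %in% domain])
    keep <- vapply(terms, length, 1L) > 0L
    AnnotationSet(terms[keep], domain = domain,
                  descriptions = setNames(descr, ids)[keep])
}

#' Write an AnnotationSet in GMT format
#'
#' @param object an \linkS4class{AnnotationSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGmt <- function(object, path) {
    lines <- mapply(function(id, d, genes)
        paste(c(id, d, genes), collapse = "\t"),
        names(geneSets(object)), termDescriptions(object), geneSets(object))
    writeLines(unlist(lines, use.names = FALSE), path)
    invisible(path)
}

#' Write result tables and return a file manifest
#'
#' Writes one TSV per table (tab-separated, UTF-8, "." decimal, fixed column
#' order as held in the data.frame) and returns a manifest listing each file
#' and its row count. Empty tables produce a header-only file.
#'
#' @param tables non-empty named list of data.frames.
#' @param outDir output directory (created if absent).
#' @return data.frame with columns \code{name}, \code{path}, \code{rows}.
#' @export
writeResults <- function(tables, outDir) {
    if (length(tables) == 0L || is.null(names(tables)))
        stop("tables must be a non-empty named list")
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    paths <- file.path(outDir, paste0(names(tables), ".tsv"))
    for (i in seq_along(tables))
        write.table(tables[[i]], paths[i], sep = "\t", quote = FALSE,
                    row.names = FALSE, fileEncoding = "UTF-8")
    data.frame(name = names(tables), path = paths,
               rows = vapply(tables, nrow, 1L), row.names = NULL,
               stringsAsFactors = FALSE)
}
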