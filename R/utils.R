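#' Convert between symmetric fold changes and plain ratios
#'
#' Symmetric fold changes live on a scale with no values inside (-1, 1):
#' +r means r-fold up-regulation, -r means r-fold down-regulation, and a
#' neutral ratio maps to +1. \code{fcToRatio} maps a symmetric FC back to the
#' underlying positive ratio; \code{ratioToFc} is its inverse (ratios >= 1
#' map to themselves, ratios < 1 to -1/ratio).
#'
#' @param fc symmetric fold change(s), |fc| >= 1.
#' @param ratio positive ratio(s).
#' @return numeric vector.
#' @export
fcToRatio <- function(fc) {
    if (any(abs(fc) < 1))
        stop("symmetric fold changes cannot lie inside (-1, 1)")
    ifelse(fc >= 1, fc, -1 / fc)
}

#' @rdname fcToRatio
#' @export
ratioToFc <- function(ratio) {
    if (any(ratio <= 0))
        stop("ratios must be positive")
    ifelse(ratio >= 1, ratio, -1 / ratio)
}

# md5 of a deparsed R object (used to stamp pipeline outputs)
.objectHash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(deparse(x), f)
    unname(tools::md5sum(f))
}

# draw-from-integer-range helper kept separate so generators share one
# convention (inclusive bounds, uniform)
.runifInt <- function(n, range) {
    as.integer(round(runif(n, range[1], range[2])))
}
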