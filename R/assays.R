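#' Analytic crossing point of two Gaussian densities
#'
#' Solves \code{dnorm(x, m1, s1) == dnorm(x, m2, s2)} and returns the root
#' lying between the two means (for equal SDs this is their midpoint).
#' Used as the closed-form reference for the kernel-density crossing
#' threshold.
#'
#' @param m1,s1 mean and SD of the first (lower) component.
#' @param m2,s2 mean and SD of the second (higher) component.
#' @return the crossing point between \code{m1} and \code{m2}.
#' @export
gaussianCrossing <- function(m1, s1, m2, s2) {
    stopifnot(s1 > 0, s2 > 0)
    if (s1 == s2) return((m1 + m2) / 2)
    # quadratic in x from equating log densities
    a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
    b <- m1 / s1^2 - m2 / s2^2
    cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(s2 / s1)
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("densities do not cross")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    lo <- min(m1, m2); hi <- max(m1, m2)
    between <- roots[roots >= lo & roots <= hi]
    if (length(between) == 0L)
        stop("no crossing between the two means")
    between[which.min(abs(between - (m1 + m2) / 2))]
}

#' Density-crossing intensity threshold
#'
#' Estimates Gaussian-kernel densities (Silverman's rule-of-thumb
#' bandwidth) for the control and treated intensity samples on a common
#' grid and returns the x-position where the two densities cross — the
#' cut-off above which an object is "greener than randomly expected". A
#' Kolmogorov-Smirnov test must first reject (p < 0.05) that the two
#' samples share a distribution; otherwise there are no separable
#' populations and an error is raised. The crossing is searched above the
#' control mean (not only up to the treated mean: when only a fraction of
#' treated cells carries the high signal, the crossing lies above the
#' treated sample mean), ignoring regions where both densities are below
#' 1\% of the maximum; with several candidate crossings the one closest
#' to the midpoint of the two means is returned with a message.
#'
#' @param control,treated numeric intensity vectors, each of length >= 30;
#'   \code{mean(treated)} must exceed \code{mean(control)}.
#' @param gridSize number of grid points for the density evaluation.
#' @return the threshold (in intensity units).
#' @export
densityCrossingThreshold <- function(control, treated, gridSize = 512L) {
    if (length(control) < 30L || length(treated) < 30L)
        stop("need at least 30 objects per group")
    kt <- suppressWarnings(ks.test(control, treated))
    if (kt$p.value >= 0.05)
        stop("no separable populations (KS p = ",
             signif(kt$p.value, 3), ")")
    if (mean(treated) <= mean(control))
        stop("no valid crossing: treated mean must exceed control mean")
    lo <- min(control, treated); hi <- max(control, treated)
    dc <- density(control, bw = bw.nrd0(control), from = lo, to = hi,
                  n = gridSize)
    dt <- density(treated, bw = bw.nrd0(treated), from = lo, to = hi,
                  n = gridSize)
    gap <- dt$y - dc$y
    x <- dc$x
    m1 <- mean(control); m2 <- mean(treated)
    # search above the control mean: when the treated group is a mixture
    # (only part of its cells shifted), the crossing sits above the treated
    # sample mean, so the window cannot stop there; a density floor keeps
    # tail noise out
    floorY <- 0.01 * max(pmax(dc$y, dt$y))
    window <- which(x >= m1 & pmax(dc$y, dt$y) >= floorY)
    idx <- window[which(diff(sign(gap[window])) != 0)]
    idx <- idx[idx < gridSize]
    if (length(idx) == 0L)
        stop("no density crossing above the control mean")
    # linear interpolation of the zero of (treated - control) density
    crossings <- vapply(idx, function(i) {
        x[i] + (x[i + 1] - x[i]) * gap[i] / (gap[i] - gap[i + 1])
    }, 1)
    if (length(crossings) > 1L)
        message(length(crossings),
                " crossings between the means; using the one closest to ",
                "their midpoint")
    crossings[which.min(abs(crossings - (m1 + m2) / 2))]
}

#' Senescent-cell fraction per condition
#'
#' The percentage of blue objects whose green intensity strictly exceeds
#' the threshold, computed per condition and replicate and then averaged
#' over replicates within each condition (the per-experiment design
#' averages wells before comparing conditions).
#'
#' @param objects data.frame with columns \code{condition},
#'   \code{replicate}, \code{green}, \code{is_blue} (as produced by
#'   \code{\link{simulateCellIntensities}}).
#' @param threshold intensity cut-off from
#'   \code{\link{densityCrossingThreshold}}.
#' @param perReplicate return per-replicate values instead of the
#'   per-condition means.
#' @return data.frame with columns \code{condition}, \code{percent} (and
#'   \code{replicate} when \code{perReplicate}).
#' @export
senescentFraction <- function(objects, threshold, perReplicate = FALSE) {
    stopifnot(is.finite(threshold))
    blue <- objects[objects$is_blue, , drop = FALSE]
    if (nrow(blue) == 0L) stop("no blue objects")
    per <- aggregate(green ~ condition + replicate, data = blue,
                     FUN = function(g) 100 * mean(g > threshold))
    names(per)[names(per) == "green"] <- "percent"
    if (perReplicate) return(per)
    out <- aggregate(percent ~ condition, data = per, FUN = mean)
    out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, the reference Ct is the arithmetic mean of the two reference
#' genes' Cts (equivalent to the geometric mean of their expression),
#' \code{dCt = Ct_target - Ct_ref}, \code{ddCt} subtracts the mean dCt of
#' the calibrator condition within the same replicate, and relative
#' expression is \code{2^-ddCt}. Adding a constant to all three Cts of a
#' sample leaves the result unchanged.
#'
#' @param ct data.frame with columns \code{condition}, \code{replicate},
#'   \code{ct_target}, \code{ct_ref1}, \code{ct_ref2}.
#' @param calibratorCondition the condition used as calibrator (relative
#'   expression 1 on average), e.g. \code{"control"}.
#' @return the input with added columns \code{dct}, \code{ddct},
#'   \code{rel_expr}.
#' @export
ddct <- function(ct, calibratorCondition) {
    needed <- c("condition", "replicate", "ct_target", "ct_ref1", "ct_ref2")
    missing <- setdiff(needed, colnames(ct))
    if (length(missing))
        stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
    if (anyNA(ct[, c("ct_target", "ct_ref1", "ct_ref2")]))
        stop("missing Ct value(s)")
    if (!calibratorCondition %in% ct$condition)
        stop("calibrator condition '", calibratorCondition, "' absent")
    ct$dct <- ct$ct_target - (ct$ct_ref1 + ct$ct_ref2) / 2
    calMean <- tapply(ct$dct[ct$condition == calibratorCondition],
                      ct$replicate[ct$condition == calibratorCondition],
                      mean)
    if (!all(ct$replicate %in% names(calMean)))
        stop("replicate(s) without calibrator sample: ",
             paste(setdiff(unique(ct$replicate), names(calMean)),
                   collapse = ", "))
    ct$ddct <- ct$dct - as.numeric(calMean[as.character(ct$replicate)])
    ct$rel_expr <- 2^(-ct$ddct)
    ct
}

#' Paired Wilcoxon signed-rank test for assay readouts
#'
#' Two-sided paired Wilcoxon signed-rank test, exact for up to 25 pairs
#' (falling back to the normal approximation in the presence of ties or
#' zero differences). All-zero differences are declared p = 1.
#'
#' @param valuesA,valuesB paired numeric vectors (>= 4 pairs), ordered by
#'   replicate.
#' @return the two-sided p-value.
#' @export
pairedGroupTest <- function(valuesA, valuesB) {
    stopifnot(length(valuesA) == length(valuesB))
    if (length(valuesA) < 4L) stop("need at least 4 pairs")
    d <- valuesA - valuesB
    if (all(d == 0)) return(1)
    exact <- length(d) <= 25L
    suppressWarnings(
        wilcox.test(valuesA, valuesB, paired = TRUE,
                    exact = exact)$p.value)
}

#' Single-observation chi-squared outlier test
#'
#' Tests whether the value furthest from the group mean is an outlier:
#' the statistic is its squared deviation over the sample variance,
#' referred to a chi-squared distribution with one degree of freedom.
#' \code{removeOutlier} applies the test at most once per group and drops
#' the flagged value when p falls below \code{alpha}.
#'
#' @param x numeric vector (>= 3 values).
#' @param alpha removal threshold for \code{removeOutlier}.
#' @return \code{chisqOutlierTest}: list with \code{statistic}, \code{p},
#'   \code{index}, \code{value}. \code{removeOutlier}: the (possibly
#'   shortened) vector.
#' @export
chisqOutlierTest <- function(x) {
    stopifnot(length(x) >= 3L)
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    stat <- dev[i]^2 / var(x)
    list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
         index = i, value = x[i])
}

#' @rdname chisqOutlierTest
#' @export
removeOutlier <- function(x, alpha = 0.05) {
    res <- chisqOutlierTest(x)
    if (res$p < alpha) x[-res$index] else x
}
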