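#' Configuration for the synthetic count generator
#'
#' Describes a paired multi-arm experiment: every animal (block) contributes
#' one sample per treatment arm. Counts are negative binomial with
#' gene-specific baselines, a log-normal per-gene, per-animal block effect
#' shared across all of an animal's samples, and library sizes drawn
#' uniformly per sample. Treatment effects are planted on the symmetric
#' fold-change scale so that the additivity null of the synergy test is
#' exactly representable.
#'
#' Combined arms (listed in \code{algebra}) receive their planted effect from
#' the gene's \code{synergyMode}: \code{"additive"} genes get exactly the
#' additivity expectation of their single-arm effects; \code{"stimulatory"} /
#' \code{"inhibitory"} genes get that expectation multiplied / divided by
#' \code{deviation} on the ratio scale; \code{"none"} genes keep whatever is
#' planted explicitly in \code{effects} (default: no effect).
#'
#' @param nGenes number of genes.
#' @param nAnimals number of animals (blocks); the emulated design uses 5-6.
#' @param treatments condition labels; must include \code{"control"}.
#' @param algebra named list decomposing combined arms into their single
#'   constituents, e.g. \code{list(EU = c("E", "U"))}.
#' @param baselineLogMeanRange range (natural-log scale) of baseline mean
#'   expression in FPM units.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param animalSd SD of the log-scale per-gene animal effect.
#' @param librarySizeRange integer range of per-sample library sizes.
#' @param effects data.frame with columns \code{gene} (index or id),
#'   \code{condition}, \code{fc} (symmetric FC target); omitted genes and
#'   conditions default to FC 1.
#' @param synergyMode per-gene mode, one of \code{"additive"},
#'   \code{"stimulatory"}, \code{"inhibitory"}, \code{"none"}; recycled if
#'   length 1.
#' @param deviation ratio-scale deviation from additivity for
#'   stimulatory/inhibitory genes.
#' @param timepoint timepoint label stamped on all samples.
#' @param seed integer seed; equal seeds give bit-identical output.
#'
#' @return A list of class \code{"SimConfig"}.
#' @seealso [simulateCounts()]
#' @export
simConfig <- function(nGenes = 2000L, nAnimals = 6L,
                      treatments = c("control", "E", "U", "EU"),
                      algebra = list(EU = c("E", "U")),
                      baselineLogMeanRange = log(c(20, 500)),
                      dispersion = 0.1, animalSd = 0.5,
                      librarySizeRange = c(15e6, 30e6),
                      effects = NULL,
                      synergyMode = "none",
                      deviation = 2,
                      timepoint = "24h",
                      seed = 1L) {
    if (length(treatments) == 0L)
        stop("treatment list is empty")
    if (!"control" %in% treatments)
        stop("treatments must include 'control'")
    if (dispersion <= 0)
        stop("dispersion must be positive")
    if (animalSd < 0)
        stop("animalSd must be non-negative")
    if (nGenes < 1L || nAnimals < 1L)
        stop("nGenes and nAnimals must be positive")
    if (!all(names(algebra) %in% treatments) ||
        !all(unlist(algebra) %in% treatments))
        stop("algebra references unknown treatment labels")
    mode <- rep_len(as.character(synergyMode), nGenes)
    bad <- setdiff(unique(mode),
                   c("additive", "stimulatory", "inhibitory", "none"))
    if (length(bad))
        stop("unknown synergyMode: ", paste(bad, collapse = ", "))
    if (!is.null(effects)) {
        effects <- as.data.frame(effects)
        stopifnot(all(c("gene", "condition", "fc") %in% colnames(effects)))
        if (any(abs(effects$fc) < 1))
            stop("planted symmetric FCs cannot lie inside (-1, 1)")
        if (!all(effects$condition %in% treatments))
            stop("effects reference unknown treatment labels")
    }
    structure(list(
        nGenes = as.integer(nGenes), nAnimals = as.integer(nAnimals),
        treatments = treatments, algebra = algebra,
        baselineLogMeanRange = baselineLogMeanRange,
        dispersion = dispersion, animalSd = animalSd,
        librarySizeRange = librarySizeRange,
        effects = effects, synergyMode = mode, deviation = deviation,
        timepoint = timepoint, seed = as.integer(seed)),
        class = "SimConfig")
}

# per-gene x treatment matrix of planted symmetric-FC targets
.plantedFcMatrix <- function(config) {
    genes <- sprintf("gene%05d", seq_len(config$nGenes))
    fc <- matrix(1, config$nGenes, length(config$treatments),
                 dimnames = list(genes, config$treatments))
    eff <- config$effects
    if (!is.null(eff)) {
        idx <- if (is.numeric(eff$gene)) as.integer(eff$gene)
               else match(as.character(eff$gene), genes)
        if (anyNA(idx) || any(idx < 1L) || any(idx > config$nGenes))
            stop("effects reference unknown genes")
        fc[cbind(idx, match(eff$condition, config$treatments))] <- eff$fc
    }
    for (combo in names(config$algebra)) {
        parts <- config$algebra[[combo]]
        for (g in seq_len(config$nGenes)) {
            mode <- config$synergyMode[g]
            if (mode == "none") next
            exp_fc <- Reduce(expectedFC, fc[g, parts])
            if (abs(exp_fc) < 1)
                stop("additive expectation for gene ", g, " in ", combo,
                     " falls inside (-1, 1); choose single-arm effects ",
                     "whose additivity target is representable")
            r <- fcToRatio(exp_fc)
            r <- switch(mode,
                        additive = r,
                        stimulatory = r * config$deviation,
                        inhibitory = r / config$deviation)
            fc[g, combo] <- ratioToFc(r)
        }
    }
    fc
}

#' Simulate a paired multi-arm count experiment with planted effects
#'
#' Draws negative-binomial counts for the design described by a
#' \code{\link{simConfig}}: each animal contributes one sample per treatment
#' arm, gene means are baseline x planted-ratio x animal effect, scaled by
#' the sample's library size. Identical seeds give bit-identical output.
#'
#' @param config a \code{SimConfig}.
#' @return A list with elements \code{experiment}
#'   (\linkS4class{CountExperiment}) and \code{truth} (data.frame with one
#'   row per gene: id, synergy mode, expression flag, and the true symmetric
#'   FC per non-control treatment in columns \code{fc_<treatment>}).
#' @examples
#' sim <- simulateCounts(simConfig(nGenes = 50, nAnimals = 3, seed = 7))
#' sim$experiment
#' head(sim$truth)
#' @export
simulateCounts <- function(config) {
    if (!inherits(config, "SimConfig"))
        config <- do.call(simConfig, config)
    set.seed(config$seed)
    nG <- config$nGenes
    nA <- config$nAnimals
    trts <- config$treatments
    genes <- sprintf("gene%05d", seq_len(nG))
    animals <- sprintf("a%02d", seq_len(nA))
    fc <- .plantedFcMatrix(config)
    ratio <- matrix(fcToRatio(fc), nG, length(trts),
                    dimnames = dimnames(fc))

    baseFpm <- exp(runif(nG, config$baselineLogMeanRange[1],
                         config$baselineLogMeanRange[2]))
    animalEff <- matrix(exp(rnorm(nG * nA, 0, config$animalSd)), nG, nA)

    sheet <- expand.grid(treatment = trts, animal = animals,
                         stringsAsFactors = FALSE)
    sheet <- data.frame(
        sample = paste0(sheet$animal, "_", sheet$treatment),
        animal = sheet$animal, treatment = sheet$treatment,
        timepoint = config$timepoint, batch = config$timepoint,
        stringsAsFactors = FALSE)
    nS <- nrow(sheet)
    libSize <- .runifInt(nS, config$librarySizeRange)

    counts <- matrix(0L, nG, nS, dimnames = list(genes, sheet$sample))
    for (s in seq_len(nS)) {
        a <- match(sheet$animal[s], animals)
        mu <- baseFpm * ratio[, sheet$treatment[s]] * animalEff[, a] *
            libSize[s] / 1e6
        counts[, s] <- rnbinom(nG, size = 1 / config$dispersion, mu = mu)
    }
    storage.mode(counts) <- "integer"

    truth <- data.frame(gene = genes, synergy_mode = config$synergyMode,
                        is_expressed = baseFpm >= 5,
                        stringsAsFactors = FALSE)
    for (t in setdiff(trts, "control"))
        truth[[paste0("fc_", t)]] <- fc[, t]

    list(experiment = CountExperiment(counts, sheet), truth = truth)
}

#' Simulate a gene-set annotation
#'
#' Draws \code{nTerms} gene sets uniformly without replacement from a domain
#' of \code{nGenes} genes (ids matching those of \code{\link{simulateCounts}}
#' unless \code{genes} is supplied).
#'
#' @param nGenes domain size (ignored when \code{genes} is given).
#' @param nTerms number of terms; 0 gives an empty annotation.
#' @param termSizeRange inclusive integer range of term sizes; must not
#'   exceed the domain size.
#' @param seed integer seed.
#' @param genes optional character vector to use as the domain.
#' @return An \linkS4class{AnnotationSet}.
#' @export
simulateAnnotation <- function(nGenes, nTerms, termSizeRange = c(10, 100),
                               seed = 1L, genes = NULL) {
    if (is.null(genes))
        genes <- sprintf("gene%05d", seq_len(nGenes))
    if (max(termSizeRange) > length(genes))
        stop("term sizes cannot exceed the number of genes")
    if (min(termSizeRange) < 1L)
        stop("term sizes must be >= 1")
    set.seed(seed)
    terms <- vector("list", nTerms)
    for (i in seq_len(nTerms)) {
        size <- if (termSizeRange[1] == termSizeRange[2]) termSizeRange[1]
                else sample(seq(termSizeRange[1], termSizeRange[2]), 1L)
        terms[[i]] <- sample(genes, size)
    }
    names(terms) <- sprintf("T%04d", seq_len(nTerms))
    AnnotationSet(terms, domain = genes,
                  descriptions = setNames(
                      rep("synthetic term", nTerms), names(terms)))
}

#' Simulate per-cell fluorescence intensities
#'
#' Emulates a two-group senescence staining readout: every object carries a
#' blue (nuclear) intensity and a green (reporter) intensity. Control objects
#' draw green from the low-signal Gaussian; treated objects draw from a
#' mixture in which a fraction \code{senescentFraction} comes from the
#' high-signal component.
#'
#' @param nCellsPerGroup objects per condition.
#' @param controlMean,controlSd low-signal Gaussian parameters.
#' @param treatedMean,treatedSd high-signal Gaussian parameters
#'   (\code{treatedMean >= controlMean}).
#' @param senescentFraction fraction of treated objects from the high
#'   component, in [0, 1].
#' @param seed integer seed.
#' @param replicate replicate label stamped on all rows.
#' @return data.frame with columns \code{object}, \code{replicate},
#'   \code{condition}, \code{blue}, \code{green}, \code{is_blue}, and the
#'   per-object truth flag \code{is_senescent}.
#' @export
simulateCellIntensities <- function(nCellsPerGroup,
                                    controlMean = 10, controlSd = 2,
                                    treatedMean = 20, treatedSd = 2,
                                    senescentFraction = 0.3,
                                    seed = 1L, replicate = "r1") {
    if (controlSd <= 0 || treatedSd <= 0)
        stop("intensity SDs must be positive")
    if (treatedMean < controlMean)
        stop("treatedMean must be >= controlMean")
    if (senescentFraction < 0 || senescentFraction > 1)
        stop("senescentFraction must lie in [0, 1]")
    set.seed(seed)
    n <- as.integer(nCellsPerGroup)
    greenCtrl <- rnorm(n, controlMean, controlSd)
    high <- runif(n) < senescentFraction
    greenTrt <- ifelse(high, rnorm(n, treatedMean, treatedSd),
                       rnorm(n, controlMean, controlSd))
    out <- data.frame(
        object = sprintf("obj%06d", seq_len(2L * n)),
        replicate = replicate,
        condition = rep(c("control", "treated"), each = n),
        blue = runif(2L * n, 50, 150),
        green = pmax(c(greenCtrl, greenTrt), 0),
        is_blue = TRUE,
        is_senescent = c(rep(FALSE, n), high),
        stringsAsFactors = FALSE)
    out
}
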