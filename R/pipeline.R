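#' Read a pipeline configuration from YAML
#'
#' The file may specify input paths (\code{counts}, \code{sheet},
#' \code{gmt}), an output directory (\code{out_dir}), the contrasts to
#' test, the condition \code{algebra} (combined arm -> constituents),
#' threshold overrides and a \code{seed}. Missing thresholds fall back to
#' the package defaults (FDR 0.05, FPM 5, synergy alpha 0.05, enrichment
#' adjusted p 0.001, E 3).
#'
#' @param path YAML file path.
#' @return a named list suitable for \code{\link{runPipeline}}.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    defaults <- list(fdrMax = 0.05, fpmMin = 5, alpha = 0.05,
                     enrichPMax = 0.001, eMin = 3, calibrationRuns = 100,
                     seed = 1L)
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    if (!is.null(cfg$algebra)) {
        cfg$algebra <- lapply(cfg$algebra, as.character)
        for (combo in names(cfg$algebra)) {
            if (!is.null(cfg$contrasts) &&
                !all(cfg$algebra[[combo]] %in% cfg$contrasts))
                stop("constituents of '", combo,
                     "' are not all listed as contrasts")
        }
    }
    stopifnot(cfg$fdrMax > 0, cfg$fpmMin > 0, cfg$alpha > 0,
              cfg$enrichPMax > 0, cfg$eMin > 0)
    cfg
}

#' Run the full synergy analysis pipeline
#'
#' Stages, per timepoint: expression filter, TMM/FPM normalization,
#' differential expression per contrast by both procedures, consensus DEG,
#' exclusive DEG-set intersections with qualitative-synergy labels,
#' distribution-shift (KS) tests on shared genes of single/combined
#' contrast pairs, and the quantitative synergy table per combined arm.
#' Across timepoints: the targeted pairwise FPM screen per combined arm.
#' With an annotation: over-representation analysis per intersection and
#' the random-set calibration of the significance threshold. All tables
#' are written as TSVs with a manifest; reruns with identical inputs and
#' seed are bit-identical.
#'
#' @param experiment a \linkS4class{CountExperiment} (may span timepoints;
#'   each is analyzed separately).
#' @param annotation optional \linkS4class{AnnotationSet} for enrichment.
#' @param outDir output directory for TSVs.
#' @param contrasts treatment labels to test against control; default all
#'   non-control arms.
#' @param algebra named list decomposing combined arms, e.g.
#'   \code{list(EU = c("E", "U"))}.
#' @param control control label.
#' @param fdrMax,fpmMin consensus DEG thresholds.
#' @param alpha synergy / screen significance level.
#' @param enrichPMax,eMin enrichment filtering thresholds.
#' @param calibrationRuns random-set calibration runs (0 to skip).
#' @param seed integer seed for the calibration draws.
#' @return list with elements \code{deg} (per timepoint, per contrast),
#'   \code{deTables}, \code{intersections}, \code{ksShifts},
#'   \code{synergy}, \code{screen}, \code{enrichment},
#'   \code{calibration}, \code{manifest}, \code{configHash}.
#' @export
runPipeline <- function(experiment, annotation = NULL,
                        outDir = tempfile("synergyde_"),
                        contrasts = NULL, algebra = list(),
                        control = "control",
                        fdrMax = 0.05, fpmMin = 5, alpha = 0.05,
                        enrichPMax = 0.001, eMin = 3,
                        calibrationRuns = 100, seed = 1L) {
    if (is.null(contrasts))
        contrasts <- setdiff(unique(treatments(experiment)), control)
    if (!all(unlist(algebra) %in% contrasts))
        stop("every combined contrast's constituents must be contrasts")
    cfgHash <- .objectHash(list(contrasts, algebra, control, fdrMax,
                                fpmMin, alpha, enrichPMax, eMin,
                                calibrationRuns, seed))
    tps <- unique(timepoints(experiment))
    fpmList <- list(); exList <- list()
    deg <- list(); deTables <- list(); intersections <- list()
    ksShifts <- list(); synergy <- list()

    for (tp in tps) {
        ex <- experiment[, timepoints(experiment) == tp]
        exList[[tp]] <- ex
        tested <- filterExpressed(ex)
        fm <- fpm(ex)
        fpmList[[tp]] <- fm
        tpContrasts <- intersect(contrasts, unique(treatments(ex)))
        deg[[tp]] <- list()
        for (cond in tpContrasts) {
            resA <- deTest(ex, cond, control, method = "edgeR",
                           testedGenes = tested)
            resB <- deTest(ex, cond, control, method = "DESeq2",
                           testedGenes = tested)
            full <- consensusDeg(resA, resB, fm, ex, fdrMax = fdrMax,
                                 fpmMin = fpmMin, full = TRUE)
            deTables[[paste0("de_", tp, "_", cond)]] <- full
            deg[[tp]][[cond]] <- full[full$consensus, , drop = FALSE]
        }
        sets <- lapply(deg[[tp]], function(d) d$gene)
        nonEmpty <- sets[lengths(sets) > 0]
        if (length(sets) >= 2L) {
            intersections[[tp]] <-
                intersectDegSets(sets, algebra = algebra)
        }
        for (combo in intersect(names(algebra), tpContrasts)) {
            parts <- intersect(algebra[[combo]], tpContrasts)
            if (length(parts) < length(algebra[[combo]])) next
            degGenes <- unique(unlist(lapply(c(parts, combo),
                function(cc) deg[[tp]][[cc]]$gene)))
            if (length(degGenes) == 0L) next
            synergy[[paste0(tp, "_", combo)]] <-
                buildSynergyTable(fm, ex, combo, parts, genes = degGenes,
                                  control = control, alpha = alpha)
            for (s in parts) {
                shared <- intersect(deg[[tp]][[s]]$gene,
                                    deg[[tp]][[combo]]$gene)
                if (length(shared) < 5L) next
                lfcS <- deg[[tp]][[s]]
                lfcC <- deg[[tp]][[combo]]
                ks <- ksShiftTest(
                    lfcS$log2FC_A[match(shared, lfcS$gene)],
                    lfcC$log2FC_A[match(shared, lfcC$gene)],
                    direction = lfcS$direction[match(shared, lfcS$gene)])
                if (!is.null(ks) && nrow(ks)) {
                    ks$single <- s; ks$combined <- combo; ks$timepoint <- tp
                    ksShifts[[paste0(tp, "_", s, "_", combo)]] <- ks
                }
            }
        }
    }

    screen <- list()
    for (combo in names(algebra)) {
        parts <- algebra[[combo]]
        eligible <- unique(unlist(lapply(tps, function(tp)
            unlist(lapply(c(parts, combo),
                          function(cc) deg[[tp]][[cc]]$gene)))))
        exclude <- unique(unlist(lapply(intersections, function(it) {
            if (is.null(it$label)) return(character())
            unlist(strsplit(it$genes[it$label != "none"], ";",
                            fixed = TRUE))
        })))
        okTps <- tps[vapply(tps, function(tp)
            all(c(combo, parts, control) %in%
                unique(treatments(exList[[tp]]))), TRUE)]
        if (length(okTps) == 0L || length(eligible) == 0L) next
        screen[[combo]] <- targetedPairwiseScreen(
            fpmList[okTps], exList[okTps], combo, parts,
            eligibleGenes = eligible, excludeGenes = exclude,
            control = control, alpha = alpha)
    }

    enrichment <- list(); calibration <- NULL
    if (!is.null(annotation)) {
        for (tp in names(intersections)) {
            memb <- attr(intersections[[tp]], "membership")
            for (i in seq_len(nrow(intersections[[tp]]))) {
                id <- intersections[[tp]]$id[i]
                genes <- memb[[intersections[[tp]]$signature[i]]]
                if (sum(genes %in% annotationDomain(annotation)) == 0L)
                    next
                enr <- suppressMessages(
                    hypergeomEnrich(genes, annotation))
                enr$intersection <- id; enr$timepoint <- tp
                enrichment[[paste0(tp, "_", id)]] <-
                    filterEnriched(enr, pMax = enrichPMax, eMin = eMin)
            }
        }
        if (calibrationRuns > 0 && length(intersections)) {
            sizes <- unique(unlist(lapply(intersections,
                                          function(it) it$n_genes)))
            sizes <- sizes[sizes >= 5]
            if (length(sizes))
                calibration <- calibrateThreshold(
                    annotation, sort(sizes), nRuns = calibrationRuns,
                    seed = seed)
        }
    }

    tables <- deTables
    for (tp in names(intersections))
        tables[[paste0("intersections_", tp)]] <-
            intersections[[tp]][, setdiff(colnames(intersections[[tp]]),
                                          character(0))]
    if (length(ksShifts))
        tables$ks_shifts <- do.call(rbind,
            c(ksShifts, list(make.row.names = FALSE)))
    for (nm in names(synergy)) tables[[paste0("synergy_", nm)]] <-
        synergy[[nm]]
    for (nm in names(screen)) tables[[paste0("screen_", nm)]] <-
        screen[[nm]]
    if (length(enrichment))
        tables$enrichment <- do.call(rbind,
            c(enrichment, list(make.row.names = FALSE)))
    if (!is.null(calibration))
        tables$calibration <- as.data.frame(calibration)
    manifest <- writeResults(tables, outDir)
    manifest$config_hash <- cfgHash

    list(deg = deg, deTables = deTables, intersections = intersections,
         ksShifts = ksShifts, synergy = synergy, screen = screen,
         enrichment = enrichment, calibration = calibration,
         manifest = manifest, configHash = cfgHash)
}

#' Build the miniature demonstration dataset
#'
#' A 500-gene, 6-animal experiment with arms control/E/U/EU at one
#' timepoint: 20 genes with planted stimulatory synergy, 20 inhibitory,
#' 60 additive, and 50 further genes with single-arm effects only, plus a
#' 50-term synthetic annotation. Used by the documentation and tests.
#'
#' @param seed integer seed.
#' @param dir optional directory; when given, the counts, sheet and GMT
#'   files are written there.
#' @return list with \code{experiment}, \code{truth}, \code{annotation},
#'   \code{config} (and \code{paths} when \code{dir} is given).
#' @export
makeDemo <- function(seed = 1L, dir = NULL) {
    nGenes <- 500L
    mode <- rep("none", nGenes)
    mode[1:20] <- "stimulatory"
    mode[21:40] <- "inhibitory"
    mode[41:100] <- "additive"
    set.seed(seed)
    # synergy genes: same-sign single-arm effects so the additivity target
    # stays on the symmetric-FC scale
    idx <- 1:100
    sgn <- sample(c(-1, 1), 100, replace = TRUE)
    effects <- rbind(
        data.frame(gene = idx, condition = "E",
                   fc = sgn * runif(100, 1.5, 3)),
        data.frame(gene = idx, condition = "U",
                   fc = sgn * runif(100, 1.5, 3)),
        # single-arm-only effects (mode none): DEG material for E and U
        data.frame(gene = 101:125, condition = "E",
                   fc = sample(c(-1, 1), 25, TRUE) * runif(25, 2, 5)),
        data.frame(gene = 126:150, condition = "U",
                   fc = sample(c(-1, 1), 25, TRUE) * runif(25, 2, 5)))
    cfg <- simConfig(nGenes = nGenes, nAnimals = 6L,
                     treatments = c("control", "E", "U", "EU"),
                     algebra = list(EU = c("E", "U")),
                     effects = effects, synergyMode = mode,
                     deviation = 3, seed = seed)
    sim <- simulateCounts(cfg)
    annotation <- simulateAnnotation(nGenes, nTerms = 50L,
                                     termSizeRange = c(10, 60),
                                     seed = seed)
    out <- list(experiment = sim$experiment, truth = sim$truth,
                annotation = annotation, config = cfg)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        paths <- c(counts = file.path(dir, "counts.tsv"),
                   sheet = file.path(dir, "samples.tsv"),
                   gmt = file.path(dir, "annotation.gmt"))
        writeCounts(sim$experiment, paths["counts"], paths["sheet"])
        writeGmt(annotation, paths["gmt"])
        out$paths <- paths
    }
    out
}
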