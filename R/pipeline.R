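#' Assemble and validate a pipeline configuration
#'
#' Collects the file paths, condition pair and printed-constant parameters
#' that drive [runPipeline()].  All thresholds are validated up front so a
#' bad configuration is rejected before any stage runs.
#'
#' @param countsFile,samplesFile count matrix + sample map TSVs (see
#'   [readCountMatrix()]).  The sample map distinguishes transcription-
#'   arrest samples (with \code{timepoint_min}) from steady-state samples
#'   (empty timepoint).
#' @param conditions character vector of length 2: the condition pair to
#'   compare (reference first).
#' @param doublingTimes numeric vector of length 2, hours, same order.
#' @param referenceGene,referenceHalflife reference gene id and its assigned
#'   half-life in minutes (default 120).
#' @param degFiles optional named character vector of per-method DEG TSVs;
#'   when absent the built-in [simpleDETest()] supplies a single table.
#' @param operonFile optional operon map TSV; when present, reads are also
#'   pooled per operon and an operon-level DEG table is produced.
#' @param modelFile optional metabolic model (JSON/SBML); enables the flux
#'   stage.
#' @param substrateExchanges named character vector (one per condition) of
#'   substrate exchange reaction ids (required with \code{modelFile}).
#' @param alphaDE,alphaShift,alphaBiomass significance levels (default
#'   0.01 each).
#' @param cvMax half-life QC threshold (default 0.5).
#' @param fluxFoldThreshold flux fold-change call threshold (default 2).
#' @param nOrderings biomass-fit orderings (default 96).
#' @param seed integer seed.
#' @return a validated configuration (class
#'   \code{"decayflux_pipeline_config"}).
#' @export
pipelineConfig <- function(countsFile, samplesFile, conditions,
                           doublingTimes,
                           referenceGene, referenceHalflife = 120,
                           degFiles = NULL, operonFile = NULL,
                           modelFile = NULL, substrateExchanges = NULL,
                           alphaDE = 0.01, alphaShift = 0.01,
                           alphaBiomass = 0.01, cvMax = 0.5,
                           fluxFoldThreshold = 2, nOrderings = 96,
                           seed = 1) {
    for (a in c(alphaDE = alphaDE, alphaShift = alphaShift,
                alphaBiomass = alphaBiomass))
        if (!is.finite(a) || a <= 0 || a >= 1)
            stop("significance levels must lie in (0, 1)")
    if (!is.finite(cvMax) || cvMax <= 0) stop("cvMax must be positive")
    if (!is.finite(fluxFoldThreshold) || fluxFoldThreshold <= 0)
        stop("fluxFoldThreshold must be positive")
    if (!is.finite(referenceHalflife) || referenceHalflife <= 0)
        stop("referenceHalflife must be positive minutes")
    if (length(conditions) != 2)
        stop("exactly two conditions must be named")
    if (length(doublingTimes) != 2 || any(!is.finite(doublingTimes)) ||
        any(doublingTimes <= 0))
        stop("doublingTimes must be two positive values (hours)")
    if (nOrderings < 1) stop("nOrderings must be >= 1")
    if (!is.null(modelFile) &&
        (is.null(substrateExchanges) || length(substrateExchanges) != 2))
        stop("substrateExchanges (one per condition) required with a model")
    cfg <- list(countsFile = countsFile, samplesFile = samplesFile,
                conditions = conditions, doublingTimes = doublingTimes,
                referenceGene = referenceGene,
                referenceHalflife = referenceHalflife,
                degFiles = degFiles, operonFile = operonFile,
                modelFile = modelFile,
                substrateExchanges = substrateExchanges,
                alphaDE = alphaDE, alphaShift = alphaShift,
                alphaBiomass = alphaBiomass, cvMax = cvMax,
                fluxFoldThreshold = fluxFoldThreshold,
                nOrderings = nOrderings, seed = as.integer(seed))
    class(cfg) <- "decayflux_pipeline_config"
    cfg
}

#' Run the full analysis pipeline
#'
#' Executes the three stages in order -- half-life estimation (RPKM
#' normalization, reference-gene rescaling, decay fitting, QC), regulation
#' analysis (differential expression or consensus over supplied method
#' tables, optional operon pooling, control coefficients and regime calls)
#' and, when a model is configured, the flux stage (growth-matched FBA,
#' biomass-coefficient fitting, flux-change classification) -- writing every
#' result table as TSV into \code{outDir} plus a JSON run manifest with a
#' checksum for each output.  Reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param config a configuration from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir) {
    stopifnot(inherits(config, "decayflux_pipeline_config"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage_counts <- list()
    outputs <- character()
    emit <- function(df, name) {
        path <- file.path(outDir, name)
        .writeTSV(df, path)
        outputs <<- c(outputs, path)
        path
    }

    ## stage 1: half-lives -------------------------------------------------
    counts <- readCountMatrix(config$countsFile, config$samplesFile)
    cd <- colData(counts)
    if (!"timepoint_min" %in% colnames(cd))
        stop("[halflife] sample map has no timepoint_min column")
    rpkm <- rpkmNormalize(counts)
    records <- list()
    for (cond in config$conditions) {
        sel <- cd$condition == cond & !is.na(cd$timepoint_min)
        if (sum(sel) == 0)
            stop("[halflife] no transcription-arrest samples for ", cond)
        de <- DecayExperiment(rpkm[, sel, drop = FALSE],
                              timepoint = cd$timepoint_min[sel],
                              replicate = cd$replicate[sel],
                              condition = cond)
        de <- referenceScale(de, config$referenceGene,
                             config$referenceHalflife)
        rec <- fitDecay(de, cvMax = config$cvMax)
        emit(rec, paste0("halflife_", cond, ".tsv"))
        stage_counts[[paste0("halflife_", cond)]] <-
            c(genes = nrow(rec), qc_pass = sum(rec$qc_pass))
        records[[cond]] <- rec
    }

    ## stage 2: regulation --------------------------------------------------
    steady <- lapply(config$conditions, function(cond) {
        sel <- cd$condition == cond & is.na(cd$timepoint_min)
        if (sum(sel) == 0)
            stop("[regulation] no steady-state samples for ", cond)
        sel
    })
    names(steady) <- config$conditions
    expr <- lapply(steady, function(sel)
        rowMeans(rpkm[, sel, drop = FALSE]))
    if (!is.null(config$degFiles)) {
        tables <- lapply(config$degFiles, readDEGTable)
        deg <- consensusDEG(tables, alpha = config$alphaDE)
    } else {
        de_tab <- simpleDETest(
            assay(counts, "counts")[, steady[[1]], drop = FALSE],
            assay(counts, "counts")[, steady[[2]], drop = FALSE])
        deg <- data.frame(gene_id = de_tab$gene_id,
                          p_builtin = de_tab$pvalue,
                          log2fc = de_tab$log2fc,
                          consensus = de_tab$pvalue <= config$alphaDE)
    }
    emit(deg, "deg_consensus.tsv")
    stage_counts$deg <- c(genes = nrow(deg),
                          consensus = sum(deg$consensus))
    if (!is.null(config$operonFile)) {
        operons <- readOperonMap(config$operonFile)
        pooled <- poolOperons(counts, operons)
        op_de <- simpleDETest(
            assay(pooled, "counts")[, steady[[1]], drop = FALSE],
            assay(pooled, "counts")[, steady[[2]], drop = FALSE])
        emit(op_de, "deg_operon.tsv")
        stage_counts$operons <- c(units = nrow(op_de),
                                  de = sum(op_de$pvalue <= config$alphaDE))
    }
    control <- controlAnalysis(records[[1]], records[[2]],
                               expr[[1]], expr[[2]], cvMax = config$cvMax)
    emit(control, paste0("control_", config$conditions[1], "_vs_",
                         config$conditions[2], ".tsv"))
    stage_counts$control <- c(genes = nrow(control),
                              determinate = sum(!is.na(control$rho_D)))
    shifts <- classifyShift(records[[1]], records[[2]],
                            alpha = config$alphaShift)
    emit(shifts, "halflife_shifts.tsv")
    stage_counts$shifts <- table(shifts$class)

    ## stage 3: flux fitting -------------------------------------------------
    if (!is.null(config$modelFile)) {
        model <- readMetabolicModel(config$modelFile, verbose = FALSE)
        ref <- conditionSpec(config$conditions[1],
                             config$substrateExchanges[1],
                             config$doublingTimes[1], expr[[1]])
        alt <- conditionSpec(config$conditions[2],
                             config$substrateExchanges[2],
                             config$doublingTimes[2], expr[[2]])
        deg_in <- data.frame(gene_id = deg$gene_id[deg$consensus])
        fit <- fitBiomassCoefficients(model, ref, alt, deg_in,
                                      nOrderings = config$nOrderings,
                                      alpha = config$alphaBiomass,
                                      seed = config$seed)
        emit(fit, "biomass_fit.tsv")
        stage_counts$biomass <- table(fit$class)
        g1 <- matchGrowth(model, ref@substrateExchange, growthRate(ref))
        model2 <- model
        for (i in seq_len(nrow(fit)))
            model2 <- setBiomassCoefficient(model2, fit$metabolite[i],
                                            max(fit$b_mean[i], 1e-9))
        g2 <- matchGrowth(model2, alt@substrateExchange, growthRate(alt))
        fc <- classifyFluxChanges(g1$solution, g2$solution,
                                  threshold = config$fluxFoldThreshold)
        emit(fc, "flux_changes.tsv")
        stage_counts$flux <- table(fc$class)
    }

    manifest <- list(
        package = "decayflux",
        version = as.character(utils::packageVersion("decayflux")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = config$seed,
        config = unclass(config),
        stage_counts = lapply(stage_counts, function(x)
            as.list(setNames(as.numeric(x), names(x)))),
        outputs = lapply(outputs, function(p)
            list(file = basename(p),
                 md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    invisible(manifest)
}
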