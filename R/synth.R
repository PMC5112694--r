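#' Simulate a transcription-arrest decay time course with known half-lives
#'
#' Generates a replicate-resolved expression time series in which every
#' gene decays exponentially from its initial abundance,
#' \eqn{R_i(t) = R_{i,0} 2^{-t/\tau_i}}, multiplied by (i) per-replicate,
#' per-timepoint lognormal noise with coefficient of variation
#' \code{noiseCV} and (ii) a global per-timepoint lognormal drift factor
#' shared by all genes and replicates, with log-scale amplitude
#' \code{driftAmplitude}.  The drift emulates the residual transcription /
#' normalization artifacts that reference-gene anchoring
#' ([referenceScale()]) exists to remove.  One designated reference gene
#' always has a true half-life of \code{referenceHalflife} minutes.
#'
#' @param nGenes number of genes (including the reference gene).
#' @param timepoints strictly increasing sampling times in minutes after
#'   arrest (default 5, 10, 20, 30, 60, 120, 240).
#' @param nReplicates biological replicates per timepoint (default 3).
#' @param noiseCV coefficient of variation of the multiplicative noise
#'   (>= 0; default 0.1).
#' @param driftAmplitude lognormal sigma of the shared per-timepoint drift
#'   (default 0 = no drift).
#' @param halflifeDist list describing the half-life distribution:
#'   \code{list(dist = "lognormal", meanlog, sdlog)} (default median 60 min,
#'   sdlog 0.5).
#' @param initialDist same structure for initial abundances (default median
#'   100, sdlog 1).
#' @param referenceGene id given to the reference gene (default
#'   \code{"MA1574"}).
#' @param referenceHalflife its true half-life in minutes (default 120).
#' @param condition,doublingTime labels stored in the experiment metadata.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with \code{experiment} (a \linkS4class{DecayExperiment}) and
#'   \code{truth} (data.frame \code{gene_id}, \code{true_halflife_min},
#'   \code{true_initial}, \code{regime_label}); genes whose half-life
#'   exceeds the last timepoint are labelled \code{"stable"}, the rest
#'   \code{"decaying"}.
#' @export
simulateDecayExperiment <- function(nGenes = 500,
                                    timepoints = c(5, 10, 20, 30, 60, 120, 240),
                                    nReplicates = 3,
                                    noiseCV = 0.1,
                                    driftAmplitude = 0,
                                    halflifeDist = list(dist = "lognormal",
                                                        meanlog = log(60),
                                                        sdlog = 0.5),
                                    initialDist = list(dist = "lognormal",
                                                       meanlog = log(100),
                                                       sdlog = 1),
                                    referenceGene = "MA1574",
                                    referenceHalflife = 120,
                                    condition = "synthetic",
                                    doublingTime = NA_real_,
                                    seed = 1) {
    if (any(diff(timepoints) <= 0) || any(timepoints <= 0))
        stop("timepoints must be strictly increasing and positive")
    if (noiseCV < 0) stop("noiseCV must be >= 0")
    if (nReplicates < 1) stop("nReplicates must be >= 1")
    set.seed(seed)
    ids <- c(referenceGene,
             sprintf("gene%04d", seq_len(nGenes - 1)))
    tau <- c(referenceHalflife, .sampleDist(halflifeDist, nGenes - 1))
    if (any(tau <= 0)) stop("half-life distribution produced values <= 0")
    R0 <- .sampleDist(initialDist, nGenes)
    tp_rep <- rep(timepoints, each = nReplicates)
    rep_id <- rep(seq_len(nReplicates), times = length(timepoints))
    clean <- outer(1 / tau, tp_rep) # t/tau
    clean <- R0 * 2^(-clean)
    sig <- sqrt(log(1 + noiseCV^2))
    noise <- if (noiseCV > 0)
        matrix(rlnorm(nGenes * length(tp_rep), -sig^2 / 2, sig),
               nGenes, length(tp_rep))
    else 1
    drift <- if (driftAmplitude > 0)
        rlnorm(length(timepoints), -driftAmplitude^2 / 2, driftAmplitude)
    else rep(1, length(timepoints))
    x <- clean * noise *
        rep(drift, each = nReplicates)[col(clean)]
    dimnames(x) <- list(ids, paste0("t", tp_rep, "_r", rep_id))
    exp <- DecayExperiment(x, timepoint = tp_rep, replicate = rep_id,
                           condition = condition,
                           doublingTime = doublingTime)
    truth <- data.frame(gene_id = ids, true_halflife_min = tau,
                        true_initial = R0,
                        regime_label = ifelse(tau > max(timepoints),
                                              "stable", "decaying"))
    list(experiment = exp, truth = truth)
}

.sampleDist <- function(spec, n) {
    if (n == 0) return(numeric())
    switch(spec$dist,
        lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
        uniform = runif(n, spec$min, spec$max),
        fixed = rep(spec$value, n),
        stop("unknown distribution: ", spec$dist))
}

#' Simulate an overdispersed two-condition count dataset with planted DEGs
#'
#' Counts are drawn from a gamma-Poisson (negative binomial) model, the
#' standard overdispersed surrogate for RNA-seq: gene means are lognormal,
#' condition-2 means are scaled by \code{2^log2fc} for the planted genes,
#' and counts have dispersion \code{dispersion}
#' (variance \eqn{\mu + \phi \mu^2}).
#'
#' @param nGenes number of genes.
#' @param plantedLog2FC named numeric vector: log2 fold changes
#'   (condition 2 over condition 1) for a subset of gene ids; every name
#'   must be one of the generated ids \code{sprintf("gene\%04d", 1:nGenes)}.
#' @param dispersion negative-binomial dispersion, > 0 (default 0.1).
#' @param nReplicates replicates per condition (default 3).
#' @param baselineMeanlog,baselineSdlog lognormal parameters of the gene
#'   mean counts (defaults log(200), 1).
#' @param geneLength gene lengths in bases (default 1000, recycled).
#' @param seed integer seed.
#' @return list with \code{counts} (a \linkS4class{CountMatrix} with
#'   conditions \code{"cond1"}/\code{"cond2"}) and \code{truth}
#'   (data.frame \code{gene_id}, \code{log2fc}, \code{planted}).
#' @export
simulateCountExperiment <- function(nGenes = 1000,
                                    plantedLog2FC = numeric(),
                                    dispersion = 0.1,
                                    nReplicates = 3,
                                    baselineMeanlog = log(200),
                                    baselineSdlog = 1,
                                    geneLength = 1000,
                                    seed = 1) {
    if (dispersion <= 0) stop("dispersion must be positive")
    ids <- sprintf("gene%04d", seq_len(nGenes))
    if (length(plantedLog2FC)) {
        bad <- setdiff(names(plantedLog2FC), ids)
        if (length(bad))
            stop("fold change specified for unknown gene(s): ",
                 paste(bad, collapse = ", "))
    }
    set.seed(seed)
    mu1 <- rlnorm(nGenes, baselineMeanlog, baselineSdlog)
    lfc <- setNames(rep(0, nGenes), ids)
    lfc[names(plantedLog2FC)] <- plantedLog2FC
    mu2 <- mu1 * 2^lfc
    draw <- function(mu) matrix(
        rnbinom(nGenes * nReplicates, mu = rep(mu, nReplicates),
                size = 1 / dispersion),
        nGenes, nReplicates)
    cts <- cbind(draw(mu1), draw(mu2))
    dimnames(cts) <- list(ids, c(paste0("cond1_r", seq_len(nReplicates)),
                                 paste0("cond2_r", seq_len(nReplicates))))
    cm <- CountMatrix(cts, length = rep_len(geneLength, nGenes),
                      sampleData = data.frame(
                          condition = rep(c("cond1", "cond2"),
                                          each = nReplicates),
                          replicate = rep(seq_len(nReplicates), 2)))
    list(counts = cm,
         truth = data.frame(gene_id = ids, log2fc = unname(lfc),
                            planted = ids %in% names(plantedLog2FC)))
}

#' Build a toy metabolic model with planted biomass-demand shifts
#'
#' Constructs a small, fully identifiable network: one substrate exchange,
#' an uptake reaction into a hub metabolite, \code{nBranches} independent
#' two-step linear branches (each step carrying its own single-gene GPR),
#' and a biomass reaction consuming the branch end products with
#' coefficients \code{b_j}.  Because each end product is made by exactly
#' one branch, the optimal branch fluxes are uniquely
#' \eqn{v_j = b_j \mu}; with uptake rescaled to each condition's growth
#' rate, the flux ratio through branch j between the reference and
#' alternative condition is \eqn{b_j \mu_1 / (s_j b_j \mu_2)} where
#' \eqn{s_j} is the planted demand multiplier.  The emitted expression
#' values are constructed so that each branch gene's expression ratio
#' equals exactly that flux ratio, giving ground truth for
#' [fitBiomassCoefficients()].
#'
#' @param plantedShift named numeric vector of multiplicative demand changes
#'   (> 0) for biomass metabolites (ids \code{"P1"} ... \code{"P<n>"});
#'   empty for a null model.
#' @param nBranches number of biosynthetic branches (default 6).
#' @param refDoubling,altDoubling doubling times (hours) of the reference
#'   and alternative condition (defaults 7.5 and 24.6).
#' @param uptakeBound default uptake capacity of the substrate exchange
#'   (default 10 mmol/gDW/h).
#' @param seed integer seed (used for the baseline expression levels).
#' @return list with \code{model} (\linkS4class{MetabolicModel}),
#'   \code{ref} and \code{alt} (\linkS4class{ConditionSpec} with expression
#'   maps), \code{deg} (data.frame of the differentially expressed branch
#'   genes), and \code{truth} (data.frame \code{metabolite},
#'   \code{b_original}, \code{multiplier}, \code{class}).
#' @examples
#' toy <- makeToyModel(plantedShift = c(P2 = 2))
#' toy$model
#' @export
makeToyModel <- function(plantedShift = numeric(),
                         nBranches = 6,
                         refDoubling = 7.5,
                         altDoubling = 24.6,
                         uptakeBound = 10,
                         seed = 1) {
    if (length(plantedShift) &&
        (is.null(names(plantedShift)) || any(plantedShift <= 0)))
        stop("plantedShift must be a named vector of positive multipliers")
    prods <- paste0("P", seq_len(nBranches))
    bad <- setdiff(names(plantedShift), prods)
    if (length(bad))
        stop("planted metabolite(s) absent from biomass: ",
             paste(bad, collapse = ", "))
    inters <- paste0("I", seq_len(nBranches))
    mets <- data.frame(id = c("S", "H", inters, prods),
                       compartment = "c")
    b <- setNames(rep_len(c(0.5, 1, 1.5, 0.8, 1.2, 2), nBranches), prods)
    rxns <- c("EX_substrate", "UPT",
              paste0("BRA", seq_len(nBranches)),
              paste0("BRB", seq_len(nBranches)), "BIOMASS")
    stoich <- c(
        list(c(S = -1),                 # exchange: uptake = negative flux
             c(S = -1, H = 1)),
        lapply(seq_len(nBranches), function(j)
            setNames(c(-1, 1), c("H", inters[j]))),
        lapply(seq_len(nBranches), function(j)
            setNames(c(-1, 1), c(inters[j], prods[j]))),
        list(setNames(-b, prods)))
    gpr <- c("", "g_upt",
             paste0("gA", seq_len(nBranches)),
             paste0("gB", seq_len(nBranches)), "")
    model <- metabolicModel(
        metabolites = mets, reactions = rxns, stoichiometry = stoich,
        lb = c(-uptakeBound, rep(0, length(rxns) - 1)),
        ub = rep(1000, length(rxns)),
        gpr = gpr, biomass = "BIOMASS", exchanges = "EX_substrate")

    mu1 <- log(2) / refDoubling
    mu2 <- log(2) / altDoubling
    s <- setNames(rep(1, nBranches), prods)
    s[names(plantedShift)] <- plantedShift
    # branch fluxes at matched growth: v1_j = b_j mu1 ; v2_j = s_j b_j mu2
    ratio <- (b * mu1) / (s * b * mu2)
    set.seed(seed)
    base <- rlnorm(nBranches, log(100), 0.3)
    genes <- c(paste0("gA", seq_len(nBranches)),
               paste0("gB", seq_len(nBranches)), "g_upt")
    m2 <- setNames(c(base, base,
                     100), genes)
    upt_ratio <- (sum(b) * mu1) / (sum(s * b) * mu2)
    m1 <- m2 * c(rep(ratio, 2), upt_ratio)
    ref <- conditionSpec("cond1", "EX_substrate", refDoubling, m1)
    alt <- conditionSpec("cond2", "EX_substrate", altDoubling, m2)
    shifted <- prods[s != 1]
    deg_genes <- c(paste0("gA", match(shifted, prods)),
                   paste0("gB", match(shifted, prods)))
    deg <- data.frame(gene_id = deg_genes,
                      pvalue = rep(1e-4, length(deg_genes)),
                      log2fc = log2(m2[deg_genes] / m1[deg_genes]),
                      row.names = NULL)
    truth <- data.frame(metabolite = prods, b_original = unname(b),
                        multiplier = unname(s),
                        class = ifelse(s > 1, "higher",
                                       ifelse(s < 1, "lower", "unchanged")))
    list(model = model, ref = ref, alt = alt, deg = deg, truth = truth)
}
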