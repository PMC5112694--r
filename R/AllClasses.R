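#' CountMatrix: gene-level read counts with sample metadata
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one assay
#' \code{"counts"} (genes x samples, non-negative), per-gene lengths in
#' \code{rowData()$length} (bases), and the sample map in \code{colData()}
#' with columns \code{condition}, \code{replicate} and (optionally, for
#' transcription-arrest time courses) \code{timepoint_min}.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso [CountMatrix()] for the constructor, [rpkmNormalize()],
#'   [orpkmNormalize()], [poolOperons()].
#' @export
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(!is.finite(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be finite and non-negative")
    }
    if (!"length" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData column 'length' (gene length in bases) is required")
    else if (any(!is.finite(rowData(object)$length)) ||
             any(rowData(object)$length <= 0))
        msg <- c(msg, "gene lengths must be positive")
    need <- c("condition", "replicate")
    if (!all(need %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain 'condition' and 'replicate'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (length(msg)) msg else TRUE
})

#' DecayExperiment: expression time series after transcription arrest
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one assay
#' \code{"rpkm"} (genes x samples) of normalized expression measured at a
#' series of timepoints after transcription was blocked, with
#' \code{colData()} columns \code{timepoint_min} (minutes, strictly positive)
#' and \code{replicate}.  The growth condition label and culture doubling
#' time (hours) live in \code{metadata()} as \code{condition} and
#' \code{doubling_time_h}.  At least four distinct timepoints are required
#' for decay fitting.
#'
#' @seealso [DecayExperiment()] for the constructor, [referenceScale()],
#'   [fitDecay()].
#' @export
setClass("DecayExperiment", contains = "SummarizedExperiment")

setValidity("DecayExperiment", function(object) {
    msg <- character()
    if (!"rpkm" %in% assayNames(object))
        msg <- c(msg, "assay 'rpkm' is required")
    else if (any(assay(object, "rpkm") < 0, na.rm = TRUE))
        msg <- c(msg, "rpkm values must be non-negative")
    need <- c("timepoint_min", "replicate")
    if (!all(need %in% colnames(colData(object)))) {
        msg <- c(msg, "colData must contain 'timepoint_min' and 'replicate'")
    } else {
        tp <- sort(unique(colData(object)$timepoint_min))
        if (any(tp <= 0)) msg <- c(msg, "timepoints must be positive minutes")
        if (length(tp) < 2) msg <- c(msg, "at least two distinct timepoints required")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (length(msg)) msg else TRUE
})

#' MetabolicModel: a constraint-based metabolic network
#'
#' Stoichiometry, flux bounds, gene-protein-reaction (GPR) rules, the biomass
#' reaction and the exchange reaction set of a genome-scale (or toy)
#' metabolic model, as used for flux balance analysis.
#'
#' Exchange reactions are written in the conventional orientation
#' \code{met ->} so that uptake corresponds to negative flux and the uptake
#' capacity is the (negative) lower bound.
#'
#' @slot metabolites DataFrame with columns \code{id}, \code{compartment}.
#' @slot reactions character vector of reaction identifiers.
#' @slot stoichiometry dgCMatrix (metabolites x reactions).
#' @slot lowerBounds,upperBounds numeric flux bounds per reaction.
#' @slot gpr character GPR rule per reaction (\code{""} when none).
#' @slot genes character vector of all genes appearing in GPRs.
#' @slot biomassId identifier of the biomass (objective) reaction.
#' @slot exchanges identifiers of exchange reactions.
#' @seealso [readMetabolicModel()], [fbaSolve()], [biomassCoefficients()].
#' @export
setClass("MetabolicModel",
    representation(
        metabolites = "DataFrame",
        reactions = "character",
        stoichiometry = "Matrix",
        lowerBounds = "numeric",
        upperBounds = "numeric",
        gpr = "character",
        genes = "character",
        biomassId = "character",
        exchanges = "character"))

setValidity("MetabolicModel", function(object) {
    msg <- character()
    n <- length(object@reactions)
    if (ncol(object@stoichiometry) != n)
        msg <- c(msg, "stoichiometry column count must match reactions")
    if (nrow(object@stoichiometry) != nrow(object@metabolites))
        msg <- c(msg, "stoichiometry row count must match metabolites")
    if (length(object@lowerBounds) != n || length(object@upperBounds) != n)
        msg <- c(msg, "bounds must have one entry per reaction")
    if (any(object@lowerBounds > object@upperBounds))
        msg <- c(msg, "lower bound exceeds upper bound")
    if (length(object@gpr) != n)
        msg <- c(msg, "gpr must have one entry per reaction")
    if (!(length(object@biomassId) == 1L && object@biomassId %in% object@reactions))
        msg <- c(msg, "biomassId must name one existing reaction")
    if (!all(object@exchanges %in% object@reactions))
        msg <- c(msg, "unknown exchange reaction id")
    if (anyDuplicated(object@reactions))
        msg <- c(msg, "duplicate reaction identifiers")
    if (anyDuplicated(object@metabolites$id))
        msg <- c(msg, "duplicate metabolite identifiers")
    if (length(msg)) msg else TRUE
})

#' FluxSolution: one flux balance analysis solution
#'
#' @slot fluxes named numeric vector of reaction fluxes (mmol/gDW/h; the
#'   biomass flux is the growth rate in 1/h).
#' @slot objectiveValue optimal objective value.
#' @slot objectiveId identifier of the objective reaction.
#' @slot status solver status: \code{"optimal"}, \code{"infeasible"} or
#'   \code{"unbounded"}.
#' @seealso [fbaSolve()]
#' @export
setClass("FluxSolution",
    representation(
        fluxes = "numeric",
        objectiveValue = "numeric",
        objectiveId = "character",
        status = "character"))

#' ConditionSpec: a growth condition for flux fitting
#'
#' @slot name condition label.
#' @slot substrateExchange identifier of the substrate exchange reaction
#'   whose uptake bound is tuned to reach the measured growth rate.
#' @slot doublingTime culture doubling time in hours.
#' @slot expression named numeric vector of per-gene steady-state expression.
#' @seealso [conditionSpec()], [fitBiomassCoefficients()]
#' @export
setClass("ConditionSpec",
    representation(
        name = "character",
        substrateExchange = "character",
        doublingTime = "numeric",
        expression = "numeric"))

setValidity("ConditionSpec", function(object) {
    msg <- character()
    if (length(object@doublingTime) != 1L || !is.finite(object@doublingTime) ||
        object@doublingTime <= 0)
        msg <- c(msg, "doublingTime must be a positive number of hours")
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (length(msg)) msg else TRUE
})
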