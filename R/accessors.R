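#' @name model-accessors
#' @title Accessors for MetabolicModel and FluxSolution objects
#' @param model a \linkS4class{MetabolicModel}
#' @param x a \linkS4class{FluxSolution}
NULL

#' @describeIn model-accessors reaction identifiers
#' @export
reactionIds <- function(model) model@reactions

#' @describeIn model-accessors metabolite identifiers
#' @export
metaboliteIds <- function(model) model@metabolites$id

#' @describeIn model-accessors dense stoichiometric matrix
#'   (metabolites x reactions)
#' @export
stoichMatrix <- function(model) as.matrix(model@stoichiometry)

#' @describeIn model-accessors data.frame of lower/upper flux bounds
#' @export
fluxBounds <- function(model)
    data.frame(reaction = model@reactions, lb = model@lowerBounds,
               ub = model@upperBounds, row.names = NULL)

#' @describeIn model-accessors id of the biomass (objective) reaction
#' @export
biomassReaction <- function(model) model@biomassId

#' @describeIn model-accessors exchange reaction ids
#' @export
exchangeReactions <- function(model) model@exchanges

#' @describeIn model-accessors GPR rule strings, named by reaction
#' @export
gprRules <- function(model) setNames(model@gpr, model@reactions)

#' @describeIn model-accessors all genes appearing in GPR rules
#' @export
modelGenes <- function(model) model@genes

#' Biomass coefficients of a model
#'
#' The biomass reaction consumes precursor metabolites with stoichiometric
#' coefficients -b_j (mmol per gram dry weight).  This accessor returns the
#' demands as positive numbers b_j, named by metabolite; the sign convention
#' is handled internally.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @return named numeric vector of positive demands.
#' @export
biomassCoefficients <- function(model) {
    col <- model@stoichiometry[, match(model@biomassId, model@reactions)]
    b <- -col[col < 0]
    setNames(as.numeric(b), model@metabolites$id[col < 0])
}

#' Replace one biomass coefficient
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param metabolite metabolite id on the consumption side of the biomass
#'   reaction.
#' @param value new positive demand b_j (mmol/gDW).
#' @return the modified model.
#' @export
setBiomassCoefficient <- function(model, metabolite, value) {
    i <- match(metabolite, model@metabolites$id)
    j <- match(model@biomassId, model@reactions)
    if (is.na(i)) stop("unknown metabolite: ", metabolite)
    if (model@stoichiometry[i, j] >= 0)
        stop("metabolite '", metabolite,
             "' is not consumed by the biomass reaction")
    if (!is.finite(value) || value <= 0)
        stop("biomass coefficient must be positive")
    model@stoichiometry[i, j] <- -value
    model
}

#' Set flux bounds of one reaction
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param reaction reaction id.
#' @param lb,ub new bounds (either may be omitted).
#' @return the modified model.
#' @export
setFluxBounds <- function(model, reaction, lb = NULL, ub = NULL) {
    j <- match(reaction, model@reactions)
    if (is.na(j)) stop("unknown reaction: ", reaction)
    if (!is.null(lb)) model@lowerBounds[j] <- lb
    if (!is.null(ub)) model@upperBounds[j] <- ub
    if (model@lowerBounds[j] > model@upperBounds[j])
        stop("lower bound exceeds upper bound for ", reaction)
    model
}

#' Gene-to-reaction association map
#'
#' A reaction is associated with a gene when the gene appears anywhere in the
#' reaction's GPR rule (set membership; no and/or semantics).
#'
#' @param model a \linkS4class{MetabolicModel}
#' @return named list mapping each gene to the character vector of reaction
#'   ids it is associated with.
#' @export
geneReactionMap <- function(model) {
    per_rxn <- lapply(model@gpr, .gprGenes)
    out <- lapply(setNames(model@genes, model@genes), function(g)
        model@reactions[vapply(per_rxn, function(s) g %in% s, logical(1))])
    out
}

#' Model size report
#'
#' Counts reactions and GPR-associated genes the way genome-scale
#' reconstructions are conventionally described: non-biomass reactions
#' excluding exchanges, the same including exchanges, and the number of
#' distinct genes appearing in GPR rules.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @return list with elements \code{nonBiomassReactions},
#'   \code{withExchanges}, \code{genes}, \code{metabolites},
#'   \code{reactions} (total including biomass).
#' @export
modelStats <- function(model) {
    non_bio <- setdiff(model@reactions, model@biomassId)
    list(nonBiomassReactions = length(setdiff(non_bio, model@exchanges)),
         withExchanges = length(non_bio),
         genes = length(model@genes),
         metabolites = nrow(model@metabolites),
         reactions = length(model@reactions))
}

#' @describeIn model-accessors named flux vector of a solution
#' @export
fluxes <- function(x) x@fluxes

#' @describeIn model-accessors objective value of a solution
#' @export
objectiveValue <- function(x) x@objectiveValue

#' @describeIn model-accessors solver status of a solution
#' @export
solverStatus <- function(x) x@status

setMethod("show", "MetabolicModel", function(object) {
    st <- modelStats(object)
    cat("MetabolicModel with", st$reactions, "reactions (",
        st$nonBiomassReactions, "non-biomass,", st$withExchanges,
        "incl. exchanges ),", st$metabolites, "metabolites,",
        st$genes, "genes\n")
    cat("  biomass:", object@biomassId, "|",
        length(biomassCoefficients(object)), "biomass precursors\n")
})

setMethod("show", "FluxSolution", function(object) {
    cat("FluxSolution (", object@status, "): objective",
        object@objectiveId, "=",
        format(object@objectiveValue, digits = 6), "\n")
    cat(" ", length(object@fluxes), "fluxes;",
        sum(abs(object@fluxes) > 1e-9), "non-zero\n")
})

setMethod("show", "ConditionSpec", function(object) {
    cat("ConditionSpec '", object@name, "': Td = ", object@doublingTime,
        " h (mu = ", format(log(2) / object@doublingTime, digits = 4),
        " /h), substrate exchange ", object@substrateExchange, ", ",
        length(object@expression), " expression values\n", sep = "")
})
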