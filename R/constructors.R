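#' Construct a CountMatrix
#'
#' @param counts integer-like matrix of read counts, genes x samples, with
#'   row and column names.
#' @param length numeric vector of gene lengths in bases (recycled against
#'   rows of \code{counts} by name when named).
#' @param sampleData data.frame (or DataFrame) with one row per sample and at
#'   least columns \code{condition} and \code{replicate};
#'   \code{timepoint_min} is required for decay time courses.
#' @return A \linkS4class{CountMatrix}.
#' @examples
#' cm <- CountMatrix(
#'     counts = matrix(c(10, 20, 30, 40), 2, 2,
#'                     dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'     length = c(g1 = 1000, g2 = 2000),
#'     sampleData = data.frame(condition = c("a", "b"), replicate = c(1, 1)))
#' cm
#' @export
CountMatrix <- function(counts, length, sampleData) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("counts must have gene identifiers as rownames")
    if (!is.null(names(length)))
        length <- length[rownames(counts)]
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(length = as.numeric(length),
                            row.names = rownames(counts)),
        colData = DataFrame(sampleData, row.names = colnames(counts)))
    new("CountMatrix", se)
}

#' Construct a DecayExperiment
#'
#' @param rpkm numeric matrix of normalized expression, genes x samples.
#' @param timepoint numeric vector, minutes after transcription arrest, one
#'   per sample.
#' @param replicate replicate label per sample.
#' @param condition single condition label.
#' @param doublingTime culture doubling time in hours (optional, used by
#'   [scaleByDoubling()]).
#' @return A \linkS4class{DecayExperiment}.
#' @export
DecayExperiment <- function(rpkm, timepoint, replicate,
                            condition = NA_character_,
                            doublingTime = NA_real_) {
    rpkm <- as.matrix(rpkm)
    if (is.null(colnames(rpkm)))
        colnames(rpkm) <- paste0("t", timepoint, "_r", replicate)
    se <- SummarizedExperiment(
        assays = list(rpkm = rpkm),
        colData = DataFrame(timepoint_min = as.numeric(timepoint),
                            replicate = replicate,
                            row.names = colnames(rpkm)))
    metadata(se)$condition <- condition
    metadata(se)$doubling_time_h <- doublingTime
    new("DecayExperiment", se)
}

#' Construct a ConditionSpec
#'
#' @param name condition label (e.g. \code{"methanol"}).
#' @param substrateExchange exchange reaction id of the growth substrate.
#' @param doublingTime doubling time in hours; the growth rate is
#'   \code{log(2)/doublingTime} per hour.
#' @param expression named numeric vector of per-gene expression.
#' @return A \linkS4class{ConditionSpec}.
#' @export
conditionSpec <- function(name, substrateExchange, doublingTime,
                          expression = numeric()) {
    new("ConditionSpec", name = name, substrateExchange = substrateExchange,
        doublingTime = as.numeric(doublingTime),
        expression = expression)
}

#' @describeIn conditionSpec Growth rate (1/h) implied by the doubling time.
#' @param x a \code{ConditionSpec}
#' @export
growthRate <- function(x) log(2) / x@doublingTime

#' Assemble a MetabolicModel from parts
#'
#' Low-level constructor; most users will call [readMetabolicModel()] or
#' [makeToyModel()].
#'
#' @param metabolites data.frame with columns \code{id} and
#'   \code{compartment}.
#' @param reactions character vector of reaction ids.
#' @param stoichiometry list (per reaction) of named numeric vectors, or a
#'   metabolites x reactions matrix.
#' @param lb,ub numeric bounds per reaction.
#' @param gpr character GPR rule per reaction (\code{""} for none).
#' @param biomass id of the biomass reaction.
#' @param exchanges character vector of exchange reaction ids.
#' @return A \linkS4class{MetabolicModel}.
#' @export
metabolicModel <- function(metabolites, reactions, stoichiometry, lb, ub,
                           gpr = rep("", length(reactions)),
                           biomass, exchanges = character()) {
    metabolites <- DataFrame(metabolites)
    if (is.list(stoichiometry) && !is.matrix(stoichiometry)) {
        S <- Matrix::Matrix(0, nrow = nrow(metabolites),
                            ncol = length(reactions), sparse = TRUE,
                            dimnames = list(metabolites$id, reactions))
        for (j in seq_along(reactions)) {
            st <- stoichiometry[[j]]
            bad <- setdiff(names(st), metabolites$id)
            if (length(bad))
                stop("reaction '", reactions[j],
                     "' references unknown metabolite(s): ",
                     paste(bad, collapse = ", "))
            S[names(st), j] <- as.numeric(st)
        }
    } else {
        S <- Matrix::Matrix(as.matrix(stoichiometry), sparse = TRUE,
                            dimnames = list(metabolites$id, reactions))
    }
    genes <- sort(unique(unlist(lapply(gpr, .gprGenes))))
    new("MetabolicModel", metabolites = metabolites, reactions = reactions,
        stoichiometry = methods::as(S, "CsparseMatrix"),
        lowerBounds = as.numeric(lb),
        upperBounds = as.numeric(ub), gpr = gpr, genes = genes,
        biomassId = biomass, exchanges = exchanges)
}

# Tokens of a GPR string that are gene identifiers.
.gprGenes <- function(rule) {
    if (is.na(rule) || !nzchar(rule)) return(character())
    tok <- strsplit(gsub("[()]", " ", rule), "[[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    setdiff(tok, c("and", "or", "AND", "OR", "&", "|"))
}
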