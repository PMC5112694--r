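# Fluxes below this magnitude are treated as numerically zero when forming
# flux ratios; see the methods vignette for the rationale.
.FLUXEPS <- 1e-9

.fluxVec <- function(v) {
    if (is(v, "FluxSolution")) fluxes(v) else v
}

# clamp a flux away from zero, preserving sign (sign(0) -> +1)
.clampFlux <- function(x, eps = .FLUXEPS) {
    s <- ifelse(x < 0, -1, 1)
    s * pmax(abs(x), eps)
}

#' Deviation of flux ratios from expression ratios
#'
#' The fitting score for expression-constrained biomass adjustment: the sum,
#' over differentially expressed genes i and the reactions r associated with
#' each, of \eqn{| v_{1,r}/v_{2,r} - m_{1,i}/m_{2,i} |}, where condition 1
#' is the reference.  Fluxes with magnitude below \code{eps} are replaced by
#' \code{eps} (sign preserved); gene-reaction pairs in which both condition
#' fluxes are below \code{eps} are skipped, since their ratio is undefined
#' and including them would reward degenerate solutions.
#'
#' @param v1,v2 \linkS4class{FluxSolution} objects or named flux vectors for
#'   the reference and alternative condition.
#' @param m1,m2 named expression vectors.
#' @param degSet character vector of differentially expressed gene ids.
#' @param geneReactions named list mapping genes to associated reaction ids
#'   (see [geneReactionMap()]).
#' @param eps zero-flux threshold (default 1e-9).
#' @return non-negative score (0 means a perfect match; empty
#'   \code{degSet} scores 0).
#' @export
expressionFluxObjective <- function(v1, v2, m1, m2, degSet, geneReactions,
                                    eps = .FLUXEPS) {
    v1 <- .fluxVec(v1); v2 <- .fluxVec(v2)
    if (!length(degSet)) return(0)
    miss <- setdiff(degSet, intersect(names(m1), names(m2)))
    if (length(miss))
        stop("gene(s) in DEG set without expression values: ",
             paste(miss, collapse = ", "))
    score <- 0
    for (g in degSet) {
        rxns <- intersect(geneReactions[[g]], names(v1))
        if (!length(rxns)) next
        f1 <- v1[rxns]; f2 <- v2[rxns]
        keep <- !(abs(f1) < eps & abs(f2) < eps)
        if (!any(keep)) next
        score <- score +
            sum(abs(.clampFlux(f1[keep], eps) / .clampFlux(f2[keep], eps) -
                    m1[g] / m2[g]))
    }
    unname(score)
}

#' Fit biomass coefficients to expression ratios between two conditions
#'
#' Implements expression-constrained refitting of the biomass composition.
#' The reference condition keeps the model's original biomass reaction; for
#' the alternative condition each biomass coefficient is allowed to change
#' so that predicted flux ratios between the conditions track measured
#' expression ratios of differentially expressed (DE) genes.
#'
#' The procedure: the biomass coefficients are put in random order; swept in
#' that order, each coefficient is optimized over a one-dimensional
#' multiplicative candidate grid (default \eqn{b_j \times 2^{-3} \ldots
#' 2^{3}}, 25 log2-spaced points).  Every candidate re-tunes the substrate
#' uptake so the alternative condition reaches its measured growth rate
#' ([matchGrowth()]), re-solves the flux distribution parsimoniously, and
#' evaluates [expressionFluxObjective()]; the arg-min is kept (ties broken
#' toward the smallest change from the original coefficient, so an
#' uninformative coefficient stays put), and the sweep proceeds.  The whole
#' sweep is repeated for \code{nOrderings} random orderings; the per-ordering
#' final coefficient vectors form the sample from which each metabolite's
#' mean, SD and a two-sided one-sample t-test against the original
#' coefficient are computed.  Infeasible candidates are discarded; if every
#' candidate for a coefficient is infeasible it is left at its original
#' value and flagged.
#'
#' @param model a \linkS4class{MetabolicModel} (reference biomass).
#' @param ref,alt \linkS4class{ConditionSpec} for the reference and
#'   alternative condition (growth rates \code{log(2)/doublingTime};
#'   expression maps used for the ratios).
#' @param deg data.frame with column \code{gene_id} (e.g. from
#'   [consensusDEG()], consensus rows) naming the DE genes; genes without a
#'   GPR association are ignored.
#' @param nOrderings number of random coefficient orderings (default 96).
#' @param grid multiplicative candidate factors (default
#'   \code{2^seq(-3, 3, length.out = 25)}).
#' @param alpha significance level of the t-test (default 0.01).
#' @param seed integer seed for the orderings.
#' @param maxUptake forwarded to [matchGrowth()].
#' @return data.frame with one row per biomass metabolite: \code{metabolite},
#'   \code{b_orig}, \code{b_mean}, \code{b_sd}, \code{pvalue}, \code{class}
#'   (\code{higher}/\code{lower}/\code{unchanged}), \code{all_infeasible};
#'   the per-ordering fitted vectors are attached as
#'   \code{attr(, "samples")} and the final per-ordering scores as
#'   \code{attr(, "scores")}.
#' @export
fitBiomassCoefficients <- function(model, ref, alt, deg,
                                   nOrderings = 96,
                                   grid = 2^seq(-3, 3, length.out = 25),
                                   alpha = 0.01, seed = 1,
                                   maxUptake = 1000) {
    stopifnot(is(model, "MetabolicModel"), is(ref, "ConditionSpec"),
              is(alt, "ConditionSpec"))
    if (!1 %in% grid)
        grid <- sort(c(1, grid))
    b_orig <- biomassCoefficients(model)
    mets <- names(b_orig)
    mu1 <- growthRate(ref); mu2 <- growthRate(alt)
    degGenes <- intersect(unique(deg$gene_id), modelGenes(model))
    grmap <- geneReactionMap(model)[degGenes]
    m1 <- ref@expression; m2 <- alt@expression
    if (length(degGenes)) {
        miss <- setdiff(degGenes, intersect(names(m1), names(m2)))
        if (length(miss))
            stop("DE gene(s) missing expression values: ",
                 paste(miss, collapse = ", "))
    }
    v1 <- matchGrowth(model, ref@substrateExchange, mu1,
                      maxUptake = maxUptake)$solution
    if (solverStatus(v1) != "optimal")
        stop("reference condition infeasible at its growth rate")
    # precomputed evaluator for the alternative condition: maps a biomass
    # stoichiometry column to growth-matched parsimonious fluxes
    S <- as.matrix(model@stoichiometry)
    rxn_ids <- model@reactions
    jBio <- match(model@biomassId, rxn_ids)
    jEx <- match(alt@substrateExchange, rxn_ids)
    if (is.na(jEx)) stop("unknown exchange reaction: ",
                         alt@substrateExchange)
    lbA <- model@lowerBounds
    lbA[jEx] <- -maxUptake
    evalFlux <- .makeFluxEvaluator(S, lbA, model@upperBounds, jBio, mu2)
    met_rows <- match(mets, model@metabolites$id)
    bioColFor <- function(bvec) {
        col <- S[, jBio]
        col[met_rows] <- -bvec
        col
    }
    scoreFor <- function(v2) {
        names(v2) <- rxn_ids
        expressionFluxObjective(v1, v2, m1, m2, degGenes, grmap)
    }
    # candidate order for tie-breaking: smallest |log2 factor| first
    cand_order <- order(abs(log2(grid)))
    set.seed(seed)
    samples <- matrix(NA_real_, nOrderings, length(mets),
                      dimnames = list(NULL, mets))
    scores <- numeric(nOrderings)
    infeasible_flag <- setNames(rep(FALSE, length(mets)), mets)
    for (o in seq_len(nOrderings)) {
        perm <- sample(mets)
        bcur <- b_orig
        best_score <- NA_real_
        for (met in perm) {
            cand_scores <- rep(NA_real_, length(grid))
            for (ci in cand_order) {
                bc <- bcur
                bc[met] <- b_orig[met] * grid[ci]
                v2 <- evalFlux(bioColFor(bc))
                if (is.null(v2)) next
                cand_scores[ci] <- scoreFor(v2)
            }
            if (all(is.na(cand_scores))) {
                infeasible_flag[met] <- TRUE
                next
            }
            best <- min(cand_scores, na.rm = TRUE)
            pick <- cand_order[which(!is.na(cand_scores[cand_order]) &
                                     cand_scores[cand_order] <=
                                         best + 1e-9)[1]]
            bcur[met] <- b_orig[met] * grid[pick]
            best_score <- cand_scores[pick]
        }
        samples[o, ] <- bcur
        scores[o] <- if (is.na(best_score)) 0 else best_score
    }
    out <- do.call(rbind, lapply(mets, function(met) {
        xs <- samples[, met]
        mu <- mean(xs); s <- sd(xs)
        p <- if (s == 0) {
            if (mu == b_orig[met]) 1 else 0
        } else t.test(xs, mu = b_orig[met])$p.value
        cls <- if (p < alpha && mu > b_orig[met]) "higher"
               else if (p < alpha && mu < b_orig[met]) "lower"
               else "unchanged"
        data.frame(metabolite = met, b_orig = unname(b_orig[met]),
                   b_mean = mu, b_sd = s, pvalue = p, class = cls,
                   all_infeasible = unname(infeasible_flag[met]))
    }))
    rownames(out) <- NULL
    attr(out, "samples") <- samples
    attr(out, "scores") <- scores
    out
}

#' Classify per-reaction flux changes between two conditions
#'
#' A reaction carries more flux in condition 2 when
#' \eqn{|v_2|/|v_1| >} \code{threshold} (default 2-fold), more in
#' condition 1 when the inverse ratio exceeds the threshold, and is
#' unchanged otherwise.  Flux magnitudes below \code{eps} are treated as
#' \code{eps}, so a reaction switching off (flux 0) counts as a fold change.
#'
#' @param v1,v2 \linkS4class{FluxSolution} objects or named flux vectors.
#' @param threshold fold-change threshold (default 2).
#' @param eps zero-flux floor (default 1e-9).
#' @return data.frame with \code{reaction}, \code{flux_cond1},
#'   \code{flux_cond2}, \code{class} in
#'   \code{c("higher_in_1", "higher_in_2", "unchanged")}.
#' @export
classifyFluxChanges <- function(v1, v2, threshold = 2, eps = .FLUXEPS) {
    v1 <- .fluxVec(v1); v2 <- .fluxVec(v2)
    rxns <- intersect(names(v1), names(v2))
    a1 <- pmax(abs(v1[rxns]), eps)
    a2 <- pmax(abs(v2[rxns]), eps)
    cls <- ifelse(a2 / a1 > threshold, "higher_in_2",
                  ifelse(a1 / a2 > threshold, "higher_in_1", "unchanged"))
    data.frame(reaction = rxns, flux_cond1 = unname(v1[rxns]),
               flux_cond2 = unname(v2[rxns]), class = unname(cls),
               row.names = NULL)
}

#' Paired flux and expression log-ratios with their correlation
#'
#' For each supplied gene-reaction pair, emits the flux log-ratio
#' \eqn{\ln(v_1/v_2)} (magnitudes, floored at \code{eps}) and the expression
#' log-ratio \eqn{\ln(m_1/m_2)}, plus the Pearson correlation across pairs.
#' Pairs with missing or non-positive expression are excluded.
#'
#' @param v1,v2 \linkS4class{FluxSolution} objects or named flux vectors.
#' @param m1,m2 named expression vectors.
#' @param pairs data.frame with columns \code{gene_id} and \code{reaction}.
#' @param eps zero-flux floor (default 1e-9).
#' @return list with \code{pairs} (data.frame \code{gene_id},
#'   \code{reaction}, \code{log_flux_ratio}, \code{log_expr_ratio}) and
#'   \code{r} (Pearson; \code{NA} when degenerate, e.g. all flux ratios
#'   identical).
#' @export
fluxExpressionCorrelation <- function(v1, v2, m1, m2, pairs,
                                      eps = .FLUXEPS) {
    v1 <- .fluxVec(v1); v2 <- .fluxVec(v2)
    stopifnot(all(c("gene_id", "reaction") %in% colnames(pairs)))
    ok <- pairs$reaction %in% intersect(names(v1), names(v2)) &
        pairs$gene_id %in% intersect(names(m1), names(m2))
    pairs <- pairs[ok, , drop = FALSE]
    e1 <- m1[pairs$gene_id]; e2 <- m2[pairs$gene_id]
    keep <- is.finite(e1) & e1 > 0 & is.finite(e2) & e2 > 0
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) stop("no valid gene-reaction pairs")
    lfr <- log(pmax(abs(v1[pairs$reaction]), eps) /
               pmax(abs(v2[pairs$reaction]), eps))
    ler <- log(e1[keep] / e2[keep])
    r <- if (sd(lfr) == 0 || sd(ler) == 0) NA_real_ else cor(lfr, ler)
    list(pairs = data.frame(gene_id = pairs$gene_id,
                            reaction = pairs$reaction,
                            log_flux_ratio = unname(lfr),
                            log_expr_ratio = unname(ler),
                            row.names = NULL),
         r = r)
}
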