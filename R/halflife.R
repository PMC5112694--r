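#' Reference-gene rescaling of a decay time course
#'
#' Corrects a transcription-arrest time course for global per-timepoint
#' drift (e.g. residual transcription, library-size artifacts) by anchoring
#' a designated highly stable reference gene to a known half-life.  The
#' replicate-mean trajectory of the reference gene is forced onto an exact
#' exponential with half-life \code{referenceHalflife}: every sample at
#' timepoint t is multiplied by
#' \deqn{f(t) = \bar R_{ref}(t_1) 2^{-(t - t_1)/\tau_{ref}} / \bar R_{ref}(t),}
#' where \eqn{t_1} is the first measured timepoint, treated as the decay
#' origin (configurable through \code{timeOffset}).  After rescaling, fitting
#' the reference gene returns exactly the reference half-life.  The operation
#' is idempotent.
#'
#' @param series a \linkS4class{DecayExperiment}.
#' @param referenceGene identifier of the reference gene; it must have a
#'   positive replicate-mean value at every timepoint.
#' @param referenceHalflife assigned half-life of the reference gene in
#'   minutes (default 120, i.e. two hours).
#' @return the rescaled \linkS4class{DecayExperiment}; the correction factors
#'   are recorded in \code{metadata()$reference_correction}.
#' @export
referenceScale <- function(series, referenceGene, referenceHalflife = 120) {
    stopifnot(is(series, "DecayExperiment"))
    if (!referenceGene %in% rownames(series))
        stop("reference gene '", referenceGene, "' not present")
    if (referenceHalflife <= 0) stop("referenceHalflife must be positive")
    x <- assay(series, "rpkm")
    tp <- colData(series)$timepoint_min
    upt <- sort(unique(tp))
    ref_mean <- vapply(upt, function(t) mean(x[referenceGene, tp == t]),
                       numeric(1))
    if (any(!is.finite(ref_mean)) || any(ref_mean <= 0))
        stop("reference gene has non-positive mean at timepoint(s) ",
             paste(upt[ref_mean <= 0], collapse = ", "))
    target <- ref_mean[1] * 2^(-(upt - upt[1]) / referenceHalflife)
    f <- target / ref_mean
    x <- sweep(x, 2, f[match(tp, upt)], "*")
    assay(series, "rpkm") <- x
    metadata(series)$reference_correction <-
        data.frame(timepoint_min = upt, factor = f)
    metadata(series)$reference_gene <- referenceGene
    metadata(series)$reference_halflife_min <- referenceHalflife
    series
}

#' Fit first-order decay to every gene of a time course
#'
#' Each gene's trajectory after transcription arrest is modeled as
#' first-order exponential decay, \eqn{R(t) = R_0 e^{-k t}}, with the
#' half-life \eqn{\tau = \ln 2 / k}.  By default \eqn{R_0} is fixed to the
#' replicate-mean expression at the first timepoint (the decay origin) and
#' only the decay rate k is estimated, by Levenberg-Marquardt nonlinear least
#' squares on the untransformed scale with all replicates entering as pooled
#' points (so the standard error of k reflects replicate scatter).  Setting
#' \code{freeR0 = TRUE} fits a two-parameter model with \eqn{R_0} free.
#'
#' The reported \code{cv} is \code{se_k / k}, the relative uncertainty of the
#' decay rate; because \eqn{\tau = \ln 2/k}, the relative uncertainty of the
#' half-life is the identical number.  \code{fit_pvalue} is the two-sided
#' p-value of the t-statistic \code{k/se_k} (no decay as null).  A record
#' passes QC when \code{k > 0} and \code{cv < 0.5}.
#'
#' @param series a \linkS4class{DecayExperiment} with at least four distinct
#'   timepoints.
#' @param freeR0 logical; also estimate \eqn{R_0} (default \code{FALSE}).
#' @param cvMax QC threshold on \code{cv} (default 0.5).
#' @return data.frame with one row per gene and columns \code{gene_id},
#'   \code{k_per_min}, \code{tau_min}, \code{R0}, \code{se_k}, \code{cv},
#'   \code{fit_pvalue}, \code{df_resid}, \code{qc_pass}.  Genes that cannot
#'   be fit (all-zero series, degenerate data) get \code{NA} estimates and
#'   \code{qc_pass = FALSE}.
#' @examples
#' tp <- c(5, 10, 20, 30, 60, 120, 240)
#' de <- DecayExperiment(rbind(g1 = 100 * 2^(-(tp - 5) / 120)), tp,
#'                       replicate = rep(1, 7))
#' fitDecay(de)$tau_min  # 120
#' @export
fitDecay <- function(series, freeR0 = FALSE, cvMax = 0.5) {
    stopifnot(is(series, "DecayExperiment"))
    x <- assay(series, "rpkm")
    tp <- colData(series)$timepoint_min
    upt <- sort(unique(tp))
    if (length(upt) < 4)
        stop("decay fitting requires at least 4 distinct timepoints")
    tshift <- tp - upt[1]
    first <- tp == upt[1]
    res <- lapply(rownames(x), function(g)
        .fitDecayOne(as.numeric(x[g, ]), tshift, mean(x[g, first]), freeR0))
    out <- do.call(rbind, res)
    out <- data.frame(gene_id = rownames(x), out, row.names = NULL)
    out$qc_pass <- !is.na(out$k_per_min) & out$k_per_min > 0 &
        !is.na(out$cv) & out$cv < cvMax
    out
}

.fitDecayOne <- function(y, t, R0, freeR0) {
    empty <- data.frame(k_per_min = NA_real_, tau_min = NA_real_,
                        R0 = NA_real_, se_k = NA_real_, cv = NA_real_,
                        fit_pvalue = NA_real_, df_resid = NA_real_)
    ok <- is.finite(y)
    y <- y[ok]; t <- t[ok]
    if (length(y) < 4 || all(y == 0) || !is.finite(R0) || (!freeR0 && R0 <= 0))
        return(empty)
    # log-linear start value (positive values only)
    pos <- y > 0
    k0 <- if (sum(pos) >= 2) {
        sl <- -unname(stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2])
        if (is.finite(sl) && sl != 0) sl else 1e-3
    } else 1e-3
    par <- if (freeR0) list(A = max(R0, max(y), 1e-8), k = k0)
           else list(k = k0)
    fn <- if (freeR0) function(p) y - p$A * exp(-p$k * t)
          else function(p) y - R0 * exp(-p$k * t)
    out <- tryCatch(
        minpack.lm::nls.lm(par, fn = fn,
                           control = minpack.lm::nls.lm.control(
                               maxiter = 200)),
        error = function(e) NULL)
    if (is.null(out)) return(empty)
    k <- out$par$k
    dfres <- length(y) - length(par)
    sigma2 <- sum(out$fvec^2) / dfres
    # analytic Jacobian of the residuals at the optimum for the covariance
    A_hat <- if (freeR0) out$par$A else R0
    J <- cbind(k = A_hat * t * exp(-k * t))
    if (freeR0) J <- cbind(A = -exp(-k * t), J)
    covm <- tryCatch(solve(crossprod(J)) * sigma2,
                     error = function(e) NULL)
    if (is.null(covm) || any(!is.finite(diag(covm)))) return(empty)
    se <- sqrt(covm["k", "k"])
    pval <- 2 * stats::pt(-abs(k / se), df = dfres)
    data.frame(k_per_min = k, tau_min = log(2) / k,
               R0 = if (freeR0) out$par$A else R0,
               se_k = se, cv = se / k, fit_pvalue = pval, df_resid = dfres)
}

#' Quality-control filter on decay fits
#'
#' Retains exactly those records with a positive decay rate and a
#' coefficient of variation of the fit below \code{cvMax}; genes with
#' negative half-life or large fitting residual are removed.
#'
#' @param records data.frame from [fitDecay()].
#' @param cvMax maximum allowed \code{se_k/k} (default 0.5).
#' @return the retained subset (always a subset of the input).
#' @export
qcFilter <- function(records, cvMax = 0.5) {
    stopifnot(all(c("k_per_min", "cv") %in% colnames(records)))
    keep <- !is.na(records$k_per_min) & records$k_per_min > 0 &
        !is.na(records$cv) & records$cv < cvMax
    records[keep, , drop = FALSE]
}

#' Half-lives as a fraction of the cell cycle
#'
#' Divides each half-life by the culture doubling time, giving the fraction
#' of a cell cycle that a transcript persists.  The summary mean is reported
#' with the inverse-variance weighted standard deviation.
#'
#' @param records QC-passing data.frame from [fitDecay()].
#' @param doublingTime doubling time in hours.
#' @return list with \code{fractions} (per-gene data.frame), \code{mean}, and
#'   \code{weightedSD}.
#' @export
scaleByDoubling <- function(records, doublingTime) {
    if (!is.finite(doublingTime) || doublingTime <= 0)
        stop("doublingTime must be positive hours")
    td_min <- doublingTime * 60
    frac <- records$tau_min / td_min
    se_tau <- log(2) * records$se_k / records$k_per_min^2
    w <- 1 / (se_tau / td_min)^2
    mu <- mean(frac)
    wsd <- sqrt(sum(w * (frac - mu)^2) / sum(w))
    list(fractions = data.frame(gene_id = records$gene_id, fraction = frac),
         mean = mu, weightedSD = wsd)
}

#' Classify per-gene half-life shifts between two conditions
#'
#' For genes passing QC in both conditions, a two-sided t statistic is
#' formed from the half-life difference and the propagated standard errors
#' (\eqn{se_\tau = \ln 2 \, se_k / k^2}), with Welch-Satterthwaite degrees
#' of freedom from the two fits.  A gene is called \code{"longer"} when the
#' second condition's half-life is significantly larger, \code{"shorter"}
#' when significantly smaller, and \code{"no_change"} otherwise
#' (p > \code{alpha}).
#'
#' @param recordsA,recordsB data.frames from [fitDecay()] for the first and
#'   second condition.
#' @param alpha significance level (default 0.01).
#' @return data.frame with columns \code{gene_id}, \code{tau_a},
#'   \code{tau_b}, \code{statistic}, \code{pvalue}, \code{class}.
#' @export
classifyShift <- function(recordsA, recordsB, alpha = 0.01) {
    a <- qcFilter(recordsA); b <- qcFilter(recordsB)
    genes <- intersect(a$gene_id, b$gene_id)
    if (!length(genes)) stop("no genes pass QC in both conditions")
    a <- a[match(genes, a$gene_id), ]
    b <- b[match(genes, b$gene_id), ]
    se_a <- log(2) * a$se_k / a$k_per_min^2
    se_b <- log(2) * b$se_k / b$k_per_min^2
    d <- b$tau_min - a$tau_min
    se <- sqrt(se_a^2 + se_b^2)
    tstat <- d / se
    df <- (se_a^2 + se_b^2)^2 /
        (se_a^4 / a$df_resid + se_b^4 / b$df_resid)
    p <- 2 * stats::pt(-abs(tstat), df = df)
    p[d == 0] <- 1
    cls <- ifelse(p > alpha, "no_change",
                  ifelse(d > 0, "longer", "shorter"))
    data.frame(gene_id = genes, tau_a = a$tau_min, tau_b = b$tau_min,
               statistic = tstat, pvalue = p, class = cls)
}

#' Genes with unchanged half-life across all pairwise comparisons
#'
#' The unregulated "core" set: genes called \code{no_change} in every
#' supplied pairwise shift classification.
#'
#' @param ... data.frames from [classifyShift()].
#' @return character vector of gene ids.
#' @export
coreUnregulated <- function(...) {
    shifts <- list(...)
    stopifnot(length(shifts) >= 1)
    sets <- lapply(shifts, function(s) s$gene_id[s$class == "no_change"])
    Reduce(intersect, sets)
}

#' Compare two half-life distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the half-life values,
#' exact for small samples (both n <= 8, no ties) and mid-rank/normal
#' approximation otherwise.
#'
#' @param recordsA,recordsB data.frames from [fitDecay()] (QC applied
#'   internally), or bare numeric vectors of half-lives.
#' @return list with \code{statistic} (rank-sum U) and \code{pvalue}.
#' @export
compareDistributions <- function(recordsA, recordsB) {
    tau_a <- if (is.data.frame(recordsA)) qcFilter(recordsA)$tau_min else recordsA
    tau_b <- if (is.data.frame(recordsB)) qcFilter(recordsB)$tau_min else recordsB
    if (!length(tau_a) || !length(tau_b)) stop("empty half-life set")
    exact <- max(length(tau_a), length(tau_b)) <= 8
    wt <- suppressWarnings(
        stats::wilcox.test(tau_a, tau_b, exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), pvalue = wt$p.value)
}

#' Summarize half-lives by functional category
#'
#' Median half-life per category (e.g. COG class) with inverse-variance
#' weighted standard deviation (weights \eqn{1/se_\tau^2}).  Genes without an
#' annotation are assigned \code{"unclassified"}.
#'
#' @param records data.frame from [fitDecay()] (QC-passing rows are used).
#' @param annotation named character vector mapping gene id to category.
#' @return data.frame with columns \code{category}, \code{n},
#'   \code{median_tau}, \code{weighted_sd}.
#' @export
summarizeByCategory <- function(records, annotation) {
    r <- qcFilter(records)
    cat_ <- annotation[r$gene_id]
    cat_[is.na(cat_)] <- "unclassified"
    se_tau <- log(2) * r$se_k / r$k_per_min^2
    sp <- split(seq_len(nrow(r)), cat_)
    out <- lapply(names(sp), function(cc) {
        i <- sp[[cc]]
        tau <- r$tau_min[i]
        w <- 1 / se_tau[i]^2
        mu <- mean(tau)
        data.frame(category = cc, n = length(i), median_tau = median(tau),
                   weighted_sd = sqrt(sum(w * (tau - mu)^2) / sum(w)))
    })
    do.call(rbind, out)
}
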