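#' Steady-state transcription rate
#'
#' At steady state the synthesis rate of a transcript balances its removal:
#' \code{k_trn = (gamma + mu) * m}, where \code{gamma} is the first-order
#' degradation rate (per minute), \code{m} the steady-state abundance and
#' \code{mu} an optional dilution rate from growth.  Dilution is neglected by
#' default because fitted decay rates dominate it here (shortest doubling
#' time 450 min against mean half-lives well below that).
#'
#' @param m steady-state expression (RPKM or copies per cell), >= 0.
#' @param gamma per-minute degradation rate, > 0.
#' @param mu optional per-minute dilution rate added to \code{gamma}
#'   (default 0); use \code{log(2) / (doubling_time_h * 60)}.
#' @return per-minute synthesis rate, same units as \code{m} per minute.
#' @export
transcriptionRate <- function(m, gamma, mu = 0) {
    if (any(!is.finite(gamma)) || any(gamma <= 0))
        stop("gamma must be positive")
    if (any(m < 0, na.rm = TRUE)) stop("m must be non-negative")
    (gamma + mu) * m
}

#' Absolute transcript copies per cell
#'
#' Distributes a known total mRNA pool over genes proportionally to their
#' relative expression: \code{copies = rpkm / sum(rpkm) * total}.
#'
#' @param rpkm named numeric vector of expression values for the whole
#'   transcriptome.
#' @param totalPerCell total mRNA copies per cell (a required, user-supplied
#'   constant).
#' @return named numeric vector of copies per cell (sums to
#'   \code{totalPerCell}).
#' @export
copiesPerCell <- function(rpkm, totalPerCell) {
    if (!is.finite(totalPerCell) || totalPerCell <= 0)
        stop("totalPerCell must be positive")
    tot <- sum(rpkm)
    if (!is.finite(tot) || tot <= 0) stop("total expression is zero")
    rpkm / tot * totalPerCell
}

#' Transcriptional and degradational control coefficients
#'
#' For a gene whose steady-state abundance changes from \code{m1} to
#' \code{m2} while its degradation rate changes from \code{gamma1} to
#' \code{gamma2}, the finite-difference control coefficients are
#' \deqn{\rho_D = -\ln(\gamma_2/\gamma_1) / \ln(m_2/m_1), \qquad
#'       \rho_T = \ln(k_{trn,2}/k_{trn,1}) / \ln(m_2/m_1),}
#' with \eqn{k_{trn} = \gamma m} (steady state).  They satisfy
#' \eqn{\rho_T + \rho_D = 1} whenever defined.  \eqn{\rho_D \ge 1} means the
#' abundance change is driven by degradation, \eqn{\rho_D \le 0} by
#' transcription, values in between by both.  Genes with
#' \eqn{|\ln(m_2/m_1)|} below \code{tol} are returned as indeterminate
#' (\code{NA}) rather than producing exploding coefficients.
#'
#' @param m1,m2 positive expression levels in the two conditions (vectors
#'   allowed).  Because only ratios enter, any proportional expression scale
#'   (RPKM, copies per cell) gives identical coefficients.
#' @param gamma1,gamma2 positive degradation rates (per minute).
#' @param tol indeterminacy threshold on \eqn{|\ln(m_2/m_1)|}
#'   (default 1e-6).
#' @return data.frame with columns \code{rho_T}, \code{rho_D},
#'   \code{determinate}.
#' @examples
#' controlCoefficients(1, 2, 1, 1)      # abundance doubled, gamma fixed:
#'                                      # purely transcriptional
#' controlCoefficients(1, 2, 1, 0.5)    # k_trn fixed: purely degradational
#' @export
controlCoefficients <- function(m1, m2, gamma1, gamma2, tol = 1e-6) {
    n <- max(length(m1), length(m2), length(gamma1), length(gamma2))
    m1 <- rep_len(m1, n); m2 <- rep_len(m2, n)
    gamma1 <- rep_len(gamma1, n); gamma2 <- rep_len(gamma2, n)
    if (any(c(m1, m2, gamma1, gamma2) <= 0, na.rm = TRUE))
        stop("m and gamma must be positive")
    dlm <- log(m2 / m1)
    det <- is.finite(dlm) & abs(dlm) >= tol
    rho_D <- rho_T <- rep(NA_real_, n)
    rho_D[det] <- -log(gamma2[det] / gamma1[det]) / dlm[det]
    rho_T[det] <- log((gamma2[det] * m2[det]) /
                      (gamma1[det] * m1[det])) / dlm[det]
    data.frame(rho_T = rho_T, rho_D = rho_D, determinate = det)
}

#' Classify the regulatory regime from rho_D
#'
#' Thresholds: \code{rho_D >= 1} is degradationally controlled,
#' \code{rho_D <= 0} transcriptionally controlled, values strictly between 0
#' and 1 are shared control.  \code{NA} (indeterminate input, e.g. half-life
#' QC failure) passes through as \code{"indeterminate"}.
#'
#' Values within \code{boundaryTol} of the regime boundaries 0 and 1 are
#' snapped onto them first: the finite-difference coefficients carry
#' floating-point error of a few ulp, and a gene whose degradation-rate
#' ratio exactly mirrors its abundance ratio must classify as
#' degradational, not drift into "shared" by 1e-16.
#'
#' @param rhoD numeric vector of degradational control coefficients.
#' @param boundaryTol snap distance to the boundaries (default 1e-9).
#' @return character vector in
#'   \code{c("transcriptional", "shared", "degradational", "indeterminate")}.
#' @export
classifyRegime <- function(rhoD, boundaryTol = 1e-9) {
    rhoD[!is.na(rhoD) & abs(rhoD - 1) < boundaryTol] <- 1
    rhoD[!is.na(rhoD) & abs(rhoD) < boundaryTol] <- 0
    out <- rep("indeterminate", length(rhoD))
    det <- !is.na(rhoD)
    out[det & rhoD >= 1] <- "degradational"
    out[det & rhoD <= 0] <- "transcriptional"
    out[det & rhoD > 0 & rhoD < 1] <- "shared"
    out
}

#' Per-gene control analysis between two conditions
#'
#' Joins half-life fits and steady-state expression for a condition pair and
#' computes degradation rates, transcription rates, control coefficients and
#' regime calls.  Genes failing half-life QC (CV >= \code{cvMax}) in either
#' condition are reported as indeterminate.
#'
#' @param recordsA,recordsB data.frames from [fitDecay()] for conditions 1
#'   and 2.
#' @param exprA,exprB named numeric vectors of steady-state expression.
#' @param cvMax QC threshold forwarded to [qcFilter()] (default 0.5).
#' @param tol indeterminacy threshold on \eqn{|\ln(m_2/m_1)|}.
#' @return data.frame with columns \code{gene_id}, \code{m1}, \code{m2},
#'   \code{gamma1}, \code{gamma2}, \code{ktrn1}, \code{ktrn2}, \code{rho_T},
#'   \code{rho_D}, \code{regime}.
#' @export
controlAnalysis <- function(recordsA, recordsB, exprA, exprB, cvMax = 0.5,
                            tol = 1e-6) {
    genes <- intersect(intersect(recordsA$gene_id, recordsB$gene_id),
                       intersect(names(exprA), names(exprB)))
    if (!length(genes)) stop("no genes shared by all four inputs")
    a <- recordsA[match(genes, recordsA$gene_id), ]
    b <- recordsB[match(genes, recordsB$gene_id), ]
    okA <- !is.na(a$k_per_min) & a$k_per_min > 0 & !is.na(a$cv) & a$cv < cvMax
    okB <- !is.na(b$k_per_min) & b$k_per_min > 0 & !is.na(b$cv) & b$cv < cvMax
    m1 <- exprA[genes]; m2 <- exprB[genes]
    ok <- okA & okB & is.finite(m1) & m1 > 0 & is.finite(m2) & m2 > 0
    rho_T <- rho_D <- rep(NA_real_, length(genes))
    if (any(ok)) {
        cc <- controlCoefficients(m1[ok], m2[ok], a$k_per_min[ok],
                                  b$k_per_min[ok], tol = tol)
        rho_T[ok] <- cc$rho_T
        rho_D[ok] <- cc$rho_D
    }
    data.frame(gene_id = genes, m1 = unname(m1), m2 = unname(m2),
               gamma1 = ifelse(ok, a$k_per_min, NA_real_),
               gamma2 = ifelse(ok, b$k_per_min, NA_real_),
               ktrn1 = ifelse(ok, a$k_per_min * m1, NA_real_),
               ktrn2 = ifelse(ok, b$k_per_min * m2, NA_real_),
               rho_T = rho_T, rho_D = rho_D,
               regime = classifyRegime(rho_D))
}

#' Consensus differentially expressed genes across methods
#'
#' The consensus set contains the genes called differentially expressed
#' (p <= \code{alpha}) simultaneously by every supplied method.  In strict
#' mode all tables must share an identical gene universe.
#'
#' @param tables named list (>= 2 elements) of per-method data.frames with
#'   columns \code{gene_id} and \code{pvalue} (optionally \code{log2fc}).
#' @param alpha significance threshold (default 0.01).
#' @param strict require identical gene universes (default \code{TRUE}).
#' @return data.frame with \code{gene_id}, one p-value column per method
#'   (\code{p_<method>}), \code{log2fc} (from the first table that has it),
#'   and logical \code{consensus}; per-method DEG sets are attached as
#'   \code{attr(, "method_sets")}.
#' @export
consensusDEG <- function(tables, alpha = 0.01, strict = TRUE) {
    if (length(tables) < 2) stop("need at least two method tables")
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
        names(tables) <- paste0("method", seq_along(tables))
    if (!all(is.finite(alpha)) || alpha <= 0 || alpha >= 1)
        stop("alpha must be in (0, 1)")
    universe <- sort(tables[[1]]$gene_id)
    for (nm in names(tables)) {
        tb <- tables[[nm]]
        if (!all(c("gene_id", "pvalue") %in% colnames(tb)))
            stop("table '", nm, "' needs columns gene_id and pvalue")
        if (strict && !identical(sort(tb$gene_id), universe))
            stop("table '", nm, "' has a different gene universe")
    }
    genes <- Reduce(intersect, lapply(tables, `[[`, "gene_id"))
    pm <- vapply(tables, function(tb) tb$pvalue[match(genes, tb$gene_id)],
                 numeric(length(genes)))
    pm <- matrix(pm, nrow = length(genes),
                 dimnames = list(NULL, paste0("p_", names(tables))))
    consensus <- rowSums(pm <= alpha) == ncol(pm)
    lfc <- rep(NA_real_, length(genes))
    for (tb in tables) {
        if ("log2fc" %in% colnames(tb)) {
            lfc <- tb$log2fc[match(genes, tb$gene_id)]
            break
        }
    }
    out <- data.frame(gene_id = genes, pm, log2fc = lfc,
                      consensus = consensus)
    attr(out, "method_sets") <- lapply(seq_along(tables), function(i)
        genes[pm[, i] <= alpha])
    names(attr(out, "method_sets")) <- names(tables)
    out
}

#' Simple differential-expression test (pipeline plumbing)
#'
#' A two-sided moderated t-test per gene on
#' \code{log2(library-size-normalized counts + 0.5)}, fitted with limma's
#' linear model and empirical-Bayes variance shrinkage.  This is pipeline
#' plumbing so that the workflow can run end to end without external count
#' model tools; it is \emph{not} a re-implementation of edgeR, DESeq2 or
#' PoissonSeq, whose p-value tables are the intended input to
#' [consensusDEG()].
#'
#' @param countsA,countsB count matrices (genes x replicates) for the two
#'   conditions, >= 2 replicates each, identical rownames.
#' @return data.frame with \code{gene_id}, \code{pvalue}, \code{log2fc}
#'   (condition B over A).
#' @export
simpleDETest <- function(countsA, countsB) {
    countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
    if (ncol(countsA) < 2 || ncol(countsB) < 2)
        stop("need at least 2 replicates per condition")
    if (!identical(rownames(countsA), rownames(countsB)))
        stop("count matrices must share the same genes in the same order")
    logx <- .logNorm(cbind(countsA, countsB))
    group <- rep(0:1, c(ncol(countsA), ncol(countsB)))
    design <- cbind(intercept = 1, group = group)
    fit <- limma::lmFit(logx, design)
    lfc <- fit$coefficients[, "group"]
    p <- rep(NA_real_, nrow(logx))
    informative <- is.finite(fit$sigma) & fit$sigma > 1e-10
    if (any(informative)) {
        eb <- limma::eBayes(fit[informative, ])
        p[informative] <- eb$p.value[, "group"]
    }
    # genes with zero residual variance the shrinkage cannot touch:
    # identical replicates decide the call directly
    p[!informative] <- ifelse(abs(lfc[!informative]) < 1e-12, 1, 0)
    p[!is.finite(p)] <- 1
    data.frame(gene_id = rownames(countsA), pvalue = unname(p),
               log2fc = unname(lfc))
}

.logNorm <- function(cts) {
    sf <- colSums(cts)
    sf <- sf / mean(sf)
    sf[sf == 0] <- 1
    log2(sweep(cts, 2, sf, "/") + 0.5)
}

#' Bootstrap uncertainty of the DEG count
#'
#' Resamples replicates with replacement within each condition \code{B}
#' times, recomputes the number of differentially expressed genes each time
#' (with [simpleDETest()] at \code{alpha}), and reports the relative
#' standard deviation (SD/mean) of the count.  Replicate-level resampling is
#' used as the resampling unit.
#'
#' @param countsA,countsB count matrices (genes x replicates).
#' @param B number of bootstrap resamples (>= 2; default 200).
#' @param alpha DE threshold (default 0.01).
#' @param seed integer seed for reproducibility.
#' @return list with \code{relativeSD}, \code{mean}, \code{sd},
#'   \code{counts} (the B bootstrap DEG counts).
#' @export
bootstrapDEGUncertainty <- function(countsA, countsB, B = 200, alpha = 0.01,
                                    seed = 1) {
    if (B < 2) stop("B must be >= 2")
    countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
    set.seed(seed)
    counts <- vapply(seq_len(B), function(i) {
        ia <- sample.int(ncol(countsA), replace = TRUE)
        ib <- sample.int(ncol(countsB), replace = TRUE)
        de <- simpleDETest(countsA[, ia, drop = FALSE],
                           countsB[, ib, drop = FALSE])
        sum(de$pvalue <= alpha, na.rm = TRUE)
    }, numeric(1))
    list(relativeSD = if (mean(counts) == 0) 0 else sd(counts) / mean(counts),
         mean = mean(counts), sd = sd(counts), counts = counts)
}
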