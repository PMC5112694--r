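#' RPKM normalization
#'
#' Reads are normalized per kilobase of gene length and then per one million
#' mapped reads in the sample:
#' \code{RPKM = count / (length/1000) / (sample_total/1e6)}.
#'
#' @param counts a \linkS4class{CountMatrix}.
#' @return numeric matrix of RPKM values, genes x samples.
#' @examples
#' cm <- CountMatrix(matrix(c(100, 999900), 2, 1,
#'                          dimnames = list(c("g1", "g2"), "s1")),
#'                   length = c(1000, 1000),
#'                   sampleData = data.frame(condition = "a", replicate = 1))
#' rpkmNormalize(cm)["g1", ]  # 100 reads, 1 kb, 1e6 total -> 100
#' @export
rpkmNormalize <- function(counts) {
    stopifnot(is(counts, "CountMatrix"))
    cts <- assay(counts, "counts")
    totals <- colSums(cts)
    if (any(totals <= 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(cts)[totals <= 0], collapse = ", "))
    len_kb <- rowData(counts)$length / 1000
    sweep(cts / len_kb, 2, totals / 1e6, "/")
}

#' Operon-averaged RPKM (ORPKM) normalization
#'
#' Reads are normalized per kilobase of gene length, the per-kilobase values
#' are then averaged across the member genes of each operon (every member
#' receives the operon mean; genes outside any operon are treated as
#' singletons), and finally normalized per one million mapped reads.
#'
#' @param counts a \linkS4class{CountMatrix}.
#' @param operons operon map as returned by [readOperonMap()]: a data.frame
#'   with columns \code{operon_id} and \code{gene_id} (no gene may belong to
#'   two operons).
#' @return numeric matrix of ORPKM values, genes x samples.
#' @export
orpkmNormalize <- function(counts, operons) {
    stopifnot(is(counts, "CountMatrix"))
    .checkOperonMap(operons)
    cts <- assay(counts, "counts")
    totals <- colSums(cts)
    if (any(totals <= 0))
        stop("sample(s) with zero total counts")
    len_kb <- rowData(counts)$length / 1000
    perkb <- cts / len_kb
    grp <- operons$operon_id[match(rownames(cts), operons$gene_id)]
    single <- is.na(grp)
    grp[single] <- paste0(".singleton.", rownames(cts)[single])
    sums <- rowsum(perkb, grp)
    means <- sums / as.vector(table(grp)[rownames(sums)])
    out <- means[grp, , drop = FALSE]
    dimnames(out) <- dimnames(cts)
    sweep(out, 2, totals / 1e6, "/")
}

#' Pool read counts over operons
#'
#' Operon-level counts are the per-sample sums of member gene counts; the
#' operon length is the sum of member gene lengths.  Genes outside any operon
#' pass through unchanged as singletons.  Per-sample total counts are
#' conserved.
#'
#' @param counts a \linkS4class{CountMatrix}.
#' @param operons operon map data.frame (\code{operon_id}, \code{gene_id}).
#' @return a \linkS4class{CountMatrix} whose rows are operons and singleton
#'   genes.
#' @export
poolOperons <- function(counts, operons) {
    stopifnot(is(counts, "CountMatrix"))
    .checkOperonMap(operons)
    cts <- assay(counts, "counts")
    grp <- operons$operon_id[match(rownames(cts), operons$gene_id)]
    single <- is.na(grp)
    grp[single] <- rownames(cts)[single]
    pooled <- rowsum(cts, grp)
    lens <- rowsum(rowData(counts)$length, grp)[, 1]
    CountMatrix(pooled, length = lens[rownames(pooled)],
                sampleData = as.data.frame(colData(counts)))
}

.checkOperonMap <- function(operons) {
    if (!is.data.frame(operons) ||
        !all(c("operon_id", "gene_id") %in% colnames(operons)))
        stop("operon map needs columns 'operon_id' and 'gene_id'")
    dup <- duplicated(operons$gene_id)
    if (any(dup))
        stop("gene(s) assigned to more than one operon: ",
             paste(unique(operons$gene_id[dup]), collapse = ", "))
    invisible(TRUE)
}
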