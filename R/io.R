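# Tab-delimited tables ('#' comments, UTF-8) are the universal dialect for
# all tabular inputs and outputs; gene identifiers are opaque strings.

.readTSV <- function(path, required, what = "table") {
    if (!file.exists(path)) stop(what, " file not found: ", path)
    df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character")
    miss <- setdiff(required, colnames(df))
    if (length(miss))
        stop(what, " '", path, "' is missing column(s): ",
             paste(miss, collapse = ", "))
    df
}

# strict numeric conversion: any non-numeric cell is an error with its row
.numCol <- function(df, col, path) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(df[[col]] %in% c("NA", "")))
    if (length(bad))
        stop("non-numeric value in column '", col, "' of ", path,
             " (data row ", bad[1], ": '", df[[col]][bad[1]], "')")
    x
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    invisible(path)
}

#' Read a count matrix and its sample map
#'
#' The counts file has columns \code{gene_id}, \code{length} and one column
#' per sample; the sample map has columns \code{sample}, \code{condition},
#' \code{replicate} and optionally \code{timepoint_min} (minutes after
#' transcription arrest; empty/NA for steady-state samples).  Malformed
#' input (negative counts, non-numeric cells, duplicate genes, unmapped
#' samples) is rejected with a row-naming error.
#'
#' @param countsPath path to the counts TSV.
#' @param samplesPath path to the sample-map TSV.
#' @return a \linkS4class{CountMatrix}.
#' @export
readCountMatrix <- function(countsPath, samplesPath) {
    cdf <- .readTSV(countsPath, c("gene_id", "length"), "counts")
    sdf <- .readTSV(samplesPath, c("sample", "condition", "replicate"),
                    "sample map")
    samples <- setdiff(colnames(cdf), c("gene_id", "length"))
    if (!length(samples)) stop("no sample columns in ", countsPath)
    if (anyDuplicated(cdf$gene_id))
        stop("duplicate gene_id in ", countsPath, ": ",
             cdf$gene_id[duplicated(cdf$gene_id)][1])
    unmapped <- setdiff(samples, sdf$sample)
    if (length(unmapped))
        stop("sample(s) missing from sample map: ",
             paste(unmapped, collapse = ", "))
    cts <- sapply(samples, function(s) {
        x <- .numCol(cdf, s, countsPath)
        bad <- which(x < 0)
        if (length(bad))
            stop("negative count for gene '", cdf$gene_id[bad[1]],
                 "', sample '", s, "' in ", countsPath)
        x
    })
    cts <- matrix(cts, ncol = length(samples),
                  dimnames = list(cdf$gene_id, samples))
    lens <- .numCol(cdf, "length", countsPath)
    if (any(!is.finite(lens) | lens <= 0))
        stop("non-positive gene length in ", countsPath)
    sdf <- sdf[match(samples, sdf$sample), ]
    sample_data <- data.frame(condition = sdf$condition,
                              replicate = sdf$replicate)
    if ("timepoint_min" %in% colnames(sdf))
        sample_data$timepoint_min <- suppressWarnings(
            as.numeric(sdf$timepoint_min))
    CountMatrix(cts, length = lens, sampleData = sample_data)
}

#' Write a count matrix and its sample map
#'
#' @param counts a \linkS4class{CountMatrix}.
#' @param countsPath,samplesPath output TSV paths.
#' @return invisibly, the two paths.
#' @export
writeCountMatrix <- function(counts, countsPath, samplesPath) {
    cts <- assay(counts, "counts")
    .writeTSV(data.frame(gene_id = rownames(cts),
                         length = rowData(counts)$length,
                         cts, check.names = FALSE), countsPath)
    cd <- as.data.frame(colData(counts))
    .writeTSV(data.frame(sample = colnames(cts), cd, check.names = FALSE),
              samplesPath)
    invisible(c(countsPath, samplesPath))
}

#' Read an operon map
#'
#' Expects columns \code{operon_id}, \code{gene_id} and optionally
#' \code{position}; a gene may belong to at most one operon within a source.
#'
#' @param path TSV path.
#' @param source optional label of the prediction source, stored as
#'   \code{attr(, "source")}.
#' @return data.frame with the operon map.
#' @export
readOperonMap <- function(path, source = NA_character_) {
    df <- .readTSV(path, c("operon_id", "gene_id"), "operon map")
    .checkOperonMap(df)
    attr(df, "source") <- source
    df
}

#' Read a per-method differential-expression table
#'
#' Expects columns \code{gene_id}, \code{pvalue} and optionally
#' \code{log2fc}.
#'
#' @param path TSV path.
#' @return data.frame suitable for [consensusDEG()].
#' @export
readDEGTable <- function(path) {
    df <- .readTSV(path, c("gene_id", "pvalue"), "DEG table")
    out <- data.frame(gene_id = df$gene_id,
                      pvalue = .numCol(df, "pvalue", path))
    if (any(out$pvalue < 0 | out$pvalue > 1, na.rm = TRUE))
        stop("p-values outside [0, 1] in ", path)
    if ("log2fc" %in% colnames(df))
        out$log2fc <- .numCol(df, "log2fc", path)
    out
}

#' Write / read half-life fit tables
#'
#' Columns: \code{gene_id}, \code{k_per_min}, \code{tau_min}, \code{R0},
#' \code{se_k}, \code{cv}, \code{fit_pvalue}, \code{df_resid},
#' \code{qc_pass}.
#'
#' @param records data.frame from [fitDecay()].
#' @param path TSV path.
#' @return [writeHalfLifeTable()] the path, invisibly;
#'   [readHalfLifeTable()] the records data.frame.
#' @export
writeHalfLifeTable <- function(records, path) .writeTSV(records, path)

#' @rdname writeHalfLifeTable
#' @export
readHalfLifeTable <- function(path) {
    df <- .readTSV(path, c("gene_id", "k_per_min", "tau_min", "se_k", "cv"),
                   "half-life table")
    out <- data.frame(gene_id = df$gene_id)
    for (col in setdiff(colnames(df), c("gene_id", "qc_pass")))
        out[[col]] <- .numCol(df, col, path)
    out$qc_pass <- if ("qc_pass" %in% colnames(df))
        df$qc_pass %in% c("TRUE", "true", "1") else
        !is.na(out$k_per_min) & out$k_per_min > 0 &
            !is.na(out$cv) & out$cv < 0.5
    out
}

#' Read a metabolic model (JSON or SBML L3/FBC)
#'
#' The native JSON schema is
#' \preformatted{
#' {"metabolites": [{"id": ..., "compartment": ...}],
#'  "reactions":   [{"id": ..., "stoich": {"met": coef, ...},
#'                   "lb": ..., "ub": ..., "gpr": "..."}],
#'  "biomass": "reaction_id", "exchanges": ["EX_...", ...]}
#' }
#' SBML Level 3 with the FBC package is detected from the file content and
#' mapped onto the same structure (species, stoichiometric
#' reactant/product references, fbc flux-bound parameters and
#' gene-product associations).
#'
#' @param path model file.
#' @param format \code{"auto"} (default), \code{"json"} or \code{"sbml"}.
#' @param verbose print the size report (reactions with/without exchanges,
#'   associated genes) as a message (default \code{TRUE}).
#' @return a \linkS4class{MetabolicModel}.
#' @export
readMetabolicModel <- function(path, format = c("auto", "json", "sbml"),
                               verbose = TRUE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("model file not found: ", path)
    if (format == "auto") {
        head1 <- readChar(path, 200)
        format <- if (grepl("<sbml", head1, fixed = TRUE)) "sbml" else "json"
    }
    model <- if (format == "json") .readModelJSON(path) else
        .readModelSBML(path)
    if (verbose) {
        st <- modelStats(model)
        message("model '", basename(path), "': ",
                st$nonBiomassReactions, " non-biomass reactions (",
                st$withExchanges, " when including metabolite exchange), ",
                st$genes, " associated genes")
    }
    model
}

.readModelJSON <- function(path) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    for (key in c("metabolites", "reactions", "biomass"))
        if (is.null(doc[[key]]))
            stop("model JSON missing required field '", key, "'")
    mets <- data.frame(
        id = vapply(doc$metabolites, `[[`, character(1), "id"),
        compartment = vapply(doc$metabolites, function(m)
            if (is.null(m$compartment)) "c" else m$compartment,
            character(1)))
    rxn_ids <- vapply(doc$reactions, `[[`, character(1), "id")
    stoich <- lapply(doc$reactions, function(r) {
        st <- unlist(r$stoich)
        if (is.null(st)) stop("reaction '", r$id, "' has empty stoichiometry")
        st
    })
    lb <- vapply(doc$reactions, function(r)
        if (is.null(r$lb)) -1000 else as.numeric(r$lb), numeric(1))
    ub <- vapply(doc$reactions, function(r)
        if (is.null(r$ub)) 1000 else as.numeric(r$ub), numeric(1))
    gpr <- vapply(doc$reactions, function(r)
        if (is.null(r$gpr)) "" else r$gpr, character(1))
    if (!doc$biomass %in% rxn_ids)
        stop("biomass reaction '", doc$biomass, "' not among reactions")
    metabolicModel(metabolites = mets, reactions = rxn_ids,
                   stoichiometry = stoich, lb = lb, ub = ub, gpr = gpr,
                   biomass = doc$biomass,
                   exchanges = as.character(unlist(doc$exchanges)))
}

#' Write a metabolic model to the native JSON schema
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMetabolicModel <- function(model, path) {
    S <- model@stoichiometry
    rxns <- lapply(seq_along(model@reactions), function(j) {
        col <- S[, j]
        nz <- which(col != 0)
        list(id = model@reactions[j],
             stoich = as.list(setNames(as.numeric(col[nz]),
                                       model@metabolites$id[nz])),
             lb = model@lowerBounds[j], ub = model@upperBounds[j],
             gpr = model@gpr[j])
    })
    doc <- list(
        metabolites = lapply(seq_len(nrow(model@metabolites)), function(i)
            list(id = model@metabolites$id[i],
                 compartment = model@metabolites$compartment[i])),
        reactions = rxns,
        biomass = model@biomassId,
        exchanges = as.list(model@exchanges))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

# Minimal SBML Level 3 + FBC reader: species, reactions with
# reactant/product stoichiometry, flux bounds via fbc parameter references,
# GPRs via fbc:geneProductAssociation, objective via fbc:listOfObjectives.
.readModelSBML <- function(path) {
    doc <- xml2::read_xml(path)
    ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
            fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
    sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
    mets <- data.frame(
        id = xml2::xml_attr(sp, "id"),
        compartment = xml2::xml_attr(sp, "compartment"))
    pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
    parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                       xml2::xml_attr(pars, "id"))
    gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/*", ns)
    gplab <- setNames(xml2::xml_attr(gps, "label"),
                      xml2::xml_attr(gps, "id"))
    rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
    if (!length(rx)) stop("no reactions found in SBML file ", path)
    rxn_ids <- xml2::xml_attr(rx, "id")
    getStoich <- function(node) {
        refs <- xml2::xml_find_all(
            node, "./s:listOfReactants/s:speciesReference", ns)
        prods <- xml2::xml_find_all(
            node, "./s:listOfProducts/s:speciesReference", ns)
        st <- c(setNames(-as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                         xml2::xml_attr(refs, "species")),
                setNames(as.numeric(xml2::xml_attr(prods, "stoichiometry")),
                         xml2::xml_attr(prods, "species")))
        if (!length(st)) stop("reaction '", xml2::xml_attr(node, "id"),
                              "' has no species references")
        st
    }
    stoich <- lapply(rx, getStoich)
    boundOf <- function(node, attr, default) {
        ref <- xml2::xml_attr(node, attr)
        if (is.na(ref)) return(default)
        if (!ref %in% names(parval))
            stop("flux bound parameter '", ref, "' not defined")
        parval[[ref]]
    }
    lb <- vapply(rx, boundOf, numeric(1), "lowerFluxBound", -1000)
    ub <- vapply(rx, boundOf, numeric(1), "upperFluxBound", 1000)
    gpr <- vapply(rx, function(node) {
        refs <- xml2::xml_find_all(
            node, ".//fbc:geneProductAssociation//fbc:geneProductRef", ns)
        if (!length(refs)) return("")
        ids <- xml2::xml_attr(refs, "geneProduct")
        labs <- ifelse(ids %in% names(gplab) & !is.na(gplab[ids]),
                       gplab[ids], ids)
        paste(unique(labs), collapse = " or ")
    }, character(1))
    objref <- xml2::xml_find_first(
        doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
    if (inherits(objref, "xml_missing"))
        stop("SBML file has no fbc objective (biomass reaction)")
    biomass <- xml2::xml_attr(objref, "reaction")
    exchanges <- rxn_ids[vapply(stoich, function(st)
        length(st) == 1 || all(st < 0), logical(1)) &
        grepl("^(EX_|R_EX_)", rxn_ids)]
    metabolicModel(metabolites = mets, reactions = rxn_ids,
                   stoichiometry = stoich, lb = lb, ub = ub, gpr = gpr,
                   biomass = biomass, exchanges = exchanges)
}

#' Write control-coefficient and flux tables
#'
#' Convenience TSV writers with the conventional column layouts:
#' \code{gene_id rho_T rho_D regime} for control records and
#' \code{reaction flux_cond1 flux_cond2 class} for flux comparisons.
#'
#' @param x the data.frame to write.
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
writeControlTable <- function(x, path)
    .writeTSV(x[, intersect(c("gene_id", "m1", "m2", "gamma1", "gamma2",
                              "rho_T", "rho_D", "regime"), colnames(x))],
              path)

#' @rdname writeControlTable
#' @export
writeFluxTable <- function(x, path) .writeTSV(x, path)
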