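#' Read a probe-to-gene multimap
#'
#' TSV with columns \code{probe_id} and \code{symbols} (semicolon-joined
#' gene symbols).  Every mapped probe must carry at least one symbol.
#'
#' @param path TSV path.
#' @return named list: probe id -> character vector of gene symbols.
#' @export
readProbeGeneMap <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("probe_id", "symbols") %in% colnames(tab)))
        stop("map needs columns probe_id and symbols")
    if (anyDuplicated(tab$probe_id))
        stop("duplicated probe id in map: '",
             tab$probe_id[anyDuplicated(tab$probe_id)], "'")
    map <- strsplit(tab$symbols, ";", fixed = TRUE)
    map <- lapply(map, function(s) s[nzchar(s)])
    if (any(!lengths(map)))
        stop("mapped probes must carry at least one symbol")
    stats::setNames(map, tab$probe_id)
}

#' Convert a probe signature to a gene signature
#'
#' Probes mapping to a single gene transfer directly.  A probe mapping to
#' several genes contributes exactly those of its genes that possess a
#' gene-specific probe (a probe mapping to that gene alone) inside the
#' relaxed candidate list — a longer differential list obtained at a relaxed
#' FDR, used only to resolve ambiguity.  Genes hit by several probes
#' collapse to a single entry whose provenance lists all of them; their
#' directions must agree, a conflict aborts naming the probes.
#'
#' @param sig probe-space [GeneSignature-class].
#' @param map probe -> symbols multimap ([readProbeGeneMap()] or a named
#'   list).
#' @param relaxedCandidates character vector of probes differential at a
#'   relaxed threshold, used to resolve multi-gene probes.
#' @return gene-space [GeneSignature-class].
#' @export
probesToGenes <- function(sig, map, relaxedCandidates = character()) {
    stopifnot(methods::is(sig, "GeneSignature"))
    if (sig@featureSpace != "probe")
        stop("signature must be in probe space")
    entries <- signatureTable(sig)
    geneDir <- list(); geneSrc <- list(); order0 <- character()
    addGene <- function(g, dir, src) {
        if (is.null(geneDir[[g]])) {
            geneDir[[g]] <<- dir
            geneSrc[[g]] <<- src
            order0 <<- c(order0, g)
        } else {
            if (geneDir[[g]] != dir)
                stop("conflicting directions for gene '", g, "' from probes ",
                     paste(unique(c(geneSrc[[g]], src)), collapse = ", "))
            geneSrc[[g]] <<- union(geneSrc[[g]], src)
        }
    }
    specific <- function(g)
        names(map)[vapply(map, function(s) identical(s, g), logical(1L))]
    for (i in seq_len(nrow(entries))) {
        probe <- entries$feature_id[i]
        genes <- map[[probe]]
        if (is.null(genes)) {
            warning("probe '", probe, "' has no gene mapping; dropped")
            next
        }
        if (length(genes) == 1L) {
            addGene(genes, entries$direction[i], probe)
        } else {
            for (g in genes) {
                sp <- intersect(specific(g), relaxedCandidates)
                if (length(sp))
                    addGene(g, entries$direction[i],
                            c(probe, sp))
            }
        }
    }
    GeneSignature(order0,
                  vapply(order0, function(g) geneDir[[g]], character(1L)),
                  vapply(order0, function(g)
                      paste(geneSrc[[g]], collapse = ";"), character(1L)),
                  featureSpace = "gene")
}

#' Restrict a signature to a platform's feature set
#'
#' Intersection preserving order and direction; warns (and returns an empty
#' signature) when nothing survives.
#'
#' @param sig a [GeneSignature-class].
#' @param platformFeatures feature ids present on the platform.
#' @return the restricted [GeneSignature-class].
#' @export
restrictToPlatform <- function(sig, platformFeatures) {
    stopifnot(methods::is(sig, "GeneSignature"))
    e <- signatureTable(sig)
    keep <- e$feature_id %in% platformFeatures
    if (!any(keep))
        warning("no signature feature is present on the platform")
    methods::new("GeneSignature", entries = e[keep, , drop = FALSE],
                 featureSpace = sig@featureSpace)
}

#' Read / write signature TSV
#'
#' Columns \code{feature_id}, \code{direction}, \code{source_probes}
#' (semicolon-joined).
#'
#' @param path TSV path.
#' @param featureSpace \code{"probe"} or \code{"gene"}.
#' @return [GeneSignature-class] (read) or the path, invisibly (write).
#' @export
readSignature <- function(path, featureSpace = c("gene", "probe")) {
    featureSpace <- match.arg(featureSpace)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    GeneSignature(tab$feature_id, tab$direction, tab$source_probes,
                  featureSpace = featureSpace)
}

#' @rdname readSignature
#' @param sig the signature to write.
#' @export
writeSignature <- function(sig, path) {
    stopifnot(methods::is(sig, "GeneSignature"))
    utils::write.table(signatureTable(sig), path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' The packaged 33-gene liver-metastasis signature
#'
#' The published colorectal liver-metastasis signature shipped with the
#' package: 34 Affymetrix U133A probes resolved to 33 gene symbols (two
#' genes are covered by two probes each, and one immunoglobulin probe
#' resolves to the two symbols IGHD and IGHG1), with the direction of change
#' in hepatic metastasis versus paired primary tumor.
#'
#' @param space \code{"gene"} (33 entries) or \code{"probe"} (34 entries).
#' @return a [GeneSignature-class].
#' @examples
#' length(liverMetastasisSignature("gene"))   # 33
#' length(liverMetastasisSignature("probe"))  # 34
#' @export
liverMetastasisSignature <- function(space = c("gene", "probe")) {
    space <- match.arg(space)
    path <- system.file("extdata",
                        paste0("liver_metastasis_signature_",
                               space, "s.tsv"),
                        package = "metasig", mustWork = TRUE)
    readSignature(path, featureSpace = space)
}
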