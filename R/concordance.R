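#' Call differentially expressed genes by fixed thresholds
#'
#' Flags a gene as a DEG when `p <= pThreshold` and `|logfc| >=
#' logfcThreshold` (both inclusive; the conventional 0.05 / 0.5 cutoffs by
#' default), with direction given by the sign of the log fold change.
#'
#' @param geneTable data.frame with columns `gene`, `logfc`, `p`.
#' @param pThreshold significance threshold (default 0.05).
#' @param logfcThreshold minimum |log fold change| (default 0.5).
#' @return the table with added logical `called` and `direction`
#'   (`up`/`down`/`none`) columns.
#' @export
callDEG <- function(geneTable, pThreshold = 0.05, logfcThreshold = 0.5) {
    need <- c("gene", "logfc", "p")
    if (!all(need %in% colnames(geneTable)))
        stop("gene table lacks columns: ",
             paste(setdiff(need, colnames(geneTable)), collapse = ", "))
    if (anyDuplicated(geneTable$gene)) stop("duplicate gene symbols")
    if (any(geneTable$p < 0 | geneTable$p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    called <- geneTable$p <= pThreshold &
              abs(geneTable$logfc) >= logfcThreshold
    called[is.na(called)] <- FALSE
    geneTable$called <- called
    geneTable$direction <- ifelse(!called, "none",
                                  ifelse(geneTable$logfc > 0, "up", "down"))
    geneTable
}

#' Intersect differentially abundant proteins with DEGs
#'
#' Maps differentially abundant protein ids to gene symbols through a
#' user-supplied two-column map and intersects with the DEG symbol list.
#' Proteins absent from the map are reported in a side list, never silently
#' dropped.
#'
#' @param daProteins character vector of differentially abundant protein ids.
#' @param degs character vector of DEG gene symbols.
#' @param idMap data.frame with columns `protein_id` and `gene`.
#' @return list with `shared` (sorted gene symbols present in both layers)
#'   and `unmapped` (protein ids without a map entry).
#' @export
intersectMolecules <- function(daProteins, degs, idMap) {
    if (!all(c("protein_id", "gene") %in% colnames(idMap)))
        stop("'idMap' needs columns 'protein_id' and 'gene'")
    unmapped <- setdiff(daProteins, idMap$protein_id)
    genes <- idMap$gene[match(intersect(daProteins, idMap$protein_id),
                              idMap$protein_id)]
    list(shared = sort(intersect(unique(genes), unique(degs))),
         unmapped = sort(unmapped))
}

#' Intersect significant category lists between omics layers
#'
#' @param proteinSig category ids significant in the proteomic layer.
#' @param geneSig category ids significant in the transcriptomic layer.
#' @return sorted intersection.
#' @export
intersectCategories <- function(proteinSig, geneSig) {
    sort(intersect(unique(proteinSig), unique(geneSig)))
}
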