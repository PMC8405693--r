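#' Assemble a proteomics experiment object
#'
#' Bundles a log2 intensity matrix (rows = protein groups, columns = samples,
#' `NA` = not quantified) with its study design (disease group and sample
#' preparation batch) into a [SummarizedExperiment::SummarizedExperiment]
#' carrying one assay named `"log2intensity"`.
#'
#' The disease group must have exactly two levels. When the levels are
#' `"DM"`/`"NDM"` (the diabetic / non-diabetic contrast), `"NDM"` is taken as
#' the reference so downstream effects read as DM minus NDM on the log2
#' scale; otherwise the first factor level is the reference.
#'
#' @param intensity numeric matrix of log2 intensities with unique, non-empty
#'   row and column names; missing quantifications as `NA`.
#' @param group character or factor of length `ncol(intensity)`.
#' @param batch character or factor of length `ncol(intensity)`; sample
#'   preparation batch labels.
#' @return a `SummarizedExperiment` with colData columns `group` and `batch`.
#' @examples
#' m <- matrix(rnorm(12, 25), 3, 4,
#'     dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' se <- ProteomicsExperiment(m, c("NDM", "NDM", "DM", "DM"),
#'     c("B1", "B2", "B1", "B2"))
#' @export
ProteomicsExperiment <- function(intensity, group, batch) {
    if (!is.matrix(intensity) || !is.numeric(intensity))
        stop("'intensity' must be a numeric matrix")
    rid <- rownames(intensity); cid <- colnames(intensity)
    if (is.null(rid) || anyNA(rid) || any(rid == ""))
        stop("intensity matrix must have non-empty protein row names")
    if (anyDuplicated(rid))
        stop(sprintf("duplicate protein ids: %s",
            paste(unique(rid[duplicated(rid)]), collapse = ", ")))
    if (is.null(cid) || anyDuplicated(cid))
        stop("intensity matrix must have unique sample column names")
    if (length(group) != ncol(intensity) || length(batch) != ncol(intensity))
        stop("'group' and 'batch' must have one entry per sample")
    group <- as.factor(as.character(group))
    if (nlevels(group) != 2L)
        stop("'group' must have exactly two levels")
    if (all(levels(group) %in% c("DM", "NDM")))
        group <- stats::relevel(group, ref = "NDM")
    batch <- as.factor(as.character(batch))
    if (any(table(batch) < 1L)) stop("every batch needs at least one sample")
    SummarizedExperiment(
        assays = list(log2intensity = intensity),
        colData = DataFrame(group = group, batch = batch, row.names = cid))
}

.assayMatrix <- function(se) {
    if (!"log2intensity" %in% SummarizedExperiment::assayNames(se))
        stop("expected an assay named 'log2intensity'")
    assay(se, "log2intensity")
}

.groups <- function(se) {
    g <- colData(se)$group
    if (is.null(g)) stop("colData lacks a 'group' column")
    as.factor(g)
}

.batches <- function(se) {
    b <- colData(se)$batch
    if (is.null(b)) stop("colData lacks a 'batch' column")
    as.factor(b)
}

#' @rdname ProteomicsExperiment
#' @param se a `SummarizedExperiment` built by `ProteomicsExperiment()`.
#' @export
groupLabels <- function(se) .groups(se)

#' @rdname ProteomicsExperiment
#' @export
batchLabels <- function(se) .batches(se)

#' Ground truth of a simulated experiment
#'
#' Accessor for the truth table attached by [simulateProteome()]: per-protein
#' true log2 fold change, true residual variance, differential-abundance flag
#' and group-unique status.
#'
#' @param se a `SummarizedExperiment` from [simulateProteome()].
#' @return a `DataFrame` with columns `protein_id`, `true_log2fc`,
#'   `true_var`, `is_da`, `unique_group`.
#' @export
simulationTruth <- function(se) {
    rd <- rowData(se)
    need <- c("true_log2fc", "true_var", "is_da", "unique_group")
    if (!all(need %in% colnames(rd)))
        stop("no simulation truth attached to this experiment")
    DataFrame(protein_id = rownames(se), rd[, need])
}
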