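#' Median-normalize sample intensities
#'
#' Shifts each sample's observed log2 intensities additively so that every
#' sample median equals the median of the original per-sample medians
#' (equivalently, a multiplicative rescaling on the raw scale). Missing
#' entries are ignored when computing medians and remain missing.
#'
#' @param se a `SummarizedExperiment` from [ProteomicsExperiment()].
#' @return the experiment with normalized `log2intensity` assay.
#' @export
medianNormalize <- function(se) {
    m <- .assayMatrix(se)
    nObs <- colSums(!is.na(m))
    if (any(nObs == 0))
        stop(sprintf("sample(s) with no observed values: %s",
            paste(colnames(m)[nObs == 0], collapse = ", ")))
    meds <- apply(m, 2, stats::median, na.rm = TRUE)
    target <- stats::median(meds)
    m <- sweep(m, 2, target - meds, `+`)
    SummarizedExperiment::assay(se, "log2intensity") <- m
    se
}

#' Route proteins by per-group missingness
#'
#' Splits proteins into the quantitative-analysis path (observed in at least
#' `minPerGroup` samples in *both* groups) and the detection-limit heuristic
#' path (everything else). The default of 4 reflects the usual requirement of
#' at least 4 quantifications per group for moderated-regression analysis.
#'
#' @param se a `SummarizedExperiment` with group labels in `colData`.
#' @param minPerGroup minimum observed values per group for the quantitative
#'   path (default 4).
#' @return list with `quantitative` (ids), `heuristic` (ids) and `counts`
#'   (data.frame of per-group observed counts). The two id vectors partition
#'   the row names.
#' @export
routeByMissingness <- function(se, minPerGroup = 4) {
    .checkCount(minPerGroup, "minPerGroup")
    m <- .assayMatrix(se)
    g <- .groups(se)
    lv <- levels(g)
    nObs <- vapply(lv, function(l) rowSums(!is.na(m[, g == l, drop = FALSE])),
                   numeric(nrow(m)))
    if (nrow(m) == 1L) nObs <- matrix(nObs, nrow = 1,
                                      dimnames = list(rownames(m), lv))
    quant <- nObs[, 1] >= minPerGroup & nObs[, 2] >= minPerGroup
    counts <- data.frame(protein_id = rownames(m), nObs, check.names = FALSE,
                         stringsAsFactors = FALSE, row.names = NULL)
    colnames(counts)[-1] <- paste0("n_obs_", lv)
    list(quantitative = rownames(m)[quant],
         heuristic = rownames(m)[!quant],
         counts = counts)
}

#' Detection-limit heuristic for sparsely quantified proteins
#'
#' Classifies proteins on the heuristic path as uniquely expressed in one
#' group ("below limit of detection in one group but not the other"): a
#' protein is called unique to group G when it is observed in at least
#' `nminPresent` samples of G and at most `nmaxAbsent` samples of the other
#' group; otherwise the evidence is `insufficient`. Defaults scale with group
#' size as `ceiling(0.7 * n)` present and `floor(0.1 * n)` absent — 7 and 1
#' for 10-per-group designs.
#'
#' @param se a `SummarizedExperiment` with group labels in `colData`.
#' @param heuristicIds proteins to classify (default: the heuristic list from
#'   [routeByMissingness()] at its defaults).
#' @param nminPresent,nmaxAbsent inclusive thresholds (per group; see above).
#' @return data.frame with columns `protein_id`, `call`
#'   (`unique_<group>` or `insufficient`) and per-group observed counts.
#' @export
classifyDetectionLimit <- function(se, heuristicIds = NULL,
        nminPresent = NULL, nmaxAbsent = NULL) {
    m <- .assayMatrix(se)
    g <- .groups(se)
    lv <- levels(g)
    nPer <- table(g)
    if (is.null(heuristicIds))
        heuristicIds <- routeByMissingness(se)$heuristic
    if (!all(heuristicIds %in% rownames(m)))
        stop("'heuristicIds' must be row names of the experiment")
    if (is.null(nminPresent))
        nminPresent <- stats::setNames(ceiling(0.7 * as.numeric(nPer)), lv)
    else nminPresent <- stats::setNames(rep_len(nminPresent, 2), lv)
    if (is.null(nmaxAbsent))
        nmaxAbsent <- stats::setNames(floor(0.1 * as.numeric(nPer)), lv)
    else nmaxAbsent <- stats::setNames(rep_len(nmaxAbsent, 2), lv)

    sub <- m[heuristicIds, , drop = FALSE]
    nObs <- vapply(lv, function(l)
        rowSums(!is.na(sub[, g == l, drop = FALSE])),
        numeric(length(heuristicIds)))
    if (length(heuristicIds) == 1L)
        nObs <- matrix(nObs, nrow = 1, dimnames = list(heuristicIds, lv))
    call <- rep("insufficient", length(heuristicIds))
    for (i in 1:2) {
        pres <- lv[i]; abs <- lv[3 - i]
        hit <- nObs[, pres] >= nminPresent[pres] &
               nObs[, abs] <= nmaxAbsent[abs]
        call[hit] <- paste0("unique_", pres)
    }
    out <- data.frame(protein_id = heuristicIds, call = call, nObs,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      row.names = NULL)
    colnames(out)[3:4] <- paste0("n_obs_", lv)
    out
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Extracts protein-group ids and per-sample LFQ (or raw) intensity columns
#' from a tab-separated `proteinGroups.txt`-like file, dropping rows flagged
#' as reverse-database hits or contaminants when those columns are present.
#' Intensities of 0 are treated as not quantified and the matrix is returned
#' on the log2 scale.
#'
#' @param path file path.
#' @param idColumn column holding protein-group identifiers.
#' @param intensityPrefix prefix of per-sample intensity columns; falls back
#'   to `"Intensity "` when no `"LFQ intensity "` columns exist.
#' @return numeric matrix of log2 intensities (`NA` = not quantified) whose
#'   column names are the sample names with the prefix stripped.
#' @export
readProteinGroups <- function(path, idColumn = "Majority protein IDs",
        intensityPrefix = "LFQ intensity ") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!idColumn %in% colnames(tab))
        stop(sprintf("id column '%s' not found", idColumn))
    for (flag in c("Reverse", "Potential contaminant", "Contaminant")) {
        if (flag %in% colnames(tab)) tab <- tab[tab[[flag]] != "+", ]
    }
    cols <- grep(paste0("^", intensityPrefix), colnames(tab), value = TRUE)
    if (!length(cols) && intensityPrefix == "LFQ intensity ") {
        intensityPrefix <- "Intensity "
        cols <- grep("^Intensity .", colnames(tab), value = TRUE)
    }
    if (!length(cols)) stop("no per-sample intensity columns found")
    ids <- as.character(tab[[idColumn]])
    if (anyDuplicated(ids))
        stop(sprintf("duplicate protein ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    m <- as.matrix(tab[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    m[m == 0] <- NA_real_
    m <- log2(m)
    dimnames(m) <- list(ids, sub(paste0("^", intensityPrefix), "", cols))
    m
}
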