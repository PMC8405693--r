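#' Simulate a label-free proteomics experiment with known ground truth
#'
#' Generates a proteins x samples log2 intensity matrix mimicking a two-group
#' (DM vs NDM) LFQ study: per-protein baselines, a disease effect in a
#' minority of proteins, additive sample-preparation batch offsets, per-protein
#' residual variances drawn from a scaled inverse-chi-square distribution
#' (the empirical-Bayes model fitted downstream), probit left-censoring of low
#' intensities (missing-not-at-random), and a set of group-unique proteins
#' forced entirely missing in one group. Ground truth is stored in
#' `rowData()` and retrievable with [simulationTruth()].
#'
#' The intensity model for protein g in sample s is
#' `y_gs = baseline_g + delta_g * I(s in DM) + b_batch(s) + e_gs`, with
#' `e_gs ~ N(0, sigma_g^2)` and `sigma_g^2 ~ priorVar * priorDf / chisq(priorDf)`.
#' An entry is observed with probability
#' `1 - pnorm((censorMid - y_gs) / censorWidth)`; `censorMid = -Inf` disables
#' censoring. Batches are assigned round-robin within each group so that
#' disease and batch are never confounded.
#'
#' @param nProteins number of proteins to simulate.
#' @param nPerGroup samples per group (default 10, as in a 10 DM vs 10 NDM
#'   design).
#' @param nBatches number of preparation batches (default 2).
#' @param baselineMean,baselineSd mean and between-protein SD of baseline
#'   log2 intensity.
#' @param priorDf,priorVar degrees of freedom and scale of the inverse-
#'   chi-square residual-variance distribution.
#' @param fracDA fraction of proteins with a nonzero disease effect.
#' @param effectSize absolute log2 fold change of affected proteins (random
#'   sign).
#' @param batchSd SD of additive batch offsets (log2 scale).
#' @param censorMid log2 intensity at which an entry is missing with
#'   probability 0.5.
#' @param censorWidth probit censoring slope (> 0).
#' @param fracUnique fraction of proteins forced group-unique (all entries of
#'   one group removed); these proteins carry no quantitative effect.
#' @param seed integer seed; identical seeds give identical output.
#' @return a `SummarizedExperiment` (see [ProteomicsExperiment()]) with the
#'   truth table in `rowData()` and the simulation parameters in `metadata()`.
#' @examples
#' se <- simulateProteome(200, fracDA = 0.1, seed = 1)
#' table(simulationTruth(se)$is_da)
#' @export
simulateProteome <- function(nProteins, nPerGroup = 10, nBatches = 2,
        baselineMean = 25, baselineSd = 2, priorDf = 6, priorVar = 0.16,
        fracDA = 0.1, effectSize = 1, batchSd = 0.25,
        censorMid = 23.45, censorWidth = 1, fracUnique = 0.02, seed = 1) {
    .checkCount(nProteins, "nProteins"); .checkCount(nPerGroup, "nPerGroup")
    .checkCount(nBatches, "nBatches")
    .checkFrac(fracDA, "fracDA"); .checkFrac(fracUnique, "fracUnique")
    if (fracDA + fracUnique > 1)
        stop("fracDA + fracUnique must not exceed 1")
    .checkPos(baselineSd, "baselineSd"); .checkPos(priorDf, "priorDf")
    .checkPos(priorVar, "priorVar"); .checkPos(censorWidth, "censorWidth")
    if (batchSd < 0 || effectSize < 0)
        stop("batchSd and effectSize must be non-negative")
    .checkSeed(seed)

    set.seed(as.integer(seed))
    nS <- 2L * nPerGroup
    group <- factor(rep(c("NDM", "DM"), each = nPerGroup),
                    levels = c("NDM", "DM"))
    batch <- factor(paste0("B", rep_len(seq_len(nBatches), nPerGroup)))
    batch <- factor(c(as.character(batch), as.character(batch)))
    sid <- c(sprintf("NDM_%02d", seq_len(nPerGroup)),
             sprintf("DM_%02d", seq_len(nPerGroup)))
    pid <- sprintf("PROT%05d", seq_len(nProteins))

    nDA <- round(fracDA * nProteins)
    nUn <- round(fracUnique * nProteins)
    shuffled <- sample.int(nProteins)
    daIdx <- shuffled[seq_len(nDA)]
    unIdx <- shuffled[nDA + seq_len(nUn)]

    delta <- numeric(nProteins)
    if (nDA > 0)
        delta[daIdx] <- sample(c(-1, 1), nDA, replace = TRUE) * effectSize
    sigma2 <- priorVar * priorDf / stats::rchisq(nProteins, df = priorDf)
    baseline <- stats::rnorm(nProteins, baselineMean, baselineSd)
    bEff <- stats::rnorm(nBatches, 0, batchSd)
    names(bEff) <- paste0("B", seq_len(nBatches))

    y <- baseline +
        outer(delta, as.numeric(group == "DM")) +
        matrix(bEff[as.character(batch)], nProteins, nS, byrow = TRUE) +
        matrix(stats::rnorm(nProteins * nS, 0, rep(sqrt(sigma2), nS)),
               nProteins, nS)
    dimnames(y) <- list(pid, sid)

    if (is.finite(censorMid) || censorMid > -Inf) {
        pMiss <- stats::pnorm((censorMid - y) / censorWidth)
        y[stats::runif(length(y)) < pMiss] <- NA_real_
    }

    uniqueGroup <- rep("none", nProteins)
    if (nUn > 0) {
        presentIn <- rep_len(c("DM", "NDM"), nUn)
        uniqueGroup[unIdx] <- presentIn
        for (k in seq_len(nUn)) {
            absent <- if (presentIn[k] == "DM") "NDM" else "DM"
            y[unIdx[k], group == absent] <- NA_real_
        }
    }

    se <- ProteomicsExperiment(y, group, batch)
    rowData(se)$true_log2fc <- delta
    rowData(se)$true_var <- sigma2
    rowData(se)$is_da <- delta != 0
    rowData(se)$unique_group <- uniqueGroup
    S4Vectors::metadata(se)$simulation <- list(
        nProteins = nProteins, nPerGroup = nPerGroup, nBatches = nBatches,
        baselineMean = baselineMean, baselineSd = baselineSd,
        priorDf = priorDf, priorVar = priorVar, fracDA = fracDA,
        effectSize = effectSize, batchSd = batchSd, censorMid = censorMid,
        censorWidth = censorWidth, fracUnique = fracUnique, seed = seed)
    se
}

#' Simulate a gene-level differential-expression table
#'
#' Produces per-gene log fold changes and p-values for the concordance stage.
#' Non-DEG genes receive `logFC ~ N(0, 0.1)` and `p ~ U(0, 1)`; DEG genes
#' receive `|logFC| >= effectSize` (random sign, exponential excess) and small
#' p-values, so they pass the standard thresholds (p <= 0.05, |logFC| >= 0.5)
#' when `effectSize >= 0.5`.
#'
#' @param nGenes number of genes.
#' @param fracDEG fraction of genes differentially expressed (ignored when
#'   `degIds` is given).
#' @param effectSize minimum |logFC| of DEG genes.
#' @param seed integer seed.
#' @param geneIds optional gene identifiers (default `GENE00001`, ...).
#' @param degIds optional explicit set of DEG gene ids (subset of `geneIds`).
#' @return list with `genes` (data.frame: gene, logfc, p) and `truth`
#'   (data.frame: gene, is_deg, true_logfc).
#' @export
simulateGeneTable <- function(nGenes, fracDEG = 0.1, effectSize = 1,
        seed = 1, geneIds = NULL, degIds = NULL) {
    .checkCount(nGenes, "nGenes"); .checkFrac(fracDEG, "fracDEG")
    .checkSeed(seed)
    if (is.null(geneIds)) geneIds <- sprintf("GENE%05d", seq_len(nGenes))
    if (length(geneIds) != nGenes || anyDuplicated(geneIds))
        stop("'geneIds' must be ", nGenes, " unique identifiers")
    set.seed(as.integer(seed))
    if (is.null(degIds)) {
        nDEG <- round(fracDEG * nGenes)
        degIds <- sample(geneIds, nDEG)
    } else if (!all(degIds %in% geneIds)) {
        stop("'degIds' must be a subset of 'geneIds'")
    }
    isDeg <- geneIds %in% degIds
    logfc <- stats::rnorm(nGenes, 0, 0.1)
    p <- stats::runif(nGenes)
    nDEG <- sum(isDeg)
    if (nDEG > 0) {
        sgn <- sample(c(-1, 1), nDEG, replace = TRUE)
        logfc[isDeg] <- sgn * (effectSize + stats::rexp(nDEG, rate = 4))
        p[isDeg] <- stats::runif(nDEG, 0, 0.01)
    }
    list(genes = data.frame(gene = geneIds, logfc = logfc, p = p,
                            stringsAsFactors = FALSE),
         truth = data.frame(gene = geneIds, is_deg = isDeg,
                            true_logfc = ifelse(isDeg, logfc, 0),
                            stringsAsFactors = FALSE))
}

#' Build a synthetic category collection for enrichment testing
#'
#' Draws random membership categories over a protein universe, optionally
#' "planting" categories that preferentially sample proteins whose true log2
#' fold change has a given sign (alternating positive/negative across planted
#' categories), and always appends a near-duplicate (>= 90% shared members) of
#' the first unplanted category to exercise redundancy clustering.
#'
#' @param proteinIds universe of protein identifiers.
#' @param nCategories number of categories (>= 2; the last one is the
#'   near-duplicate).
#' @param sizeRange integer pair: min and max category size.
#' @param nPlanted number of planted (signal-bearing) categories.
#' @param plantedBias sampling-weight multiplier for proteins matching the
#'   planted sign; 0 = no planting signal.
#' @param seed integer seed.
#' @param trueLog2fc named numeric vector of true effects over `proteinIds`
#'   (required when `nPlanted > 0`).
#' @return a [CategorySets-class] object.
#' @export
makeCategoryCollection <- function(proteinIds, nCategories,
        sizeRange = c(10, 40), nPlanted = 0, plantedBias = 0, seed = 1,
        trueLog2fc = NULL) {
    if (anyDuplicated(proteinIds)) stop("'proteinIds' must be unique")
    .checkCount(nCategories, "nCategories")
    if (nCategories < 2L) stop("'nCategories' must be at least 2")
    if (length(sizeRange) != 2L || sizeRange[1] < 2L ||
        sizeRange[2] > length(proteinIds) || sizeRange[1] > sizeRange[2])
        stop("'sizeRange' must lie within [2, number of proteins]")
    if (nPlanted > nCategories - 1L)
        stop("'nPlanted' must leave room for the duplicate pair")
    if (nPlanted > 0 && is.null(trueLog2fc))
        stop("'trueLog2fc' is required when planting categories")
    .checkSeed(seed)
    set.seed(as.integer(seed))

    n <- length(proteinIds)
    ids <- sprintf("CAT%03d", seq_len(nCategories))
    sets <- vector("list", nCategories)
    desc <- character(nCategories)
    sizes <- sample(seq(sizeRange[1], sizeRange[2]), nCategories,
                    replace = TRUE)
    plantSign <- rep_len(c(1, -1), max(nPlanted, 1L))
    for (k in seq_len(nCategories - 1L)) {
        if (k <= nPlanted) {
            sgn <- plantSign[k]
            w <- 1 + plantedBias *
                as.numeric(sign(trueLog2fc[proteinIds]) == sgn)
            sets[[k]] <- sort(sample(proteinIds, sizes[k], prob = w))
            desc[k] <- sprintf("planted_%s", if (sgn > 0) "up" else "down")
        } else {
            sets[[k]] <- sort(sample(proteinIds, sizes[k]))
            desc[k] <- "random"
        }
    }
    # near-duplicate of the first unplanted category (>= 90% shared members)
    src <- min(nPlanted + 1L, nCategories - 1L)
    base <- sets[[src]]
    nSwap <- floor(length(base) / 10)
    dup <- base
    if (nSwap > 0) {
        out <- setdiff(proteinIds, base)
        dup <- sort(c(base[-sample.int(length(base), nSwap)],
                      sample(out, nSwap)))
    }
    sets[[nCategories]] <- dup
    desc[nCategories] <- sprintf("near_duplicate_of_%s", ids[src])
    names(sets) <- ids
    new("CategorySets", sets = sets, descriptions = desc)
}
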