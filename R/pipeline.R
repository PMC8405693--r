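#' Default pipeline configuration
#'
#' Returns the full configuration list accepted by [runPipeline()], with the
#' documented defaults for every stage. Unknown keys in a user configuration
#' are rejected; values given by the user override these defaults.
#'
#' @return nested named list with sections `seed`, `simulate`, `preprocess`,
#'   `diffabund`, `enrichment`, `concordance`.
#' @export
defaultPipelineConfig <- function() {
    list(
        seed = 1,
        simulate = list(
            nProteins = 300, nPerGroup = 10, nBatches = 2,
            baselineMean = 25, baselineSd = 2, priorDf = 6, priorVar = 0.16,
            fracDA = 0.1, effectSize = 1, batchSd = 0.25,
            censorMid = 23.45, censorWidth = 1, fracUnique = 0.02,
            nCategories = 25, categorySizeRange = c(10, 40), nPlanted = 2,
            plantedBias = 20, nGenes = 500, fracDEG = 0.1,
            geneEffectSize = 1),
        preprocess = list(minPerGroup = 4, nminPresent = NULL,
                          nmaxAbsent = NULL),
        diffabund = list(nImputations = 20, qThreshold = 0.1, minPass = NULL,
                         qMethod = "bh"),
        enrichment = list(nPerm = 2000, fdr = 0.10, minNodes = 3,
                          cutHeight = 0.7),
        concordance = list(pThreshold = 0.05, logfcThreshold = 0.5))
}

.mergeConfig <- function(default, user, path = "config") {
    if (is.null(user)) return(default)
    bad <- setdiff(names(user), names(default))
    if (length(bad))
        stop(sprintf("unknown %s key(s): %s", path,
                     paste(bad, collapse = ", ")))
    for (k in names(user)) {
        default[[k]] <- if (is.list(default[[k]]) && is.list(user[[k]]))
            .mergeConfig(default[[k]], user[[k]], paste0(path, "$", k))
            else user[[k]]
    }
    default
}

.logLine <- function(con, stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    message(line)
    if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> preprocess (median normalization, missingness
#' routing, detection-limit heuristic) -> repeated-imputation stability
#' selection -> mean-t category enrichment with redundancy clustering ->
#' transcriptome concordance, writing every stage table, a log and a run
#' manifest to `outDir`. Re-running with an identical configuration
#' reproduces byte-identical output tables.
#'
#' @param config nested list (see [defaultPipelineConfig()]) or path to a
#'   YAML file with the same structure; partial configurations are completed
#'   with the defaults, unknown keys are rejected.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest as a named list (also written to
#'   `manifest.txt`): parameter snapshot, per-stage record counts and md5
#'   digests of every output table.
#' @export
runPipeline <- function(config = list(), outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    cfg <- .mergeConfig(defaultPipelineConfig(), config)
    da <- cfg$diffabund
    if (!is.null(da$minPass) && da$minPass > da$nImputations)
        stop("validation error: minPass exceeds nImputations")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    t0 <- Sys.time()
    logCon <- file(file.path(outDir, "pipeline.log"), open = "wt")
    on.exit(close(logCon), add = TRUE)
    counts <- list()

    sim <- cfg$simulate
    se <- simulateProteome(sim$nProteins, sim$nPerGroup, sim$nBatches,
        sim$baselineMean, sim$baselineSd, sim$priorDf, sim$priorVar,
        sim$fracDA, sim$effectSize, sim$batchSd, sim$censorMid,
        sim$censorWidth, sim$fracUnique, seed = cfg$seed)
    truth <- as.data.frame(simulationTruth(se))
    utils::write.table(truth, file.path(outDir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeIntensityTsv(.assayMatrix(se), file.path(outDir, "intensity.tsv"))
    writeDesignTsv(se, file.path(outDir, "design.tsv"))
    counts$proteins_simulated <- nrow(se)
    .logLine(logCon, "simulate", sprintf("%d proteins x %d samples",
             nrow(se), ncol(se)))

    gene <- simulateGeneTable(sim$nGenes, sim$fracDEG, sim$geneEffectSize,
                              seed = cfg$seed + 1L)
    writeGeneTable(gene$genes, file.path(outDir, "genes.tsv"))

    sets <- makeCategoryCollection(rownames(se), sim$nCategories,
        sim$categorySizeRange, sim$nPlanted, sim$plantedBias,
        seed = cfg$seed + 2L, trueLog2fc = stats::setNames(truth$true_log2fc,
                                                           truth$protein_id))
    writeGmt(sets, file.path(outDir, "categories.gmt"))

    se <- medianNormalize(se)
    writeIntensityTsv(.assayMatrix(se), file.path(outDir, "normalized.tsv"))
    pp <- cfg$preprocess
    routing <- routeByMissingness(se, pp$minPerGroup)
    utils::write.table(routing$counts, file.path(outDir, "routing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    uniq <- classifyDetectionLimit(se, routing$heuristic,
                                   pp$nminPresent, pp$nmaxAbsent)
    utils::write.table(uniq, file.path(outDir, "unique_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$proteins_quantitative <- length(routing$quantitative)
    counts$proteins_heuristic <- length(routing$heuristic)
    counts$unique_calls <- sum(uniq$call != "insufficient")
    .logLine(logCon, "preprocess", sprintf(
        "%d quantitative, %d heuristic (%d unique calls)",
        counts$proteins_quantitative, counts$proteins_heuristic,
        counts$unique_calls))

    res <- runStabilitySelection(se[routing$quantitative, ],
        nImputations = da$nImputations, qThreshold = da$qThreshold,
        minPass = da$minPass, qMethod = da$qMethod, seed = cfg$seed)
    resTab <- as.data.frame(resultsTable(res))
    utils::write.table(resTab, file.path(outDir, "diffabund_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(perRoundTable(res)),
                       file.path(outDir, "diffabund_per_round.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$proteins_called <- sum(resTab$called)
    .logLine(logCon, "diffabund", sprintf("%d called (%d up, %d down)",
        counts$proteins_called, sum(resTab$direction == "up"),
        sum(resTab$direction == "down")))

    en <- cfg$enrichment
    tStats <- stats::setNames(resTab$median_t, resTab$protein_id)
    enr <- meanStatEnrichment(tStats, sets, nPerm = en$nPerm, fdr = en$fdr,
                              seed = cfg$seed)
    enrTab <- as.data.frame(resultsTable(enr))
    utils::write.table(enrTab, file.path(outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$categories_significant <- sum(enrTab$significant)
    if (counts$categories_significant > 0) {
        clus <- clusterCategories(enr, sets, minNodes = en$minNodes,
                                  cutHeight = en$cutHeight)
    } else {
        clus <- data.frame(cluster_id = character(), n_members = integer(),
                           members = character(),
                           representative_id = character(),
                           included = logical())
    }
    utils::write.table(clus, file.path(outDir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    counts$clusters_included <- sum(clus$included)
    .logLine(logCon, "enrich", sprintf(
        "%d significant categories, %d clusters (>= %d nodes)",
        counts$categories_significant, counts$clusters_included,
        en$minNodes))

    co <- cfg$concordance
    degTab <- callDEG(gene$genes, co$pThreshold, co$logfcThreshold)
    degs <- degTab$gene[degTab$called]
    idMap <- data.frame(protein_id = rownames(se), gene = rownames(se),
                        stringsAsFactors = FALSE)
    mol <- intersectMolecules(calledProteins(res), degs, idMap)
    summaryLines <- c(
        sprintf("deg_called\t%d", length(degs)),
        sprintf("shared_molecules\t%d", length(mol$shared)),
        sprintf("shared_molecule_ids\t%s",
                paste(mol$shared, collapse = ",")),
        sprintf("unmapped_proteins\t%d", length(mol$unmapped)))
    writeLines(summaryLines, file.path(outDir, "concordance_summary.txt"))
    counts$degs_called <- length(degs)
    counts$shared_molecules <- length(mol$shared)
    .logLine(logCon, "concord", sprintf("%d DEGs, %d shared molecules",
             counts$degs_called, counts$shared_molecules))

    outputs <- c("truth.tsv", "intensity.tsv", "design.tsv", "genes.tsv",
                 "categories.gmt", "normalized.tsv", "routing.tsv",
                 "unique_calls.tsv", "diffabund_results.tsv",
                 "diffabund_per_round.tsv", "enrichment.tsv", "clusters.tsv",
                 "concordance_summary.txt")
    digests <- tools::md5sum(file.path(outDir, outputs))
    names(digests) <- outputs
    manifest <- list(package_version =
                         as.character(utils::packageVersion("lfqStability")),
                     started = format(t0, "%Y-%m-%d %H:%M:%S"),
                     finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     parameters = cfg, record_counts = counts,
                     digests = as.list(digests))
    writeLines(yaml::as.yaml(manifest), file.path(outDir, "manifest.txt"))
    invisible(manifest)
}
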