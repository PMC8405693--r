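#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData rowData<-
NULL

#' Collection of named categories (gene/protein sets)
#'
#' Thin S4 container for GO-style category collections as read from GMT files
#' or produced by [makeCategoryCollection()]. Each category has a unique id,
#' a free-text description and a character vector of member identifiers.
#'
#' @slot sets named list of character vectors (members per category).
#' @slot descriptions character vector parallel to `sets`.
#' @export
setClass("CategorySets",
    slots = c(sets = "list", descriptions = "character"))

setValidity("CategorySets", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (length(object@sets) == 0L)
        msg <- c(msg, "collection contains no categories")
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        msg <- c(msg, "every category must be named")
    if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate category ids: %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (!all(vapply(object@sets, is.character, logical(1))))
        msg <- c(msg, "category members must be character vectors")
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "descriptions must parallel sets")
    if (length(msg)) msg else TRUE
})

#' Results of repeated-imputation stability selection
#'
#' Holds the per-protein aggregate over imputation rounds (effect size, fold
#' change, q-value summary, pass rate, call and direction), the per-round long
#' table, the empirical-Bayes prior estimated in each round and the run
#' parameters. Created by [runStabilitySelection()].
#'
#' @slot results `DataFrame`, one row per protein (aggregate).
#' @slot perRound `DataFrame`, one row per protein x imputation round.
#' @slot priors `DataFrame`, per-round prior degrees of freedom and variance.
#' @slot params list of run parameters (rounds, thresholds, q method, seed).
#' @export
setClass("DifferentialResults",
    slots = c(results = "DataFrame", perRound = "DataFrame",
              priors = "DataFrame", params = "list"))

setValidity("DifferentialResults", function(object) {
    msg <- character()
    need <- c("protein_id", "median_log2fc", "fold_change", "median_q",
              "pass_rate", "n_pass", "called", "direction")
    miss <- setdiff(need, colnames(object@results))
    if (length(miss))
        msg <- c(msg, sprintf("results lacks columns: %s",
            paste(miss, collapse = ", ")))
    if (!length(msg)) {
        pr <- object@results$pass_rate
        if (any(pr < 0 | pr > 1))
            msg <- c(msg, "pass_rate outside [0, 1]")
        if (anyDuplicated(object@results$protein_id))
            msg <- c(msg, "duplicate protein ids in results")
    }
    if (length(msg)) msg else TRUE
})

#' Results of mean-statistic category enrichment
#'
#' One row per category: member count after universe restriction, observed
#' mean t-statistic, directional permutation p-values, per-direction BH
#' q-values, significance flag and direction. Created by
#' [meanStatEnrichment()].
#'
#' @slot table `DataFrame` of per-category results.
#' @slot params list (permutations, FDR threshold, seed, universe size).
#' @export
setClass("EnrichmentResults",
    slots = c(table = "DataFrame", params = "list"))

setValidity("EnrichmentResults", function(object) {
    need <- c("category_id", "n_members", "mean_t", "p_up", "p_down",
              "q_up", "q_down", "significant", "direction")
    miss <- setdiff(need, colnames(object@table))
    if (length(miss))
        sprintf("table lacks columns: %s", paste(miss, collapse = ", "))
    else TRUE
})
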