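#' @describeIn CategorySets-class number of categories.
#' @export
setMethod("length", "CategorySets", function(x) length(x@sets))

#' @describeIn CategorySets-class category ids.
#' @export
setMethod("names", "CategorySets", function(x) names(x@sets))

#' @describeIn CategorySets-class list of member vectors, named by category id.
#' @export
setMethod("categoryMembers", "CategorySets", function(x) x@sets)

#' @describeIn CategorySets-class descriptions, named by category id.
#' @export
setMethod("categoryDescriptions", "CategorySets", function(x) {
    stats::setNames(x@descriptions, names(x@sets))
})

#' @describeIn CategorySets-class extract a sub-collection.
#' @param i index (id, integer or logical) of categories to keep.
#' @export
setMethod("[", "CategorySets", function(x, i) {
    new("CategorySets", sets = x@sets[i], descriptions = x@descriptions[i])
})

setMethod("show", "CategorySets", function(object) {
    sz <- lengths(object@sets)
    cat("CategorySets with", length(object@sets), "categories\n")
    cat("  member counts:", min(sz), "-", max(sz),
        sprintf("(median %g)\n", stats::median(sz)))
})

#' @describeIn DifferentialResults-class per-protein aggregate table.
#' @export
setMethod("resultsTable", "DifferentialResults", function(x) x@results)

#' @describeIn DifferentialResults-class per-round long table.
#' @export
setMethod("perRoundTable", "DifferentialResults", function(x) x@perRound)

#' @describeIn DifferentialResults-class ids of proteins called differentially
#'   abundant under the stability rule.
#' @export
setMethod("calledProteins", "DifferentialResults", function(x) {
    as.character(x@results$protein_id[x@results$called])
})

#' @describeIn DifferentialResults-class per-round empirical-Bayes priors.
#' @export
setMethod("roundPriors", "DifferentialResults", function(x) x@priors)

setMethod("show", "DifferentialResults", function(object) {
    p <- object@params
    cat("DifferentialResults:", nrow(object@results), "proteins,",
        p$nImputations, "imputation rounds\n")
    cat(sprintf("  stability rule: q < %g in >= %d rounds (%s q-values)\n",
        p$qThreshold, p$minPass, p$qMethod))
    n <- sum(object@results$called)
    cat("  called:", n,
        sprintf("(%d up, %d down)\n",
            sum(object@results$direction == "up"),
            sum(object@results$direction == "down")))
})

#' @describeIn EnrichmentResults-class per-category table.
#' @export
setMethod("resultsTable", "EnrichmentResults", function(x) x@table)

#' @describeIn EnrichmentResults-class ids of significant categories.
#' @export
setMethod("significantCategories", "EnrichmentResults", function(x) {
    as.character(x@table$category_id[x@table$significant])
})

setMethod("show", "EnrichmentResults", function(object) {
    cat("EnrichmentResults:", nrow(object@table), "categories,",
        object@params$nPerm, "permutations\n")
    cat(sprintf("  significant at %g%% FDR: %d\n",
        100 * object@params$fdr, sum(object@table$significant)))
})
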