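#' @rdname DifferentialResults-class
#' @param x a `DifferentialResults` or `EnrichmentResults` object.
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname DifferentialResults-class
#' @export
setGeneric("perRoundTable", function(x) standardGeneric("perRoundTable"))

#' @rdname DifferentialResults-class
#' @export
setGeneric("calledProteins", function(x) standardGeneric("calledProteins"))

#' @rdname DifferentialResults-class
#' @export
setGeneric("roundPriors", function(x) standardGeneric("roundPriors"))

#' @rdname EnrichmentResults-class
#' @param x an `EnrichmentResults` object.
#' @export
setGeneric("significantCategories",
    function(x) standardGeneric("significantCategories"))

#' @rdname CategorySets-class
#' @param x a `CategorySets` object.
#' @export
setGeneric("categoryMembers", function(x) standardGeneric("categoryMembers"))

#' @rdname CategorySets-class
#' @export
setGeneric("categoryDescriptions",
    function(x) standardGeneric("categoryDescriptions"))
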