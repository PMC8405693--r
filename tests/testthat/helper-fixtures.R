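# small fixtures shared across test files

# tiny complete experiment with known group/batch structure
tinyExperiment <- function(nProteins = 6, nPerGroup = 3, values = NULL,
                           batch = NULL) {
    n <- 2 * nPerGroup
    if (is.null(values)) {
        set.seed(42)
        values <- matrix(rnorm(nProteins * n, 25), nProteins, n)
    }
    dimnames(values) <- list(sprintf("P%02d", seq_len(nProteins)),
                             sprintf("S%02d", seq_len(n)))
    group <- rep(c("NDM", "DM"), each = nPerGroup)
    if (is.null(batch)) batch <- rep("B1", n)
    ProteomicsExperiment(values, group, batch)
}

# two-category collection over an explicit universe
tinySets <- function(sets, desc = NULL) {
    if (is.null(desc)) desc <- rep("fixture", length(sets))
    new("CategorySets", sets = sets, descriptions = desc)
}

# classical OLS oracle: per-protein lm() fit, disease coefficient stats
olsOracle <- function(se) {
    m <- SummarizedExperiment::assay(se)
    g <- groupLabels(se); b <- batchLabels(se)
    out <- lapply(rownames(m), function(p) {
        d <- data.frame(y = m[p, ], group = g, batch = b)
        fit <- if (nlevels(b) > 1) lm(y ~ group + batch, d)
               else lm(y ~ group, d)
        sm <- summary(fit)
        co <- grep("^group", rownames(sm$coefficients))
        data.frame(protein_id = p,
                   coef = sm$coefficients[co, 1],
                   t = sm$coefficients[co, 3],
                   p = sm$coefficients[co, 4],
                   s_sq = sm$sigma^2,
                   df = fit$df.residual)
    })
    do.call(rbind, out)
}
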