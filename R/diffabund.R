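#' Single group-wise Gaussian imputation of missing intensities
#'
#' Replaces every missing entry of protein g in disease group G by an
#' independent draw from a normal distribution with the mean and standard
#' deviation of the *observed* (g, G) values — the imputation model used for
#' repeated-imputation inference. Observed entries are untouched.
#'
#' @param se a `SummarizedExperiment`; every protein must have at least 2
#'   observed values per group (guaranteed upstream by routing with
#'   `minPerGroup >= 4`).
#' @param seed integer seed; a fixed seed gives an identical completion.
#' @return the experiment with a complete `log2intensity` assay.
#' @export
imputeOnce <- function(se, seed = 1) {
    .checkSeed(seed)
    m <- .imputeMatrix(.assayMatrix(se), .groups(se), seed)
    SummarizedExperiment::assay(se, "log2intensity") <- m
    se
}

.imputeMatrix <- function(m, g, seed) {
    set.seed(as.integer(seed))
    for (lv in levels(g)) {
        idx <- which(g == lv)
        sub <- m[, idx, drop = FALSE]
        nObs <- rowSums(!is.na(sub))
        bad <- nObs < 2 & rowSums(is.na(sub)) > 0
        if (any(nObs < 2))
            stop(sprintf(
                "protein(s) with fewer than 2 observed values in group %s: %s",
                lv, paste(utils::head(rownames(m)[nObs < 2], 5),
                          collapse = ", ")))
        mu <- rowMeans(sub, na.rm = TRUE)
        sd <- .rowSdNA(sub)
        pos <- which(is.na(sub))
        if (length(pos)) {
            rows <- ((pos - 1L) %% nrow(sub)) + 1L
            sub[pos] <- stats::rnorm(length(pos), mu[rows], sd[rows])
            m[, idx] <- sub
        }
    }
    m
}

#' Per-protein ordinary least squares with disease and batch predictors
#'
#' Fits, for every protein, the linear model
#' `log2 intensity ~ group + batch` (intercept, disease indicator, reference-
#' coded batch indicators) on a *complete* matrix, sharing one design matrix
#' across proteins. The disease coefficient is DM minus NDM on the log2
#' scale. The batch term is dropped automatically when only one batch exists.
#'
#' @param se a `SummarizedExperiment` with a complete assay (no `NA`), e.g.
#'   from [imputeOnce()].
#' @return data.frame with columns `protein_id`, `log2fc` (disease
#'   coefficient), `stdev_unscaled` (unscaled SE multiplier), `s_sq`
#'   (residual variance), `df_residual`.
#' @export
fitLinearModels <- function(se) {
    m <- .assayMatrix(se)
    if (anyNA(m)) stop("matrix must be complete; impute first")
    X <- .designMatrix(.groups(se), .batches(se))
    .fitMatrix(m, X)
}

.designMatrix <- function(g, b) {
    df <- data.frame(group = g, batch = b)
    X <- if (nlevels(b) > 1L) stats::model.matrix(~ group + batch, df)
         else stats::model.matrix(~ group, df)
    if (qr(X)$rank < ncol(X))
        stop("design error: disease and batch predictors are confounded ",
             "(rank-deficient design matrix)")
    X
}

.fitMatrix <- function(m, X) {
    fit <- stats::lm.fit(X, t(m))
    dfRes <- nrow(X) - ncol(X)
    if (dfRes < 1L) stop("design error: no residual degrees of freedom")
    coefIdx <- grep("^group", colnames(X))
    res <- fit$residuals
    if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
    cf <- fit$coefficients
    if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1L)
    sSq <- colSums(res^2) / dfRes
    xtxInv <- chol2inv(chol(crossprod(X)))
    data.frame(protein_id = rownames(m),
               log2fc = unname(cf[coefIdx, ]),
               stdev_unscaled = sqrt(xtxInv[coefIdx, coefIdx]),
               s_sq = unname(sSq),
               df_residual = dfRes,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Estimates the hyperparameters (prior degrees of freedom `d0`, prior
#' variance `s0Sq`) of the scaled inverse-chi-square distribution assumed for
#' per-protein residual variances, by moment matching on the log scale: with
#' `s_g^2 ~ s0^2 * (chisq_df/df) / (chisq_d0/d0)`, the variance of
#' `log(s_g^2)` equals `trigamma(df/2) + trigamma(d0/2)`, so `d0` solves
#' `trigamma(d0/2) = var(log s^2) - trigamma(df/2)` and `s0Sq` follows from
#' the mean of `log(s^2)`. When the moment equation has no positive solution
#' the variances are fully pooled (`d0 = Inf`) and `s0Sq` is their arithmetic
#' mean. `dfResidual = Inf` is supported for variances that are direct draws
#' from the prior.
#'
#' Zero or non-finite variances are excluded from estimation (they are still
#' moderated normally afterwards).
#'
#' @param sSq per-protein residual variances.
#' @param dfResidual residual degrees of freedom (scalar).
#' @return list with `d0` and `s0Sq`.
#' @export
estimateEBPrior <- function(sSq, dfResidual) {
    ok <- is.finite(sSq) & sSq > 0
    if (sum(ok) < 2L)
        stop("need at least 2 finite positive variances to estimate the prior")
    z <- log(sSq[ok])
    corr <- if (is.finite(dfResidual))
        digamma(dfResidual / 2) - log(dfResidual / 2) else 0
    triDf <- if (is.finite(dfResidual)) trigamma(dfResidual / 2) else 0
    target <- stats::var(z) - triDf
    if (is.na(target) || target <= 0) {
        return(list(d0 = Inf, s0Sq = mean(sSq[ok])))
    }
    d0 <- 2 * .trigammaInverse(target)
    s0Sq <- exp(mean(z) - corr + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0Sq = s0Sq)
}

# Newton solve of trigamma(y) = x (x > 0)
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in seq_len(50)) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
        y <- y + dif
        if (abs(dif) / y < 1e-10) break
    }
    y
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each protein's residual variance toward the empirical-Bayes prior,
#' `s_tilde^2 = (d0 * s0Sq + df * s^2) / (d0 + df)`, and forms the moderated
#' statistic `t = coef / (stdev_unscaled * s_tilde)` with `d0 + df` total
#' degrees of freedom (normal tail when `d0 = Inf`, where `s_tilde^2 = s0Sq`
#' for every protein). `d0 = 0` reduces exactly to classical OLS t-tests.
#'
#' @param fits data.frame from [fitLinearModels()].
#' @param prior list from [estimateEBPrior()] (or a manual `list(d0, s0Sq)`).
#' @return `fits` with added columns `s_tilde_sq`, `t`, `df_total`, `p`.
#' @export
moderateT <- function(fits, prior) {
    d0 <- prior$d0; s0 <- prior$s0Sq
    if (is.null(d0) || is.null(s0) || d0 < 0 || s0 <= 0)
        stop("invalid prior: need d0 >= 0 and s0Sq > 0")
    df <- fits$df_residual
    sTilde <- if (is.infinite(d0)) rep(s0, nrow(fits))
              else (d0 * s0 + df * fits$s_sq) / (d0 + df)
    fits$s_tilde_sq <- sTilde
    fits$t <- fits$log2fc / (fits$stdev_unscaled * sqrt(sTilde))
    fits$df_total <- d0 + df
    fits$p <- 2 * stats::pt(-abs(fits$t), df = fits$df_total)
    fits
}

#' q-values for multiple-testing control
#'
#' Benjamini-Hochberg step-up adjusted p-values (`method = "bh"`, the
#' default) or Storey q-values with the pi0 estimate from the lambda = 0.5
#' tail (`method = "storey"`), capped at 1. BH output is always >= the input
#' p-value; Storey values may be smaller when pi0 < 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"storey"`.
#' @return vector of q-values, same order as `p`.
#' @export
computeQvalues <- function(p, method = c("bh", "storey")) {
    method <- match.arg(method)
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    if (method == "bh") return(stats::p.adjust(p, method = "BH"))
    lambda <- 0.5
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    if (pi0 <= 0) pi0 <- 1 / length(p)
    pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Aggregate per-round fits into stability-selected calls
#'
#' Implements the stability rule over repeated imputations: a protein is
#' called differentially abundant when its q-value fell below `qThreshold` in
#' at least `minPass` of the imputation rounds (default `ceiling(0.6 * M)`,
#' i.e. 30 of 50). Reported effect sizes are medians across rounds; the
#' direction follows the sign of the median log2 fold change for called
#' proteins and is `"none"` otherwise.
#'
#' @param perRound data.frame/DataFrame with columns `round`, `protein_id`,
#'   `log2fc`, `t`, `q` covering the same protein set in every round.
#' @param nImputations number of rounds M.
#' @param qThreshold per-round significance cutoff (default 0.1, strict `<`).
#' @param minPass minimum passing rounds for a call (default
#'   `ceiling(0.6 * nImputations)`).
#' @return `DataFrame`, one row per protein: `protein_id`, `median_log2fc`,
#'   `fold_change` (`2^median_log2fc`), `median_t`, `median_q`, `n_pass`,
#'   `pass_rate`, `called`, `direction`.
#' @export
stabilityAggregate <- function(perRound, nImputations, qThreshold = 0.1,
        minPass = NULL) {
    .checkCount(nImputations, "nImputations")
    .checkFrac(qThreshold, "qThreshold")
    if (is.null(minPass)) minPass <- ceiling(0.6 * nImputations)
    perRound <- as.data.frame(perRound)
    need <- c("round", "protein_id", "log2fc", "t", "q")
    if (!all(need %in% colnames(perRound)))
        stop("perRound lacks columns: ",
             paste(setdiff(need, colnames(perRound)), collapse = ", "))
    rounds <- sort(unique(perRound$round))
    if (length(rounds) != nImputations)
        stop("aggregation error: expected ", nImputations,
             " rounds, found ", length(rounds))
    firstSet <- sort(perRound$protein_id[perRound$round == rounds[1]])
    for (r in rounds) {
        if (!identical(sort(perRound$protein_id[perRound$round == r]),
                       firstSet))
            stop("aggregation error: imputation rounds cover different ",
                 "protein sets")
    }
    sp <- split(perRound, perRound$protein_id)
    agg <- do.call(rbind, lapply(sp, function(d) {
        nPass <- sum(d$q < qThreshold)
        data.frame(protein_id = d$protein_id[1],
                   median_log2fc = stats::median(d$log2fc),
                   median_t = stats::median(d$t),
                   median_q = stats::median(d$q),
                   n_pass = nPass, stringsAsFactors = FALSE)
    }))
    agg <- agg[order(agg$protein_id), , drop = FALSE]
    agg$fold_change <- 2^agg$median_log2fc
    agg$pass_rate <- agg$n_pass / nImputations
    agg$called <- agg$n_pass >= minPass
    agg$direction <- ifelse(!agg$called, "none",
                            ifelse(agg$median_log2fc > 0, "up", "down"))
    DataFrame(agg[, c("protein_id", "median_log2fc", "fold_change",
                      "median_t", "median_q", "n_pass", "pass_rate",
                      "called", "direction")], row.names = NULL)
}

#' Stability call and direction from printed summaries
#'
#' Applies the stability-selection decision rule to per-protein fold changes
#' and imputation pass rates as they appear in a published results table:
#' called when the pass rate is at least `minPassRate` (the 30-of-50
#' fraction, 0.6), direction up when the fold change exceeds 1 and down when
#' below 1.
#'
#' @param foldChange per-protein fold change (raw scale, DM / NDM).
#' @param passRate fraction of imputation rounds with q below threshold.
#' @param minPassRate minimum pass rate for a call (default 0.6).
#' @return data.frame with columns `called` and `direction`.
#' @export
applyStabilityRule <- function(foldChange, passRate, minPassRate = 0.6) {
    if (length(foldChange) != length(passRate))
        stop("'foldChange' and 'passRate' must have equal length")
    called <- passRate >= minPassRate - 1e-12
    data.frame(called = called,
               direction = ifelse(!called, "none",
                                  ifelse(foldChange > 1, "up", "down")),
               stringsAsFactors = FALSE)
}

#' Repeated-imputation moderated regression with stability selection
#'
#' The central inference routine: for each of `nImputations` rounds, complete
#' the matrix by group-wise Gaussian imputation ([imputeOnce()]), fit
#' per-protein linear models with disease and batch predictors
#' ([fitLinearModels()]), re-estimate the empirical-Bayes variance prior on
#' that completed dataset ([estimateEBPrior()]), moderate ([moderateT()]) and
#' convert p-values to q-values ([computeQvalues()]); then aggregate rounds
#' with the stability rule ([stabilityAggregate()]). Round r uses an
#' independent child seed derived from the master seed, so the full run is
#' reproducible and individual rounds can be replayed.
#'
#' @param se a `SummarizedExperiment`, normally restricted to the
#'   quantitative routing list (>= 4 observations per group per protein).
#' @param nImputations number of imputation rounds (default 50).
#' @param qThreshold per-round q cutoff (default 0.1).
#' @param minPass rounds required for a call (default `ceiling(0.6 * M)`).
#' @param qMethod `"bh"` or `"storey"`.
#' @param seed master seed.
#' @return a [DifferentialResults-class] object.
#' @examples
#' se <- simulateProteome(150, seed = 7)
#' se <- medianNormalize(se)
#' keep <- routeByMissingness(se)$quantitative
#' res <- runStabilitySelection(se[keep, ], nImputations = 5, seed = 7)
#' resultsTable(res)
#' @export
runStabilitySelection <- function(se, nImputations = 50, qThreshold = 0.1,
        minPass = NULL, qMethod = c("bh", "storey"), seed = 1) {
    qMethod <- match.arg(qMethod)
    .checkCount(nImputations, "nImputations")
    if (is.null(minPass)) minPass <- ceiling(0.6 * nImputations)
    .checkCount(minPass, "minPass")
    if (minPass > nImputations)
        stop("'minPass' cannot exceed 'nImputations'")
    .checkSeed(seed)
    m <- .assayMatrix(se)
    g <- .groups(se)
    X <- .designMatrix(g, .batches(se))
    seeds <- .childSeeds(seed, nImputations)
    perRound <- vector("list", nImputations)
    priors <- data.frame(round = seq_len(nImputations), d0 = NA_real_,
                         s0_sq = NA_real_)
    for (r in seq_len(nImputations)) {
        comp <- .imputeMatrix(m, g, seeds[r])
        fits <- .fitMatrix(comp, X)
        prior <- estimateEBPrior(fits$s_sq, fits$df_residual[1])
        mod <- moderateT(fits, prior)
        mod$q <- computeQvalues(mod$p, method = qMethod)
        mod$round <- r
        perRound[[r]] <- mod[, c("round", "protein_id", "log2fc", "s_sq",
                                 "t", "p", "q")]
        priors$d0[r] <- prior$d0
        priors$s0_sq[r] <- prior$s0Sq
    }
    perRound <- do.call(rbind, perRound)
    agg <- stabilityAggregate(perRound, nImputations, qThreshold, minPass)
    new("DifferentialResults",
        results = agg,
        perRound = DataFrame(perRound, row.names = NULL),
        priors = DataFrame(priors, row.names = NULL),
        params = list(nImputations = nImputations, qThreshold = qThreshold,
                      minPass = minPass, qMethod = qMethod, seed = seed))
}
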