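test_that("imputation touches only missing entries and matches the observed moments", {
    se <- simulateProteome(40, seed = 19)
    keep <- routeByMissingness(se)$quantitative
    se <- se[keep, ]
    m0 <- SummarizedExperiment::assay(se)
    c1 <- SummarizedExperiment::assay(imputeOnce(se, seed = 1))
    c2 <- SummarizedExperiment::assay(imputeOnce(se, seed = 1))
    c3 <- SummarizedExperiment::assay(imputeOnce(se, seed = 2))
    expect_false(anyNA(c1))
    expect_identical(c1, c2)
    obs <- !is.na(m0)
    expect_identical(c1[obs], m0[obs])
    expect_identical(c3[obs], m0[obs])
    expect_false(identical(c1[!obs], c3[!obs]))

    # fully observed matrix is returned unchanged
    full <- tinyExperiment(5, 4)
    expect_identical(SummarizedExperiment::assay(imputeOnce(full, 3)),
                     SummarizedExperiment::assay(full))
})

test_that("imputed draws reproduce the observed group mean", {
    # one protein: observed DM values with mean 20, sd 1; 3 missing DM entries
    set.seed(99)
    obsDM <- as.numeric(scale(rnorm(7))) + 20   # exact mean 20, sd 1
    v <- matrix(rnorm(20, 20), 1, 20)
    v[1, 11:17] <- obsDM
    v[1, 18:20] <- NA
    se <- tinyExperiment(1, 10, values = v)
    draws <- vapply(seq_len(3000), function(i)
        SummarizedExperiment::assay(imputeOnce(se, i))[1, 18:20],
        numeric(3))
    mcse <- 1 / sqrt(length(draws))
    expect_lt(abs(mean(draws) - 20), 3 * mcse)
    expect_equal(sd(draws), 1, tolerance = 0.05)
})

test_that("imputation errors on proteins with under 2 observations in a group", {
    v <- matrix(rnorm(20, 25), 1, 20)
    v[1, 1:9] <- NA
    se <- tinyExperiment(1, 10, values = v)
    expect_error(imputeOnce(se, 1), "P01")
})

test_that("per-protein OLS matches hand computation and the lm() oracle", {
    # single batch, DM (1,2,3) vs NDM (2,3,4)
    v <- matrix(c(2, 3, 4, 1, 2, 3), 1, 6)
    se <- tinyExperiment(1, 3, values = v)
    f <- fitLinearModels(se)
    expect_equal(f$log2fc, -1)
    expect_equal(f$s_sq, 1)
    expect_identical(f$df_residual, 4L)
    expect_equal(f$log2fc / (f$stdev_unscaled * sqrt(f$s_sq)), -1.2247,
                 tolerance = 1e-4)

    # identical group patterns with equal means -> zero coefficient
    v2 <- matrix(rep(c(1, 2, 3), 2), 1, 6)
    expect_equal(fitLinearModels(tinyExperiment(1, 3, values = v2))$log2fc, 0)

    # with batches: agrees with a per-protein lm() refit oracle
    se3 <- simulateProteome(30, censorMid = -Inf, fracUnique = 0, seed = 23)
    f3 <- fitLinearModels(se3)
    o3 <- olsOracle(se3)
    expect_equal(f3$log2fc, o3$coef, tolerance = 1e-10)
    expect_equal(f3$s_sq, o3$s_sq, tolerance = 1e-10)

    # shifting one batch moves batch coefficients, not the disease one
    m <- SummarizedExperiment::assay(se3)
    shift <- ifelse(batchLabels(se3) == "B2", 5, 0)
    m2 <- sweep(m, 2, shift, `+`)
    se4 <- ProteomicsExperiment(m2, as.character(groupLabels(se3)),
                                as.character(batchLabels(se3)))
    expect_equal(fitLinearModels(se4)$log2fc, f3$log2fc, tolerance = 1e-10)
})

test_that("confounded disease and batch is refused before fitting", {
    v <- matrix(rnorm(12, 25), 2, 6)
    se <- tinyExperiment(2, 3, values = v,
                         batch = c("B1", "B1", "B1", "B2", "B2", "B2"))
    expect_error(fitLinearModels(se), "confounded")
})

test_that("EB prior recovery from direct draws, data, and the grid oracle", {
    # direct draws from the prior (df = Inf)
    set.seed(7)
    s2 <- 1 * 4 / rchisq(5000, 4)
    pr <- estimateEBPrior(s2, Inf)
    expect_equal(pr$d0, 4, tolerance = 0.2)
    expect_equal(pr$s0Sq, 1, tolerance = 0.1)

    # sample variances with finite df on top of the prior
    sigma2 <- 1 * 4 / rchisq(5000, 4)
    s2f <- sigma2 * rchisq(5000, 16) / 16
    prf <- estimateEBPrior(s2f, 16)
    expect_equal(prf$d0, 4, tolerance = 0.2)
    expect_equal(prf$s0Sq, 1, tolerance = 0.1)

    # brute-force grid oracle: maximize the scaled-F likelihood of s^2
    grid <- expand.grid(d0 = seq(2, 8, by = 0.1),
                        s0 = seq(0.5, 2, by = 0.02))
    ll <- mapply(function(d0, s0) {
        sum(stats::df(s2f / s0, 16, d0, log = TRUE)) -
            length(s2f) * log(s0)
    }, grid$d0, grid$s0)
    best <- grid[which.max(ll), ]
    expect_equal(prf$d0, best$d0, tolerance = 0.15)
    expect_equal(prf$s0Sq, best$s0, tolerance = 0.1)

    # all-equal variances pool fully to the common value
    pe <- estimateEBPrior(rep(0.3, 50), 16)
    expect_identical(pe$d0, Inf)
    expect_equal(pe$s0Sq, 0.3)

    expect_error(estimateEBPrior(c(0.5), 16), "at least 2")
})

test_that("EB prior agrees with the limma cross-check", {
    skip_if_not_installed("limma")
    set.seed(15)
    sigma2 <- 0.16 * 6 / rchisq(3000, 6)
    s2 <- sigma2 * rchisq(3000, 16) / 16
    ours <- estimateEBPrior(s2, 16)
    lim <- limma::fitFDist(s2, df1 = 16)
    expect_equal(ours$d0, lim$df2, tolerance = 0.02)
    expect_equal(ours$s0Sq, lim$scale, tolerance = 0.02)
})

test_that("moderation limits: d0 = 0 is classical OLS, d0 = Inf pools fully", {
    se <- simulateProteome(100, censorMid = -Inf, fracUnique = 0, seed = 29)
    fits <- fitLinearModels(se)
    # no-moderation limit against the from-scratch lm() oracle
    mod0 <- moderateT(fits, list(d0 = 0, s0Sq = 1))
    oracle <- olsOracle(se)
    expect_equal(mod0$t, oracle$t, tolerance = 1e-10)
    expect_equal(mod0$p, oracle$p, tolerance = 1e-10)
    # full pooling: common variance, ordering by |coef|
    modInf <- moderateT(fits, list(d0 = Inf, s0Sq = 0.2))
    expect_true(all(modInf$s_tilde_sq == 0.2))
    expect_identical(order(abs(modInf$t)), order(abs(fits$log2fc)))
})

test_that("moderated variances shrink toward truth (lower MSE than raw)", {
    se <- simulateProteome(2000, censorMid = -Inf, fracUnique = 0, seed = 31)
    fits <- fitLinearModels(se)
    prior <- estimateEBPrior(fits$s_sq, fits$df_residual[1])
    mod <- moderateT(fits, prior)
    truth <- simulationTruth(se)$true_var
    mseRaw <- mean((fits$s_sq - truth)^2)
    mseMod <- mean((mod$s_tilde_sq - truth)^2)
    expect_lt(mseMod, mseRaw)
})

test_that("q-values: BH hand oracle, monotonicity, Storey", {
    expect_equal(computeQvalues(0.01), 0.01)
    expect_equal(computeQvalues(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4))
    set.seed(3)
    p <- runif(200)^2
    q <- computeQvalues(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    perm <- sample(200)
    expect_equal(computeQvalues(p[perm]), q[perm])
    # Storey with pi0 < 1 can drop below BH but never below pi0 * BH
    qs <- computeQvalues(p, "storey")
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    expect_equal(qs, pmin(1, pi0 * q))
    expect_error(computeQvalues(c(0.5, 1.2)), "0, 1")
})

test_that("stability aggregation implements the 30-of-50 rule and medians", {
    set.seed(41)
    M <- 50
    mkRound <- function(r, qs) {
        data.frame(round = r, protein_id = c("A", "B", "C"),
                   log2fc = c(-1, 0.5, 0.1) + rnorm(3, 0, 0.01),
                   t = c(-5, 3, 0.5), q = qs)
    }
    # A: significant in 34 rounds; B: 29 rounds; C: never
    perRound <- do.call(rbind, lapply(1:M, function(r)
        mkRound(r, c(if (r <= 34) 0.01 else 0.5,
                     if (r <= 29) 0.01 else 0.5, 0.8))))
    agg <- as.data.frame(stabilityAggregate(perRound, M))
    expect_identical(agg$n_pass, c(34L, 29L, 0L))
    expect_equal(agg$pass_rate, c(0.68, 0.58, 0))
    expect_identical(agg$called, c(TRUE, FALSE, FALSE))
    expect_identical(agg$direction, c("down", "none", "none"))
    expect_equal(agg$fold_change[1], 2^agg$median_log2fc[1])

    # inconsistent protein sets across rounds are refused
    bad <- perRound[!(perRound$round == 2 & perRound$protein_id == "A"), ]
    expect_error(stabilityAggregate(bad, M), "different protein sets")
})

test_that("stability calls are coherent with per-round significance", {
    se <- simulateProteome(300, seed = 43)
    keep <- routeByMissingness(se)$quantitative
    res <- runStabilitySelection(se[keep, ], nImputations = 8, seed = 43)
    pr <- as.data.frame(perRoundTable(res))
    tab <- as.data.frame(resultsTable(res))
    nPass <- tapply(pr$q < 0.1, pr$protein_id, sum)[tab$protein_id]
    expect_identical(as.integer(nPass), as.integer(tab$n_pass))
    expect_true(all(tab$called[tab$n_pass == 8]))
    expect_true(all(!tab$called[tab$n_pass == 0]))
})

test_that("the full stability run is reproducible for a fixed master seed", {
    se <- simulateProteome(120, seed = 47)
    keep <- routeByMissingness(se)$quantitative
    r1 <- runStabilitySelection(se[keep, ], nImputations = 4, seed = 9)
    r2 <- runStabilitySelection(se[keep, ], nImputations = 4, seed = 9)
    expect_identical(as.data.frame(resultsTable(r1)),
                     as.data.frame(resultsTable(r2)))
    expect_identical(as.data.frame(perRoundTable(r1)),
                     as.data.frame(perRoundTable(r2)))
    r3 <- runStabilitySelection(se[keep, ], nImputations = 4, seed = 10)
    expect_false(identical(as.data.frame(perRoundTable(r1)),
                           as.data.frame(perRoundTable(r3))))
})

test_that("power is non-decreasing in effect size", {
    sens <- vapply(c(0.5, 1, 2), function(es) {
        se <- simulateProteome(400, fracDA = 0.15, effectSize = es,
                               fracUnique = 0, seed = 53)
        keep <- routeByMissingness(se)$quantitative
        res <- runStabilitySelection(se[keep, ], nImputations = 10,
                                     seed = 53)
        tr <- as.data.frame(simulationTruth(se))
        tab <- merge(as.data.frame(resultsTable(res)), tr,
                     by = "protein_id")
        mean(tab$called[tab$is_da])
    }, numeric(1))
    expect_true(all(diff(sens) >= -0.05))
    expect_gt(sens[3], sens[1])
})
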