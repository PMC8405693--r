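test_that("permutation p matches the exhaustive subset-sampling oracle", {
    t4 <- c(p1 = 2, p2 = 2, p3 = -2, p4 = -2)
    cc <- tinySets(list(SET = c("p1", "p2")))
    # exhaustive oracle: all 6 size-2 subsets, only {p1,p2} has mean >= 2
    subs <- combn(names(t4), 2)
    exact <- mean(apply(subs, 2, function(s) mean(t4[s])) >= 2)
    expect_equal(exact, 1 / 6)
    B <- 10000
    res <- meanStatEnrichment(t4, cc, nPerm = B, seed = 1)
    tab <- as.data.frame(resultsTable(res))
    expect_equal(tab$mean_t, 2)
    mcse <- sqrt(exact * (1 - exact) / B)
    expect_lt(abs(tab$p_up - exact), 3 * mcse)
    # directional tails of one null distribution overlap at the observed draw
    expect_gte(tab$p_up + tab$p_down, 1)
})

test_that("degenerate categories give p = 1 in both directions", {
    t4 <- c(a = 1, b = -2, c = 0.5, d = 3)
    whole <- tinySets(list(ALL = names(t4)))
    tab <- as.data.frame(resultsTable(
        meanStatEnrichment(t4, whole, nPerm = 200, seed = 2)))
    expect_equal(tab$p_up, 1)
    expect_equal(tab$p_down, 1)

    flat <- stats::setNames(rep(1.3, 10), paste0("x", 1:10))
    cc <- tinySets(list(A = c("x1", "x2"), B = c("x3", "x4", "x5")))
    tabF <- as.data.frame(resultsTable(
        meanStatEnrichment(flat, cc, nPerm = 200, seed = 3)))
    expect_true(all(tabF$mean_t == 1.3))
    expect_true(all(tabF$p_up == 1 & tabF$p_down == 1))
})

test_that("universe restriction drops undersized categories with a warning", {
    tv <- stats::setNames(rnorm(20), paste0("u", 1:20))
    cc <- tinySets(list(OK = c("u1", "u2", "u3"),
                        GONE = c("zz1", "u4")))
    expect_warning(res <- meanStatEnrichment(tv, cc, nPerm = 100, seed = 4),
                   "GONE")
    expect_identical(as.data.frame(resultsTable(res))$category_id, "OK")
})

test_that("null p-values are valid (stochastically at least uniform)", {
    set.seed(55)
    tv <- stats::setNames(rnorm(400), sprintf("n%03d", 1:400))
    cc <- makeCategoryCollection(names(tv), 200, sizeRange = c(5, 30),
                                 seed = 56)
    res <- meanStatEnrichment(tv, cc, nPerm = 500, seed = 57)
    tab <- as.data.frame(resultsTable(res))
    ks <- suppressWarnings(
        stats::ks.test(tab$p_up, "punif", alternative = "greater"))
    expect_gt(ks$p.value, 0.001)
    expect_lte(sum(tab$significant), 5)
})

test_that("overlap distance is the overlap-coefficient complement", {
    expect_equal(overlapDistance(c("a", "b"), c("a", "b")), 0)
    expect_equal(overlapDistance(c("a", "b"), c("c", "d")), 1)
    expect_equal(overlapDistance(c("a", "b", "c"), c("b", "c", "d", "e")),
                 1 - 2 / 3)
    # nested sets are at distance 0; symmetric; bounded
    expect_equal(overlapDistance(c("a", "b"), c("a", "b", "c", "d")), 0)
    set.seed(6)
    for (i in 1:20) {
        a <- sample(letters, sample(2:10, 1))
        b <- sample(letters, sample(2:10, 1))
        expect_equal(overlapDistance(a, b), overlapDistance(b, a))
        d <- overlapDistance(a, b)
        expect_true(d >= 0 && d <= 1)
    }
    expect_error(overlapDistance(character(0), "a"), "non-empty")
})

test_that("redundancy clustering collapses duplicates and applies the 3-node rule", {
    mkEnr <- function(ids, p, meanT) {
        tab <- S4Vectors::DataFrame(category_id = ids,
            n_members = rep(3L, length(ids)), mean_t = meanT, p_up = p,
            p_down = 1 - p, q_up = p, q_down = 1 - p,
            significant = rep(TRUE, length(ids)),
            direction = rep("up", length(ids)))
        new("EnrichmentResults", table = tab,
            params = list(nPerm = 100, fdr = 0.1, seed = 1,
                          universeSize = 10))
    }
    # three identical categories cluster together; lowest p is representative
    cc <- tinySets(list(A = c("x", "y", "z"), B = c("x", "y", "z"),
                        C = c("x", "y", "z")))
    cl <- clusterCategories(mkEnr(c("A", "B", "C"), c(0.02, 0.001, 0.04),
                                  c(2, 2.5, 1.8)), cc)
    expect_identical(nrow(cl), 1L)
    expect_identical(cl$n_members, 3L)
    expect_true(cl$included)
    expect_identical(cl$representative_id, "B")

    # a pair of near-duplicates stays below the 3-node inclusion bar
    cc2 <- tinySets(list(A = c("x", "y", "z"), B = c("x", "y", "w")))
    cl2 <- clusterCategories(mkEnr(c("A", "B"), c(0.01, 0.02), c(2, 2)), cc2)
    expect_identical(nrow(cl2), 1L)
    expect_false(cl2$included)

    # duplicate pair co-clusters, unrelated category does not (distance 1)
    cc3 <- tinySets(list(A = paste0("m", 1:10),
                         B = c(paste0("m", 1:9), "m99"),
                         Z = paste0("q", 1:5)))
    cl3 <- clusterCategories(mkEnr(c("A", "B", "Z"), c(0.01, 0.02, 0.03),
                                   c(2, 2, 2)), cc3)
    expect_identical(nrow(cl3), 2L)
    ab <- cl3[grepl("A", cl3$members), ]
    expect_identical(ab$members, "A,B")
    # brute-force check of the 3x3 distance matrix driving the cut
    expect_lt(overlapDistance(paste0("m", 1:10),
                              c(paste0("m", 1:9), "m99")), 0.7)
    expect_equal(overlapDistance(paste0("m", 1:10), paste0("q", 1:5)), 1)

    # invariant to category input order
    cl3b <- clusterCategories(mkEnr(c("Z", "B", "A"), c(0.03, 0.02, 0.01),
                                    c(2, 2, 2)), cc3)
    expect_identical(cl3, cl3b)

    # singleton significant category: one cluster, not included
    cc4 <- tinySets(list(A = c("x", "y")))
    cl4 <- clusterCategories(mkEnr("A", 0.01, 2), cc4)
    expect_identical(nrow(cl4), 1L)
    expect_false(cl4$included)
})

test_that("planted categories are recovered with the right direction", {
    se <- simulateProteome(800, fracDA = 0.15, effectSize = 1.5,
                           fracUnique = 0, seed = 61)
    keep <- routeByMissingness(se)$quantitative
    res <- runStabilitySelection(se[keep, ], nImputations = 8, seed = 61)
    tab <- as.data.frame(resultsTable(res))
    tStats <- stats::setNames(tab$median_t, tab$protein_id)
    tr <- as.data.frame(simulationTruth(se))
    cc <- makeCategoryCollection(tab$protein_id, 20, sizeRange = c(15, 25),
        nPlanted = 2, plantedBias = 50, seed = 62,
        trueLog2fc = stats::setNames(tr$true_log2fc, tr$protein_id))
    enr <- meanStatEnrichment(tStats, cc, nPerm = 2000, seed = 63)
    etab <- as.data.frame(resultsTable(enr))
    planted <- etab[etab$category_id %in% c("CAT001", "CAT002"), ]
    expect_true(all(planted$significant))
    expect_identical(planted$direction[planted$category_id == "CAT001"], "up")
    expect_identical(planted$direction[planted$category_id == "CAT002"],
                     "down")
})
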