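#' Mean-t-statistic category enrichment with a permutation null
#'
#' Scores each category by the mean of its members' moderated t-statistics
#' and tests it against a protein-sampling null: `nPerm` random subsets of
#' the universe of the same size, drawn without replacement. Directional
#' p-values use the add-one estimator
#' `p_up = (1 + #[null mean >= observed]) / (nPerm + 1)` (and `<=` for
#' `p_down`), so p is never 0. Benjamini-Hochberg q-values are computed
#' within each direction and a category is significant when
#' `min(q_up, q_down) < fdr`.
#'
#' Categories are first restricted to the universe (the names of
#' `tByProtein`); restricted categories with fewer than 2 members are dropped
#' with a warning.
#'
#' @param tByProtein named numeric vector: moderated t (typically the median
#'   across imputation rounds) per protein; its names define the universe.
#' @param sets a [CategorySets-class] collection.
#' @param nPerm number of null draws (default 10000).
#' @param fdr significance threshold on the directional q-values
#'   (default 0.10).
#' @param seed integer seed for the null draws.
#' @return an [EnrichmentResults-class] object.
#' @export
meanStatEnrichment <- function(tByProtein, sets, nPerm = 10000, fdr = 0.10,
        seed = 1) {
    .checkCount(nPerm, "nPerm"); .checkFrac(fdr, "fdr"); .checkSeed(seed)
    if (is.null(names(tByProtein)) || anyDuplicated(names(tByProtein)))
        stop("'tByProtein' must be named with unique protein ids")
    if (anyNA(tByProtein)) stop("'tByProtein' contains missing values")
    universe <- names(tByProtein)
    members <- lapply(categoryMembers(sets), intersect, y = universe)
    keep <- lengths(members) >= 2L
    if (!all(keep)) {
        warning(sprintf(
            "dropping %d categor%s with < 2 members after universe restriction: %s",
            sum(!keep), if (sum(!keep) == 1L) "y" else "ies",
            paste(names(members)[!keep], collapse = ", ")))
        members <- members[keep]
    }
    if (!length(members)) stop("no categories left after universe restriction")
    sizes <- lengths(members)
    if (max(sizes) > length(universe))
        stop("universe smaller than the largest category")

    set.seed(as.integer(seed))
    tv <- as.numeric(tByProtein)
    N <- length(tv)
    nullBySize <- lapply(sort(unique(sizes)), function(k) {
        if (k == N) return(rep(mean(tv), nPerm))
        vapply(seq_len(nPerm),
               function(i) mean(tv[sample.int(N, k)]), numeric(1))
    })
    names(nullBySize) <- as.character(sort(unique(sizes)))

    obs <- vapply(members, function(mm) mean(tByProtein[mm]), numeric(1))
    pUp <- pDown <- numeric(length(members))
    for (i in seq_along(members)) {
        null <- nullBySize[[as.character(sizes[i])]]
        pUp[i] <- (1 + sum(null >= obs[i])) / (nPerm + 1)
        pDown[i] <- (1 + sum(null <= obs[i])) / (nPerm + 1)
    }
    qUp <- computeQvalues(pUp, "bh")
    qDown <- computeQvalues(pDown, "bh")
    tab <- DataFrame(category_id = names(members), n_members = sizes,
                     mean_t = unname(obs), p_up = pUp, p_down = pDown,
                     q_up = qUp, q_down = qDown,
                     significant = pmin(qUp, qDown) < fdr,
                     direction = ifelse(qUp <= qDown, "up", "down"),
                     row.names = NULL)
    new("EnrichmentResults", table = tab,
        params = list(nPerm = nPerm, fdr = fdr, seed = seed,
                      universeSize = N))
}

#' Overlap-coefficient distance between two member sets
#'
#' `1 - |A intersect B| / min(|A|, |B|)`. Nested categories (one contained in
#' the other) are at distance 0, which makes GO parent/child terms read as
#' redundant — the behaviour wanted for redundancy clustering.
#'
#' @param membersA,membersB non-empty character vectors.
#' @return a number in `[0, 1]`.
#' @export
overlapDistance <- function(membersA, membersB) {
    a <- unique(membersA); b <- unique(membersB)
    if (!length(a) || !length(b))
        stop("overlap distance requires non-empty sets")
    1 - length(intersect(a, b)) / min(length(a), length(b))
}

#' Redundancy clustering of significant categories
#'
#' Clusters significant categories on pairwise overlap-coefficient distance
#' with average-linkage hierarchical clustering and an adaptive cut: a static
#' cut at `cutHeight`, followed by iterative merging of clusters smaller than
#' `minNodes` into their nearest cluster whenever the average-linkage merge
#' height is at most `cutHeight + mergeSlack`. Clusters of at least
#' `minNodes` members are flagged `included`; each cluster reports the member
#' with the lowest directional p-value as its representative (ties broken by
#' larger `|mean_t|`, then lexically smallest id). Results are invariant to
#' category input order.
#'
#' @param enrichment an [EnrichmentResults-class] object; only significant
#'   categories are clustered.
#' @param sets the [CategorySets-class] collection defining memberships.
#' @param minNodes minimum cluster size for inclusion (default 3).
#' @param cutHeight static cut height on the overlap distance (default 0.7).
#' @param mergeSlack extra height allowed when absorbing small clusters
#'   (default 0.1).
#' @return data.frame with one row per cluster: `cluster_id`, `n_members`,
#'   `members` (comma-separated ids), `representative_id`, `included`.
#' @export
clusterCategories <- function(enrichment, sets, minNodes = 3,
        cutHeight = 0.7, mergeSlack = 0.1) {
    .checkCount(minNodes, "minNodes")
    tab <- as.data.frame(resultsTable(enrichment))
    sig <- tab[tab$significant, , drop = FALSE]
    if (nrow(sig) == 0L) stop("no significant categories to cluster")
    sig <- sig[order(sig$category_id), , drop = FALSE]
    ids <- sig$category_id
    mem <- categoryMembers(sets)[ids]
    if (anyNA(names(mem)))
        stop("significant categories missing from the collection")

    if (nrow(sig) == 1L) {
        cl <- stats::setNames(1L, ids)
    } else {
        n <- length(ids)
        D <- matrix(0, n, n, dimnames = list(ids, ids))
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            D[i, j] <- D[j, i] <- overlapDistance(mem[[i]], mem[[j]])
        hc <- stats::hclust(stats::as.dist(D), method = "average")
        cl <- stats::cutree(hc, h = cutHeight)
        cl <- .mergeSmallClusters(cl, D, minNodes, cutHeight + mergeSlack)
    }

    out <- lapply(sort(unique(cl)), function(k) {
        kids <- sort(names(cl)[cl == k])
        sub <- sig[match(kids, sig$category_id), , drop = FALSE]
        pBest <- pmin(sub$p_up, sub$p_down)
        ord <- order(pBest, -abs(sub$mean_t), sub$category_id)
        data.frame(n_members = length(kids),
                   members = paste(kids, collapse = ","),
                   representative_id = sub$category_id[ord[1]],
                   included = length(kids) >= minNodes,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    # stable, order-free cluster ids: numbered by lexically smallest member
    ord <- order(vapply(strsplit(out$members, ","), `[`, character(1), 1))
    out <- out[ord, , drop = FALSE]
    data.frame(cluster_id = sprintf("CL%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE, row.names = NULL)
}

# absorb clusters below minNodes into their average-linkage nearest neighbour
# while the merge height stays within maxHeight
.mergeSmallClusters <- function(cl, D, minNodes, maxHeight) {
    repeat {
        sizes <- table(cl)
        small <- names(sizes)[sizes < minNodes]
        if (!length(small) || length(sizes) < 2L) return(cl)
        merged <- FALSE
        # process deterministically: smallest cluster first, ties by id
        small <- small[order(sizes[small], small)]
        for (s in small) {
            inS <- names(cl)[cl == s]
            others <- setdiff(names(table(cl)), s)
            h <- vapply(others, function(o) {
                inO <- names(cl)[cl == o]
                mean(D[inS, inO, drop = FALSE])
            }, numeric(1))
            best <- others[order(h, others)][1]
            if (h[best] <= maxHeight) {
                cl[cl == s] <- as.integer(best)
                merged <- TRUE
                break
            }
        }
        if (!merged) return(cl)
    }
}
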