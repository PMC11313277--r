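test_that("rank statistic follows -log10(p) x L2FC", {
    expect_equal(rankStatistic(0.01, 2), 4)
    expect_equal(rankStatistic(1, 5), 0)
    expect_equal(rankStatistic(0.1, -1), -1)
    expect_error(rankStatistic(0, 1), "\\(0, 1\\]")
    expect_error(rankStatistic(0.5, Inf), "finite")
})

test_that("ranked lists are ordered, deterministic, and reject duplicates", {
    de <- S4Vectors::DataFrame(
        pvalue = c(0.001, 0.1, 0.1, 0.5, NA),
        log2FoldChange = c(1, -1, 1, 2, 3),
        row.names = c("gB", "gD", "gC", "gA", "gE"))
    r <- buildRankedList(de)
    expect_equal(names(r)[1], "gB")
    expect_equal(names(r)[length(r)], "gD")
    expect_false("gE" %in% names(r))  # flagged gene excluded
    expect_true(all(diff(r) <= 0))

    # tie in rank value: lexicographically smaller gene id first
    tie <- S4Vectors::DataFrame(pvalue = c(0.1, 0.1),
                                log2FoldChange = c(1, 1),
                                row.names = c("gZ", "gA"))
    expect_equal(names(buildRankedList(tie)), c("gA", "gZ"))

    perm <- withr::with_seed(3, sample(nrow(de)))
    expect_identical(buildRankedList(de[perm, ]), r)

    dup <- S4Vectors::DataFrame(pvalue = c(0.1, 0.2),
                                log2FoldChange = c(1, 1))
    rownames(dup) <- c("g1", "g1")
    expect_error(buildRankedList(dup), "unique")
})

test_that("enrichment score matches the brute-force running sum", {
    # hand-enumerable toy list: 5 genes, 2-gene set, exponent 1
    rv <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
    es <- enrichmentScore(rv, c("a", "c"))
    expect_equal(es$es, esOracle(rv, c("a", "c")))
    # by hand: a steps up 3/4 (peak), then 0.75 - 1/3 + 1/4 = 2/3 at c
    expect_equal(es$es, 3 / 4)
    expect_equal(es$peak, 1)

    # top-k positive block peaks at position k
    rv2 <- withr::with_seed(4, sort(runif(30, 0.1, 2), decreasing = TRUE))
    names(rv2) <- sprintf("g%02d", 1:30)
    top <- enrichmentScore(rv2, names(rv2)[1:6])
    expect_gt(top$es, 0)
    expect_equal(top$peak, 6)

    # antisymmetry: reversing the list and negating the values negates ES
    flipped <- rev(-rv2)
    set <- withr::with_seed(5, sample(names(rv2), 8))
    expect_equal(enrichmentScore(flipped, set)$es,
                 -enrichmentScore(rv2, set)$es)

    expect_error(enrichmentScore(rv2, c("zz")), "no overlap")
})

test_that("enrichment score equals the oracle across random cases", {
    for (rep in 1:20) {
        rv <- withr::with_seed(100 + rep, {
            x <- rnorm(40)
            names(x) <- sprintf("g%02d", 1:40)
            sort(x, decreasing = TRUE)
        })
        set <- withr::with_seed(200 + rep, sample(names(rv), 7))
        for (expo in c(0, 1, 2)) {
            expect_equal(enrichmentScore(rv, set, expo)$es,
                         esOracle(rv, set, expo), tolerance = 1e-12)
        }
    }
})

test_that("enrichment score agrees with an external implementation", {
    skip_if_not_installed("fgsea")
    rv <- withr::with_seed(6, {
        x <- rnorm(60)
        names(x) <- sprintf("g%02d", 1:60)
        sort(x, decreasing = TRUE)
    })
    for (rep in 1:10) {
        set <- withr::with_seed(300 + rep, sample(names(rv), 12))
        expect_equal(
            enrichmentScore(rv, set, 1)$es,
            fgsea::calcGseaStat(rv, which(names(rv) %in% set),
                                gseaParam = 1),
            tolerance = 1e-12)
    }
})

test_that("preranked GSEA is deterministic and bounded", {
    rv <- withr::with_seed(7, {
        x <- rnorm(300)
        names(x) <- sprintf("g%03d", 1:300)
        sort(x, decreasing = TRUE)
    })
    col <- simulateGeneSets(names(rv), 15, c(10, 40), seed = 8)
    a <- gseaPreranked(rv, col, nPerm = 200, seed = 9, minSize = 5,
                       maxSize = 100)
    b <- gseaPreranked(rv, col, nPerm = 200, seed = 9, minSize = 5,
                       maxSize = 100)
    expect_identical(as.data.frame(a[, 1:7]), as.data.frame(b[, 1:7]))
    expect_true(all(abs(a$ES) <= 1))
    expect_true(all(a$qval >= 0 & a$qval <= 1))
    expect_identical(a$direction, ifelse(a$ES >= 0, "up", "down"))

    # size filter skips and records
    small <- simulateGeneSets(names(rv), 3, c(2, 4), seed = 10)
    expect_warning(res <- gseaPreranked(rv, small, nPerm = 100, seed = 1),
                   "size filter")
    expect_equal(nrow(res), 0L)
    expect_equal(nrow(S4Vectors::metadata(res)$skipped), 3L)
})

test_that("doubling permutations moves p by less than 2 Monte Carlo SE", {
    rv <- withr::with_seed(11, {
        x <- rnorm(400)
        names(x) <- sprintf("g%03d", 1:400)
        sort(x, decreasing = TRUE)
    })
    col <- simulateGeneSets(names(rv), 8, c(15, 40), seed = 12)
    a <- gseaPreranked(rv, col, nPerm = 500, seed = 13)
    b <- gseaPreranked(rv, col, nPerm = 1000, seed = 14)
    pbar <- (a$pval + b$pval) / 2
    # the sign-matched exceedance uses ~nPerm/2 nulls of the matching sign,
    # so that is the effective Monte Carlo sample size
    seMC <- sqrt(pbar * (1 - pbar) * (1 / 250 + 1 / 500))
    expect_true(all(abs(a$pval - b$pval) < 2 * seMC + 1 / 250))
})

test_that("compareStrata partitions significant pathways per direction", {
    cn <- c("P1", "P2", "P3")
    A <- makeEnrichment(c("P1", "P2"), c("up", "up"), c(0.01, 0.01), cn)
    B <- makeEnrichment(c("P2", "P3"), c("up", "up"), c(0.01, 0.2), cn)
    cmp <- compareStrata(A, B, strataNames = c("female", "male"))
    expect_equal(cmp@up$shared, "P2")
    expect_equal(cmp@up$uniqueA, "P1")
    expect_equal(cmp@up$uniqueB, character(0))
    ct <- comparisonCounts(cmp)
    expect_equal(ct$total_female[ct$direction == "up"], 2)
    expect_equal(ct$total_male[ct$direction == "up"], 1)

    # identical inputs leave both unique sets empty
    cmpAA <- compareStrata(A, A)
    expect_equal(cmpAA@up$uniqueA, character(0))
    expect_equal(cmpAA@up$uniqueB, character(0))

    other <- makeEnrichment("P9", "up", 0.01, c("P9"))
    expect_error(compareStrata(A, other), "same collection")
})
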