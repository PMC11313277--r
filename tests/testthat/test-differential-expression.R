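test_that("median-of-ratios size factors behave under scaling", {
    m <- makeCounts(50, 4, seed = 1)
    same <- m[, c(1, 1, 1)]
    colnames(same) <- c("a", "b", "c")
    expect_equal(unname(computeSizeFactors(same)), rep(1, 3))

    doubled <- cbind(m, doubled = m[, 1] * 2L)
    sf <- computeSizeFactors(doubled)
    expect_equal(unname(sf["doubled"] / sf[1]), 2, tolerance = 1e-12)

    zeros <- m
    zeros[, 1] <- 0L
    zeros[1:49, 2] <- 0L
    zeros[50, ] <- 0L
    expect_error(computeSizeFactors(zeros), "pseudo-reference")
})

test_that("size factors recover generative library-size multipliers", {
    mult <- rep(c(0.5, 1, 2), each = 20)
    mu <- withr::with_seed(2, rlnorm(1000, log(200), 1))
    counts <- withr::with_seed(3, {
        m <- vapply(mult, function(f)
            rnbinom(1000, mu = mu * f, size = 1 / 0.1), numeric(1000))
        dimnames(m) <- list(sprintf("g%04d", 1:1000),
                            sprintf("s%02d", 1:60))
        storage.mode(m) <- "integer"
        m
    })
    sf <- computeSizeFactors(counts)
    rel <- sf / exp(mean(log(sf)))
    target <- mult / exp(mean(log(mult)))
    expect_true(all(abs(rel / target - 1) < 0.05))
})

test_that("method-of-moments dispersion recovers the generative alpha", {
    grp <- factor(rep(c("CTL", "AD"), each = 100))
    nb <- makeCounts(400, 200, mu = 100, seed = 4)  # size 5 => alpha 0.2
    d <- estimateDispersion(nb, rep(1, 200), grp)
    expect_true(median(d$alpha) > 0.15 && median(d$alpha) < 0.25)

    pois <- withr::with_seed(5, {
        m <- matrix(rpois(400 * 200, 100), 400,
                    dimnames = dimnames(nb))
        storage.mode(m) <- "integer"
        m
    })
    dp <- estimateDispersion(pois, rep(1, 200), grp)
    expect_lte(median(dp$alpha), 0.01)

    zero <- nb
    zero[1, ] <- 0L
    dz <- estimateDispersion(zero, rep(1, 200), grp)
    expect_equal(dz$alpha[1], 0)
    expect_true(dz$flagged[1])
})

test_that("Wald test is symmetric and exact on degenerate designs", {
    md <- makeMetadata(20, seed = 6)
    # AD samples are literal copies of the CTL samples
    base <- makeCounts(30, 10, seed = 7)
    counts <- cbind(base, base)
    colnames(counts) <- md$sample_id
    md$Age <- rep(md$Age[1:10], 2)
    md$RIN <- rep(md$RIN[1:10], 2)
    md$PMI <- rep(md$PMI[1:10], 2)
    de <- nbWaldTest(counts, md)
    expect_true(all(abs(de$log2FoldChange) < 1e-8))

    # swapping the diagnosis labels flips the sign, not the p-value
    md2 <- makeMetadata(40, seed = 8)
    counts2 <- makeCounts(25, 40, seed = 9)
    deA <- nbWaldTest(counts2, md2)
    md2$diagnosis <- ifelse(md2$diagnosis == "AD", "CTL", "AD")
    deB <- nbWaldTest(counts2, md2)
    expect_equal(deA$log2FoldChange, -deB$log2FoldChange,
                 tolerance = 1e-6)
    expect_equal(deA$pvalue, deB$pvalue, tolerance = 1e-6)
})

test_that("Wald fits agree with DESeq2 at fixed dispersions", {
    skip_if_not_installed("DESeq2")
    st <- data.frame(label = "female", nCTL = 15L, nAD = 15L)
    se <- simulateCohort(simConfig(nGenes = 80, strata = st,
                                   pmiMissingRate = 0, seed = 10))
    counts <- SummarizedExperiment::assay(se)
    md <- imputePMI(as.data.frame(SummarizedExperiment::colData(se)))
    sf <- computeSizeFactors(counts)
    disp <- estimateDispersion(counts, sf, md$diagnosis)$alpha
    de <- nbWaldTest(counts, md, sizeFactors = sf, dispersions = disp)
    suppressMessages({
        md$diagnosis <- factor(md$diagnosis, levels = c("CTL", "AD"))
        dds <- DESeq2::DESeqDataSetFromMatrix(
            counts, md, ~ Age + RIN + PMI + diagnosis)
        DESeq2::sizeFactors(dds) <- sf
        DESeq2::dispersions(dds) <- pmax(disp, 1e-8)
        res <- DESeq2::results(DESeq2::nbinomWaldTest(dds))
    })
    ok <- !is.na(de$log2FoldChange) & !is.na(res$log2FoldChange)
    expect_gt(mean(ok), 0.9)
    expect_lt(max(abs(de$log2FoldChange[ok] - res$log2FoldChange[ok])),
              0.01)
    expect_gt(cor(de$pvalue[ok], res$pvalue[ok]), 0.999)
})

test_that("flagged genes carry missing p-values, never silent results", {
    md <- makeMetadata(20, seed = 12)
    counts <- makeCounts(10, 20, seed = 13)
    counts[3, ] <- 0L
    de <- suppressMessages(nbWaldTest(counts, md))
    expect_equal(de$flag[3], "all_zero")
    expect_true(is.na(de$pvalue[3]))
    expect_true(is.na(de$padj[3]))
    expect_true(all(de$pvalue[-3] >= 0 & de$pvalue[-3] <= 1))
    expect_true(all(de$padj >= de$pvalue, na.rm = TRUE))
})

test_that("adjustBH matches hand-derived values and handles missing", {
    expect_equal(adjustBH(0.03), 0.03)
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
    expect_error(adjustBH(c(0.1, 1.3)), "\\[0, 1\\]")

    p <- c(0.01, NA, 0.5, 0.04)
    adj <- adjustBH(p)
    expect_true(is.na(adj[2]))
    expect_equal(adj[-2], bhOracle(p[-2]))

    # order invariance
    p2 <- withr::with_seed(14, runif(9))
    perm <- withr::with_seed(15, sample(9))
    expect_equal(adjustBH(p2)[perm], adjustBH(p2[perm]))
})
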