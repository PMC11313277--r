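test_that("simulated cohort matches the configured layout", {
    cfg <- simConfig(nGenes = 120, seed = 5)
    se <- simulateCohort(cfg)
    md <- as.data.frame(SummarizedExperiment::colData(se))
    expect_equal(nrow(md), 119)   # 36 + 28 female, 39 + 16 male
    tab <- table(md$sex, md$diagnosis)
    expect_equal(tab["female", "CTL"], 36)
    expect_equal(tab["female", "AD"], 28)
    expect_equal(tab["male", "CTL"], 39)
    expect_equal(tab["male", "AD"], 16)
    expect_equal(dim(se), c(120L, 119L))
    counts <- SummarizedExperiment::assay(se, "counts")
    expect_true(all(counts >= 0))
    expect_true(all(counts == round(counts)))
})

test_that("no planted effects means empty ground-truth sets", {
    se <- simulateCohort(simConfig(nGenes = 50, deFraction = 0, seed = 2))
    truth <- S4Vectors::metadata(se)$groundTruth
    expect_true(all(vapply(truth, nrow, integer(1)) == 0L))
})

test_that("identical configurations reproduce bit-identical cohorts", {
    cfg <- simConfig(nGenes = 80, seed = 17)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(SummarizedExperiment::assay(a),
                     SummarizedExperiment::assay(b))
    expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                     as.data.frame(SummarizedExperiment::colData(b)))
    expect_identical(S4Vectors::metadata(a)$groundTruth,
                     S4Vectors::metadata(b)$groundTruth)
})

test_that("counts obey the NB moment relation at fixed dispersion", {
    alpha <- 0.2
    cfg <- simConfig(
        nGenes = 1000,
        strata = data.frame(label = "female", nCTL = 100L, nAD = 100L),
        dispersionLog = c(meanlog = log(alpha), sdlog = 0),
        deFraction = 0, covariateEffectScale = 0, libsizeLogSd = 0,
        seed = 7)
    counts <- SummarizedExperiment::assay(simulateCohort(cfg))
    m <- rowMeans(counts)
    v <- apply(counts, 1, var)
    alphaHat <- (v - m) / m^2
    se <- sd(alphaHat) / sqrt(length(alphaHat))
    expect_lt(abs(mean(alphaHat) - alpha), 3 * se)
})

test_that("missing-PMI rate matches the configuration within binomial CI", {
    rate <- 0.2
    cfg <- simConfig(
        nGenes = 10,
        strata = data.frame(label = "female", nCTL = 300L, nAD = 300L),
        pmiMissingRate = rate, seed = 9)
    md <- as.data.frame(SummarizedExperiment::colData(simulateCohort(cfg)))
    n <- nrow(md)
    phat <- mean(is.na(md$PMI))
    expect_lt(abs(phat - rate), 3 * sqrt(rate * (1 - rate) / n))
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(nGenes = 0), "nGenes")
    expect_error(simConfig(deFraction = 1.5), "\\[0, 1\\]")
    expect_error(
        simConfig(strata = data.frame(label = "female", nCTL = 1L,
                                      nAD = 10L)),
        ">= 2 samples")
})

test_that("simulateGeneSets honours planted sets, sizes and seeds", {
    universe <- sprintf("G%03d", 1:100)
    one <- simulateGeneSets(universe, nSets = 0,
                            planted = list(P = universe[1:5]), seed = 1)
    expect_equal(length(one), 1L)
    expect_equal(one[["P"]], universe[1:5])

    a <- simulateGeneSets(universe, 10, c(5, 20), seed = 3)
    b <- simulateGeneSets(universe, 10, c(5, 20), seed = 3)
    expect_identical(geneSets(a), geneSets(b))
    expect_true(all(lengths(geneSets(a)) >= 5 & lengths(geneSets(a)) <= 20))
    expect_true(all(unlist(geneSets(a)) %in% universe))

    expect_error(simulateGeneSets(universe, 1, c(5, 20),
                                  planted = list(P = c("G001", "NOPE")),
                                  seed = 1),
                 "outside the universe")
    expect_error(simulateGeneSets(universe, 1, c(0, 20), seed = 1),
                 "sizeRange")
})

test_that("literature corpus respects the true relatedness proportions", {
    labs <- sprintf("PW%03d", 1:200)
    zero <- simulateLiteratureCorpus(labs[1:5], rTrue = 0, seed = 2)
    expect_true(all(literatureCounts(zero)$coMentions == 0))
    one <- simulateLiteratureCorpus(labs[1:5], rTrue = 1, seed = 2)
    df <- literatureCounts(one)
    expect_equal(df$coMentions, df$total)

    corp <- simulateLiteratureCorpus(
        labs, rTrue = 0.3,
        totalCountsLog = c(meanlog = log(5000), sdlog = 0.2), seed = 4)
    df <- literatureCounts(corp)
    phat <- sum(df$coMentions) / sum(df$total)
    expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / sum(df$total)))

    expect_error(simulateLiteratureCorpus(labs[1:2], rTrue = 1.2, seed = 1),
                 "\\[0, 1\\]")
    expect_identical(
        literatureCounts(simulateLiteratureCorpus(labs, 0.1, seed = 8)),
        literatureCounts(simulateLiteratureCorpus(labs, 0.1, seed = 8)))
})
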