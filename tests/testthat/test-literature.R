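test_that("queries are normalized and phrase-wrapped", {
    expect_equal(buildQuery("INTERLEUKIN-10 SIGNALING"),
                 '"interleukin 10 signaling"')
    expect_equal(buildQuery("AUTOPHAGY"), "autophagy")
    expect_equal(buildQuery("SELECTIVE_AUTOPHAGY", "Alzheimer's disease"),
                 '"selective autophagy" AND "alzheimer\'s disease"')
    expect_error(buildQuery("_-_"), "empty")
})

test_that("relatedness proportion follows the convention", {
    expect_equal(as.numeric(relatednessProportion(5, 50)), 0.1)
    expect_equal(as.numeric(relatednessProportion(50, 50)), 1)
    r0 <- relatednessProportion(0, 0)
    expect_equal(as.numeric(r0), 0)
    expect_true(attr(r0, "zeroDenominator"))
    expect_error(relatednessProportion(6, 5), "exceeds")
})

test_that("fixture provider is deterministic and strict about labels", {
    lc <- simulateLiteratureCorpus(c("A", "B"), rTrue = 0.1, seed = 1)
    prov <- fixtureProvider(lc)
    expect_identical(prov("A"), prov("A"))
    expect_lte(prov("A", withDisease = TRUE), prov("A"))
    expect_error(prov("MISSING"), "not in the fixture")
})

test_that("null sampling uses the whole universe when sizes match", {
    labs <- sprintf("PW%04d", 1:50)
    lc <- simulateLiteratureCorpus(
        labs, rTrue = 0.02,
        totalCountsLog = c(meanlog = log(5000), sdlog = 0.2), seed = 2)
    prov <- fixtureProvider(lc)
    null <- sampleNullProportions(labs, nNull = 50, prov, seed = 3)
    expect_setequal(names(null), labs)
    expect_lt(abs(mean(null) - 0.02), 0.005)
    expect_lt(sd(null), 0.01)

    expect_identical(sampleNullProportions(labs, 30, prov, seed = 4),
                     sampleNullProportions(labs, 30, prov, seed = 4))
    expect_error(sampleNullProportions(labs, 100, prov, seed = 1),
                 "smaller than")
})

test_that("impactZ is the standardized deviation from the null", {
    expect_equal(impactZ(0.05, c(0.01, 0.02, 0.03))$z,
                 (0.05 - 0.02) / sd(c(0.01, 0.02, 0.03)))
    null <- c(0.01, 0.02, 0.03)
    expect_equal(impactZ(mean(null), null)$z, 0)
    # direct formula example: r 0.05 against null mean 0.02, sd 0.01
    null2 <- c(0.01, 0.02, 0.03)  # mean 0.02, sd 0.01
    expect_equal(impactZ(0.05, null2)$z, 3)
    expect_error(impactZ(0.5, rep(0.1, 10)), "zero spread")
    expect_error(impactZ(0.5, 0.1), "at least 2")

    # affine shift invariance: Z(r + c | null + c) = Z(r | null)
    shift <- 0.17
    expect_equal(impactZ(0.05 + shift, null2 + shift)$z,
                 impactZ(0.05, null2)$z)
})

test_that("scorePathways recovers a planted disease-linked pathway", {
    labs <- sprintf("PW%04d", 1:400)
    rTrue <- stats::setNames(rep(0.02, 400), labs)
    rTrue["PW0001"] <- 0.3
    lc <- simulateLiteratureCorpus(
        labs, rTrue,
        totalCountsLog = c(meanlog = log(8000), sdlog = 0.2), seed = 5)
    prov <- fixtureProvider(lc)
    scored <- scorePathways(labs[1:10], labs[11:400], prov, nNull = 300,
                            seed = 6)
    expect_equal(scored$label[which.max(scored$z)], "PW0001")
    expect_gt(scored["PW0001", "z"], 5)
    expect_true(all(abs(scored$z[-1]) < 3))

    # uniform count scaling leaves every Z unchanged
    df <- literatureCounts(lc)
    df$total <- df$total * 2L
    df$coMentions <- df$coMentions * 2L
    prov2 <- fixtureProvider(new("LiteratureCounts", counts = df))
    scored2 <- scorePathways(labs[1:10], labs[11:400], prov2, nNull = 300,
                             seed = 6)
    expect_equal(scored$z, scored2$z)

    empty <- scorePathways(character(0), labs, prov, nNull = 10, seed = 1)
    expect_equal(nrow(empty), 0L)
})

test_that("the JSON cache short-circuits repeated provider calls", {
    labs <- sprintf("PW%04d", 1:60)
    lc <- simulateLiteratureCorpus(labs, rTrue = 0.05,
                                   totalCountsLog = c(log(1000), 0.3),
                                   seed = 7)
    calls <- new.env(); calls$n <- 0L
    counting <- local({
        inner <- fixtureProvider(lc)
        function(label, withDisease = FALSE) {
            calls$n <- calls$n + 1L
            inner(label, withDisease)
        }
    })
    cache <- withr::local_tempfile(fileext = ".json")
    s1 <- scorePathways(labs[1:5], labs[6:60], counting, nNull = 50,
                        seed = 8, cachePath = cache)
    firstCalls <- calls$n
    expect_gt(firstCalls, 0L)
    s2 <- scorePathways(labs[1:5], labs[6:60], counting, nNull = 50,
                        seed = 8, cachePath = cache)
    expect_equal(calls$n, firstCalls)  # everything served from the cache
    expect_equal(s1$z, s2$z)
})

test_that("failing providers mark labels unscored instead of fabricating", {
    labs <- sprintf("PW%04d", 1:30)
    lc <- simulateLiteratureCorpus(labs, 0.05,
                                   totalCountsLog = c(log(1000), 0.3),
                                   seed = 9)
    flaky <- local({
        inner <- fixtureProvider(lc)
        function(label, withDisease = FALSE) {
            if (label == "BROKEN") stop("service unavailable")
            inner(label, withDisease)
        }
    })
    expect_warning(
        scored <- scorePathways(c("PW0001", "BROKEN"), labs, flaky,
                                nNull = 20, seed = 10),
        "provider failed")
    expect_true(is.na(scored["BROKEN", "z"]))
    expect_false(is.na(scored["PW0001", "z"]))
})
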