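#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   colData<- rowData
NULL

#' Cohort simulation configuration
#'
#' Holds every parameter of the negative binomial cohort generator:
#' the gene universe size, the stratum layout (one row per stratum with
#' control and case group sizes), the log-scale location/scale of per-gene
#' baseline means and NB dispersions, the fraction of genes carrying a true
#' diagnosis effect within each stratum, the distribution of true log2
#' fold changes, the magnitude of nuisance covariate effects, the
#' missing-PMI rate, the per-sample library-size spread, and the seed.
#'
#' @slot nGenes Number of genes simulated.
#' @slot strata `data.frame` with columns `label`, `nCTL`, `nAD`.
#' @slot baselineMeanLog Length-2 numeric `(location, scale)` of the
#'   per-gene natural-log baseline mean.
#' @slot dispersionLog Length-2 numeric `(meanlog, sdlog)` of the per-gene
#'   log-normal NB dispersion alpha (variance = mu + alpha * mu^2).
#' @slot deFraction Fraction of genes with a true diagnosis effect in each
#'   stratum.
#' @slot effectSizeLog2 Length-2 numeric `(mean, sd)` of the magnitude of
#'   true log2 fold changes; signs are assigned at random.
#' @slot covariateEffectScale Standard deviation of per-gene coefficients
#'   for the standardized Age/RIN/PMI covariates on the log-mean scale.
#' @slot pmiMissingRate Probability that a sample's PMI is recorded as
#'   missing in the metadata.
#' @slot libsizeLogSd Standard deviation of log library-size multipliers.
#' @slot seed Integer seed; identical configurations reproduce bit-identical
#'   cohorts.
#'
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig",
    representation(
        nGenes = "integer",
        strata = "data.frame",
        baselineMeanLog = "numeric",
        dispersionLog = "numeric",
        deFraction = "numeric",
        effectSizeLog2 = "numeric",
        covariateEffectScale = "numeric",
        pmiMissingRate = "numeric",
        libsizeLogSd = "numeric",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@nGenes) != 1L || is.na(object@nGenes) ||
        object@nGenes < 1L)
        msg <- c(msg, "nGenes must be a single integer >= 1")
    st <- object@strata
    if (!all(c("label", "nCTL", "nAD") %in% names(st)))
        msg <- c(msg, "strata needs columns label, nCTL, nAD")
    else {
        if (anyDuplicated(st$label))
            msg <- c(msg, "stratum labels must be unique")
        if (any(st$nCTL < 2L) || any(st$nAD < 2L))
            msg <- c(msg, "every stratum needs >= 2 samples per diagnosis group")
    }
    for (nm in c("baselineMeanLog", "dispersionLog", "effectSizeLog2")) {
        if (length(slot(object, nm)) != 2L || any(!is.finite(slot(object, nm))))
            msg <- c(msg, sprintf("%s must be a finite length-2 numeric", nm))
    }
    for (nm in c("deFraction", "pmiMissingRate")) {
        v <- slot(object, nm)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("%s must be a single value in [0, 1]", nm))
    }
    if (object@covariateEffectScale < 0)
        msg <- c(msg, "covariateEffectScale must be >= 0")
    if (object@libsizeLogSd < 0)
        msg <- c(msg, "libsizeLogSd must be >= 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' Gene-set collection
#'
#' An ordered collection of named gene sets as carried by GMT files:
#' each set has a unique name, a free-text description, and a non-empty
#' character vector of member gene identifiers.
#'
#' @slot setNames Character vector of unique set names.
#' @slot descriptions Character vector, one description per set.
#' @slot members List of character vectors of member gene ids.
#'
#' @seealso [readGmt()], [writeGmt()], [simulateGeneSets()]
#' @export
setClass("GeneSetCollection",
    representation(
        setNames = "character",
        descriptions = "character",
        members = "list"
    )
)

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    n <- length(object@setNames)
    if (length(object@descriptions) != n || length(object@members) != n)
        msg <- c(msg, "setNames, descriptions and members must be parallel")
    if (anyDuplicated(object@setNames))
        msg <- c(msg, "set names must be unique")
    if (n > 0) {
        if (!all(vapply(object@members, is.character, logical(1))))
            msg <- c(msg, "members must be character vectors")
        else if (any(lengths(object@members) == 0L))
            msg <- c(msg, "every set must have at least one member")
    }
    if (length(msg)) msg else TRUE
})

#' Literature count cache
#'
#' Per-pathway bibliographic counts: the number of documents mentioning the
#' pathway at all (`total`) and the number co-mentioning it with the disease
#' term (`coMentions`), with `coMentions <= total` for every label.
#'
#' @slot counts `data.frame` with columns `label`, `total`, `coMentions`.
#'
#' @seealso [readLiteratureCounts()], [fixtureProvider()]
#' @export
setClass("LiteratureCounts",
    representation(counts = "data.frame")
)

setValidity("LiteratureCounts", function(object) {
    df <- object@counts
    msg <- character()
    if (!all(c("label", "total", "coMentions") %in% names(df)))
        msg <- c(msg, "counts needs columns label, total, coMentions")
    else {
        if (anyDuplicated(df$label))
            msg <- c(msg, "labels must be unique")
        if (any(df$total < 0) || any(df$coMentions < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(df$coMentions > df$total))
            msg <- c(msg, "coMentions must not exceed total for any label")
    }
    if (length(msg)) msg else TRUE
})

#' Differential expression results
#'
#' A `DFrame` with one row per gene and columns `baseMean`,
#' `log2FoldChange` (AD vs CTL, positive = higher in AD), `stat` (Wald
#' statistic), `pvalue`, `padj` (Benjamini-Hochberg), `dispersion` and
#' `flag` (empty string for clean fits).
#'
#' @seealso [nbWaldTest()]
#' @export
setClass("DEResults", contains = "DFrame")

#' Per-gene variance fractions
#'
#' A `DFrame` with one row per gene giving the fraction of expression
#' variance attributed to Age, RIN, PMI and Diagnosis, the residual
#' fraction, and a `flagged` column marking zero-variance genes. For
#' non-flagged genes the five fractions sum to one.
#'
#' @seealso [partitionVariance()], [filterGenes()]
#' @export
setClass("VarianceFractions", contains = "DFrame")

#' Pre-ranked enrichment results
#'
#' A `DFrame` with one row per tested pathway: `pathway`, `size` (overlap
#' with the ranked universe), `ES`, `NES`, `pval` (permutation), `qval`
#' (Benjamini-Hochberg across pathways), `direction` ("up"/"down") and
#' `leadingEdge` (a `CharacterList`).
#'
#' @seealso [gseaPreranked()], [compareStrata()]
#' @export
setClass("EnrichmentResults", contains = "DFrame")

#' Literature impact scores
#'
#' A `DFrame` with one row per scored pathway label: the relatedness
#' proportion `r`, the counts it came from, the shared-null mean and
#' standard deviation, the impact `z` score, and a `zeroDenominator` flag.
#'
#' @seealso [scorePathways()], [impactZ()]
#' @export
setClass("ImpactScores", contains = "DFrame")

#' Cross-stratum pathway comparison
#'
#' For each direction (up / down), the pathways significant in both strata
#' and those unique to each, at a fixed q threshold.
#'
#' @slot strataNames Length-2 character, the two stratum labels.
#' @slot up List with elements `shared`, `uniqueA`, `uniqueB`.
#' @slot down Same structure for down-regulated pathways.
#' @slot qThreshold Significance threshold used.
#'
#' @seealso [compareStrata()], [comparisonCounts()]
#' @export
setClass("StratumComparison",
    representation(
        strataNames = "character",
        up = "list",
        down = "list",
        qThreshold = "numeric"
    )
)

setValidity("StratumComparison", function(object) {
    msg <- character()
    if (length(object@strataNames) != 2L)
        msg <- c(msg, "strataNames must have length 2")
    for (d in c("up", "down")) {
        x <- slot(object, d)
        if (!all(c("shared", "uniqueA", "uniqueB") %in% names(x)))
            msg <- c(msg, sprintf("%s needs shared, uniqueA, uniqueB", d))
        else {
            if (length(intersect(x$uniqueA, x$shared)) ||
                length(intersect(x$uniqueB, x$shared)) ||
                length(intersect(x$uniqueA, x$uniqueB)))
                msg <- c(msg, sprintf("%s sets must be disjoint", d))
        }
    }
    if (length(msg)) msg else TRUE
})
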