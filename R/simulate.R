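#' Build a cohort simulation configuration
#'
#' Defaults emulate a two-stratum post-mortem temporal-cortex case/control
#' cohort: a female stratum with 36 controls and 28 cases and a male stratum
#' with 39 controls and 16 cases (119 subjects in total), with Age, RIN and
#' PMI as nuisance covariates and missing PMI values in the metadata.
#'
#' Counts follow a gamma-Poisson (negative binomial) model with
#' `var = mu + alpha * mu^2`. Per-gene baseline means are log-normal around
#' ~100 counts, dispersions log-normal around 0.15 (typical for bulk brain
#' RNA-seq), 10% of genes carry a true diagnosis effect per stratum with
#' |log2 fold change| ~ N(1, 0.25), and covariates perturb the log-mean
#' through small gene-specific coefficients.
#'
#' @param nGenes number of genes.
#' @param strata `data.frame` with columns `label`, `nCTL`, `nAD`.
#' @param baselineMeanLog `(location, scale)` of per-gene log baseline mean.
#' @param dispersionLog `(meanlog, sdlog)` of log-normal dispersions.
#' @param deFraction fraction of genes truly differential per stratum.
#' @param effectSizeLog2 `(mean, sd)` of |true log2 fold change|.
#' @param covariateEffectScale sd of gene-level covariate coefficients on
#'   the log-mean scale (per standardized covariate unit).
#' @param pmiMissingRate probability a PMI entry is missing.
#' @param libsizeLogSd sd of log library-size multipliers.
#' @param seed integer seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 200, seed = 7)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L,
                      strata = data.frame(
                          label = c("female", "male"),
                          nCTL = c(36L, 39L),
                          nAD = c(28L, 16L)),
                      baselineMeanLog = c(location = log(100), scale = 1),
                      dispersionLog = c(meanlog = log(0.15), sdlog = 0.5),
                      deFraction = 0.1,
                      effectSizeLog2 = c(mean = 1, sd = 0.25),
                      covariateEffectScale = 0.05,
                      pmiMissingRate = 0.1,
                      libsizeLogSd = 0.2,
                      seed = 1L) {
    strata$label <- as.character(strata$label)
    strata$nCTL <- as.integer(strata$nCTL)
    strata$nAD <- as.integer(strata$nAD)
    new("SimConfig",
        nGenes = as.integer(nGenes),
        strata = strata,
        baselineMeanLog = as.numeric(baselineMeanLog),
        dispersionLog = as.numeric(dispersionLog),
        deFraction = as.numeric(deFraction),
        effectSizeLog2 = as.numeric(effectSizeLog2),
        covariateEffectScale = as.numeric(covariateEffectScale),
        pmiMissingRate = as.numeric(pmiMissingRate),
        libsizeLogSd = as.numeric(libsizeLogSd),
        seed = as.integer(seed))
}

# Fixed standardization constants so covariate effects are comparable
# across strata and runs (not re-estimated from each sample draw).
.covCenters <- c(Age = 77.5, RIN = 8, PMI = 12)
.covScales <- c(Age = 10, RIN = 1, PMI = 6)

#' Simulate a stratified case/control RNA-seq cohort
#'
#' Draws a gene-by-sample negative binomial count matrix with per-stratum
#' planted diagnosis effects, nuisance covariate effects on the log-mean,
#' library-size variation, and metadata with missing PMI entries. The
#' ground truth (which genes are differential in which stratum, with their
#' true log2 effects) is stored in the object metadata.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `colData` columns `sample_id`, `sex`, `diagnosis`, `Age`,
#'   `RIN`, `PMI` (with `NA` for missing), and `metadata()` entries
#'   `groundTruth` (per-stratum `data.frame` of `gene`, `trueLog2FC`),
#'   `trueSizeFactors`, and `config`.
#' @examples
#' se <- simulateCohort(simConfig(nGenes = 100, seed = 3))
#' dim(se)
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    withSeed(config@seed, {
        nG <- config@nGenes
        genes <- sprintf("G%05d", seq_len(nG))
        logBase <- stats::rnorm(nG, config@baselineMeanLog[1],
                                config@baselineMeanLog[2])
        alpha <- stats::rlnorm(nG, config@dispersionLog[1],
                               config@dispersionLog[2])
        # gene x covariate nuisance coefficients (per standardized unit)
        beta <- matrix(stats::rnorm(nG * 3L, 0, config@covariateEffectScale),
                       nrow = nG,
                       dimnames = list(genes, c("Age", "RIN", "PMI")))

        st <- config@strata
        nDE <- floor(config@deFraction * nG)
        truth <- list()
        deEffect <- matrix(0, nrow = nG, ncol = nrow(st),
                           dimnames = list(genes, st$label))
        for (i in seq_len(nrow(st))) {
            idx <- if (nDE > 0) sample.int(nG, nDE) else integer()
            mag <- stats::rnorm(length(idx), config@effectSizeLog2[1],
                                config@effectSizeLog2[2])
            sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
            lfc <- mag * sgn
            deEffect[idx, i] <- lfc
            truth[[st$label[i]]] <- data.frame(
                gene = genes[idx], trueLog2FC = lfc,
                stringsAsFactors = FALSE)
        }

        mdList <- list()
        countList <- list()
        sfList <- list()
        for (i in seq_len(nrow(st))) {
            n <- st$nCTL[i] + st$nAD[i]
            dx <- c(rep("CTL", st$nCTL[i]), rep("AD", st$nAD[i]))
            ids <- sprintf("%s_%s_%02d", st$label[i], dx,
                           c(seq_len(st$nCTL[i]), seq_len(st$nAD[i])))
            age <- stats::runif(n, 60, 95)
            rin <- rtruncnorm(n, 8, 1, 5, 10)
            pmi <- rtruncnorm(n, 12, 6, 1, 40)
            sf <- exp(stats::rnorm(n, 0, config@libsizeLogSd))
            z <- rbind(Age = (age - .covCenters["Age"]) / .covScales["Age"],
                       RIN = (rin - .covCenters["RIN"]) / .covScales["RIN"],
                       PMI = (pmi - .covCenters["PMI"]) / .covScales["PMI"])
            logMu <- logBase + beta %*% z +
                log(2) * outer(deEffect[, i], as.numeric(dx == "AD"))
            mu <- sweep(exp(logMu), 2, sf, "*")
            cnt <- matrix(stats::rnbinom(nG * n, mu = mu,
                                         size = rep(1 / alpha, n)),
                          nrow = nG, dimnames = list(genes, ids))
            pmiMiss <- stats::runif(n) < config@pmiMissingRate
            pmiObs <- pmi
            pmiObs[pmiMiss] <- NA_real_
            mdList[[i]] <- data.frame(
                sample_id = ids, sex = st$label[i], diagnosis = dx,
                Age = age, RIN = rin, PMI = pmiObs,
                stringsAsFactors = FALSE)
            countList[[i]] <- cnt
            sfList[[i]] <- sf
        }
        counts <- do.call(cbind, countList)
        md <- do.call(rbind, mdList)
        rownames(md) <- md$sample_id
        SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(md),
            metadata = list(groundTruth = truth,
                            trueSizeFactors = stats::setNames(
                                unlist(sfList), md$sample_id),
                            config = config))
    })
}

#' Simulate a gene-set collection
#'
#' Returns any planted sets followed by `nSets` random sets drawn from the
#' gene universe with sizes uniform over `sizeRange`.
#'
#' @param geneUniverse character vector of candidate gene ids.
#' @param nSets number of random sets to draw.
#' @param sizeRange length-2 integer `(min, max)` random-set size.
#' @param planted named list of character vectors to include verbatim; all
#'   members must lie in the universe.
#' @param seed integer seed.
#' @return a [GeneSetCollection-class].
#' @export
simulateGeneSets <- function(geneUniverse, nSets,
                             sizeRange = c(15L, 50L),
                             planted = list(), seed = 1L) {
    stopifnot(is.character(geneUniverse), length(geneUniverse) > 0,
              nSets >= 0)
    if (anyDuplicated(geneUniverse))
        stop("gene universe must not contain duplicates")
    if (sizeRange[1] < 1L || sizeRange[2] > length(geneUniverse) ||
        sizeRange[1] > sizeRange[2])
        stop("sizeRange must lie within [1, length(geneUniverse)]")
    if (length(planted)) {
        if (is.null(names(planted)) || any(!nzchar(names(planted))))
            stop("planted sets must be named")
        outside <- unlist(lapply(planted, setdiff, y = geneUniverse))
        if (length(outside))
            stop("planted genes outside the universe: ",
                 paste(utils::head(outside, 5), collapse = ", "))
    }
    withSeed(seed, {
        nms <- names(planted)
        desc <- rep("planted", length(planted))
        members <- unname(lapply(planted, unique))
        if (nSets > 0) {
            sizes <- sample(seq(sizeRange[1], sizeRange[2]), nSets,
                            replace = TRUE)
            rnd <- lapply(sizes, function(k) sample(geneUniverse, k))
            nms <- c(nms, sprintf("RANDOM_SET_%03d", seq_len(nSets)))
            desc <- c(desc, rep("random", nSets))
            members <- c(members, rnd)
        }
        new("GeneSetCollection", setNames = nms, descriptions = desc,
            members = members)
    })
}

#' Simulate a literature count corpus
#'
#' For each pathway label, draws a total mention count from a log-normal
#' distribution (rounded, at least 0) and a disease co-mention count from a
#' binomial with the label's true relatedness proportion. This is the
#' fixture behind the literature impact statistic, standing in for live
#' bibliographic queries.
#'
#' @param labels character vector of pathway labels.
#' @param rTrue named numeric of true co-mention proportions in `[0, 1]`;
#'   recycled scalar allowed.
#' @param totalCountsLog `(meanlog, sdlog)` of the log-normal total counts.
#' @param seed integer seed.
#' @return a [LiteratureCounts-class].
#' @export
simulateLiteratureCorpus <- function(labels, rTrue,
                                     totalCountsLog = c(meanlog = log(500),
                                                        sdlog = 1),
                                     seed = 1L) {
    stopifnot(is.character(labels), length(labels) > 0)
    if (anyDuplicated(labels)) stop("labels must be unique")
    if (length(rTrue) == 1L)
        rTrue <- stats::setNames(rep(rTrue, length(labels)), labels)
    if (!all(labels %in% names(rTrue)))
        stop("rTrue must cover every label")
    rTrue <- rTrue[labels]
    if (any(rTrue < 0 | rTrue > 1))
        stop("rTrue values must lie in [0, 1]")
    withSeed(seed, {
        total <- pmax(0L, as.integer(round(
            stats::rlnorm(length(labels), totalCountsLog[1],
                          totalCountsLog[2]))))
        co <- stats::rbinom(length(labels), size = total, prob = rTrue)
        new("LiteratureCounts",
            counts = data.frame(label = labels, total = total,
                                coMentions = co, stringsAsFactors = FALSE))
    })
}
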