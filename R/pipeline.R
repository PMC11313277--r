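#' Assemble a pipeline configuration
#'
#' Exactly one input mode must be active: file mode (paths to a count TSV
#' and metadata TSV) or synthetic mode (a [SimConfig-class]). All stage
#' parameters live here so a configuration plus the master seed fully
#' determines every output.
#'
#' @param countsPath,metadataPath TSV inputs (file mode).
#' @param simConfig a [SimConfig-class] (synthetic mode).
#' @param gmtPath GMT collection to test; in synthetic mode `NULL` means
#'   "simulate a collection with the true DE genes of each stratum planted
#'   as one pathway per stratum".
#' @param universePath GMT (or plain label file) providing the pathway
#'   universe for the literature null; optional.
#' @param literatureCachePath JSON literature count cache; optional. The
#'   literature stage runs only when both this and `universePath` (or a
#'   provider) are available.
#' @param stratifyBy metadata column defining the strata, default `"sex"`.
#' @param minDiagnosisFraction variance-partition filter threshold.
#' @param qThreshold GSEA significance threshold.
#' @param padjThreshold,l2fcThreshold volcano significance thresholds.
#' @param nPerm,exponent,minSize,maxSize GSEA parameters.
#' @param nNull literature null size.
#' @param scoreAll score all tested pathways instead of the significant
#'   union.
#' @param disease disease term for literature queries.
#' @param seed master seed; stage seeds are derived from it.
#' @param outDir optional output directory for the report files.
#' @return a validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(countsPath = NULL, metadataPath = NULL,
                           simConfig = NULL, gmtPath = NULL,
                           universePath = NULL, literatureCachePath = NULL,
                           stratifyBy = "sex",
                           minDiagnosisFraction = 0.01,
                           qThreshold = 0.05, padjThreshold = 0.05,
                           l2fcThreshold = 1, nPerm = 1000L, exponent = 1,
                           minSize = 15L, maxSize = 500L, nNull = 1000L,
                           scoreAll = FALSE,
                           disease = "Alzheimer's disease",
                           seed = 1L, outDir = NULL) {
    fileMode <- !is.null(countsPath) || !is.null(metadataPath)
    synMode <- !is.null(simConfig)
    if (fileMode == synMode)
        stop("exactly one of file mode (countsPath + metadataPath) or ",
             "synthetic mode (simConfig) must be active")
    if (fileMode) {
        for (p in c(countsPath, metadataPath))
            if (!file.exists(p)) stop("input file not found: ", p)
    } else {
        stopifnot(is(simConfig, "SimConfig"))
    }
    for (p in c(gmtPath, universePath))
        if (!is.null(p) && !file.exists(p))
            stop("input file not found: ", p)
    cfg <- list(countsPath = countsPath, metadataPath = metadataPath,
                simConfig = simConfig, gmtPath = gmtPath,
                universePath = universePath,
                literatureCachePath = literatureCachePath,
                stratifyBy = stratifyBy,
                minDiagnosisFraction = minDiagnosisFraction,
                qThreshold = qThreshold, padjThreshold = padjThreshold,
                l2fcThreshold = l2fcThreshold, nPerm = as.integer(nPerm),
                exponent = exponent, minSize = as.integer(minSize),
                maxSize = as.integer(maxSize), nNull = as.integer(nNull),
                scoreAll = scoreAll, disease = disease,
                seed = as.integer(seed), outDir = outDir)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Volcano-plot data table
#'
#' Classifies every gene as `up` (padj below threshold and L2FC at or
#' above the fold threshold), `down` (padj below threshold and L2FC at or
#' below minus the fold threshold) or `ns`.
#'
#' @param de a [DEResults-class].
#' @param padjThreshold adjusted-p threshold, default 0.05.
#' @param l2fcThreshold absolute log2-fold-change threshold, default 1.
#' @return `data.frame` with `gene`, `log2FoldChange`, `negLog10Padj`,
#'   `significance`.
#' @export
makeVolcanoTable <- function(de, padjThreshold = 0.05, l2fcThreshold = 1) {
    padj <- pmax(de$padj, 1e-300)
    lfc <- de$log2FoldChange
    sig <- rep("ns", nrow(de))
    sig[!is.na(padj) & padj < padjThreshold & lfc >= l2fcThreshold] <- "up"
    sig[!is.na(padj) & padj < padjThreshold & lfc <= -l2fcThreshold] <- "down"
    data.frame(gene = rownames(de), log2FoldChange = lfc,
               negLog10Padj = -log10(padj), significance = sig,
               stringsAsFactors = FALSE)
}

#' Top genes by the adjusted-p rank statistic
#'
#' Orders genes by `|-log10(padj) * L2FC|` descending - regardless of
#' direction - with ties broken by gene id, and returns the top `k` with
#' their signed rank values.
#'
#' @param de a [DEResults-class].
#' @param k number of genes, default 20.
#' @return `data.frame` with `gene`, `log2FoldChange`, `padj`, `rankValue`.
#' @export
topGenes <- function(de, k = 20L) {
    stopifnot(k >= 1L)
    keep <- !is.na(de$padj) & !is.na(de$log2FoldChange)
    genes <- rownames(de)[keep]
    rv <- rankStatistic(pmax(de$padj[keep], 1e-300),
                        de$log2FoldChange[keep])
    ord <- order(-abs(rv), genes)
    take <- utils::head(ord, k)
    data.frame(gene = genes[take],
               log2FoldChange = de$log2FoldChange[keep][take],
               padj = de$padj[keep][take],
               rankValue = rv[take],
               stringsAsFactors = FALSE)
}

# Flatten a config (incl. SimConfig) into JSON-serializable lists.
.configManifest <- function(config) {
    out <- unclass(config)
    if (!is.null(out$simConfig)) {
        sc <- out$simConfig
        out$simConfig <- list(
            nGenes = sc@nGenes, strata = sc@strata,
            baselineMeanLog = sc@baselineMeanLog,
            dispersionLog = sc@dispersionLog,
            deFraction = sc@deFraction,
            effectSizeLog2 = sc@effectSizeLog2,
            covariateEffectScale = sc@covariateEffectScale,
            pmiMissingRate = sc@pmiMissingRate,
            libsizeLogSd = sc@libsizeLogSd, seed = sc@seed)
    }
    out
}

#' Rebuild a pipeline configuration from a run manifest
#'
#' In synthetic (fixture) mode the manifest suffices to reproduce every
#' output bit for bit: this reads the manifest JSON written by
#' [runStratifiedPipeline()] and reconstitutes the `PipelineConfig`.
#'
#' @param manifestPath path to `manifest.json`.
#' @param outDir optional new output directory.
#' @return a `PipelineConfig`.
#' @export
configFromManifest <- function(manifestPath, outDir = NULL) {
    man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    cfg <- man$config
    # JSON has no distinct NULL-vs-absent: normalize empties back to NULL
    cfg <- lapply(cfg, function(x) if (length(x) == 0L) NULL else x)
    sim <- NULL
    if (!is.null(cfg$simConfig))
        sim <- simConfig(
            nGenes = cfg$simConfig$nGenes,
            strata = as.data.frame(cfg$simConfig$strata),
            baselineMeanLog = cfg$simConfig$baselineMeanLog,
            dispersionLog = cfg$simConfig$dispersionLog,
            deFraction = cfg$simConfig$deFraction,
            effectSizeLog2 = cfg$simConfig$effectSizeLog2,
            covariateEffectScale = cfg$simConfig$covariateEffectScale,
            pmiMissingRate = cfg$simConfig$pmiMissingRate,
            libsizeLogSd = cfg$simConfig$libsizeLogSd,
            seed = cfg$simConfig$seed)
    pipelineConfig(
        countsPath = cfg$countsPath, metadataPath = cfg$metadataPath,
        simConfig = sim, gmtPath = cfg$gmtPath,
        universePath = cfg$universePath,
        literatureCachePath = cfg$literatureCachePath,
        stratifyBy = cfg$stratifyBy,
        minDiagnosisFraction = cfg$minDiagnosisFraction,
        qThreshold = cfg$qThreshold, padjThreshold = cfg$padjThreshold,
        l2fcThreshold = cfg$l2fcThreshold, nPerm = cfg$nPerm,
        exponent = cfg$exponent, minSize = cfg$minSize,
        maxSize = cfg$maxSize, nNull = cfg$nNull,
        scoreAll = cfg$scoreAll, disease = cfg$disease,
        seed = cfg$seed, outDir = outDir %||% cfg$outDir)
}

# Run impute -> variance filter -> DE -> rank -> GSEA for one stratum.
.runStratum <- function(label, counts, md, collection, config) {
    md <- imputePMI(md)
    sf <- computeSizeFactors(counts)
    expr <- transformCounts(counts, sf)
    vp <- partitionVariance(expr, md)
    kept <- filterGenes(vp, config$minDiagnosisFraction)
    message(sprintf("[%s] variance filter kept %d / %d genes",
                    label, length(kept), nrow(counts)))
    de <- nbWaldTest(counts[kept, , drop = FALSE], md, sizeFactors = sf)
    ranked <- buildRankedList(de)
    # one shared permutation seed across strata: identical strata then
    # yield identical tables, and both strata face the same null
    enr <- gseaPreranked(ranked, collection,
                         nPerm = config$nPerm,
                         seed = deriveSeed(config$seed, "gsea"),
                         exponent = config$exponent,
                         minSize = config$minSize,
                         maxSize = config$maxSize)
    list(label = label, varianceFractions = vp, keptGenes = kept,
         de = de, ranked = ranked, enrichment = enr,
         volcano = makeVolcanoTable(de, config$padjThreshold,
                                    config$l2fcThreshold),
         topGenes = topGenes(de, 20L))
}

#' Run the full stratified analysis
#'
#' Splits samples by the stratifying column and, within each stratum with
#' at least two samples per diagnosis group, runs PMI imputation, the
#' variance-partition gene filter, negative binomial Wald differential
#' expression, rank-statistic construction and pre-ranked GSEA with
#' identical parameters. With exactly two analyzable strata their
#' significant pathways are compared, and (when a literature cache and
#' pathway universe are configured) the union of significant pathways is
#' scored against the disease literature. Strata with too few samples are
#' skipped with a warning and the pipeline continues.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return a `ReportBundle` list: per-stratum results, the
#'   `StratumComparison`, the `ImpactScores` (or `NULL`), and the run
#'   manifest. When `outDir` is set, all tables are also written as
#'   TSV/JSON under it.
#' @export
runStratifiedPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (!is.null(config$simConfig)) {
        se <- simulateCohort(config$simConfig)
        counts <- assay(se, "counts")
        md <- as.data.frame(colData(se))
        truth <- metadata(se)$groundTruth
    } else {
        counts <- readCounts(config$countsPath)
        md <- readSampleMetadata(config$metadataPath)
        if (!setequal(md$sample_id, colnames(counts)))
            stop("metadata samples and count columns do not match")
        md <- md[match(colnames(counts), md$sample_id), ]
        truth <- NULL
    }
    for (col in setdiff(c("sample_id", "sex", "diagnosis", "Age", "RIN"),
                        "PMI"))
        if (anyNA(md[[col]]))
            stop("missing values in metadata column '", col,
                 "'; only PMI may be missing")

    collection <- if (!is.null(config$gmtPath)) {
        readGmt(config$gmtPath)
    } else if (!is.null(truth)) {
        # plant one set per stratum and direction: a mixed up/down set
        # would cancel its own running sum
        planted <- list()
        for (s in names(truth)) {
            planted[[paste0("TRUE_DE_", toupper(s), "_UP")]] <-
                truth[[s]]$gene[truth[[s]]$trueLog2FC > 0]
            planted[[paste0("TRUE_DE_", toupper(s), "_DOWN")]] <-
                truth[[s]]$gene[truth[[s]]$trueLog2FC < 0]
        }
        planted <- planted[lengths(planted) > 0]
        # keep the default collection small: the permutation p floor is
        # ~2/nPerm, so BH q < 0.05 is only attainable when the number of
        # tested sets stays below ~nPerm/40
        simulateGeneSets(rownames(counts), nSets = 20L,
                         sizeRange = c(config$minSize,
                                       min(config$maxSize, 50L)),
                         planted = planted,
                         seed = deriveSeed(config$seed, "genesets"))
    } else stop("file mode requires gmtPath")

    strata <- split(seq_len(nrow(md)), as.character(md[[config$stratifyBy]]))
    results <- list()
    for (label in names(strata)) {
        i <- strata[[label]]
        tab <- table(md$diagnosis[i])
        if (length(tab) < 2L || min(tab) < 2L) {
            warning("stratum '", label, "' skipped: fewer than 2 samples ",
                    "in a diagnosis group", call. = FALSE, immediate. = TRUE)
            next
        }
        results[[label]] <- .runStratum(
            label, counts[, i, drop = FALSE], md[i, ], collection, config)
    }

    comparison <- NULL
    if (length(results) == 2L) {
        labs <- names(results)
        comparison <- compareStrata(results[[1]]$enrichment,
                                    results[[2]]$enrichment,
                                    qThreshold = config$qThreshold,
                                    strataNames = labs)
    }

    impact <- NULL
    if (!is.null(config$literatureCachePath) &&
        !is.null(config$universePath) &&
        file.exists(config$literatureCachePath)) {
        sig <- unique(unlist(lapply(results, function(r) {
            e <- r$enrichment
            if (config$scoreAll) e$pathway
            else e$pathway[!is.na(e$qval) & e$qval < config$qThreshold]
        })))
        universe <- names(readGmt(config$universePath))
        prov <- fixtureProvider(readLiteratureCounts(
            config$literatureCachePath))
        impact <- scorePathways(sort(sig), universe, prov,
                                nNull = config$nNull,
                                seed = deriveSeed(config$seed,
                                                  "literature"))
    }

    manifest <- list(config = .configManifest(config),
                     package = "strataTx",
                     packageVersion = as.character(
                         utils::packageVersion("strataTx")),
                     rVersion = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))
    bundle <- list(strata = results, comparison = comparison,
                   impact = impact, collection = collection,
                   groundTruth = truth, manifest = manifest)
    class(bundle) <- "ReportBundle"
    if (!is.null(config$outDir)) .writeBundle(bundle, config$outDir)
    bundle
}

# TSV/JSON serialization of a ReportBundle.
.writeBundle <- function(bundle, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (r in bundle$strata) {
        pre <- file.path(outDir, r$label)
        de <- as.data.frame(r$de)
        .writeTsv(cbind(gene = rownames(de), de), paste0(pre, "_de.tsv"))
        vp <- as.data.frame(r$varianceFractions)
        .writeTsv(cbind(gene = rownames(vp), vp),
                  paste0(pre, "_variance_fractions.tsv"))
        .writeTsv(r$volcano, paste0(pre, "_volcano.tsv"))
        .writeTsv(r$topGenes, paste0(pre, "_top_genes.tsv"))
        e <- as.data.frame(r$enrichment[, setdiff(colnames(r$enrichment),
                                                  "leadingEdge")])
        e$leadingEdge <- vapply(r$enrichment$leadingEdge,
                                paste, character(1), collapse = ";")
        .writeTsv(e, paste0(pre, "_enrichment.tsv"))
    }
    if (!is.null(bundle$comparison)) {
        ct <- comparisonCounts(bundle$comparison)
        .writeTsv(ct, file.path(outDir, "stratum_comparison.tsv"))
        jsonlite::write_json(
            list(up = bundle$comparison@up, down = bundle$comparison@down,
                 counts = ct),
            file.path(outDir, "stratum_comparison.json"),
            auto_unbox = TRUE)
    }
    if (!is.null(bundle$impact)) {
        im <- as.data.frame(bundle$impact)
        .writeTsv(im, file.path(outDir, "impact_scores.tsv"))
    }
    jsonlite::write_json(bundle$manifest,
                         file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(outDir)
}

#' @export
print.ReportBundle <- function(x, ...) {
    cat("ReportBundle with", length(x$strata), "analyzed strata:",
        paste(names(x$strata), collapse = ", "), "\n")
    for (r in x$strata) {
        nsig <- sum(r$de$padj < 0.05, na.rm = TRUE)
        e <- r$enrichment
        cat(sprintf(
            "  %s: %d genes tested, %d at padj < 0.05; %d/%d pathways up/down at q < 0.05\n",
            r$label, nrow(r$de), nsig,
            sum(e$qval < 0.05 & e$direction == "up", na.rm = TRUE),
            sum(e$qval < 0.05 & e$direction == "down", na.rm = TRUE)))
    }
    if (!is.null(x$comparison)) print(comparisonCounts(x$comparison))
    invisible(x)
}
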