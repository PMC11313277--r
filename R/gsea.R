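#' Per-gene rank statistic
#'
#' `-log10(p) * L2FC`: large positive for strongly up-regulated genes,
#' large negative for strongly down-regulated ones, 0 at p = 1.
#'
#' @param p p-values in `(0, 1]` (floor underflowed values upstream).
#' @param l2fc finite log2 fold changes.
#' @return numeric rank values.
#' @examples
#' rankStatistic(0.01, 2)  # 4
#' @export
rankStatistic <- function(p, l2fc) {
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p must lie in (0, 1]")
    if (any(!is.finite(l2fc)))
        stop("l2fc must be finite")
    -log10(p) * l2fc
}

#' Build a ranked gene list from DE results
#'
#' Orders genes by the rank statistic, descending, breaking ties by
#' lexicographic gene id so the ordering is deterministic. Flagged genes
#' (missing p or fold change) are excluded.
#'
#' @param de a [DEResults-class] (or any data frame with rownames,
#'   `pvalue` and `log2FoldChange`).
#' @param useAdjusted rank on `padj` instead of the raw p-value (reporting
#'   convention; enrichment uses the raw p-value by default).
#' @return named numeric vector of rank values, descending.
#' @export
buildRankedList <- function(de, useAdjusted = FALSE) {
    genes <- rownames(de)
    if (is.null(genes) || anyDuplicated(genes))
        stop("DE table must have unique gene rownames")
    p <- if (useAdjusted) de$padj else de$pvalue
    lfc <- de$log2FoldChange
    keep <- !is.na(p) & !is.na(lfc)
    genes <- genes[keep]
    val <- rankStatistic(pmax(p[keep], 1e-300), lfc[keep])
    ord <- order(-val, genes)
    stats::setNames(val[ord], genes[ord])
}

# ES from sorted hit positions, given the precomputed |rank|^exponent
# vector. Running sum: hits step up by weight / total hit weight, misses
# step down by 1 / (N - k). Extrema candidates sit at hit positions (tops)
# and just before hits (bottoms); ties between |max| and |min| resolve to
# the positive extremum.
.esCore <- function(weights, N, pos) {
    k <- length(pos)
    w <- weights[pos]
    if (sum(w) == 0) w <- rep(1, k)    # all-zero ranks: unweighted steps
    cumhit <- cumsum(w) / sum(w)
    drop <- (pos - seq_len(k)) / (N - k)
    top <- cumhit - drop
    bottom <- top - w / sum(w)
    maxTop <- max(top)
    minBot <- min(bottom)
    # positive extremum wins ties, up to accumulated rounding
    if (maxTop - (-minBot) >= -1e-12)
        list(es = maxTop, peak = pos[which.max(top)])
    else
        list(es = minBot, peak = pos[which.min(bottom)] - 1L)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic running-sum statistic on a ranked list: positions in the set
#' increment by `|rank|^exponent` (normalized over set hits), positions
#' outside decrement by `1 / (N - k)`; the score is the extremum of
#' largest magnitude with its sign preserved. Always in `[-1, 1]`.
#'
#' @param ranked named numeric rank values, descending
#'   (from [buildRankedList()]).
#' @param geneSet character vector of member gene ids.
#' @param exponent non-negative rank weight; 1 by default.
#' @return list with `es` and `peak` (position of the extremum).
#' @export
enrichmentScore <- function(ranked, geneSet, exponent = 1) {
    stopifnot(is.numeric(ranked), !is.null(names(ranked)), exponent >= 0)
    N <- length(ranked)
    pos <- which(names(ranked) %in% geneSet)
    if (length(pos) == 0L)
        stop("gene set has no overlap with the ranked list")
    if (length(pos) == N)
        stop("gene set covers the whole ranked list; no misses to score")
    .esCore(abs(ranked)^exponent, N, pos)
}

#' Pre-ranked gene-set enrichment with a gene-sampling permutation null
#'
#' For every collection set whose overlap with the ranked universe lies in
#' `[minSize, maxSize]`, computes the weighted KS enrichment score, then a
#' null of `nPerm` scores from random same-size gene subsets of the ranked
#' list (nulls are shared across sets of equal size and seeded per size, so
#' results do not depend on collection order). The normalized score is
#' `NES = ES / mean(|null ES|)` over nulls of matching sign; the
#' permutation p-value is the sign-matched exceedance with a +1
#' pseudocount; q-values are Benjamini-Hochberg across all tested sets.
#'
#' @param ranked named numeric rank values, descending.
#' @param collection a [GeneSetCollection-class].
#' @param nPerm number of permutations, >= 100.
#' @param seed integer seed for the permutation null.
#' @param exponent rank weight exponent.
#' @param minSize,maxSize overlap-size bounds for testing a set.
#' @return an [EnrichmentResults-class]; pathways skipped by the size
#'   filter are recorded in `metadata()$skipped`.
#' @export
gseaPreranked <- function(ranked, collection, nPerm = 1000L, seed = 1L,
                          exponent = 1, minSize = 15L, maxSize = 500L) {
    stopifnot(is(collection, "GeneSetCollection"), nPerm >= 100L)
    if (anyDuplicated(names(ranked)))
        stop("ranked list contains duplicate gene ids")
    N <- length(ranked)
    weights <- abs(ranked)^exponent

    overlap <- lapply(collection@members, function(m)
        which(names(ranked) %in% m))
    sizes <- lengths(overlap)
    keep <- sizes >= minSize & sizes <= pmin(maxSize, N - 1L)
    skipped <- data.frame(pathway = collection@setNames[!keep],
                          size = sizes[!keep], stringsAsFactors = FALSE)
    if (!any(keep)) {
        warning("no pathway passed the size filter [", minSize, ", ",
                maxSize, "]")
        empty <- DataFrame(pathway = character(), size = integer(),
                           ES = numeric(), NES = numeric(),
                           pval = numeric(), qval = numeric(),
                           direction = character(),
                           leadingEdge = S4Vectors::SimpleList())
        res <- new("EnrichmentResults", empty)
        metadata(res) <- list(skipped = skipped,
                              collectionNames = collection@setNames)
        return(res)
    }
    idx <- which(keep)
    if (nrow(skipped))
        message(nrow(skipped), " pathway(s) skipped by the size filter")

    # one permutation null per distinct set size
    nulls <- new.env(parent = emptyenv())
    for (k in sort(unique(sizes[idx]))) {
        es <- withSeed(deriveSeed(seed, paste0("gene-sampling-null-", k)), {
            vapply(seq_len(nPerm), function(b) {
                .esCore(weights, N, sort(sample.int(N, k)))$es
            }, numeric(1))
        })
        assign(as.character(k), es, envir = nulls)
    }

    rows <- lapply(idx, function(i) {
        pos <- overlap[[i]]
        k <- length(pos)
        obs <- .esCore(weights, N, pos)
        null <- get(as.character(k), envir = nulls)
        same <- if (obs$es >= 0) null[null >= 0] else null[null < 0]
        if (length(same)) {
            nes <- obs$es / mean(abs(same))
            p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
        } else {
            nes <- NA_real_
            p <- 1 / (1 + nPerm)
        }
        le <- if (obs$es >= 0) pos[pos <= obs$peak] else pos[pos > obs$peak]
        list(size = k, es = obs$es, nes = nes, p = p,
             leadingEdge = names(ranked)[le])
    })
    pval <- vapply(rows, `[[`, numeric(1), "p")
    es <- vapply(rows, `[[`, numeric(1), "es")
    out <- DataFrame(
        pathway = collection@setNames[idx],
        size = vapply(rows, `[[`, numeric(1), "size"),
        ES = es,
        NES = vapply(rows, `[[`, numeric(1), "nes"),
        pval = pval,
        qval = adjustBH(pval),
        direction = ifelse(es >= 0, "up", "down"),
        leadingEdge = S4Vectors::SimpleList(lapply(rows, `[[`,
                                                   "leadingEdge")))
    rownames(out) <- out$pathway
    res <- new("EnrichmentResults", out)
    metadata(res) <- list(nPerm = nPerm, seed = seed, exponent = exponent,
                          minSize = minSize, maxSize = maxSize,
                          skipped = skipped,
                          collectionNames = collection@setNames)
    res
}

#' Compare significant pathways between two strata
#'
#' Intersects and differences the pathways called significant (at the q
#' threshold) in each direction between two enrichment result tables that
#' were produced against the same collection.
#'
#' @param resA,resB [EnrichmentResults-class] for the two strata.
#' @param qThreshold significance threshold, default 0.05.
#' @param strataNames labels for the two strata.
#' @return a [StratumComparison-class]; see [comparisonCounts()].
#' @export
compareStrata <- function(resA, resB, qThreshold = 0.05,
                          strataNames = c("A", "B")) {
    stopifnot(is(resA, "EnrichmentResults"), is(resB, "EnrichmentResults"))
    cnA <- metadata(resA)$collectionNames
    cnB <- metadata(resB)$collectionNames
    if (!identical(cnA, cnB))
        stop("the two results were not tested against the same collection")
    sig <- function(res, dir)
        res$pathway[!is.na(res$qval) & res$qval < qThreshold &
                    res$direction == dir]
    part <- function(dir) {
        a <- sig(resA, dir); b <- sig(resB, dir)
        list(shared = sort(intersect(a, b)),
             uniqueA = sort(setdiff(a, b)),
             uniqueB = sort(setdiff(b, a)))
    }
    new("StratumComparison",
        strataNames = as.character(strataNames),
        up = part("up"), down = part("down"),
        qThreshold = qThreshold)
}
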