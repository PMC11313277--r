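#' @describeIn GeneSetCollection-class number of sets
#' @param x a `GeneSetCollection`
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setNames))

#' @describeIn GeneSetCollection-class set names
#' @export
setMethod("names", "GeneSetCollection", function(x) x@setNames)

#' Member gene ids of a collection
#'
#' @param x a `GeneSetCollection`
#' @return named list of character vectors of member gene ids.
#' @export
geneSets <- function(x) {
    stopifnot(is(x, "GeneSetCollection"))
    stats::setNames(x@members, x@setNames)
}

#' Set descriptions of a collection
#'
#' @param x a `GeneSetCollection`
#' @return named character vector of descriptions.
#' @export
setDescriptions <- function(x) {
    stopifnot(is(x, "GeneSetCollection"))
    stats::setNames(x@descriptions, x@setNames)
}

#' @describeIn GeneSetCollection-class extract one set's members by name or
#'   position
#' @param i index or set name
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) {
    if (is.character(i)) {
        j <- match(i, x@setNames)
        if (is.na(j)) stop("no gene set named '", i, "'")
        i <- j
    }
    x@members[[i]]
})

#' @describeIn GeneSetCollection-class subset the collection
#' @export
setMethod("[", "GeneSetCollection", function(x, i) {
    if (is.character(i)) {
        j <- match(i, x@setNames)
        if (anyNA(j)) stop("unknown set name(s): ",
                           paste(i[is.na(j)], collapse = ", "))
        i <- j
    }
    new("GeneSetCollection",
        setNames = x@setNames[i],
        descriptions = x@descriptions[i],
        members = x@members[i])
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object), "sets\n")
    if (length(object)) {
        sz <- lengths(object@members)
        cat("  set sizes:", min(sz), "-", max(sz), "\n")
        preview <- utils::head(object@setNames, 3L)
        cat("  ", paste(preview, collapse = ", "),
            if (length(object) > 3L) ", ..." else "", "\n", sep = "")
    }
})

setMethod("show", "LiteratureCounts", function(object) {
    df <- object@counts
    cat("LiteratureCounts for", nrow(df), "labels\n")
    if (nrow(df))
        cat("  total mentions:", min(df$total), "-", max(df$total), "\n")
})

#' Literature counts as a data.frame
#'
#' @param x a `LiteratureCounts`
#' @return `data.frame` with columns `label`, `total`, `coMentions`.
#' @export
literatureCounts <- function(x) {
    stopifnot(is(x, "LiteratureCounts"))
    x@counts
}

setMethod("show", "SimConfig", function(object) {
    st <- object@strata
    cat("SimConfig:", object@nGenes, "genes;",
        sum(st$nCTL + st$nAD), "samples in", nrow(st), "strata\n")
    for (i in seq_len(nrow(st)))
        cat(sprintf("  %s: CTL = %d, AD = %d\n",
                    st$label[i], st$nCTL[i], st$nAD[i]))
    cat(sprintf("  DE fraction %.3g, |L2FC| ~ N(%.2g, %.2g), seed %d\n",
                object@deFraction, object@effectSizeLog2[1],
                object@effectSizeLog2[2], object@seed))
})

setMethod("show", "DEResults", function(object) {
    cat("DEResults:", nrow(object), "genes\n")
    ok <- !is.na(object$padj)
    cat("  ", sum(object$padj < 0.05, na.rm = TRUE),
        "genes at padj < 0.05 (", sum(!ok), " untested )\n")
    callNextMethod()
})

setMethod("show", "EnrichmentResults", function(object) {
    cat("EnrichmentResults:", nrow(object), "pathways tested\n")
    if (nrow(object))
        cat("  ", sum(object$qval < 0.05 & object$direction == "up"), "up /",
            sum(object$qval < 0.05 & object$direction == "down"),
            "down at q < 0.05\n")
    callNextMethod()
})

setMethod("show", "ImpactScores", function(object) {
    cat("ImpactScores:", nrow(object), "pathways;",
        "null n =", metadata(object)$nNull %||% NA, "\n")
    callNextMethod()
})

setMethod("show", "StratumComparison", function(object) {
    ct <- comparisonCounts(object)
    cat("StratumComparison (", object@strataNames[1], "vs",
        object@strataNames[2], ") at q <", object@qThreshold, "\n")
    print(ct)
})

#' Tabulate a cross-stratum comparison
#'
#' @param x a `StratumComparison`
#' @return `data.frame` with one row per direction and columns for the two
#'   strata's significant-set totals, the shared count, and each stratum's
#'   unique count. By construction
#'   `unique + shared = total` within each stratum and direction.
#' @export
comparisonCounts <- function(x) {
    stopifnot(is(x, "StratumComparison"))
    row <- function(d) {
        s <- slot(x, d)
        data.frame(
            direction = d,
            sharedN = length(s$shared),
            uniqueAN = length(s$uniqueA),
            uniqueBN = length(s$uniqueB),
            totalA = length(s$shared) + length(s$uniqueA),
            totalB = length(s$shared) + length(s$uniqueB),
            stringsAsFactors = FALSE
        )
    }
    out <- rbind(row("up"), row("down"))
    names(out)[c(3, 4, 5, 6)] <- c(
        paste0("unique_", x@strataNames[1]),
        paste0("unique_", x@strataNames[2]),
        paste0("total_", x@strataNames[1]),
        paste0("total_", x@strataNames[2]))
    out
}
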