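#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' non-negative integer entries. Malformed input is rejected, never
#' coerced.
#'
#' @param path TSV file path.
#' @return integer matrix with gene row names and sample column names.
#' @export
readCounts <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("count file needs a gene id column plus at least one sample")
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene id(s): ",
             paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
    mat <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(mat)))
        stop("duplicate sample id(s) in header")
    if (!is.numeric(mat) || anyNA(mat))
        stop("counts must be numeric and complete")
    bad <- which(rowSums(mat < 0) > 0)
    if (length(bad))
        stop("negative count in row for gene '", genes[bad[1]], "'")
    bad <- which(rowSums(mat != round(mat)) > 0)
    if (length(bad))
        stop("non-integer count in row for gene '", genes[bad[1]], "'")
    storage.mode(mat) <- "integer"
    rownames(mat) <- genes
    mat
}

#' @rdname readCounts
#' @param counts integer matrix (genes x samples) with dimnames.
#' @param path output TSV path.
#' @export
writeCounts <- function(counts, path) {
    .assertCountMatrix(counts)
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' Read and write sample metadata TSV
#'
#' Required columns: `sample_id`, `sex` (female/male), `diagnosis`
#' (CTL/AD), `Age`, `RIN`, `PMI`. Empty cells in `PMI` are read as missing;
#' missingness anywhere else is an error.
#'
#' @param path TSV file path.
#' @return `data.frame` with `PMI` as numeric containing `NA` for missing.
#' @export
readSampleMetadata <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
    .assertMetadata(df)
    for (col in c("Age", "RIN", "PMI"))
        df[[col]] <- as.numeric(df[[col]])
    df
}

#' @rdname readSampleMetadata
#' @param metadata metadata `data.frame`; missing PMI written as an empty
#'   cell.
#' @export
writeSampleMetadata <- function(metadata, path) {
    .assertMetadata(metadata)
    .writeTsv(as.data.frame(metadata), path)
}

#' Read a GMT gene-set file
#'
#' Broad dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are deduplicated with a warning;
#' duplicate set names or lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line ", short[1], " has fewer than 3 fields")
    nms <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(nms))
        stop("duplicate gene-set name: ", nms[duplicated(nms)][1])
    members <- lapply(fields, function(f) {
        m <- f[-c(1L, 2L)]
        m <- m[nzchar(m)]
        if (anyDuplicated(m)) {
            warning("duplicate members deduplicated in set '", f[[1L]], "'",
                    call. = FALSE)
            m <- unique(m)
        }
        m
    })
    new("GeneSetCollection",
        setNames = nms,
        descriptions = vapply(fields, `[[`, character(1), 2L),
        members = members)
}

#' @rdname readGmt
#' @param collection a [GeneSetCollection-class].
#' @export
writeGmt <- function(collection, path) {
    stopifnot(is(collection, "GeneSetCollection"))
    lines <- vapply(seq_along(collection), function(i) {
        paste(c(collection@setNames[i], collection@descriptions[i],
                collection@members[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read and write a literature count cache (JSON)
#'
#' JSON shape: `{"LABEL": {"total": n, "co_mentions": m}, ...}` with
#' `m <= n` for every label.
#'
#' @param path JSON file path.
#' @return a [LiteratureCounts-class].
#' @export
readLiteratureCounts <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(obj) == 0L)
        return(new("LiteratureCounts",
                   counts = data.frame(label = character(),
                                       total = integer(),
                                       coMentions = integer())))
    labels <- names(obj)
    total <- vapply(obj, function(x) as.numeric(x$total), numeric(1))
    co <- vapply(obj, function(x) as.numeric(x$co_mentions), numeric(1))
    if (anyNA(total) || anyNA(co))
        stop("every label needs integer 'total' and 'co_mentions'")
    bad <- which(co > total)
    if (length(bad))
        stop("co_mentions exceeds total for label '", labels[bad[1]], "'")
    new("LiteratureCounts",
        counts = data.frame(label = labels, total = as.integer(total),
                            coMentions = as.integer(co),
                            stringsAsFactors = FALSE, row.names = NULL))
}

#' @rdname readLiteratureCounts
#' @param litCounts a [LiteratureCounts-class].
#' @export
writeLiteratureCounts <- function(litCounts, path) {
    stopifnot(is(litCounts, "LiteratureCounts"))
    validObject(litCounts)
    df <- litCounts@counts
    obj <- stats::setNames(
        lapply(seq_len(nrow(df)), function(i)
            list(total = df$total[i], co_mentions = df$coMentions[i])),
        df$label)
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
    invisible(path)
}
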