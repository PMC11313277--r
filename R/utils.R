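`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a local RNG state so callers' streams are untouched.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old))
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed plus a stage tag to a 31-bit seed so
#' that pipeline stages are independently reproducible.
#'
#' @param master integer master seed.
#' @param stage character tag naming the stage.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, stage) {
    stopifnot(length(master) == 1L, length(stage) == 1L, nzchar(stage))
    code <- utf8ToInt(stage)
    h <- sum(as.numeric(code) * seq_along(code) * 131) %% 2147483647
    as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483647)
}

# Inverse-CDF truncated normal; deterministic under set.seed.
rtruncnorm <- function(n, mean, sd, lower, upper) {
    plo <- stats::pnorm(lower, mean, sd)
    phi <- stats::pnorm(upper, mean, sd)
    stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

.assertCountMatrix <- function(counts) {
    if (!is.matrix(counts) || !is.numeric(counts))
        stop("counts must be a numeric matrix")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene row names and sample column names")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate gene ids in count matrix")
    if (anyDuplicated(colnames(counts)))
        stop("duplicate sample ids in count matrix")
    if (anyNA(counts) || any(counts < 0))
        stop("counts must be non-negative and complete")
    if (any(counts != round(counts)))
        stop("counts must be integers")
    invisible(counts)
}

.assertMetadata <- function(md, requirePMI = TRUE) {
    need <- c("sample_id", "sex", "diagnosis", "Age", "RIN", "PMI")
    miss <- setdiff(need, names(md))
    if (length(miss))
        stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(md$sample_id))
        stop("duplicate sample ids in metadata")
    bad <- setdiff(unique(as.character(md$sex)), c("female", "male"))
    if (length(bad))
        stop("unknown sex level(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(as.character(md$diagnosis)), c("CTL", "AD"))
    if (length(bad))
        stop("unknown diagnosis level(s): ", paste(bad, collapse = ", "))
    for (col in c("Age", "RIN")) {
        if (anyNA(md[[col]]))
            stop("missing values in metadata column ", col,
                 " (only PMI may be missing)")
    }
    invisible(md)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}
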