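#' Impute missing post-mortem interval values
#'
#' Replaces every missing PMI with the fixed sentinel value -1, leaving all
#' other fields untouched. Imputation is a deliberate pipeline stage (the
#' simulator emits genuine missing values) so the rule itself is testable.
#'
#' @param metadata a metadata `data.frame`/`DataFrame` with a `PMI` column,
#'   or a `SummarizedExperiment` whose `colData` has one.
#' @param value the sentinel, default `-1`.
#' @return the same object with missing PMI replaced by `value`.
#' @export
imputePMI <- function(metadata, value = -1) {
    if (is(metadata, "SummarizedExperiment")) {
        cd <- colData(metadata)
        cd$PMI[is.na(cd$PMI)] <- value
        colData(metadata) <- cd
        return(metadata)
    }
    if (!"PMI" %in% names(metadata))
        stop("metadata has no PMI column")
    metadata$PMI[is.na(metadata$PMI)] <- value
    metadata
}

#' Normalized log2 expression
#'
#' `log2(count / sizeFactor + 1)` per entry; finite everywhere for valid
#' input. Doubling a sample's counts together with its size factor leaves
#' its column unchanged.
#'
#' @param counts gene x sample count matrix.
#' @param sizeFactors strictly positive per-sample scale factors (defaults
#'   to median-of-ratios factors from [computeSizeFactors()]).
#' @return numeric matrix of normalized log2 expression.
#' @export
transformCounts <- function(counts, sizeFactors = computeSizeFactors(counts)) {
    .assertCountMatrix(counts)
    if (length(sizeFactors) != ncol(counts))
        stop("need one size factor per sample")
    if (any(!is.finite(sizeFactors)) || any(sizeFactors <= 0))
        stop("size factors must be strictly positive")
    log2(sweep(counts, 2, sizeFactors, "/") + 1)
}

# Build the fixed-effect design for ~ Age + RIN + PMI + Diagnosis with
# Diagnosis coded CTL = 0, AD = 1. Errors name any constant covariate.
.vpDesign <- function(metadata) {
    .assertMetadata(metadata)
    if (anyNA(metadata$PMI))
        stop("PMI contains missing values; run imputePMI() first")
    dx <- as.numeric(as.character(metadata$diagnosis) == "AD")
    if (length(unique(dx)) < 2L || min(table(dx)) < 2L)
        stop("need >= 2 samples in each diagnosis group")
    X <- cbind(Intercept = 1, Age = metadata$Age, RIN = metadata$RIN,
               PMI = metadata$PMI, Diagnosis = dx)
    for (term in c("Age", "RIN", "PMI"))
        if (stats::var(X[, term]) == 0)
            stop("covariate '", term, "' is constant; design is rank deficient")
    if (qr(X)$rank < ncol(X))
        stop("design matrix is rank deficient (collinear covariates)")
    X
}

#' Partition per-gene expression variance across covariates
#'
#' Fits the fixed-effect linear model
#' `expression ~ Age + RIN + PMI + Diagnosis` per gene and attributes to
#' each term its marginal delta-R-squared (full-model R2 minus the R2 of
#' the model dropping that term), rescaled so that the four attributed
#' fractions plus the residual `1 - R2_full` sum to one. Genes with zero
#' expression variance are flagged with residual 1 and zero attributions.
#'
#' @param expr gene x sample matrix of (normalized log) expression.
#' @param metadata metadata `data.frame` with PMI already imputed.
#' @return a [VarianceFractions-class] `DFrame` with columns `Age`, `RIN`,
#'   `PMI`, `Diagnosis`, `Residual`, `flagged`.
#' @export
partitionVariance <- function(expr, metadata) {
    stopifnot(is.matrix(expr), is.numeric(expr))
    metadata <- as.data.frame(metadata)
    if (ncol(expr) != nrow(metadata))
        stop("expression columns and metadata rows must match")
    X <- .vpDesign(metadata)
    terms <- c("Age", "RIN", "PMI", "Diagnosis")

    Y <- t(expr)                        # samples x genes
    tss <- colSums(scale(Y, scale = FALSE)^2)
    rssFull <- colSums(qr.resid(qr(X), Y)^2)
    dRss <- sapply(terms, function(term) {
        Xd <- X[, setdiff(colnames(X), term), drop = FALSE]
        colSums(qr.resid(qr(Xd), Y)^2) - rssFull
    })
    if (is.null(dim(dRss))) dRss <- matrix(dRss, nrow = 1,
                                           dimnames = list(NULL, terms))

    flagged <- tss <= .Machine$double.eps * nrow(Y)
    r2full <- ifelse(flagged, 0, 1 - rssFull / tss)
    dR2 <- dRss / ifelse(flagged, 1, tss)
    dR2[dR2 < 0] <- 0                  # guard against numeric noise
    tot <- rowSums(dR2)
    scaleTo <- ifelse(tot > 0, r2full / tot, 0)
    frac <- dR2 * scaleTo
    frac[flagged, ] <- 0
    residual <- 1 - rowSums(frac)
    dimnames(frac) <- list(NULL, terms)
    out <- DataFrame(frac, Residual = unname(residual),
                     flagged = unname(flagged),
                     row.names = rownames(expr))
    new("VarianceFractions", out)
}

#' Filter genes by diagnosis-explained variance
#'
#' Retains (in stable input order) the non-flagged genes whose Diagnosis
#' variance fraction meets the threshold. This is the pre-test filter that
#' removes genes whose variability is not explained by the phenotype.
#'
#' @param fractions a [VarianceFractions-class].
#' @param minDiagnosisFraction threshold in `[0, 1]`; default 0.01.
#' @return character vector of retained gene ids.
#' @export
filterGenes <- function(fractions, minDiagnosisFraction = 0.01) {
    stopifnot(is(fractions, "VarianceFractions"))
    if (minDiagnosisFraction < 0 || minDiagnosisFraction > 1)
        stop("minDiagnosisFraction must lie in [0, 1]")
    keep <- !fractions$flagged &
        fractions$Diagnosis >= minDiagnosisFraction
    rownames(fractions)[keep]
}
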