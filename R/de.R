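#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes (genes with nonzero
#' counts in every sample) of the ratio of its count to the gene's
#' geometric mean, rescaled so the factors have geometric mean 1.
#'
#' @param counts gene x sample count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts) {
    .assertCountMatrix(counts)
    ref <- rowSums(counts == 0) == 0L
    if (!any(ref))
        stop("no gene has nonzero counts in all samples; ",
             "consider a pseudo-reference fallback on a filtered matrix")
    logc <- log(counts[ref, , drop = FALSE])
    logGeo <- rowMeans(logc)
    sf <- exp(apply(logc - logGeo, 2, stats::median))
    sf <- sf / exp(mean(log(sf)))
    sf
}

#' Method-of-moments NB dispersion
#'
#' Per gene, computes sample means and variances of normalized counts
#' within each design cell (diagnosis group) and pools them into
#' `alpha = max(0, sum_c w_c (s2_c - m_c) / sum_c w_c m_c^2)` with
#' `w_c = n_c - 1`, the moment estimate under `var = mu + alpha mu^2`.
#' Optionally shrinks each estimate halfway (in log space) toward a
#' mean-dispersion trend fitted by loess; off by default.
#'
#' @param counts gene x sample count matrix.
#' @param sizeFactors per-sample size factors.
#' @param groups factor of design cells (normally the diagnosis column).
#' @param shrink logical; shrink toward the alpha-vs-mean trend.
#' @return `DataFrame` with columns `alpha`, `baseMean`, `flagged`
#'   (all-zero genes, which get `alpha = 0`).
#' @export
estimateDispersion <- function(counts, sizeFactors = computeSizeFactors(counts),
                               groups, shrink = FALSE) {
    .assertCountMatrix(counts)
    groups <- as.factor(groups)
    if (length(groups) != ncol(counts))
        stop("need one group per sample")
    if (any(table(groups) < 3L))
        stop("need >= 3 samples per design cell (>= 2 residual df)")
    norm <- sweep(counts, 2, sizeFactors, "/")
    num <- 0; den <- 0
    for (g in levels(groups)) {
        sub <- norm[, groups == g, drop = FALSE]
        n <- ncol(sub)
        m <- rowMeans(sub)
        s2 <- rowSums((sub - m)^2) / (n - 1)
        num <- num + (n - 1) * (s2 - m)
        den <- den + (n - 1) * m^2
    }
    flagged <- rowSums(counts) == 0L
    alpha <- ifelse(den > 0, pmax(0, num / den), 0)
    alpha[flagged] <- 0
    baseMean <- rowMeans(norm)
    if (shrink) {
        ok <- !flagged & baseMean > 0 & alpha > 0
        if (sum(ok) >= 20L) {
            fit <- stats::loess(log(alpha[ok]) ~ log(baseMean[ok]),
                                span = 0.75, degree = 1)
            trend <- exp(stats::predict(
                fit, pmin(pmax(log(baseMean), min(log(baseMean[ok]))),
                          max(log(baseMean[ok])))))
            mix <- exp(0.5 * log(pmax(alpha, 1e-8)) + 0.5 * log(trend))
            alpha[!flagged] <- mix[!flagged]
        }
    }
    DataFrame(alpha = unname(alpha), baseMean = unname(baseMean),
              flagged = unname(flagged), row.names = rownames(counts))
}

# One NB (or Poisson for alpha ~ 0) IRLS fit at fixed dispersion; returns
# the Diagnosis coefficient, its unscaled Wald SE, and convergence status.
.nbFitOne <- function(y, X, offset, alpha, maxit) {
    fam <- if (alpha < 1e-8) stats::poisson(link = "log")
           else MASS::negative.binomial(theta = 1 / alpha, link = "log")
    fit <- suppressWarnings(
        stats::glm.fit(X, y, family = fam, offset = offset,
                       control = list(maxit = maxit)))
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(cov)) return(NULL)
    j <- match("Diagnosis", colnames(X))
    list(beta = fit$coefficients[[j]], se = sqrt(cov[j, j]),
         converged = isTRUE(fit$converged))
}

#' Stratified NB Wald differential expression
#'
#' Per gene, fits the NB log-linear model
#' `count ~ Age + RIN + PMI + Diagnosis` (offset = log size factor) by
#' iteratively reweighted least squares at fixed dispersion, and tests the
#' Diagnosis coefficient with a Wald z test. The log2 fold change is the
#' Diagnosis coefficient divided by `ln 2`, with positive values meaning
#' higher expression in AD. P-values are floored at `1e-300` and adjusted
#' by Benjamini-Hochberg. Genes failing to converge are flagged and carry
#' missing p-values rather than silently assigned results.
#'
#' @param counts gene x sample count matrix.
#' @param metadata metadata `data.frame` with PMI already imputed.
#' @param sizeFactors optional size factors; median-of-ratios by default.
#' @param dispersions optional per-gene alpha; method-of-moments within
#'   diagnosis groups by default.
#' @param shrink passed to [estimateDispersion()].
#' @param maxit IRLS iteration cap.
#' @return a [DEResults-class] `DFrame`.
#' @export
nbWaldTest <- function(counts, metadata, sizeFactors = NULL,
                       dispersions = NULL, shrink = FALSE, maxit = 50L) {
    .assertCountMatrix(counts)
    metadata <- as.data.frame(metadata)
    if (ncol(counts) != nrow(metadata))
        stop("count columns and metadata rows must match")
    X <- .vpDesign(metadata)           # errors if PMI unimputed / deficient
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
    if (is.null(dispersions))
        dispersions <- estimateDispersion(counts, sizeFactors,
                                          metadata$diagnosis,
                                          shrink = shrink)$alpha
    if (length(dispersions) != nrow(counts))
        stop("need one dispersion per gene")
    offset <- log(sizeFactors)
    norm <- sweep(counts, 2, sizeFactors, "/")

    nG <- nrow(counts)
    beta <- se <- rep(NA_real_, nG)
    flag <- rep("", nG)
    for (i in seq_len(nG)) {
        y <- counts[i, ]
        if (all(y == 0)) { flag[i] <- "all_zero"; next }
        res <- tryCatch(.nbFitOne(y, X, offset, dispersions[i], maxit),
                        error = function(e) NULL)
        if (is.null(res)) { flag[i] <- "fit_failed"; next }
        if (!res$converged) { flag[i] <- "no_converge"; next }
        beta[i] <- res$beta
        se[i] <- res$se
    }
    stat <- beta / se
    pvalue <- pmax(2 * stats::pnorm(-abs(stat)), 1e-300)
    pvalue[flag != ""] <- NA_real_
    out <- DataFrame(
        baseMean = unname(rowMeans(norm)),
        log2FoldChange = beta / log(2),
        stat = stat,
        pvalue = pvalue,
        padj = adjustBH(pvalue),
        dispersion = dispersions,
        flag = flag,
        row.names = rownames(counts))
    if (any(flag != ""))
        message(sum(flag != ""), " gene(s) flagged (",
                paste(unique(flag[flag != ""]), collapse = ", "),
                ") and excluded from testing")
    new("DEResults", out)
}

#' Benjamini-Hochberg adjustment with missing-value handling
#'
#' Standard step-up BH on the non-missing p-values; missing entries are
#' excluded from the adjustment and reinserted as missing, preserving
#' input order.
#'
#' @param pvalues numeric vector in `[0, 1]`, `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
adjustBH <- function(pvalues) {
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(pvalues))
    ok <- !is.na(pvalues)
    out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
    out
}
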