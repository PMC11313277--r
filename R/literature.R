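#' Build a bibliographic query from a pathway label
#'
#' Normalizes underscores and hyphens to spaces, collapses whitespace and
#' lower-cases the label; multi-word labels are wrapped as an exact phrase.
#' With a disease term, returns the co-mention form
#' `<pathway query> AND <disease query>`.
#'
#' @param label pathway label, e.g. `"INTERLEUKIN-10 SIGNALING"`.
#' @param disease optional disease term for the co-mention query.
#' @return a single query string.
#' @examples
#' buildQuery("INTERLEUKIN-10 SIGNALING")
#' buildQuery("SELECTIVE_AUTOPHAGY", "Alzheimer's disease")
#' @export
buildQuery <- function(label, disease = NULL) {
    norm <- function(x) {
        x <- tolower(gsub("[_-]+", " ", x))
        x <- trimws(gsub("[[:space:]]+", " ", x))
        if (!nzchar(x)) stop("label is empty after normalization")
        if (grepl(" ", x, fixed = TRUE)) paste0('"', x, '"') else x
    }
    stopifnot(length(label) == 1L)
    q <- norm(label)
    if (!is.null(disease)) q <- paste(q, "AND", norm(disease))
    q
}

#' Disease-relatedness proportion
#'
#' The fraction of documents mentioning a pathway that also mention the
#' disease: the proportion `coCount / totalCount`, with a value of 0 by convention (and a
#' `zeroDenominator` attribute) when a pathway is never mentioned at all.
#'
#' @param coCount co-mention count(s).
#' @param totalCount total mention count(s); `coCount <= totalCount`.
#' @return numeric vector of proportions with a logical attribute
#'   `zeroDenominator`.
#' @export
relatednessProportion <- function(coCount, totalCount) {
    if (any(coCount < 0) || any(totalCount < 0))
        stop("counts must be non-negative")
    if (any(coCount > totalCount))
        stop("co-mention count exceeds total count")
    zero <- totalCount == 0
    r <- ifelse(zero, 0, coCount / totalCount)
    attr(r, "zeroDenominator") <- zero
    r
}

#' Fixture count provider
#'
#' Wraps a [LiteratureCounts-class] cache as a count provider: a function
#' `f(label, withDisease = FALSE)` returning the label's total mention
#' count, or its disease co-mention count when `withDisease` is `TRUE`.
#' Repeated identical queries always return identical counts; unknown
#' labels are an error, never fabricated.
#'
#' @param litCounts a [LiteratureCounts-class].
#' @return a provider function.
#' @export
fixtureProvider <- function(litCounts) {
    stopifnot(is(litCounts, "LiteratureCounts"))
    validObject(litCounts)
    df <- litCounts@counts
    function(label, withDisease = FALSE) {
        i <- match(label, df$label)
        if (is.na(i))
            stop("label '", label, "' is not in the fixture corpus")
        if (withDisease) df$coMentions[i] else df$total[i]
    }
}

#' Live NCBI E-utilities count provider
#'
#' Returns a provider that issues `esearch` count queries against PubMed
#' through the NCBI E-utilities JSON interface. Requires network access
#' and is subject to NCBI rate limits; supply an API key to raise them.
#' All package tests use [fixtureProvider()] instead; live counts drift
#' over time and are never treated as test oracles.
#'
#' @param disease disease term used for co-mention queries.
#' @param apiKey optional NCBI API key.
#' @param delay seconds to sleep between requests.
#' @return a provider function `f(label, withDisease = FALSE)`.
#' @export
entrezProvider <- function(disease = "Alzheimer's disease", apiKey = NULL,
                           delay = 0.4) {
    base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi"
    function(label, withDisease = FALSE) {
        term <- buildQuery(label, if (withDisease) disease else NULL)
        url <- paste0(base, "?db=pubmed&rettype=count&retmode=json&term=",
                      utils::URLencode(term, reserved = TRUE),
                      if (!is.null(apiKey)) paste0("&api_key=", apiKey))
        Sys.sleep(delay)
        ans <- jsonlite::fromJSON(url)
        as.integer(ans$esearchresult$count)
    }
}

#' Sample a null distribution of relatedness proportions
#'
#' Draws `nNull` labels from the pathway universe without replacement
#' (seeded) and scores each with [relatednessProportion()] through the
#' provider. Zero-denominator labels contribute a proportion of 0 and are tallied in
#' a message.
#'
#' @param universe character vector of candidate labels (or a
#'   [GeneSetCollection-class], whose set names are used).
#' @param nNull null size, default 1000.
#' @param provider a count provider function.
#' @param seed integer seed.
#' @return numeric vector of `nNull` null proportions, named by label.
#' @export
sampleNullProportions <- function(universe, nNull = 1000L, provider,
                                  seed = 1L) {
    if (is(universe, "GeneSetCollection")) universe <- names(universe)
    stopifnot(is.character(universe), is.function(provider))
    universe <- unique(universe)
    if (length(universe) < nNull)
        stop("universe (", length(universe),
             ") is smaller than the requested null size (", nNull, ")")
    labels <- withSeed(deriveSeed(seed, "literature-null"),
                       sample(universe, nNull))
    total <- vapply(labels, provider, numeric(1), withDisease = FALSE)
    co <- vapply(labels, provider, numeric(1), withDisease = TRUE)
    r <- relatednessProportion(co, total)
    nZero <- sum(attr(r, "zeroDenominator"))
    if (nZero > 0)
        message(nZero, " null label(s) had zero total mentions (r set to 0)")
    stats::setNames(as.numeric(r), labels)
}

#' Impact Z-score of one relatedness proportion
#'
#' `Z = (r - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation. Higher positive values indicate a stronger association with
#' the disease literature than randomly chosen pathways.
#'
#' @param r observed relatedness proportion.
#' @param nullValues numeric vector of null proportions (>= 2 values with
#'   nonzero spread).
#' @return list with `z`, `nullMean`, `nullSd`, `nNull`.
#' @examples
#' impactZ(0.05, c(0.01, 0.02, 0.03))$z
#' @export
impactZ <- function(r, nullValues) {
    if (length(nullValues) < 2L)
        stop("need at least 2 null values")
    m <- mean(nullValues)
    s <- stats::sd(nullValues)
    if (s == 0)
        stop("null proportions have zero spread; ",
             "use a larger or more varied pathway universe")
    list(z = (r - m) / s, nullMean = m, nullSd = s,
         nNull = length(nullValues))
}

# Query a provider with retries; returns c(total, co) or NULL on failure.
.queryCounts <- function(provider, label, retries = 3L) {
    for (attempt in seq_len(retries)) {
        ans <- tryCatch(
            c(total = provider(label, withDisease = FALSE),
              co = provider(label, withDisease = TRUE)),
            error = function(e) e)
        if (!inherits(ans, "error")) return(ans)
        if (attempt < retries) Sys.sleep(2^(attempt - 1))
    }
    warning("provider failed for label '", label, "': ",
            conditionMessage(ans), call. = FALSE)
    NULL
}

#' Score pathways against the disease literature
#'
#' Computes one shared null of relatedness proportions from the pathway
#' universe, then scores every requested label: relatedness proportion,
#' impact Z against the shared null, and the counts used. If a cache path
#' is given, counts are served from the JSON cache when present and newly
#' queried counts are appended to it, so repeated runs issue no duplicate
#' provider calls. Labels whose provider queries fail after retries are
#' marked unscored (missing counts and Z), never fabricated.
#'
#' @param labels character vector of pathway labels to score (may be
#'   empty).
#' @param universe candidate labels for the null (character or
#'   [GeneSetCollection-class]).
#' @param provider a count provider function.
#' @param nNull null size, default 1000.
#' @param seed integer seed for the null sample.
#' @param cachePath optional JSON count cache path.
#' @return an [ImpactScores-class]; null parameters in `metadata()`.
#' @export
scorePathways <- function(labels, universe, provider, nNull = 1000L,
                          seed = 1L, cachePath = NULL) {
    stopifnot(is.character(labels))
    if (anyDuplicated(labels)) stop("labels must be unique")
    if (length(labels) == 0L) {
        out <- DataFrame(label = character(), total = integer(),
                         coMentions = integer(), r = numeric(),
                         nullMean = numeric(), nullSd = numeric(),
                         z = numeric(), zeroDenominator = logical())
        return(new("ImpactScores", out))
    }
    cacheEnv <- new.env(parent = emptyenv())
    if (!is.null(cachePath) && file.exists(cachePath)) {
        old <- literatureCounts(readLiteratureCounts(cachePath))
        for (i in seq_len(nrow(old)))
            assign(old$label[i], c(total = old$total[i],
                                   co = old$coMentions[i]),
                   envir = cacheEnv)
    }
    # serve from the cache; on a miss query both counts once and store them
    getCounts <- function(label, retries = 3L) {
        if (exists(label, envir = cacheEnv, inherits = FALSE))
            return(get(label, envir = cacheEnv))
        ans <- .queryCounts(provider, label, retries)
        if (!is.null(ans))
            assign(label, ans, envir = cacheEnv)
        ans
    }
    cachedProvider <- function(label, withDisease = FALSE) {
        ans <- getCounts(label)
        if (is.null(ans))
            stop("provider failed for null-universe label '", label, "'")
        unname(ans[[if (withDisease) "co" else "total"]])
    }

    null <- sampleNullProportions(universe, nNull, cachedProvider, seed)

    total <- co <- rep(NA_real_, length(labels))
    for (i in seq_along(labels)) {
        ans <- getCounts(labels[i])
        if (!is.null(ans)) {
            total[i] <- ans[["total"]]
            co[i] <- ans[["co"]]
        }
    }
    scored <- !is.na(total)
    r <- rep(NA_real_, length(labels))
    zero <- rep(NA, length(labels))
    if (any(scored)) {
        rp <- relatednessProportion(co[scored], total[scored])
        r[scored] <- as.numeric(rp)
        zero[scored] <- attr(rp, "zeroDenominator")
    }
    m <- mean(null)
    s <- stats::sd(null)
    if (s == 0)
        stop("null proportions have zero spread; ",
             "use a larger or more varied pathway universe")
    if (!is.null(cachePath)) {
        lab <- sort(ls(cacheEnv))
        stored <- t(vapply(lab, get, numeric(2), envir = cacheEnv))
        writeLiteratureCounts(new("LiteratureCounts", counts = data.frame(
            label = lab, total = as.integer(stored[, "total"]),
            coMentions = as.integer(stored[, "co"]),
            stringsAsFactors = FALSE)), cachePath)
    }
    out <- DataFrame(
        label = labels,
        total = as.integer(total),
        coMentions = as.integer(co),
        r = r,
        nullMean = m,
        nullSd = s,
        z = (r - m) / s,
        zeroDenominator = zero)
    rownames(out) <- labels
    res <- new("ImpactScores", out)
    metadata(res) <- list(nNull = nNull, seed = seed,
                          nullValues = unname(null))
    res
}
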