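# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results step by step, never
# calling the vectorized implementation paths they check.

# Step-up Benjamini-Hochberg computed literally from the definition.
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

# Position-by-position running-sum enrichment score; tie between |max|
# and |min| resolves to the positive extremum, as documented.
esOracle <- function(ranked, geneSet, exponent = 1) {
    N <- length(ranked)
    hit <- names(ranked) %in% geneSet
    w <- abs(ranked)^exponent
    nr <- sum(w[hit])
    if (nr == 0) { w[] <- 1; nr <- sum(w[hit]) }
    run <- 0
    best <- 0
    eps <- 1e-12   # positive extremum wins ties up to rounding
    for (i in seq_len(N)) {
        run <- if (hit[i]) run + w[i] / nr else run - 1 / (N - sum(hit))
        if (abs(run) - abs(best) > eps ||
            (abs(abs(run) - abs(best)) <= eps && run > best))
            best <- run
    }
    unname(best)
}

# Minimal valid metadata for n samples, seeded.
makeMetadata <- function(n, nAD = floor(n / 2), sex = "female", seed = 1) {
    withr::with_seed(seed, data.frame(
        sample_id = sprintf("s%03d", seq_len(n)),
        sex = sex,
        diagnosis = c(rep("CTL", n - nAD), rep("AD", nAD)),
        Age = runif(n, 60, 95),
        RIN = runif(n, 6, 10),
        PMI = runif(n, 2, 30),
        stringsAsFactors = FALSE))
}

# Tiny valid count matrix, seeded.
makeCounts <- function(nGenes, n, mu = 50, seed = 1) {
    withr::with_seed(seed, {
        m <- matrix(rnbinom(nGenes * n, mu = mu, size = 5), nrow = nGenes,
                    dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                    sprintf("s%03d", seq_len(n))))
        storage.mode(m) <- "integer"
        m
    })
}

# Hand-built EnrichmentResults table for comparison tests.
makeEnrichment <- function(pathways, direction, qval,
                           collectionNames = sort(pathways)) {
    out <- S4Vectors::DataFrame(
        pathway = pathways,
        size = rep(20L, length(pathways)),
        ES = ifelse(direction == "up", 0.5, -0.5),
        NES = ifelse(direction == "up", 1.5, -1.5),
        pval = qval, qval = qval, direction = direction,
        leadingEdge = S4Vectors::SimpleList(
            rep(list(character()), length(pathways))))
    res <- new("EnrichmentResults", out)
    S4Vectors::metadata(res) <- list(collectionNames = collectionNames)
    res
}
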