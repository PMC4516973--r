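# Independent brute-force oracles: explicit loops, no shared code with the
# package internals.

bruteSD <- function(x) {
    m <- sum(x) / length(x)
    sqrt(sum((x - m)^2) / (length(x) - 1))
}

bruteCor <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    num <- sum((x - mx) * (y - my))
    den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
    if (den == 0) 0 else num / den
}

bruteCompositeIndex <- function(genes, samples, universe = rownames(samples),
                                eps = 1e-3) {
    outside <- setdiff(universe, genes)
    sdIn <- mean(vapply(genes, function(g) bruteSD(samples[g, ]), 1))
    pin <- c()
    for (i in seq_along(genes))
        for (j in seq_along(genes))
            if (i < j)
                pin <- c(pin, abs(bruteCor(samples[genes[i], ],
                                           samples[genes[j], ])))
    pout <- c()
    for (g in genes)
        for (h in outside)
            pout <- c(pout, abs(bruteCor(samples[g, ], samples[h, ])))
    list(sdIn = sdIn, pccIn = mean(pin), pccOut = mean(pout),
         ci = sdIn * mean(pin) / max(mean(pout), eps))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small, fast simulation settings for unit tests
smallParams <- function(seed, nGenes = 200L, nDNB = 15L, ...) {
    SimulationParams(nGenes = nGenes, nDNB = nDNB, replicates = 5L,
                     seed = seed, ...)
}
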