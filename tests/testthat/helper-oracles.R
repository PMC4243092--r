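# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation (double loops, full enumeration, pairwise counts) kept
# separate from the package's own code paths.

# Energy by direct double loop over vertices and edges.
oracleEnergy <- function(collection, x, params, alphaI) {
    if (length(alphaI) == 1L) alphaI <- rep(alphaI, length(x))
    u <- 0
    for (i in seq_along(x)) u <- u - alphaI[i] * x[i]
    for (k in seq_along(networks(collection))) {
        e <- edges(networks(collection)[[k]])
        for (r in seq_len(nrow(e))) {
            xi <- x[e[r, 1L]]
            xj <- x[e[r, 2L]]
            w <- if (xi == 1 && xj == 1) params@gamma[k]
                 else if (xi == 0 && xj == 0) 1
                 else params@beta[k]
            u <- u - w
        }
    }
    u
}

# Exact conditional P(X_i = 1 | x_-i) by brute-force enumeration of the
# two completions of x at position i.
oracleConditional <- function(collection, x, i, params, alphaI) {
    x1 <- x; x1[i] <- 1L
    x0 <- x; x0[i] <- 0L
    u1 <- oracleEnergy(collection, x1, params, alphaI)
    u0 <- oracleEnergy(collection, x0, params, alphaI)
    1 / (1 + exp(u1 - u0))
}

# Exact marginals by full enumeration (independent of the package's
# enumeration code).
oracleMarginals <- function(collection, params, alphaI, clampedIdx = integer(0)) {
    n <- length(genes(collection))
    configs <- as.matrix(expand.grid(rep(list(0:1), n)))
    if (length(clampedIdx)) {
        configs <- configs[rowSums(configs[, clampedIdx, drop = FALSE]) ==
                           length(clampedIdx), , drop = FALSE]
    }
    u <- apply(configs, 1L, function(x) oracleEnergy(collection, x, params, alphaI))
    w <- exp(-(u - min(u)))
    p <- w / sum(w)
    as.vector(crossprod(configs, p))
}

# AUC as the normalized Mann-Whitney U count (ties credited 1/2).
oracleAUC <- function(label, score) {
    pos <- score[label == 1]
    neg <- score[label == 0]
    total <- 0
    for (p in pos) for (q in neg) {
        total <- total + (p > q) + 0.5 * (p == q)
    }
    total / (length(pos) * length(neg))
}

# Random small test instance: K networks over n genes, uniform theta.
randomInstance <- function(n, K = 2L, pEdge = 0.3, thetaRange = c(-3, 3)) {
    u <- GeneUniverse(sprintf("t%02d", seq_len(n)))
    nets <- lapply(seq_len(K), function(k) {
        pairs <- t(combn(n, 2L))
        keep <- runif(nrow(pairs)) < pEdge
        BioNetwork(paste0("n", k), pairs[keep, , drop = FALSE], u)
    })
    list(collection = NetworkCollection(nets),
         params = MRFParams(runif(1, thetaRange[1], thetaRange[2]),
                            runif(K, thetaRange[1], thetaRange[2]),
                            runif(K, thetaRange[1], thetaRange[2])),
         alphaI = runif(n, thetaRange[1], thetaRange[2]))
}

# Short sampler schedule for fast end-to-end tests.
fastConfig <- function(seed = 1L, ...) {
    args <- list(burnIn = 5L, total = 30L, thin = 5L, predictionSteps = 10L,
                 seed = seed)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(SamplerConfig, args)
}

# Small benchmark with a planted dense module (deterministic number of
# positives, strong guilt-by-association signal); used for fast
# end-to-end tests.
smallScenario <- function(seed = 42L, nGenes = 120L) {
    makeBenchmark(nGenes = nGenes, K = 2L, edgeProb = c(0.02, 0.03),
                  knownFraction = 0.5, nComplexes = 8L, complexSize = 6L,
                  seed = seed, truth = "planted", plantedSize = 12L,
                  plantedDensity = 0.3)
}
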