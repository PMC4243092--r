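#' Generate random networks over a shared universe
#'
#' K independent Erdos-Renyi graphs G(n, p) over one universe of synthetic
#' gene symbols.
#'
#' @param nGenes number of genes (>= 2).
#' @param K number of networks.
#' @param edgeProb per-network edge probabilities (recycled to length K).
#' @param seed RNG seed, or `NULL` to continue the current RNG stream.
#' @return A [NetworkCollection-class].
#' @export
generateNetworks <- function(nGenes, K = 1L, edgeProb = 0.01, seed = NULL) {
    stopifnot(nGenes >= 2L, all(edgeProb > 0), all(edgeProb < 1))
    if (!is.null(seed)) set.seed(seed)
    edgeProb <- rep_len(edgeProb, K)
    universe <- GeneUniverse(sprintf("g%04d", seq_len(nGenes)))
    nets <- lapply(seq_len(K), function(k) {
        g <- igraph::sample_gnp(nGenes, edgeProb[k])
        e <- igraph::as_edgelist(g, names = FALSE)
        storage.mode(e) <- "integer"
        BioNetwork(sprintf("net%d", k), e, universe)
    })
    NetworkCollection(nets)
}

# Enumerate all configurations compatible with the clamping and their
# exact Gibbs probabilities. Returns configs (rows), prob, logZ (of the
# clamped-conditional distribution).
.enumerateGibbs <- function(collection, params, alphaI, clamped = NULL) {
    n <- length(collection@universe@genes)
    if (n > 15L) {
        stop("exact enumeration is limited to 15 genes (2^N configurations); ",
             "use sampleConfigurationGibbs for larger instances")
    }
    if (length(alphaI) == 1L) alphaI <- rep(alphaI, n)
    configs <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
    dimnames(configs) <- NULL
    if (!is.null(clamped) && any(clamped)) {
        keep <- rowSums(configs[, clamped, drop = FALSE] == 1L) == sum(clamped)
        configs <- configs[keep, , drop = FALSE]
    }
    U <- -as.vector(configs %*% alphaI)
    for (k in seq_along(collection@networks)) {
        e <- collection@networks[[k]]@edges
        if (nrow(e) == 0L) next
        xi <- configs[, e[, 1L], drop = FALSE]
        xj <- configs[, e[, 2L], drop = FALSE]
        n11 <- rowSums(xi * xj)
        n10 <- rowSums(xi + xj == 1L)
        n00 <- nrow(e) - n11 - n10
        U <- U - (params@beta[k] * n10 + params@gamma[k] * n11 + n00)
    }
    mx <- max(-U)
    w <- exp(-U - mx)
    list(configs = configs, prob = w / sum(w), logZ = mx + log(sum(w)))
}

#' Exact marginals of the Gibbs distribution on a small instance
#'
#' Enumerates all 2^N configurations (N <= 15) and returns the exact
#' per-gene marginal probabilities P(X_i = 1), optionally conditional on
#' clamped genes being 1. Serves as the independent oracle for the sampler.
#'
#' @param collection a [NetworkCollection-class] over at most 15 genes.
#' @param params an [MRFParams-class].
#' @param alphaI per-gene field vector (or a single value, recycled).
#' @param clamped optional logical mask of genes fixed at 1.
#' @return numeric vector of marginals.
#' @export
exactMarginals <- function(collection, params, alphaI, clamped = NULL) {
    en <- .enumerateGibbs(collection, params, alphaI, clamped)
    as.vector(crossprod(en$configs, en$prob))
}

#' Exact log partition function of a small instance
#'
#' @inheritParams exactMarginals
#' @return log Z(theta).
#' @export
logPartition <- function(collection, params, alphaI) {
    .enumerateGibbs(collection, params, alphaI)$logZ
}

#' Draw one configuration from the exactly normalized Gibbs distribution
#'
#' @inheritParams exactMarginals
#' @return A [LabelConfig-class].
#' @export
sampleConfigurationExact <- function(collection, params, alphaI,
                                     clamped = NULL) {
    en <- .enumerateGibbs(collection, params, alphaI, clamped)
    i <- sample.int(nrow(en$configs), 1L, prob = en$prob)
    n <- length(collection@universe@genes)
    if (is.null(clamped)) clamped <- logical(n)
    LabelConfig(en$configs[i, ], clamped)
}

#' Draw a configuration by long-run Gibbs sampling
#'
#' Used to create large benchmark truths where enumeration is impossible;
#' runs `sweeps` sequential sweeps at fixed parameters and returns the
#' final configuration.
#'
#' @inheritParams exactMarginals
#' @param sweeps number of sweeps (>= 1).
#' @param seed RNG seed, or `NULL` to continue the current stream.
#' @param init optional [LabelConfig-class] starting state; defaults to
#'   independent Bernoulli(sigmoid(alpha_i)) draws with clamped genes at 1.
#' @return A [LabelConfig-class].
#' @export
sampleConfigurationGibbs <- function(collection, params, alphaI,
                                     sweeps = 500L, seed = NULL,
                                     clamped = NULL, init = NULL) {
    stopifnot(sweeps >= 1L)
    if (!is.null(seed)) set.seed(seed)
    n <- length(collection@universe@genes)
    if (length(alphaI) == 1L) alphaI <- rep(alphaI, n)
    if (is.null(clamped)) clamped <- logical(n)
    if (is.null(init)) {
        x <- rbinom(n, 1L, plogis(alphaI))
        init <- LabelConfig(x, clamped)
    }
    adj <- .prepAdjacency(collection)
    free <- which(!clamped)
    run <- cpp_gibbs_run(init@labels, as.integer(free - 1L), alphaI,
                         params@beta, params@gamma, .adjOffsets(adj),
                         .adjNbrs(adj), as.integer(sweeps), 0L, 1L, FALSE)
    LabelConfig(run$labels, clamped)
}

#' Generate a fully synthetic benchmark scenario
#'
#' Networks are Erdos-Renyi draws; the true labelling is sampled from the
#' random field itself (`truthSweeps` fixed-parameter sweeps), so
#' parameter recovery is well-posed. A fraction of the true positives is
#' revealed as known; protein complexes are sampled with true positives
#' over-weighted (`enrichment`:1) so complex-derived priors are
#' informative; true-0 genes stand in for known disease genes of other
#' classes as negative controls. A `"planted"` truth variant plants a
#' dense module instead of drawing from the model: `plantedSize` genes are
#' labelled 1 and extra edges are added among them (density
#' `plantedDensity`) in the first network, a deliberately misspecified
#' truth for robustness checks and for benchmarks needing strong
#' guilt-by-association signal.
#'
#' @param nGenes,K,edgeProb,seed as in [generateNetworks()].
#' @param thetaTrue generating [MRFParams-class].
#' @param knownFraction fraction of true positives revealed as known.
#' @param nComplexes,complexSize complex sampling dimensions.
#' @param enrichment sampling weight of true positives when building
#'   complexes (fixture constant, default 3; exposed so scenarios with
#'   strongly class-coherent complexes can be generated).
#' @param negativeRatio negative controls (true-0 stand-ins for known
#'   disease genes of other classes) per known class gene (default 10,
#'   emulating the many-class setting where other classes dominate).
#' @param truthSweeps Gibbs sweeps used to draw the truth (default 500).
#' @param truth `"gibbs"` (draw from the model) or `"planted"` (label a
#'   planted dense module of size `plantedSize`).
#' @param plantedSize module size for the planted variant.
#' @param plantedDensity extra within-module edge probability added to the
#'   first network in the planted variant.
#' @return A [BenchmarkScenario-class]. If the truth has no hidden
#'   positives or no zero-labelled genes the scenario is degenerate for
#'   evaluation; a warning flags this.
#' @export
makeBenchmark <- function(nGenes = 2000L, K = 2L, edgeProb = c(0.004, 0.006),
                          thetaTrue = MRFParams(-2, rep(1.5, K), rep(3, K)),
                          knownFraction = 0.5, nComplexes = 20L,
                          complexSize = 8L, seed = 1L, enrichment = 3,
                          negativeRatio = 10, truthSweeps = 500L,
                          truth = c("gibbs", "planted"), plantedSize = 50L,
                          plantedDensity = 0.12) {
    truth <- match.arg(truth)
    set.seed(seed)
    collection <- generateNetworks(nGenes, K, edgeProb, seed = NULL)
    drawTruth <- function() {
        if (truth == "planted") {
            x <- integer(nGenes)
            x[sample.int(nGenes, plantedSize)] <- 1L
            x
        } else {
            labels01(sampleConfigurationGibbs(
                collection, thetaTrue, thetaTrue@alpha, sweeps = truthSweeps))
        }
    }
    xTrue <- drawTruth()
    if (truth == "planted") {
        module <- which(xTrue == 1L)
        pairs <- t(utils::combn(module, 2L))
        extra <- pairs[runif(nrow(pairs)) < plantedDensity, , drop = FALSE]
        nets <- collection@networks
        nets[[1L]] <- BioNetwork(nets[[1L]]@name,
                                 rbind(nets[[1L]]@edges, extra),
                                 collection@universe)
        collection <- NetworkCollection(nets)
    }
    attempt <- 1L
    while (sum(xTrue) == 0L && attempt < 10L) {
        attempt <- attempt + 1L
        message("truth draw ", attempt - 1L,
                " had no positive gene; redrawing (attempt ", attempt, ")")
        xTrue <- drawTruth()
    }
    if (sum(xTrue) == 0L) stop("no positive gene in the truth after 10 attempts")

    ones <- which(xTrue == 1L)
    zeros <- which(xTrue == 0L)
    nKnown <- round(knownFraction * length(ones))
    known <- sort(sample(ones, nKnown))
    nNeg <- min(length(zeros), ceiling(negativeRatio * max(length(known), 1L)))
    negatives <- sort(sample(zeros, nNeg))
    if (length(setdiff(ones, known)) == 0L || length(zeros) == 0L) {
        warning("degenerate scenario: ",
                if (length(zeros) == 0L) "no zero-labelled genes"
                else "no hidden positives",
                "; ranking evaluation is not possible")
    }
    w <- rep(1, nGenes)
    w[xTrue == 1L] <- enrichment
    cmplx <- lapply(seq_len(nComplexes), function(i) {
        sort(sample.int(nGenes, complexSize, prob = w))
    })
    names(cmplx) <- sprintf("complex%02d", seq_len(nComplexes))
    new("BenchmarkScenario", collection = collection, truth = xTrue,
        knownGenes = as.integer(known), negativeControls = as.integer(negatives),
        complexes = new("ComplexSet", complexes = cmplx,
                        universe = collection@universe),
        thetaTrue = thetaTrue, knownFraction = knownFraction,
        seed = as.integer(seed))
}

#' Prior builder of a benchmark scenario
#'
#' Returns a function mapping a set of currently known class genes to the
#' complex-derived [PriorVector-class] of the scenario, for use with
#' [leaveOneOut()] and the run functions. All known disease genes (class
#' genes plus negative controls, the stand-ins for other classes) define
#' the complex denominator.
#'
#' @param scenario a [BenchmarkScenario-class].
#' @return function(classGenes) -> [PriorVector-class].
#' @export
scenarioPriorBuilder <- function(scenario) {
    function(classGenes) {
        buildPriors(scenario@collection@universe, scenario@complexes,
                    classGenes,
                    union(classGenes, scenario@negativeControls))
    }
}
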