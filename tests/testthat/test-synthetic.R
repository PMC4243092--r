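test_that("network generation is seeded and binomially sized", {
    a <- generateNetworks(100, K = 2L, edgeProb = 0.05, seed = 9L)
    b <- generateNetworks(100, K = 2L, edgeProb = 0.05, seed = 9L)
    expect_identical(lapply(networks(a), edges), lapply(networks(b), edges))
    # near-zero edge probability gives (almost surely) no edges
    tiny <- generateNetworks(100, K = 1L, edgeProb = 1e-9, seed = 2L)
    expect_identical(nEdges(networks(tiny)[[1L]]), 0L)
    # edge counts concentrate around C(n,2) p
    m <- vapply(1:20, function(s) {
        nEdges(networks(generateNetworks(100, 1L, 0.05, seed = s))[[1L]])
    }, integer(1))
    mu <- choose(100, 2) * 0.05
    sigma <- sqrt(choose(100, 2) * 0.05 * 0.95)
    expect_true(all(abs(m - mu) < 4 * sigma))
    # generator outputs satisfy the data-model invariants by construction
    expect_true(validObject(a))
})

test_that("exact enumeration defines a normalized, correct distribution", {
    # zero field and unit weights: uniform over 2^N, marginals 1/2
    u <- GeneUniverse(paste0("g", 1:4))
    col <- NetworkCollection(list(
        BioNetwork("n", rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)), u)))
    flat <- MRFParams(0, 1, 1)
    expect_equal(exactMarginals(col, flat, 0), rep(0.5, 4))
    en <- MRFGeneRank:::.enumerateGibbs(col, flat, 0)
    expect_equal(sum(en$prob), 1, tolerance = 1e-12)
    expect_equal(en$logZ, log(2^4) + 3)  # 3 edges contribute e^1 each

    # two-node closed form: single edge, alpha = 0, large gamma
    u2 <- GeneUniverse(c("a", "b"))
    pair <- NetworkCollection(list(BioNetwork("e", cbind(1L, 2L), u2)))
    strong <- MRFParams(0, 1, 10)
    Z <- exp(10) + 2 * exp(1) + exp(1)   # (1,1), (1,0), (0,1), (0,0)
    m <- exactMarginals(pair, strong, 0)
    expect_equal(m, rep((exp(10) + exp(1)) / Z, 2), tolerance = 1e-12)
    expect_gt(exp(10) / Z, 100 * (2 * exp(1)) / Z)

    # against the independent enumeration oracle on a random instance
    set.seed(19)
    inst <- randomInstance(7)
    expect_equal(exactMarginals(inst$collection, inst$params, inst$alphaI),
                 oracleMarginals(inst$collection, inst$params, inst$alphaI),
                 tolerance = 1e-12)
    # clamped-conditional marginals
    cl <- c(TRUE, rep(FALSE, 6))
    expect_equal(exactMarginals(inst$collection, inst$params, inst$alphaI, cl),
                 oracleMarginals(inst$collection, inst$params, inst$alphaI, 1L),
                 tolerance = 1e-12)
    expect_error(exactMarginals(generateNetworks(16, 1, 0.1, seed = 1),
                                flat, 0), "15 genes")
})

test_that("exact sampling matches enumerated frequencies", {
    set.seed(23)
    u <- GeneUniverse(paste0("g", 1:4))
    col <- NetworkCollection(list(
        BioNetwork("n", rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L)), u)))
    params <- MRFParams(-0.5, 1.4, 2)
    en <- MRFGeneRank:::.enumerateGibbs(col, params, -0.5)
    draws <- replicate(20000, {
        sum(labels01(sampleConfigurationExact(col, params, -0.5)) * 2L^(0:3))
    })
    ids <- as.vector(en$configs %*% 2L^(0:3))
    obs <- tabulate(match(draws, ids), nbins = length(ids))
    chi <- suppressWarnings(chisq.test(obs, p = en$prob))
    expect_gt(chi$p.value, 0.001)
})

test_that("Gibbs-drawn configurations agree with the exact sampler", {
    set.seed(29)
    inst <- randomInstance(8, K = 1L, pEdge = 0.3, thetaRange = c(-1, 1))
    exact <- exactMarginals(inst$collection, inst$params, inst$alphaI)
    draws <- replicate(400, {
        labels01(sampleConfigurationGibbs(inst$collection, inst$params,
                                          inst$alphaI, sweeps = 60L))
    })
    expect_lt(max(abs(rowMeans(draws) - exact)), 0.1)
    # clamped genes stay 1; seed determinism
    cl <- c(TRUE, rep(FALSE, 7))
    g1 <- sampleConfigurationGibbs(inst$collection, inst$params, inst$alphaI,
                                   sweeps = 30L, seed = 4L, clamped = cl)
    g2 <- sampleConfigurationGibbs(inst$collection, inst$params, inst$alphaI,
                                   sweeps = 30L, seed = 4L, clamped = cl)
    expect_identical(g1, g2)
    expect_identical(labels01(g1)[1L], 1L)
})

test_that("benchmark scenarios are reproducible and bookkept", {
    sc1 <- smallScenario(seed = 55L)
    sc2 <- smallScenario(seed = 55L)
    expect_identical(sc1, sc2)
    expect_true(all(sc1@truth[sc1@knownGenes] == 1L))
    expect_true(all(sc1@truth[sc1@negativeControls] == 0L))
    # known fraction accounting
    expect_identical(length(sc1@knownGenes), as.integer(round(0.5 * sum(sc1@truth))))
    # planted truth has exactly plantedSize positives
    expect_identical(sum(sc1@truth), 12L)
    # complexes respect the data model
    expect_true(validObject(sc1@complexes))
    # fully revealed scenario is flagged degenerate for evaluation
    expect_warning(
        makeBenchmark(nGenes = 60, K = 1L, edgeProb = 0.05,
                      knownFraction = 1, nComplexes = 4L, complexSize = 4L,
                      seed = 6L, truth = "planted", plantedSize = 6L),
        "degenerate")
})

test_that("scenario priors are informative for complex-mates of known genes", {
    sc <- smallScenario(seed = 91L)
    pri <- scenarioPriorBuilder(sc)(sc@knownGenes)
    expect_true(validObject(pri))
    # genes sharing a complex with known class genes (and with known
    # disease genes at all) get the A/B ratio, others the C/D fallback
    fallback <- length(sc@knownGenes) / nGenes(sc@collection)
    inAnyComplex <- unique(unlist(sc@complexes@complexes))
    outside <- setdiff(seq_len(nGenes(sc@collection)), inAnyComplex)
    expect_true(all(abs(priors(pri)[outside] - fallback) < 1e-9))
})
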