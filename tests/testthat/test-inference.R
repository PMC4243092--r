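test_that("pseudo-likelihood fit agrees with the ML oracle and recovers", {
    # clean logistic-generated design: recovery of (beta, gamma)
    set.seed(41)
    M0 <- rpois(2000, 3)
    M1 <- rpois(2000, 2)
    y <- rbinom(2000, 1, plogis(-2 + 0.5 * M0 + 1.5 * M1))
    X <- cbind(M0, M1)
    fit <- MRFGeneRank:::.irlsLogistic(X, y)
    oracle <- glm.fit(cbind(1, X), y, family = binomial())
    expect_lt(max(abs(fit$coef - oracle$coefficients)), 1e-6)
    beta <- fit$coef[2] + 1
    gamma <- fit$coef[3] + beta
    expect_lt(abs(beta - 1.5), 0.2)
    expect_lt(abs(gamma - 3.0), 0.2)

    # full path on a network labelling matches glm.fit on the same design
    set.seed(42)
    col <- generateNetworks(300, K = 2L, edgeProb = c(0.02, 0.03))
    x <- rbinom(300, 1, 0.3)
    params <- estimateParameters(col, x, alphaMode = "global")
    Xn <- MRFGeneRank:::.designMatrix(MRFGeneRank:::.prepAdjacency(col), x)
    expect_identical(dim(Xn), c(300L, 4L))  # one row per gene, 2K columns
    oracle2 <- glm.fit(cbind(1, Xn), x, family = binomial())$coefficients
    expect_lt(abs(params@alpha - oracle2[1]), 1e-6)
    expect_lt(max(abs(params@beta - (oracle2[c(2, 4)] + 1))), 1e-6)
    expect_lt(max(abs(params@gamma - params@beta - oracle2[c(3, 5)])), 1e-6)
})

test_that("degenerate designs are handled: constant labels error, dead columns stay finite", {
    col <- generateNetworks(50, K = 1L, edgeProb = 0.05, seed = 5L)
    expect_error(estimateParameters(col, rep(1L, 50), alphaMode = "global"),
                 "identical")
    # no 1-labelled gene has a neighbor: the M1 column is all zero
    deg <- degrees(networks(col)[[1L]])
    x <- integer(50)
    x[which(deg == 0L)[1L]] <- 1L
    if (sum(deg == 0L) == 0L) skip("no isolated gene in this draw")
    params <- estimateParameters(col, x, alphaMode = "global")
    expect_true(all(is.finite(thetaVector(params))))
})

test_that("a Gibbs sweep respects clamping, records conditionals and is seeded", {
    u <- GeneUniverse(paste0("g", 1:4))
    col <- NetworkCollection(list(
        BioNetwork("n", rbind(c(1L, 2L), c(3L, 4L)), u)))
    allClamped <- LabelConfig(rep(1L, 4), rep(TRUE, 4))
    sw <- gibbsSweep(allClamped, col, MRFParams(0, 1, 2), rep(0, 4))
    expect_identical(labels01(sw$state), rep(1L, 4))
    expect_length(sw$probs, 0L)

    # one free isolated gene with zero field: p = 0.5, labels a fair coin
    u2 <- GeneUniverse(c("a", "b"))
    col2 <- NetworkCollection(list(
        BioNetwork("n", matrix(integer(0), ncol = 2), u2)))
    st <- LabelConfig(c(0L, 1L), c(FALSE, TRUE))
    set.seed(1)
    sw2 <- gibbsSweep(st, col2, MRFParams(0, 1, 1), c(0, 0))
    expect_equal(sw2$probs, 0.5)
    adj <- MRFGeneRank:::.prepAdjacency(col2)
    set.seed(2)
    run <- MRFGeneRank:::cpp_gibbs_run(
        st@labels, 0L, c(0, 0), 1, 1, MRFGeneRank:::.adjOffsets(adj),
        MRFGeneRank:::.adjNbrs(adj), 10000L, 0L, 1L, FALSE)
    expect_lt(abs(run$lmean - 0.5), 0.02)

    # fixed seed reproduces the label sequence exactly
    set.seed(7)
    a <- gibbsSweep(st, col2, MRFParams(0, 1, 1), c(0, 0))
    set.seed(7)
    b <- gibbsSweep(st, col2, MRFParams(0, 1, 1), c(0, 0))
    expect_identical(a, b)
})

test_that("the sampling schedule records the documented snapshots", {
    sc <- smallScenario()
    pri <- scenarioPriorBuilder(sc)(sc@knownGenes)
    cfg <- SamplerConfig(burnIn = 100L, total = 1000L, thin = 10L,
                         predictionSteps = 20L, seed = 3L)
    # fixed-theta mode: same schedule bookkeeping, no re-estimation
    r1 <- runDeng(sc@collection, sc@knownGenes, sc@negativeControls, pri, cfg)
    expect_length(r1@recordedSweeps, 90L)
    expect_identical(r1@recordedSweeps[1L], 110L)
    expect_identical(nrow(thetaTrace(r1)), 1000L)

    # a single recorded sweep: posterior equals that sweep's conditionals,
    # reconstructed by replaying the seeded chain
    cfg1 <- fastConfig(seed = 11L, burnIn = 4L, total = 5L, thin = 1L)
    res <- runIMRF1(sc@collection, sc@knownGenes, pri, cfg1)
    expect_identical(res@recordedSweeps, 5L)
    set.seed(11L)
    n <- nGenes(sc@collection)
    state <- MRFGeneRank:::.initialLabels(n, sc@knownGenes, pri)
    free <- which(!clamped(state))
    x <- state@labels
    probs <- NULL
    for (t in 1:5) {
        params <- estimateParameters(sc@collection, x, pri, "prior")
        sw <- gibbsSweep(LabelConfig(x, clamped(state)), sc@collection, params,
                         fieldVector(params, pri, "prior"))
        x <- labels01(sw$state)
        probs <- sw$probs
    }
    expect_equal(res@posterior[free], probs)
})

test_that("IMRF2 freezes theta for the prediction period", {
    sc <- smallScenario()
    pri <- scenarioPriorBuilder(sc)(sc@knownGenes)
    cfg <- fastConfig(seed = 5L)
    r2 <- runIMRF2(sc@collection, sc@knownGenes, pri, cfg)
    tr <- thetaTrace(r2)
    expect_identical(nrow(tr), cfg@total + cfg@predictionSteps)
    predRows <- tr[(cfg@total + 1L):nrow(tr), , drop = FALSE]
    expect_true(all(apply(predRows, 2L, function(v) length(unique(v)) == 1L)))
    expect_equal(unname(predRows[1L, ]),
                 unname(thetaVector(thetaFinal(r2))))
    expect_identical(r2@recordedSweeps, cfg@total + seq_len(cfg@predictionSteps))

    # degenerate prediction period: output equals the IMRF1 posterior
    cfg0 <- fastConfig(seed = 5L, predictionSteps = 0L)
    r20 <- runIMRF2(sc@collection, sc@knownGenes, pri, cfg0)
    r10 <- runIMRF1(sc@collection, sc@knownGenes, pri, cfg0)
    expect_identical(r20@posterior, r10@posterior)
    expect_identical(r20@mode, "imrf2")
})

test_that("the Deng baseline fixes theta from known-labelled vertices only", {
    sc <- smallScenario()
    pri <- scenarioPriorBuilder(sc)(sc@knownGenes)
    cfg <- fastConfig(seed = 9L)
    rd <- runDeng(sc@collection, sc@knownGenes, sc@negativeControls, pri, cfg)
    tr <- thetaTrace(rd)
    expect_true(all(apply(tr, 2L, function(v) length(unique(v)) == 1L)))
    # too few known-labelled rows for 2K+1 coefficients
    expect_error(
        runDeng(sc@collection, sc@knownGenes[1L], integer(0), pri, cfg),
        "too few")
})

test_that("chain variation is the sum of squared probability changes", {
    expect_identical(chainVariation(c(0.3, 0.8), c(0.3, 0.8)), 0)
    expect_equal(chainVariation(c(0.2, 0.5), c(0.4, 0.5)), 0.04)
    set.seed(8)
    a <- runif(50)
    b <- runif(50)
    manual <- 0
    for (i in 1:50) manual <- manual + (a[i] - b[i])^2
    expect_equal(chainVariation(a, b), manual)
    expect_error(chainVariation(a, b[-1]), "length")
})

test_that("fixed-theta chains are stationary at the enumerated distribution", {
    set.seed(33)
    inst <- randomInstance(8, K = 2L, pEdge = 0.3, thetaRange = c(-1.5, 1.5))
    exact <- oracleMarginals(inst$collection, inst$params, inst$alphaI)
    adj <- MRFGeneRank:::.prepAdjacency(inst$collection)
    run <- MRFGeneRank:::cpp_gibbs_run(
        rbinom(8, 1, 0.5), 0:7, inst$alphaI, inst$params@beta,
        inst$params@gamma, MRFGeneRank:::.adjOffsets(adj),
        MRFGeneRank:::.adjNbrs(adj), 50000L, 500L, 1L, FALSE)
    expect_lt(max(abs(run$pmean - exact)), 0.02)
    # Rao-Blackwell consistency: conditional-mean and label-mean agree
    expect_lt(max(abs(run$pmean - run$lmean)), 0.02)
})

test_that("sampler results are byte-identical under identical seeds", {
    sc <- smallScenario()
    pri <- scenarioPriorBuilder(sc)(sc@knownGenes)
    cfg <- fastConfig(seed = 21L)
    expect_identical(runIMRF1(sc@collection, sc@knownGenes, pri, cfg),
                     runIMRF1(sc@collection, sc@knownGenes, pri, cfg))
    expect_identical(runIMRF2(sc@collection, sc@knownGenes, pri, cfg),
                     runIMRF2(sc@collection, sc@knownGenes, pri, cfg))
    # different seeds give different chains
    cfgB <- fastConfig(seed = 22L)
    expect_false(identical(runIMRF1(sc@collection, sc@knownGenes, pri, cfg)@posterior,
                           runIMRF1(sc@collection, sc@knownGenes, pri, cfgB)@posterior))
})
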