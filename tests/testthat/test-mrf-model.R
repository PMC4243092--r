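test_that("edge categories are counted and conserved", {
    u <- GeneUniverse(c("A", "B", "C", "D"))
    tri <- BioNetwork("tri", rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)), u)
    expect_identical(edgeCategoryCounts(tri, c(1, 1, 0, 0)),
                     c(n11 = 1L, n10 = 2L, n00 = 0L))
    expect_identical(edgeCategoryCounts(tri, c(0, 0, 0, 0)),
                     c(n11 = 0L, n10 = 0L, n00 = 3L))
    path <- BioNetwork("path", rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)), u)
    expect_identical(edgeCategoryCounts(path, c(1, 0, 1, 0)),
                     c(n11 = 0L, n10 = 3L, n00 = 0L))
    # conservation across random labellings
    set.seed(3)
    inst <- randomInstance(10)
    for (r in 1:25) {
        x <- rbinom(10, 1, runif(1))
        for (nw in networks(inst$collection)) {
            cc <- edgeCategoryCounts(nw, x)
            expect_identical(sum(cc), nEdges(nw))
        }
    }
})

test_that("neighbor counts split degrees by label per network", {
    u <- GeneUniverse(paste0("g", 1:5))
    star <- BioNetwork("s", rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)), u)
    col <- NetworkCollection(list(star, star))
    nc <- neighborCounts(1L, col, c(0, 1, 1, 0, 0))
    expect_identical(nc$m1, c(2L, 2L))
    expect_identical(nc$m0, c(1L, 1L))
    expect_identical(neighborCounts(5L, col, c(0, 1, 1, 0, 0)),
                     list(m0 = c(0L, 0L), m1 = c(0L, 0L)))
    deg <- degrees(col)
    for (g in 1:5) {
        nc <- neighborCounts(g, col, c(1, 0, 1, 0, 1))
        expect_equal(nc$m0 + nc$m1, unname(deg[g, ]))
    }
})

test_that("energy matches a direct double-loop oracle", {
    u <- GeneUniverse(c("A", "B"))
    lone <- NetworkCollection(list(BioNetwork("e", cbind(1L, 2L), u)))
    # single 1-1 edge, zero field, gamma = 2 -> U = -2
    expect_equal(energy(lone, c(1, 1), MRFParams(0, 1, 2), 0), -2)
    # edgeless graph with zero field: U = 0 for every labelling
    empty <- NetworkCollection(list(
        BioNetwork("0", matrix(integer(0), ncol = 2), u)))
    expect_equal(energy(empty, c(1, 0), MRFParams(5, 2, 3), 0), 0)
    set.seed(21)
    for (r in 1:20) {
        inst <- randomInstance(8)
        x <- rbinom(8, 1, 0.5)
        expect_equal(energy(inst$collection, x, inst$params, inst$alphaI),
                     oracleEnergy(inst$collection, x, inst$params, inst$alphaI))
    }
})

test_that("local field equals the energy difference and its closed form", {
    set.seed(5)
    u <- GeneUniverse(c("A"))
    iso <- NetworkCollection(list(BioNetwork("0", matrix(integer(0), ncol = 2), u)))
    expect_equal(localField(1L, iso, 0L, MRFParams(0.7, 1, 1), 0.7), 0.7)
    # beta = 1 and gamma = beta: neighbor terms vanish
    inst <- randomInstance(6, K = 1L)
    p1 <- MRFParams(-1.2, 1, 1)
    x <- rbinom(6, 1, 0.5)
    for (g in 1:6) {
        expect_equal(localField(g, inst$collection, x, p1, -1.2), -1.2)
    }
    # hand-computed: alpha = -2, beta = 1.5, gamma = 3, (M0, M1) = (2, 1)
    u4 <- GeneUniverse(paste0("g", 1:4))
    star <- NetworkCollection(list(
        BioNetwork("s", rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)), u4)))
    xs <- c(0, 1, 0, 0)
    ps <- MRFParams(-2, 1.5, 3)
    expect_equal(localField(1L, star, xs, ps, -2), 0.5)
    x1 <- xs; x1[1] <- 1
    x0 <- xs; x0[1] <- 0
    expect_equal(energy(star, x0, ps, -2) - energy(star, x1, ps, -2), 0.5)
})

test_that("field/energy identity holds on random triples", {
    set.seed(99)
    for (r in 1:200) {
        n <- sample(4:20, 1)
        inst <- randomInstance(n)
        x <- rbinom(n, 1, runif(1, 0.2, 0.8))
        g <- sample(n, 1)
        x1 <- x; x1[g] <- 1
        x0 <- x; x0[g] <- 0
        dU <- energy(inst$collection, x0, inst$params, inst$alphaI) -
              energy(inst$collection, x1, inst$params, inst$alphaI)
        expect_equal(localField(g, inst$collection, x, inst$params, inst$alphaI),
                     dU, tolerance = 1e-10)
    }
})

test_that("monotonicity: with gamma > beta the field grows with M1", {
    u <- GeneUniverse(paste0("g", 1:5))
    star <- NetworkCollection(list(
        BioNetwork("s", rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(1L, 5L)), u)))
    ps <- MRFParams(0, 1.2, 2.5)
    fields <- vapply(0:4, function(m1) {
        x <- c(0L, rep(1L, m1), rep(0L, 4 - m1))
        localField(1L, star, x, ps, 0)
    }, numeric(1))
    expect_true(all(diff(fields) > 0))
})

test_that("conditional probability is the Gibbs conditional, overflow-safe", {
    expect_equal(conditionalProbability(0), 0.5)
    expect_equal(conditionalProbability(1000), 1)
    expect_equal(conditionalProbability(-1000), 0)
    # against enumeration of the full Gibbs distribution on 12 genes
    set.seed(13)
    inst <- randomInstance(12, pEdge = 0.25)
    x <- rbinom(12, 1, 0.5)
    for (g in c(1L, 5L, 12L)) {
        t <- localField(g, inst$collection, x, inst$params, inst$alphaI)
        expect_equal(conditionalProbability(t),
                     oracleConditional(inst$collection, x, g, inst$params,
                                       inst$alphaI),
                     tolerance = 1e-10)
    }
})

test_that("logit is the inverse of the logistic and errors off-domain", {
    expect_equal(logit(0.5), 0)
    expect_equal(logit(0.9), log(0.9 / 0.1))
    for (v in c(-3, 0.7, 5)) {
        expect_equal(logit(conditionalProbability(v)), v, tolerance = 1e-12)
    }
    expect_error(logit(0), "0, 1")
    expect_error(logit(1.2), "0, 1")
})

test_that("complex priors use max A/B with fallback C/D and clipping", {
    u <- GeneUniverse(paste0("g", 1:20))
    cs <- new("ComplexSet", universe = u, complexes = list(
        c1 = c(2L, 3L, 4L, 11L, 12L),      # 2 class among 4 disease genes
        c2 = c(1L, 5L, 13L, 14L, 15L),     # 1 class among 4 disease genes
        c3 = c(1L, 6L, 7L, 8L, 16L, 17L),  # 3 class among 5 disease genes
        c4 = c(9L, 10L)))                  # no disease genes at all
    classGenes <- c(2L, 3L, 5L, 6L, 7L, 8L)
    allDisease <- c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 11L, 13L, 14L, 15L, 16L, 17L)
    expect_equal(complexPrior(2L, cs, classGenes, allDisease, 20), 2 / 4)
    # gene 1 sits in two complexes giving 0.25 and 0.6: maximum wins
    expect_equal(complexPrior(1L, cs, classGenes, allDisease, 20), 0.6)
    # gene in no complex (or only B = 0 complexes) falls back to C/D
    expect_equal(complexPrior(18L, cs, classGenes, allDisease, 20), 6 / 20)
    expect_equal(complexPrior(9L, cs, classGenes, allDisease, 20), 6 / 20)
    # A = 0 clips away from zero
    expect_equal(complexPrior(4L, cs, integer(0), allDisease, 20), 1e-6)
    expect_error(complexPrior(1L, cs, c(2L, 19L), allDisease, 20), "subset")
    # vectorized builder agrees with the per-gene rule
    pv <- buildPriors(u, cs, classGenes, allDisease)
    for (g in c(1L, 2L, 4L, 9L, 18L)) {
        expect_equal(priors(pv)[g],
                     complexPrior(g, cs, classGenes, allDisease, 20))
    }
})
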