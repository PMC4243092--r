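#' Log-odds transform
#'
#' @param p probability in the open interval (0, 1).
#' @return log(p / (1 - p)).
#' @export
logit <- function(p) {
    if (any(p <= 0 | p >= 1)) stop("logit is defined on (0, 1) only")
    log(p / (1 - p))
}

#' Overflow-safe logistic (inverse logit)
#'
#' The Gibbs update probability for a local field T is
#' e^T / (e^T + 1), computed as 1 / (1 + e^-T) so large positive fields do
#' not overflow.
#'
#' @param t finite real local field value(s).
#' @return probability in [0, 1].
#' @export
conditionalProbability <- function(t) 1 / (1 + exp(-t))

#' Classify the edges of a network by endpoint labels
#'
#' Edges fall in three categories: both endpoints labelled 1 (N11), mixed
#' (N10), both 0 (N00). The three counts always sum to the edge count.
#'
#' @param network a [BioNetwork-class].
#' @param labels a [LabelConfig-class] or 0/1 vector over the universe.
#' @return named integer vector `c(n11, n10, n00)`.
#' @export
edgeCategoryCounts <- function(network, labels) {
    x <- if (is(labels, "LabelConfig")) labels@labels else as.integer(labels)
    e <- network@edges
    xi <- x[e[, 1L]]
    xj <- x[e[, 2L]]
    n11 <- sum(xi * xj)
    n10 <- sum(xi + xj == 1L)
    c(n11 = n11, n10 = n10, n00 = nrow(e) - n11 - n10)
}

#' Count 0- and 1-labelled neighbors of a gene in each network
#'
#' @param gene universe index of the gene.
#' @param collection a [NetworkCollection-class].
#' @param labels a [LabelConfig-class] or 0/1 vector.
#' @return list with integer vectors `m0` and `m1` of length K;
#'   `m0[k] + m1[k]` is the gene's degree in network k.
#' @export
neighborCounts <- function(gene, collection, labels) {
    x <- if (is(labels, "LabelConfig")) labels@labels else as.integer(labels)
    m0 <- integer(length(collection@networks))
    m1 <- integer(length(collection@networks))
    for (k in seq_along(collection@networks)) {
        e <- collection@networks[[k]]@edges
        nb <- c(e[e[, 1L] == gene, 2L], e[e[, 2L] == gene, 1L])
        m1[k] <- sum(x[nb])
        m0[k] <- length(nb) - m1[k]
    }
    list(m0 = m0, m1 = m1)
}

#' Per-gene field vector entering the energy and the local field
#'
#' In `"prior"` mode (the default) a gene's field alpha_i is exactly its
#' prior log-odds logit(pi_i) -- the verbatim local-field formula; the
#' regression constant is tracked as a diagnostic but does not enter the
#' field. In `"global"` mode every gene gets the single fitted constant;
#' in `"offset"` mode the prior log-odds plus the fitted constant.
#'
#' @param params an [MRFParams-class].
#' @param priors a [PriorVector-class] (required for `"prior"`/`"offset"`).
#' @param alphaMode `"prior"`, `"global"` or `"offset"`.
#' @param n number of genes (used in `"global"` mode when `priors` is NULL).
#' @return numeric vector of per-gene alpha_i.
#' @export
fieldVector <- function(params, priors = NULL,
                        alphaMode = c("prior", "global", "offset"),
                        n = length(priors@pi)) {
    alphaMode <- match.arg(alphaMode)
    switch(alphaMode,
           prior = priorLogit(priors),
           global = rep(params@alpha, n),
           offset = priorLogit(priors) + params@alpha)
}

#' Energy of a label configuration
#'
#' U(x | theta) = - sum_i alpha_i x_i
#'              - sum_k (beta^k N10^k + gamma^k N11^k + N00^k),
#' the Ising energy over all K networks with the 0-0 edge weight fixed at 1.
#' Lower energy means higher probability under the Gibbs distribution
#' P(x) = exp(-U(x)) / Z(theta).
#'
#' @param collection a [NetworkCollection-class].
#' @param labels a [LabelConfig-class] or 0/1 vector.
#' @param params an [MRFParams-class].
#' @param alphaI per-gene field vector (see [fieldVector()]); recycled if
#'   length 1.
#' @return single numeric energy value.
#' @export
energy <- function(collection, labels, params, alphaI) {
    x <- if (is(labels, "LabelConfig")) labels@labels else as.integer(labels)
    if (length(alphaI) == 1L) alphaI <- rep(alphaI, length(x))
    u <- -sum(alphaI * x)
    for (k in seq_along(collection@networks)) {
        cc <- edgeCategoryCounts(collection@networks[[k]], x)
        u <- u - (params@beta[k] * cc[["n10"]] + params@gamma[k] * cc[["n11"]] +
                  cc[["n00"]])
    }
    u
}

#' Local field of one gene
#'
#' T(i) = alpha_i + sum_k [ (beta^k - 1) M0^k + (gamma^k - beta^k) M1^k ],
#' the energy difference U(X_i = 0, x_-i) - U(X_i = 1, x_-i); the Gibbs
#' conditional probability of label 1 is sigmoid(T(i)).
#'
#' @inheritParams energy
#' @param gene universe index of the gene.
#' @return single numeric field value.
#' @export
localField <- function(gene, collection, labels, params, alphaI) {
    x <- if (is(labels, "LabelConfig")) labels@labels else as.integer(labels)
    if (length(alphaI) == 1L) alphaI <- rep(alphaI, length(x))
    nc <- neighborCounts(gene, collection, x)
    alphaI[gene] + sum((params@beta - 1) * nc$m0 + (params@gamma - params@beta) * nc$m1)
}

#' Complex-derived prior probability of one gene
#'
#' For each complex containing the gene that holds at least one known
#' disease gene (of any class), a candidate prior A / B is formed, where A
#' is the number of known disease genes of the class of interest in the
#' complex and B the number of all known disease genes in it; the gene's
#' prior is the maximum candidate. Genes in no complex (or only in
#' complexes without known disease genes) fall back to C / D, the number of
#' known class genes over the universe size. The result is clipped to
#' [1e-6, 1 - 1e-6] so its log-odds stays finite.
#'
#' @param gene universe index.
#' @param complexes a [ComplexSet-class].
#' @param diseaseGenes integer indices of known genes of the class of
#'   interest.
#' @param allDiseaseGenes integer indices of all known disease genes (any
#'   class); must contain `diseaseGenes`.
#' @param universeSize number of genes in the genome/universe.
#' @return prior probability.
#' @export
complexPrior <- function(gene, complexes, diseaseGenes, allDiseaseGenes,
                         universeSize) {
    if (!all(diseaseGenes %in% allDiseaseGenes)) {
        stop("diseaseGenes must be a subset of allDiseaseGenes")
    }
    stopifnot(universeSize > 0)
    best <- NA_real_
    for (members in complexes@complexes) {
        if (!(gene %in% members)) next
        B <- sum(members %in% allDiseaseGenes)
        if (B == 0L) next
        A <- sum(members %in% diseaseGenes)
        cand <- A / B
        if (is.na(best) || cand > best) best <- cand
    }
    if (is.na(best)) best <- length(diseaseGenes) / universeSize
    min(max(best, .PRIOR_EPS), 1 - .PRIOR_EPS)
}

#' Build the prior vector for a whole universe
#'
#' Vectorized wrapper around [complexPrior()] producing a
#' [PriorVector-class] for all genes.
#'
#' @inheritParams complexPrior
#' @param universe a [GeneUniverse-class].
#' @return A [PriorVector-class].
#' @export
buildPriors <- function(universe, complexes, diseaseGenes, allDiseaseGenes) {
    if (!all(diseaseGenes %in% allDiseaseGenes)) {
        stop("diseaseGenes must be a subset of allDiseaseGenes")
    }
    n <- length(universe@genes)
    fallback <- length(diseaseGenes) / n
    pi <- rep(fallback, n)
    best <- rep(NA_real_, n)
    for (members in complexes@complexes) {
        B <- sum(members %in% allDiseaseGenes)
        if (B == 0L) next
        A <- sum(members %in% diseaseGenes)
        cand <- A / B
        upd <- members[is.na(best[members]) | cand > best[members]]
        best[upd] <- pmax(cand, best[upd], na.rm = TRUE)
    }
    pi[!is.na(best)] <- best[!is.na(best)]
    PriorVector(pi)
}
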