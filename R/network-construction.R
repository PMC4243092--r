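#' Build a co-expression network by Pearson correlation
#'
#' Genes i and j are linked iff the Pearson correlation of their expression
#' profiles is strictly greater than `threshold` (default 0.5). Rows with
#' zero variance have undefined correlation and produce no edges.
#'
#' @param expr an [ExpressionMatrix-class] with at least two samples.
#' @param threshold correlation cutoff in (-1, 1).
#' @param universe optional [GeneUniverse-class]; defaults to the matrix's
#'   genes in row order.
#' @param name network label.
#' @return A [BioNetwork-class].
#' @export
coexpressionNetwork <- function(expr, threshold = 0.5, universe = NULL,
                                name = "coexpression") {
    v <- expr@values
    if (ncol(v) < 2L) stop("need at least 2 samples to correlate")
    stopifnot(threshold > -1, threshold < 1)
    if (is.null(universe)) universe <- GeneUniverse(rownames(v))
    idx <- match(rownames(v), universe@genes)
    if (anyNA(idx)) stop("expression rows outside the universe")
    cc <- suppressWarnings(cor(t(v)))   # zero-variance rows give NA
    cc[is.na(cc)] <- -Inf
    hit <- which(upper.tri(cc) & cc > threshold, arr.ind = TRUE)
    BioNetwork(name, cbind(idx[hit[, 1L]], idx[hit[, 2L]]), universe)
}

#' Build a pathway co-existence network
#'
#' Two genes are linked iff they co-occur in at least one pathway, i.e. the
#' network is the union of cliques over the gene sets.
#'
#' @param sets list of gene sets (symbol vectors or integer indices).
#' @param universe a [GeneUniverse-class].
#' @param name network label.
#' @return A [BioNetwork-class].
#' @export
pathwayCoexistenceNetwork <- function(sets, universe, name = "pathway") {
    stopifnot(length(sets) >= 1L)
    pairs <- lapply(sets, function(members) {
        if (is.character(members)) {
            idx <- match(members, universe@genes)
            idx <- idx[!is.na(idx)]
        } else {
            idx <- as.integer(members)
        }
        idx <- unique(idx)
        if (length(idx) < 2L) return(NULL)
        t(utils::combn(sort(idx), 2L))
    })
    pairs <- do.call(rbind, pairs)
    if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2L)
    BioNetwork(name, pairs, universe)
}

#' Restrict the universe to genes recurring across networks
#'
#' A gene "appears" in a network if it has degree >= 1 there. Genes
#' appearing in fewer than `minCount` of the K networks are removed, the
#' universe re-indexed, and edges with a removed endpoint dropped. This is
#' the multi-network support filter (e.g. genes present in at least four
#' of five networks).
#'
#' @param collection a [NetworkCollection-class].
#' @param minCount minimum number of networks a retained gene appears in.
#' @return A [NetworkCollection-class] over the filtered universe.
#' @export
filterByNetworkFrequency <- function(collection, minCount) {
    stopifnot(minCount >= 1L)
    deg <- degrees(collection)                     # genes x K
    appearances <- rowSums(deg >= 1L)
    keep <- which(appearances >= minCount)
    if (length(keep) == 0L) {
        stop("network-frequency filter removed every gene; lower minCount")
    }
    oldGenes <- collection@universe@genes
    newUniverse <- GeneUniverse(oldGenes[keep])
    remap <- rep(NA_integer_, length(oldGenes))
    remap[keep] <- seq_along(keep)
    nets <- lapply(collection@networks, function(nw) {
        e <- nw@edges
        a <- remap[e[, 1L]]
        b <- remap[e[, 2L]]
        ok <- !is.na(a) & !is.na(b)
        BioNetwork(nw@name, cbind(a[ok], b[ok]), newUniverse)
    })
    NetworkCollection(nets)
}

#' Merge networks into one mixed network
#'
#' Union of the edge sets of all member networks (unweighted), the "mixed
#' network" integration manner used by random-walk-style baselines.
#'
#' @param collection a [NetworkCollection-class].
#' @param name label of the merged network.
#' @return A [BioNetwork-class].
#' @export
mergeNetworks <- function(collection, name = "merged") {
    e <- do.call(rbind, lapply(collection@networks, edges))
    BioNetwork(name, e, collection@universe)
}
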