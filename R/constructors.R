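#' Construct a gene universe
#'
#' @param genes character vector of unique gene symbols. Symbols are
#'   case-sensitive; no aliasing is attempted.
#' @return A [GeneUniverse-class].
#' @examples
#' GeneUniverse(c("TP53", "BRCA1", "EGFR"))
#' @export
GeneUniverse <- function(genes) {
    new("GeneUniverse", genes = as.character(genes))
}

.canonicalEdges <- function(from, to) {
    i <- pmin(from, to)
    j <- pmax(from, to)
    keep <- i != j
    e <- cbind(i[keep], j[keep])
    storage.mode(e) <- "integer"
    e <- unique(e)
    if (nrow(e)) e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
    dimnames(e) <- NULL
    e
}

#' Construct a biological network
#'
#' Self-loops are dropped and duplicate undirected edges collapsed; edges
#' are stored canonically (i < j, sorted).
#'
#' @param name network label.
#' @param edges two-column matrix of gene indices, or a two-column
#'   character matrix/data.frame of gene symbols resolved against
#'   `universe`.
#' @param universe a [GeneUniverse-class].
#' @return A [BioNetwork-class].
#' @examples
#' u <- GeneUniverse(c("A", "B", "C"))
#' BioNetwork("ppi", cbind(c(1L, 2L), c(2L, 3L)), u)
#' @export
BioNetwork <- function(name, edges, universe) {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (is.character(edges)) {
        idx <- match(edges, universe@genes)
        if (anyNA(idx)) {
            bad <- unique(edges[is.na(idx)])
            stop("unknown gene symbol(s): ", paste(bad, collapse = ", "))
        }
        edges <- matrix(idx, ncol = 2L)
    }
    if (length(edges) == 0L) {
        edges <- matrix(integer(0), ncol = 2L)
    }
    e <- .canonicalEdges(as.integer(edges[, 1L]), as.integer(edges[, 2L]))
    new("BioNetwork", name = as.character(name), edges = e, universe = universe)
}

#' Bundle networks over a shared universe
#'
#' @param networks list of [BioNetwork-class] (or a single network).
#' @return A [NetworkCollection-class].
#' @export
NetworkCollection <- function(networks) {
    if (is(networks, "BioNetwork")) networks <- list(networks)
    stopifnot(length(networks) >= 1L)
    new("NetworkCollection", networks = networks,
        universe = networks[[1L]]@universe)
}

#' Construct a disease association table
#'
#' @param classes named list; each element a vector of gene symbols or
#'   integer indices.
#' @param universe a [GeneUniverse-class].
#' @return A [DiseaseAssociationTable-class].
#' @export
DiseaseAssociationTable <- function(classes, universe) {
    classes <- lapply(classes, function(members) {
        if (is.character(members)) members <- match(members, universe@genes)
        sort(unique(as.integer(members)))
    })
    new("DiseaseAssociationTable", classes = classes, universe = universe)
}

#' Construct a protein complex set
#'
#' Members outside the universe are dropped; complexes left with fewer than
#' two members are discarded (with a message), mirroring the convention of
#' keeping only complexes of at least two proteins.
#'
#' @param sets named list of gene symbol vectors or integer index vectors.
#' @param universe a [GeneUniverse-class].
#' @return A [ComplexSet-class].
#' @export
ComplexSet <- function(sets, universe) {
    mapped <- lapply(sets, function(members) {
        if (is.character(members)) {
            idx <- match(members, universe@genes)
            idx <- idx[!is.na(idx)]
        } else {
            idx <- as.integer(members)
        }
        sort(unique(idx))
    })
    keep <- lengths(mapped) >= 2L
    if (any(!keep)) {
        message(sum(!keep), " complex(es) with < 2 members in the universe dropped")
    }
    new("ComplexSet", complexes = mapped[keep], universe = universe)
}

#' Construct an expression matrix
#'
#' @param values numeric matrix with gene symbols as row names.
#' @return An [ExpressionMatrix-class].
#' @export
ExpressionMatrix <- function(values) {
    new("ExpressionMatrix", values = values)
}

#' Construct MRF parameters
#'
#' @param alpha global field coefficient (regression constant).
#' @param beta,gamma numeric vectors of per-network edge weights for
#'   1-0 and 1-1 edges; the 0-0 weight kappa is fixed at 1.
#' @return An [MRFParams-class].
#' @examples
#' MRFParams(alpha = -2, beta = c(1.5, 1.5), gamma = c(3, 3))
#' @export
MRFParams <- function(alpha, beta, gamma) {
    new("MRFParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
        gamma = as.numeric(gamma))
}

#' Construct a label configuration
#'
#' @param labels 0/1 vector over the universe.
#' @param clamped logical mask (or integer indices) of known disease genes;
#'   clamped genes are forced to label 1.
#' @return A [LabelConfig-class].
#' @export
LabelConfig <- function(labels, clamped = logical(length(labels))) {
    labels <- as.integer(labels)
    if (!is.logical(clamped)) {
        mask <- logical(length(labels))
        mask[as.integer(clamped)] <- TRUE
        clamped <- mask
    }
    labels[clamped] <- 1L
    new("LabelConfig", labels = labels, clamped = clamped)
}

#' Construct a prior vector
#'
#' @param pi per-gene prior probabilities; clipped to [1e-6, 1 - 1e-6].
#' @return A [PriorVector-class].
#' @export
PriorVector <- function(pi) {
    new("PriorVector", pi = pmin(pmax(as.numeric(pi), .PRIOR_EPS), 1 - .PRIOR_EPS))
}

#' Configure the Gibbs sampler
#'
#' @param burnIn discarded initial sweeps (default 100).
#' @param total total sweeps (default 1000).
#' @param thin snapshot interval in the lag period (default 10; the
#'   defaults give 90 recorded snapshots).
#' @param predictionSteps frozen-parameter sweeps appended by IMRF2
#'   (default 100).
#' @param seed RNG seed.
#' @param alphaMode `"prior"`, `"global"` or `"offset"`; see
#'   [SamplerConfig-class].
#' @param updateOrder `"index"` or `"shuffled"`.
#' @return A [SamplerConfig-class].
#' @export
SamplerConfig <- function(burnIn = 100L, total = 1000L, thin = 10L,
                          predictionSteps = 100L, seed = 1L,
                          alphaMode = c("prior", "global", "offset"),
                          updateOrder = c("index", "shuffled")) {
    new("SamplerConfig", burnIn = as.integer(burnIn), total = as.integer(total),
        thin = as.integer(thin), predictionSteps = as.integer(predictionSteps),
        seed = as.integer(seed), alphaMode = match.arg(alphaMode),
        updateOrder = match.arg(updateOrder))
}
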