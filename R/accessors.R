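#' Accessors for MRFGeneRank classes
#'
#' Small accessor functions are provided instead of direct slot access:
#' `genes()` returns the symbol vector of a universe (or of any object
#' carrying one), `edges()` the canonical edge matrix, `networks()` the
#' list of member networks, `degrees()` per-gene degrees, `labels01()` and
#' `clamped()` the components of a label configuration, `priors()` /
#' `priorLogit()` the prior probabilities and their log-odds,
#' `posterior()`, `thetaTrace()`, `thetaFinal()`, `qTrace()` the sampler
#' outputs, `auc()` the area under an ROC curve, and `thetaVector()` a flat
#' named numeric view of [MRFParams-class].
#'
#' @param x the object to access.
#' @name accessors
NULL

#' @rdname accessors
setMethod("genes", "GeneUniverse", function(x) x@genes)
#' @rdname accessors
setMethod("genes", "BioNetwork", function(x) x@universe@genes)
#' @rdname accessors
setMethod("genes", "NetworkCollection", function(x) x@universe@genes)
#' @rdname accessors
setMethod("genes", "SamplerResult", function(x) x@universe@genes)

#' @rdname accessors
setMethod("edges", "BioNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("networks", "NetworkCollection", function(x) x@networks)

#' @rdname accessors
setMethod("networkNames", "NetworkCollection", function(x) {
    vapply(x@networks, function(nw) nw@name, character(1))
})

#' @rdname accessors
setMethod("degrees", "BioNetwork", function(x) {
    tabulate(x@edges, nbins = length(x@universe@genes))
})
#' @rdname accessors
setMethod("degrees", "NetworkCollection", function(x) {
    vapply(x@networks, degrees, numeric(length(x@universe@genes)))
})

#' @rdname accessors
setMethod("labels01", "LabelConfig", function(x) x@labels)
#' @rdname accessors
setMethod("clamped", "LabelConfig", function(x) x@clamped)

#' @rdname accessors
setMethod("priors", "PriorVector", function(x) x@pi)
#' @rdname accessors
setMethod("priorLogit", "PriorVector", function(x) qlogis(x@pi))

#' @rdname accessors
setMethod("posterior", "SamplerResult", function(x) {
    stats::setNames(x@posterior, x@universe@genes)
})
#' @rdname accessors
setMethod("thetaTrace", "SamplerResult", function(x) x@thetaTrace)
#' @rdname accessors
setMethod("thetaFinal", "SamplerResult", function(x) x@thetaFinal)
#' @rdname accessors
setMethod("qTrace", "SamplerResult", function(x) x@qTrace)

#' @rdname accessors
setMethod("auc", "RocResult", function(x) x@auc)

#' @rdname accessors
setMethod("thetaVector", "MRFParams", function(x) {
    K <- length(x@beta)
    v <- c(x@alpha, rbind(x@beta, x@gamma))
    names(v) <- c("alpha", paste0(rep(c("beta", "gamma"), K), rep(seq_len(K), each = 2)))
    v
})

#' @rdname accessors
#' @export
nGenes <- function(x) {
    if (is(x, "GeneUniverse")) length(x@genes) else length(genes(x))
}

#' @rdname accessors
#' @export
nEdges <- function(x) nrow(x@edges)

setMethod("show", "GeneUniverse", function(object) {
    cat("GeneUniverse with", length(object@genes), "genes:",
        paste(utils::head(object@genes, 4), collapse = ", "),
        if (length(object@genes) > 4) "..." else "", "\n")
})

setMethod("show", "BioNetwork", function(object) {
    cat("BioNetwork '", object@name, "': ", nrow(object@edges), " edges over ",
        length(object@universe@genes), " genes\n", sep = "")
})

setMethod("show", "NetworkCollection", function(object) {
    cat("NetworkCollection of", length(object@networks), "network(s) over",
        length(object@universe@genes), "genes\n")
    for (nw in object@networks) {
        cat("  -", nw@name, ":", nrow(nw@edges), "edges\n")
    }
})

setMethod("show", "MRFParams", function(object) {
    cat("MRFParams (kappa fixed at 1):\n")
    print(round(thetaVector(object), 4))
})

setMethod("show", "LabelConfig", function(object) {
    cat("LabelConfig:", sum(object@labels), "of", length(object@labels),
        "genes labelled 1;", sum(object@clamped), "clamped\n")
})

setMethod("show", "SamplerResult", function(object) {
    free <- !object@known
    cat("SamplerResult (mode ", object@mode, ", alpha mode ",
        object@config@alphaMode, ")\n", sep = "")
    cat("  ", length(object@posterior), " genes (", sum(object@known),
        " known); mean free-gene posterior ",
        round(mean(object@posterior[free]), 4), "\n", sep = "")
    cat("  theta (averaged):",
        paste(names(thetaVector(object@thetaFinal)),
              round(thetaVector(object@thetaFinal), 3),
              sep = "=", collapse = " "), "\n")
})

setMethod("show", "RocResult", function(object) {
    cat("RocResult:", length(object@thresholds), "thresholds, AUC =",
        round(object@auc, 4), "\n")
})

setMethod("show", "BenchmarkScenario", function(object) {
    cat("BenchmarkScenario (seed ", object@seed, "): ",
        length(object@truth), " genes, ", sum(object@truth), " true positives (",
        length(object@knownGenes), " revealed), ",
        length(object@negativeControls), " negative controls, K = ",
        length(object@collection@networks), "\n", sep = "")
})
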