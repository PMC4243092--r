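#' @import methods
#' @importFrom stats qlogis plogis rbinom runif cor
#' @useDynLib MRFGeneRank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.PRIOR_EPS <- 1e-6

#' GeneUniverse: the indexed set of genes under study
#'
#' An ordered collection of unique gene symbols. All other objects in the
#' package (networks, label configurations, priors) refer to genes by their
#' position in a shared universe, so the universe fixes both N (the number
#' of genes) and the gene order used everywhere.
#'
#' @slot genes character vector of unique, non-empty gene symbols.
#' @export
setClass("GeneUniverse", representation(genes = "character"))

setValidity("GeneUniverse", function(object) {
    g <- object@genes
    if (length(g) == 0L) return("universe must contain at least one gene")
    if (anyNA(g) || any(!nzchar(g))) return("gene symbols must be non-empty")
    if (anyDuplicated(g)) return("gene symbols must be unique")
    TRUE
})

#' BioNetwork: one undirected simple graph over a gene universe
#'
#' Edges are stored as a two-column integer matrix of universe indices in
#' canonical form: each row (i, j) has i < j, rows are unique and sorted.
#' Self-loops and duplicate edges are removed on construction, matching the
#' cleaning applied to interaction databases before modelling.
#'
#' @slot name single character network label.
#' @slot edges integer matrix with two columns (canonical undirected pairs).
#' @slot universe the [GeneUniverse-class] the indices refer to.
#' @export
setClass("BioNetwork", representation(
    name = "character", edges = "matrix", universe = "GeneUniverse"))

setValidity("BioNetwork", function(object) {
    e <- object@edges
    if (length(object@name) != 1L) return("name must be a single string")
    if (!is.integer(e) || ncol(e) != 2L) {
        return("edges must be an integer matrix with 2 columns")
    }
    n <- length(object@universe@genes)
    if (nrow(e)) {
        if (min(e) < 1L || max(e) > n) return("edge endpoint outside universe")
        if (any(e[, 1L] >= e[, 2L])) {
            return("edges must be canonical (i < j); self-loops forbidden")
        }
        if (anyDuplicated(e)) return("duplicate edges are forbidden")
    }
    TRUE
})

#' NetworkCollection: K networks sharing one gene universe
#'
#' @slot networks list of [BioNetwork-class] objects, all defined over the
#'   identical universe; K >= 1.
#' @slot universe the shared [GeneUniverse-class].
#' @export
setClass("NetworkCollection", representation(
    networks = "list", universe = "GeneUniverse"))

setValidity("NetworkCollection", function(object) {
    if (length(object@networks) < 1L) return("need at least one network (K >= 1)")
    ok <- vapply(object@networks, function(nw) {
        is(nw, "BioNetwork") && identical(nw@universe@genes, object@universe@genes)
    }, logical(1))
    if (!all(ok)) return("all networks must be BioNetwork over the shared universe")
    TRUE
})

#' DiseaseAssociationTable: known gene-disease class memberships
#'
#' @slot classes named list mapping disease-class name to an integer vector
#'   of universe gene indices; classes may overlap.
#' @slot universe the [GeneUniverse-class] indices refer to.
#' @export
setClass("DiseaseAssociationTable", representation(
    classes = "list", universe = "GeneUniverse"))

setValidity("DiseaseAssociationTable", function(object) {
    n <- length(object@universe@genes)
    if (length(object@classes) &&
        (is.null(names(object@classes)) || any(!nzchar(names(object@classes))))) {
        return("every disease class needs a non-empty name")
    }
    for (idx in object@classes) {
        if (!is.integer(idx) || anyNA(idx)) return("class members must be integer indices")
        if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
            return("class member index outside universe")
        }
    }
    TRUE
})

#' ComplexSet: protein-complex membership as gene sets
#'
#' Complexes feed the prior probability of association (a gene inherits the
#' fraction of disease genes among known disease genes in its complex); they
#' are deliberately not turned into a network.
#'
#' @slot complexes named list of integer vectors (universe indices); each
#'   complex has at least two members.
#' @slot universe the [GeneUniverse-class].
#' @export
setClass("ComplexSet", representation(
    complexes = "list", universe = "GeneUniverse"))

setValidity("ComplexSet", function(object) {
    n <- length(object@universe@genes)
    for (idx in object@complexes) {
        if (!is.integer(idx) || anyNA(idx)) return("complex members must be integer indices")
        if (length(idx) < 2L) return("each complex must have at least two members")
        if (anyDuplicated(idx)) return("complex members must be unique")
        if (min(idx) < 1L || max(idx) > n) return("complex member outside universe")
    }
    TRUE
})

#' ExpressionMatrix: gene x sample expression values
#'
#' @slot values numeric matrix, rows named by gene symbol, columns samples;
#'   no missing values.
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("expression values must be numeric")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v))) {
        return("rows must be uniquely named by gene symbol")
    }
    if (anyNA(v)) return("missing expression values are not allowed")
    TRUE
})

#' MRFParams: parameters of the Ising-type random field
#'
#' theta = (alpha, beta^1, gamma^1, ..., beta^K, gamma^K). Per network k,
#' gamma^k weighs edges between two 1-labelled genes, beta^k edges between a
#' 1- and a 0-labelled gene, and the weight kappa^k of 0-0 edges is fixed at
#' 1 (one of the three is redundant). alpha is the global field coefficient,
#' the constant of the pseudo-likelihood regression.
#'
#' @slot alpha single numeric field coefficient.
#' @slot beta numeric vector of length K.
#' @slot gamma numeric vector of length K.
#' @export
setClass("MRFParams", representation(
    alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("MRFParams", function(object) {
    if (length(object@alpha) != 1L) return("alpha must be a single number")
    if (length(object@beta) != length(object@gamma)) {
        return("beta and gamma must have one entry per network")
    }
    if (!all(is.finite(c(object@alpha, object@beta, object@gamma)))) {
        return("parameters must be finite")
    }
    TRUE
})

#' LabelConfig: a binary labelling of the universe with clamped genes
#'
#' Labels x_i in {0, 1} for every gene; clamped positions mark known disease
#' genes of the current class, which always carry label 1 and are never
#' updated by the sampler.
#'
#' @slot labels integer vector of 0/1 over the universe.
#' @slot clamped logical vector of the same length.
#' @export
setClass("LabelConfig", representation(
    labels = "integer", clamped = "logical"))

setValidity("LabelConfig", function(object) {
    if (length(object@labels) != length(object@clamped)) {
        return("labels and clamped must have equal length")
    }
    if (anyNA(object@labels) || !all(object@labels %in% c(0L, 1L))) {
        return("labels must be 0/1")
    }
    if (any(object@labels[object@clamped] != 1L)) {
        return("clamped genes must carry label 1")
    }
    TRUE
})

#' PriorVector: per-gene prior probabilities of association
#'
#' Probabilities are clipped to [1e-6, 1 - 1e-6] so the log-odds field
#' alpha_i = logit(pi_i) stays finite even when a complex contains no or
#' only disease genes.
#'
#' @slot pi numeric vector of prior probabilities over the universe.
#' @export
setClass("PriorVector", representation(pi = "numeric"))

setValidity("PriorVector", function(object) {
    p <- object@pi
    if (anyNA(p) || any(p < .PRIOR_EPS - 1e-15) || any(p > 1 - .PRIOR_EPS + 1e-15)) {
        return("priors must lie in [1e-6, 1 - 1e-6]")
    }
    TRUE
})

#' SamplerConfig: schedule and options of the Gibbs sampler
#'
#' The chain runs `total` sweeps; the first `burnIn` are discarded and the
#' remainder (the lag period) is recorded every `thin`-th sweep. The
#' IMRF2 variant appends `predictionSteps` further sweeps with frozen
#' parameters. Defaults reproduce the published schedule: burn-in 100,
#' 1000 sweeps in total, averaging every 10 steps (90 snapshots).
#'
#' @slot burnIn integer number of discarded initial sweeps.
#' @slot total integer total number of estimation/sampling sweeps.
#' @slot thin integer snapshot interval after burn-in.
#' @slot predictionSteps integer extra frozen-parameter sweeps (IMRF2 only).
#' @slot seed integer RNG seed.
#' @slot alphaMode `"prior"` (default: the per-gene field is the prior
#'   log-odds, the verbatim local-field formula; the regression constant is
#'   tracked as a diagnostic but does not enter the field), `"global"` (the
#'   fitted regression constant is every gene's field) or `"offset"` (prior
#'   log-odds plus the fitted constant). The anchored `"prior"` mode keeps
#'   the interleaved estimation/sampling loop in the low-prevalence phase;
#'   the other modes let the constant track the chain's base rate and can
#'   drift into the all-ones phase on sparse instances.
#' @slot updateOrder `"index"` or `"shuffled"` visitation order per sweep.
#' @export
setClass("SamplerConfig", representation(
    burnIn = "integer", total = "integer", thin = "integer",
    predictionSteps = "integer", seed = "integer",
    alphaMode = "character", updateOrder = "character"))

setValidity("SamplerConfig", function(object) {
    if (object@burnIn <= 0L || object@burnIn >= object@total) {
        return("need 0 < burnIn < total")
    }
    if (object@thin < 1L) return("thin must be >= 1")
    if (object@predictionSteps < 0L) return("predictionSteps must be >= 0")
    if (!object@alphaMode %in% c("prior", "global", "offset")) {
        return("alphaMode must be 'prior', 'global' or 'offset'")
    }
    if (!object@updateOrder %in% c("index", "shuffled")) {
        return("updateOrder must be 'index' or 'shuffled'")
    }
    TRUE
})

#' SamplerResult: posterior probabilities and chain diagnostics
#'
#' @slot posterior numeric vector over the universe; the average of the
#'   per-sweep conditional probabilities sigmoid(T(i)) for free genes, 1 for
#'   clamped (known) genes.
#' @slot known logical vector flagging clamped genes.
#' @slot prior numeric vector of the priors used.
#' @slot thetaTrace numeric matrix, one row per sweep, columns
#'   alpha, beta^k, gamma^k.
#' @slot thetaFinal [MRFParams-class] averaged over recorded sweeps.
#' @slot qTrace numeric vector of chain variation Q(t) per sweep.
#' @slot recordedSweeps integer indices of the sweeps whose conditional
#'   probabilities were averaged into the posterior (the lag-period
#'   snapshots, or the prediction-period sweeps for IMRF2).
#' @slot config the [SamplerConfig-class] used.
#' @slot mode one of `"imrf1"`, `"imrf2"`, `"deng"`.
#' @slot universe the [GeneUniverse-class].
#' @export
setClass("SamplerResult", representation(
    posterior = "numeric", known = "logical", prior = "numeric",
    thetaTrace = "matrix", thetaFinal = "MRFParams", qTrace = "numeric",
    recordedSweeps = "integer", config = "SamplerConfig", mode = "character",
    universe = "GeneUniverse"))

setValidity("SamplerResult", function(object) {
    p <- object@posterior
    if (anyNA(p) || any(p < 0) || any(p > 1)) return("posteriors must lie in [0,1]")
    if (any(p[object@known] != 1)) return("known genes must have posterior 1")
    if (!object@mode %in% c("imrf1", "imrf2", "deng")) {
        return("mode must be imrf1, imrf2 or deng")
    }
    TRUE
})

#' RocResult: ROC curve and area under it
#'
#' @slot thresholds numeric decision-score cut points (descending).
#' @slot tpr,fpr numeric vectors from (0,0) to (1,1).
#' @slot auc trapezoidal area under the curve; equals the normalized
#'   Mann-Whitney U count (ties credited 1/2).
#' @export
setClass("RocResult", representation(
    thresholds = "numeric", tpr = "numeric", fpr = "numeric", auc = "numeric"))

setValidity("RocResult", function(object) {
    if (is.unsorted(object@tpr) || is.unsorted(object@fpr)) {
        return("tpr and fpr must be non-decreasing")
    }
    if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
    TRUE
})

#' BenchmarkScenario: a fully synthetic instance of the labelling problem
#'
#' @slot collection the generated [NetworkCollection-class].
#' @slot truth integer 0/1 vector of true labels drawn from the model.
#' @slot knownGenes integer indices of revealed (clamped) true positives.
#' @slot negativeControls integer indices of true-0 genes standing in for
#'   known disease genes of other classes.
#' @slot complexes [ComplexSet-class] enriched for true positives.
#' @slot thetaTrue the generating [MRFParams-class].
#' @slot knownFraction numeric fraction of true positives revealed.
#' @slot seed integer seed the scenario is reproducible from.
#' @export
setClass("BenchmarkScenario", representation(
    collection = "NetworkCollection", truth = "integer",
    knownGenes = "integer", negativeControls = "integer",
    complexes = "ComplexSet", thetaTrue = "MRFParams",
    knownFraction = "numeric", seed = "integer"))

setValidity("BenchmarkScenario", function(object) {
    if (any(object@truth[object@knownGenes] != 1L)) {
        return("revealed known genes must all carry true label 1")
    }
    if (any(object@truth[object@negativeControls] != 0L)) {
        return("negative controls must carry true label 0")
    }
    TRUE
})
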