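#' @importFrom Matrix sparseMatrix colSums rowSums t
NULL

# CSR adjacency (0-based) per network for the C++ sampler, plus a sparse
# adjacency matrix per network for the vectorized regression design.
.prepAdjacency <- function(collection) {
    n <- length(collection@universe@genes)
    lapply(collection@networks, function(nw) {
        e <- nw@edges
        from <- c(e[, 1L], e[, 2L])
        to <- c(e[, 2L], e[, 1L])
        o <- order(from, to)
        from <- from[o]
        to <- to[o]
        offsets <- c(0L, cumsum(tabulate(from, nbins = n)))
        A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
        list(offsets = as.integer(offsets), nbr = as.integer(to - 1L),
             A = A, deg = tabulate(e, nbins = n))
    })
}

.adjOffsets <- function(adj) lapply(adj, `[[`, "offsets")
.adjNbrs <- function(adj) lapply(adj, `[[`, "nbr")

# Neighbor-count design matrix: one row per gene, columns M0^k, M1^k.
.designMatrix <- function(adj, x) {
    cols <- lapply(adj, function(a) {
        m1 <- as.vector(a$A %*% x)
        cbind(a$deg - m1, m1)
    })
    X <- do.call(cbind, cols)
    colnames(X) <- paste0(rep(c("M0.", "M1."), length(adj)),
                          rep(seq_along(adj), each = 2))
    X
}

# Ridge-penalized IRLS for binary logistic regression (pseudo-likelihood
# fit). The tiny penalty lambda keeps coefficients finite under complete
# separation and degenerate (constant) columns; Newton steps are halved
# until the penalized deviance does not increase, so near-separated fits
# drift monotonically instead of diverging. Iteration is capped at maxit,
# after which the current finite coefficients are returned with
# converged = FALSE.
.irlsLogistic <- function(X, y, offset = NULL, lambda = 1e-6, maxit = 100L,
                          tol = 1e-10, start = NULL) {
    X1 <- cbind(1, X)
    p <- ncol(X1)
    if (is.null(offset)) offset <- rep(0, length(y))
    pdev <- function(coef) {
        eta <- drop(X1 %*% coef) + offset
        # -2 log-likelihood, numerically safe for large |eta|
        2 * sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
            lambda * sum(coef^2)
    }
    coef <- if (is.null(start)) rep(0, p) else start
    dev <- pdev(coef)
    converged <- FALSE
    for (it in seq_len(maxit)) {
        eta <- drop(X1 %*% coef) + offset
        mu <- 1 / (1 + exp(-eta))
        w <- pmax(mu * (1 - mu), 1e-10)
        z <- eta - offset + (y - mu) / w
        XtW <- base::t(X1 * w)
        H <- XtW %*% X1 + diag(lambda, p)
        step <- drop(solve(H, XtW %*% z)) - coef
        newcoef <- coef + step
        newdev <- pdev(newcoef)
        halvings <- 0L
        while (newdev > dev + 1e-8 && halvings < 20L) {
            step <- step / 2
            newcoef <- coef + step
            newdev <- pdev(newcoef)
            halvings <- halvings + 1L
        }
        if (max(abs(newcoef - coef)) < tol) {
            coef <- newcoef
            converged <- TRUE
            break
        }
        coef <- newcoef
        dev <- newdev
    }
    list(coef = coef, converged = converged)
}

#' Pseudo-likelihood parameter estimation
#'
#' Fits the binary logistic regression
#' logit P(x_i = 1) = alpha + sum_k (b_k M0^k + c_k M1^k)
#' over all genes, with neighbor counts taken from the current labelling,
#' and maps the coefficients back to the field parameters:
#' beta^k = b_k + 1, gamma^k = c_k + beta^k. In `"offset"` mode the
#' per-gene prior log-odds enters as a fixed offset. A small ridge penalty
#' (1e-6) keeps coefficients finite under complete separation or constant
#' design columns.
#'
#' @param collection a [NetworkCollection-class].
#' @param labels a [LabelConfig-class] or 0/1 vector with labels assigned
#'   to all genes (known plus currently sampled unknowns).
#' @param priors a [PriorVector-class] (its log-odds is the fixed offset in
#'   `"prior"` and `"offset"` modes).
#' @param alphaMode `"prior"`, `"global"` or `"offset"`; in the first and
#'   last the fit carries the prior log-odds as a fixed per-gene offset.
#' @return An [MRFParams-class].
#' @export
estimateParameters <- function(collection, labels, priors = NULL,
                               alphaMode = c("prior", "global", "offset")) {
    alphaMode <- match.arg(alphaMode)
    x <- if (is(labels, "LabelConfig")) labels@labels else as.integer(labels)
    adj <- .prepAdjacency(collection)
    X <- .designMatrix(adj, x)
    .estimateFromDesign(X, x, priors, alphaMode)
}

.estimateFromDesign <- function(X, y, priors, alphaMode, start = NULL) {
    if (length(unique(y)) < 2L) {
        stop("degenerate estimation: all labels are identical (",
             y[1L], "); the logistic fit is undefined")
    }
    offset <- if (alphaMode %in% c("prior", "offset")) priorLogit(priors) else NULL
    fit <- .irlsLogistic(X, y, offset = offset, start = start)
    co <- fit$coef
    K <- ncol(X) / 2L
    b <- co[2L * seq_len(K)]
    cc <- co[2L * seq_len(K) + 1L]
    beta <- b + 1
    params <- MRFParams(alpha = co[1L], beta = beta, gamma = cc + beta)
    attr(params, "converged") <- fit$converged
    attr(params, "coef") <- co
    params
}

# regression coefficients (intercept, b_k, c_k) from MRFParams, for warm
# starting the next sweep's fit
.paramsToCoef <- function(params) {
    K <- length(params@beta)
    co <- numeric(1L + 2L * K)
    co[1L] <- params@alpha
    co[2L * seq_len(K)] <- params@beta - 1
    co[2L * seq_len(K) + 1L] <- params@gamma - params@beta
    co
}

#' One sequential Gibbs sweep
#'
#' Visits the unclamped genes in the configured order; for each, the local
#' field T(i) is computed from the current labels (updates earlier in the
#' same sweep already applied), the conditional probability sigmoid(T(i))
#' is recorded, and a new label is drawn Bernoulli(p). Clamped genes are
#' untouched.
#'
#' @param state a [LabelConfig-class].
#' @param collection a [NetworkCollection-class].
#' @param params an [MRFParams-class].
#' @param alphaI per-gene field vector (see [fieldVector()]).
#' @param order integer vector of unclamped gene indices in visit order;
#'   defaults to ascending index.
#' @return list with `state` (updated [LabelConfig-class]) and `probs`
#'   (conditional probabilities aligned with `order`).
#' @export
gibbsSweep <- function(state, collection, params, alphaI, order = NULL) {
    if (is.null(order)) order <- which(!state@clamped)
    adj <- .prepAdjacency(collection)
    res <- cpp_gibbs_sweep(state@labels, as.integer(order - 1L), alphaI,
                           params@beta, params@gamma,
                           .adjOffsets(adj), .adjNbrs(adj))
    list(state = LabelConfig(res$labels, state@clamped), probs = res$probs)
}

#' Chain variation between adjacent steps
#'
#' Q(t) = sum_i (P_i(t) - P_i(t-1))^2 over the free genes, a convergence
#' diagnostic of the sampler.
#'
#' @param probT,probPrev per-gene conditional probabilities of two adjacent
#'   sweeps (same gene order, unclamped genes only).
#' @return single numeric Q value.
#' @export
chainVariation <- function(probT, probPrev) {
    if (length(probT) != length(probPrev)) {
        stop("probability vectors of adjacent steps differ in length")
    }
    sum((probT - probPrev)^2)
}

.initialLabels <- function(n, knownGenes, priors) {
    clampedMask <- logical(n)
    clampedMask[knownGenes] <- TRUE
    x <- integer(n)
    free <- which(!clampedMask)
    x[free] <- rbinom(length(free), 1L, priors@pi[free])
    LabelConfig(x, clampedMask)
}

.emptyThetaTrace <- function(total, K) {
    matrix(NA_real_, nrow = total, ncol = 1L + 2L * K,
           dimnames = list(NULL, c("alpha", paste0(rep(c("beta", "gamma"), K),
                                                   rep(seq_len(K), each = 2)))))
}

.meanParams <- function(traceRows) {
    m <- colMeans(traceRows)
    K <- (length(m) - 1L) / 2L
    MRFParams(alpha = m[1L], beta = m[2L * seq_len(K)],
              gamma = m[2L * seq_len(K) + 1L])
}

# Interleaved estimation / sampling engine shared by IMRF1 and (with
# estimation disabled) the fixed-parameter modes.
.runChain <- function(collection, knownGenes, priors, config,
                      fixedParams = NULL, mode) {
    n <- length(collection@universe@genes)
    K <- length(collection@networks)
    set.seed(config@seed)
    adj <- .prepAdjacency(collection)
    offs <- .adjOffsets(adj)
    nbrs <- .adjNbrs(adj)
    state <- .initialLabels(n, knownGenes, priors)
    free <- which(!state@clamped)
    baseOrder <- as.integer(free - 1L)

    thetaTr <- .emptyThetaTrace(config@total, K)
    qTr <- rep(NA_real_, config@total)
    psum <- numeric(length(free))
    thsum <- numeric(1L + 2L * K)
    nrec <- 0L
    recorded <- integer(0)
    x <- state@labels
    prevP <- NULL
    warm <- NULL

    for (t in seq_len(config@total)) {
        if (is.null(fixedParams)) {
            X <- .designMatrix(adj, x)
            params <- tryCatch(
                .estimateFromDesign(X, x, priors, config@alphaMode, start = warm),
                error = function(e) stop("parameter estimation failed at sweep ",
                                         t, ": ", conditionMessage(e)))
            warm <- attr(params, "coef")
        } else {
            params <- fixedParams
        }
        thetaTr[t, ] <- thetaVector(params)
        alphaI <- fieldVector(params, priors, config@alphaMode, n = n)
        ord <- if (config@updateOrder == "shuffled") {
            as.integer(sample(free) - 1L)
        } else baseOrder
        sw <- cpp_gibbs_sweep(x, ord, alphaI, params@beta, params@gamma,
                              offs, nbrs)
        x <- sw$labels
        # probs come back in visit order; realign to ascending free index
        p <- numeric(length(free))
        p[match(ord, baseOrder)] <- sw$probs
        if (!is.null(prevP)) qTr[t] <- chainVariation(p, prevP)
        prevP <- p
        if (t > config@burnIn && (t - config@burnIn) %% config@thin == 0L) {
            psum <- psum + p
            thsum <- thsum + thetaTr[t, ]
            nrec <- nrec + 1L
            recorded <- c(recorded, t)
        }
    }

    posterior <- rep(1, n)
    posterior[free] <- psum / nrec
    thetaFinal <- .meanParams(matrix(thsum / nrec, nrow = 1L,
                                     dimnames = list(NULL, colnames(thetaTr))))
    new("SamplerResult", posterior = posterior, known = state@clamped,
        prior = priors@pi, thetaTrace = thetaTr, thetaFinal = thetaFinal,
        qTrace = qTr, recordedSweeps = recorded, config = config,
        mode = mode, universe = collection@universe)
}

#' Run the IMRF1 sampler
#'
#' The improved MRF procedure: unknown labels are initialized by Bernoulli
#' draws from the priors, known genes are clamped to 1, and each sweep
#' first re-estimates theta by pseudo-likelihood logistic regression on the
#' full current labelling, then performs one sequential Gibbs sweep. After
#' the burn-in, the per-sweep conditional probabilities are recorded every
#' `thin`-th sweep; the posterior is their average and the reported
#' parameters the average theta over the recorded (lag-period) sweeps.
#'
#' @param collection a [NetworkCollection-class].
#' @param knownGenes integer indices of known disease genes (clamped to 1).
#' @param priors a [PriorVector-class].
#' @param config a [SamplerConfig-class].
#' @return A [SamplerResult-class].
#' @export
runIMRF1 <- function(collection, knownGenes, priors, config = SamplerConfig()) {
    stopifnot(length(knownGenes) >= 1L)
    .runChain(collection, knownGenes, priors, config, fixedParams = NULL,
              mode = "imrf1")
}

#' Run the IMRF2 sampler
#'
#' Performs [runIMRF1()], then appends a prediction period: theta is frozen
#' at the lag-period average, unknown labels are re-initialized by
#' Bernoulli draws from the lag-period posterior, and `predictionSteps`
#' further sweeps are run with no re-estimation. The final posterior is the
#' average conditional probability over the prediction period.
#'
#' @inheritParams runIMRF1
#' @return A [SamplerResult-class] whose `thetaTrace` gains
#'   `predictionSteps` constant rows.
#' @export
runIMRF2 <- function(collection, knownGenes, priors, config = SamplerConfig()) {
    stage1 <- runIMRF1(collection, knownGenes, priors, config)
    if (config@predictionSteps == 0L) {
        stage1@mode <- "imrf2"
        return(stage1)
    }
    n <- length(collection@universe@genes)
    K <- length(collection@networks)
    params <- stage1@thetaFinal
    adj <- .prepAdjacency(collection)
    free <- which(!stage1@known)
    # re-initialize unknowns from the lag-period posterior; RNG continues
    # the seeded stream of stage 1 for end-to-end reproducibility
    x <- integer(n)
    x[stage1@known] <- 1L
    x[free] <- rbinom(length(free), 1L, stage1@posterior[free])
    alphaI <- fieldVector(params, priors, config@alphaMode, n = n)
    run <- cpp_gibbs_run(x, as.integer(free - 1L), alphaI, params@beta,
                         params@gamma, .adjOffsets(adj), .adjNbrs(adj),
                         config@predictionSteps, 0L, 1L,
                         config@updateOrder == "shuffled")
    posterior <- rep(1, n)
    posterior[free] <- run$pmean
    frozen <- matrix(rep(thetaVector(params), each = config@predictionSteps),
                     nrow = config@predictionSteps,
                     dimnames = list(NULL, colnames(stage1@thetaTrace)))
    out <- stage1
    out@mode <- "imrf2"
    out@posterior <- posterior
    out@thetaTrace <- rbind(stage1@thetaTrace, frozen)
    out@qTrace <- c(stage1@qTrace, run$qtrace)
    out@recordedSweeps <- config@total + seq_len(config@predictionSteps)
    out
}

#' Run the original MRF (Deng) baseline
#'
#' Parameters are estimated once, before sampling, from known-labelled
#' vertices only: rows are the known disease genes (label 1) and the known
#' disease genes of other classes (label 0), and the neighbor counts
#' M0/M1 are taken over known-labelled neighbors only. Theta is then fixed
#' for the whole Gibbs run, which otherwise follows the IMRF1 schedule.
#'
#' The baseline's per-gene field is the fitted regression constant (a
#' `"global"` field), because the original method estimates everything --
#' including the base rate -- from the known vertices alone. With only
#' dozens of known genes among thousands of unknown 0-vertices this
#' intercept is badly inflated, which is precisely the unreliability the
#' improved modes address; `alphaMode` in `config` therefore does not
#' apply to this mode.
#'
#' @inheritParams runIMRF1
#' @param negativeGenes integer indices of known disease genes of other
#'   classes, used as label-0 rows of the one-off fit.
#' @return A [SamplerResult-class] with a constant `thetaTrace`.
#' @export
runDeng <- function(collection, knownGenes, negativeGenes, priors,
                    config = SamplerConfig()) {
    stopifnot(length(knownGenes) >= 1L)
    K <- length(collection@networks)
    rows <- c(knownGenes, negativeGenes)
    if (length(rows) < 2L * K + 2L) {
        stop("too few known-labelled vertices (", length(rows),
             ") to fit ", 2L * K + 1L, " coefficients")
    }
    n <- length(collection@universe@genes)
    xKnown <- integer(n)
    xKnown[knownGenes] <- 1L
    inFit <- logical(n)
    inFit[rows] <- TRUE
    adj <- .prepAdjacency(collection)
    # neighbor counts restricted to known-labelled neighbors
    X <- do.call(cbind, lapply(adj, function(a) {
        m1 <- as.vector(a$A %*% (xKnown * inFit))
        mLab <- as.vector(a$A %*% as.numeric(inFit))
        cbind(mLab - m1, m1)
    }))[rows, , drop = FALSE]
    y <- xKnown[rows]
    params <- .estimateFromDesign(X, y, NULL, "global")
    cfg <- if (config@alphaMode == "global") config else
        SamplerConfig(config@burnIn, config@total, config@thin,
                      config@predictionSteps, config@seed, "global",
                      config@updateOrder)
    .runChain(collection, knownGenes, priors, cfg, fixedParams = params,
              mode = "deng")
}
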