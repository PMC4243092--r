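#' Percentile decision scores
#'
#' Converts posterior probabilities of the free (unclamped) genes into
#' fractional rank percentiles, score_i = rank(p_i) / n with average ranks
#' for ties. Because disease classes hold different numbers of known genes,
#' raw posteriors are not comparable across classes; rank percentiles are.
#'
#' @param posterior numeric vector of posterior probabilities over the
#'   free genes, or a [SamplerResult-class] (its free genes are used).
#' @return numeric scores in (0, 1], named like the input.
#' @export
decisionScores <- function(posterior) {
    if (is(posterior, "SamplerResult")) {
        free <- !posterior@known
        p <- stats::setNames(posterior@posterior[free],
                             posterior@universe@genes[free])
    } else {
        p <- posterior
    }
    if (length(p) < 1L) stop("need at least one unclamped gene")
    rank(p, ties.method = "average") / length(p)
}

#' ROC curve and AUC of a labelled score table
#'
#' Sweeps a threshold over the distinct scores (equal scores grouped at one
#' threshold) and accumulates true/false positive rates; the AUC is the
#' trapezoidal area, identical to the normalized Mann-Whitney U count with
#' ties credited 1/2.
#'
#' @param table data.frame with columns `label` (0/1) and `score`.
#' @return A [RocResult-class].
#' @export
rocAuc <- function(table) {
    lab <- table$label
    sc <- table$score
    nPos <- sum(lab == 1)
    nNeg <- sum(lab == 0)
    if (nPos == 0L || nNeg == 0L) {
        stop("ROC needs both positive and negative labels")
    }
    o <- order(sc, decreasing = TRUE)
    sc <- sc[o]
    lab <- lab[o]
    grp <- cumsum(!duplicated(sc))
    tp <- tapply(lab == 1, grp, sum)
    fp <- tapply(lab == 0, grp, sum)
    tpr <- c(0, cumsum(tp) / nPos)
    fpr <- c(0, cumsum(fp) / nNeg)
    a <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
    new("RocResult", thresholds = unique(sc), tpr = as.numeric(tpr),
        fpr = as.numeric(fpr), auc = a)
}

#' Leave-one-out cross-validation with negative controls
#'
#' Each known class gene with at least one neighbor in at least one network
#' is held out in turn: it is unclamped, its prior rebuilt as if it were
#' unknown (no leakage of its known status), the chosen sampler mode is
#' re-run, and its decision score recorded with label 1. Known disease
#' genes of other classes serve as negative controls: they are never
#' clamped in our runs, so their scores are taken from a baseline run with
#' all class genes clamped, and recorded with label 0.
#'
#' @param collection a [NetworkCollection-class].
#' @param classGenes integer indices of known genes of the class under
#'   study.
#' @param otherClassGenes integer indices of known disease genes of other
#'   classes (negative controls).
#' @param priorsBuilder function taking the vector of currently known class
#'   genes and returning a [PriorVector-class]; called per held-out gene so
#'   the held-out gene's prior is rebuilt without it.
#' @param config a [SamplerConfig-class]; each held-out run derives its own
#'   sub-seed for reproducibility.
#' @param mode `"imrf1"`, `"imrf2"` or `"deng"`.
#' @return data.frame with columns `gene` (universe index), `symbol`,
#'   `label` and `score`.
#' @export
leaveOneOut <- function(collection, classGenes, otherClassGenes, priorsBuilder,
                        config = SamplerConfig(),
                        mode = c("imrf1", "imrf2", "deng")) {
    mode <- match.arg(mode)
    stopifnot(length(classGenes) >= 1L)
    deg <- rowSums(degrees(collection))
    eligible <- classGenes[deg[classGenes] >= 1L]
    if (length(eligible) == 0L) {
        stop("no class gene has an annotated interaction partner; ",
             "nothing to validate")
    }
    runMode <- function(known, priors, seed) {
        cfg <- SamplerConfig(config@burnIn, config@total, config@thin,
                             config@predictionSteps, seed,
                             config@alphaMode, config@updateOrder)
        switch(mode,
               imrf1 = runIMRF1(collection, known, priors, cfg),
               imrf2 = runIMRF2(collection, known, priors, cfg),
               deng = runDeng(collection, known, otherClassGenes, priors, cfg))
    }
    scoresOf <- function(result) {
        free <- which(!result@known)
        stats::setNames(decisionScores(result@posterior[free]), free)
    }
    base <- runMode(classGenes, priorsBuilder(classGenes), config@seed)
    baseScores <- scoresOf(base)
    neg <- data.frame(gene = otherClassGenes,
                      label = 0L,
                      score = as.numeric(baseScores[as.character(otherClassGenes)]))
    pos <- lapply(seq_along(eligible), function(i) {
        g <- eligible[i]
        known <- setdiff(classGenes, g)
        if (length(known) == 0L) {
            stop("cannot hold out the only known class gene")
        }
        res <- runMode(known, priorsBuilder(known), config@seed + i)
        data.frame(gene = g, label = 1L,
                   score = as.numeric(scoresOf(res)[as.character(g)]))
    })
    out <- rbind(do.call(rbind, pos), neg)
    out$symbol <- collection@universe@genes[out$gene]
    rownames(out) <- NULL
    out[, c("gene", "symbol", "label", "score")]
}
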