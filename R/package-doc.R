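#' MRFGeneRank: disease gene prioritization with multi-network MRFs
#'
#' The package scores candidate disease genes by guilt-by-association
#' across several biological networks at once. A binary label x_i (disease
#' associated or not) is placed on every gene and the joint labelling is
#' modelled as an Ising-type Gibbs distribution whose energy couples each
#' network's 1-1 and 1-0 edges through per-network weights gamma^k and
#' beta^k (the 0-0 weight is fixed at 1) and each gene through a field
#' alpha_i. Known disease genes are clamped to 1; the posterior of the
#' remaining genes is estimated by Gibbs sampling while the parameters are
#' re-estimated each sweep by pseudo-likelihood binary logistic regression
#' of the current labels on per-network neighbor counts. Priors come from
#' protein-complex membership. Rankings use rank-percentile decision
#' scores, evaluated by leave-one-out cross-validation against
#' negative-control genes with ROC/AUC.
#'
#' Main entry points: [runIMRF1()], [runIMRF2()], [runDeng()],
#' [buildPriors()], [leaveOneOut()], [rocAuc()], [makeBenchmark()].
#'
#' @keywords internal
"_PACKAGE"

#' Write a reproducibility manifest next to an output artifact
#'
#' Records input file checksums, the effective configuration, seed and
#' package version as JSON so any artifact can be regenerated from its
#' manifest alone.
#'
#' @param path manifest file path (JSON).
#' @param inputs character vector of input file paths (checksummed).
#' @param config named list of effective configuration values.
#' @param seed integer seed used.
#' @return the manifest list, invisibly.
#' @export
writeManifest <- function(path, inputs = character(0), config = list(),
                          seed = NA_integer_) {
    manifest <- list(
        package = "MRFGeneRank",
        version = as.character(utils::packageVersion("MRFGeneRank")),
        seed = seed,
        config = config,
        inputs = as.list(stats::setNames(
            unname(tools::md5sum(inputs)), basename(inputs))))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(manifest)
}
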