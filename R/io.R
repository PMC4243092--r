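.splitFields <- function(lines) strsplit(lines, "[\t ]+")

#' Read a gene-gene edge list
#'
#' Reads a delimited text file (TSV or SIF-like; columns 1-2 are the
#' endpoints, extra columns such as weights or relation types are ignored).
#' Self-loops are deleted and duplicate undirected edges collapsed, the
#' standard cleaning applied to interaction databases.
#'
#' @param path file path.
#' @param universe a [GeneUniverse-class], or `NULL` to build one from the
#'   file's symbols.
#' @param universePolicy `"grow"` extends the universe with unseen symbols;
#'   `"strict"` treats them as an error.
#' @param name network label; defaults to the file name.
#' @return A [BioNetwork-class] (its universe possibly extended).
#' @export
readEdgeList <- function(path, universe = NULL,
                         universePolicy = c("grow", "strict"),
                         name = basename(path)) {
    universePolicy <- match.arg(universePolicy)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- .splitFields(trimws(lines))
    nf <- lengths(fields)
    if (any(nf < 2L)) {
        stop("malformed edge line ", which(nf < 2L)[1L], " in ", path,
             ": need at least two columns")
    }
    from <- vapply(fields, `[`, character(1), 1L)
    to <- vapply(fields, `[`, character(1), 2L)
    symbols <- unique(c(from, to))
    if (is.null(universe)) {
        if (length(symbols) == 0L) {
            stop("empty edge list and no universe given: cannot build one")
        }
        universe <- GeneUniverse(symbols)
    }
    known <- symbols %in% universe@genes
    if (any(!known)) {
        if (universePolicy == "strict") {
            stop("unknown gene symbol(s) under strict policy: ",
                 paste(utils::head(symbols[!known], 5), collapse = ", "))
        }
        universe <- GeneUniverse(c(universe@genes, symbols[!known]))
    }
    if (length(from) == 0L) {
        return(BioNetwork(name, matrix(integer(0), ncol = 2L), universe))
    }
    BioNetwork(name, cbind(match(from, universe@genes), match(to, universe@genes)),
               universe)
}

#' Write a network as a two-column edge list
#'
#' Writes the canonical edge set (one undirected edge per line, endpoints
#' as gene symbols, tab-separated). Reading the file back reproduces the
#' same canonical edge set.
#'
#' @param network a [BioNetwork-class].
#' @param path output file path.
#' @export
writeEdgeList <- function(network, path) {
    g <- network@universe@genes
    e <- network@edges
    writeLines(paste(g[e[, 1L]], g[e[, 2L]], sep = "\t"), path)
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`; members
#' are deduplicated, first-occurrence order preserved.
#'
#' @param path file path.
#' @return Named list of character vectors of gene symbols, in file order.
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L)) {
        stop("malformed GMT line ", which(nf < 3L)[1L], " in ", path,
             ": need name, description and at least one member")
    }
    sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
    names(sets) <- vapply(fields, `[`, character(1), 1L)
    sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors (or integer indices resolved
#'   against `universe`).
#' @param path output file path.
#' @param universe optional [GeneUniverse-class] used to resolve indices.
#' @export
writeGeneSets <- function(sets, path, universe = NULL) {
    lines <- vapply(seq_along(sets), function(i) {
        members <- sets[[i]]
        if (!is.character(members)) members <- universe@genes[members]
        paste(c(names(sets)[i], "na", members), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read gene-disease class associations
#'
#' Two-column TSV (gene, disease class). Genes absent from the universe are
#' dropped; a warning reports how many.
#'
#' @param path file path.
#' @param universe a [GeneUniverse-class].
#' @return A [DiseaseAssociationTable-class].
#' @export
readAssociations <- function(path, universe) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
        return(DiseaseAssociationTable(list(), universe))
    }
    fields <- .splitFields(trimws(lines))
    nf <- lengths(fields)
    if (any(nf < 2L)) {
        stop("malformed association line ", which(nf < 2L)[1L], " in ", path)
    }
    gene <- vapply(fields, `[`, character(1), 1L)
    cls <- vapply(fields, `[`, character(1), 2L)
    if (any(!nzchar(cls))) {
        stop("empty disease class name at line ", which(!nzchar(cls))[1L])
    }
    idx <- match(gene, universe@genes)
    dropped <- sum(is.na(idx))
    if (dropped > 0L) {
        warning(dropped, " association(s) to genes outside the universe dropped")
    }
    keep <- !is.na(idx)
    classes <- split(idx[keep], cls[keep])
    DiseaseAssociationTable(classes, universe)
}

#' Read a gene x sample expression matrix
#'
#' TSV with a header line; first column gene symbol, remaining columns
#' samples. Rows with missing values are rejected (dropped with a warning).
#'
#' @param path file path.
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1L]])
    bad <- apply(m, 1L, anyNA)
    if (any(bad)) {
        warning(sum(bad), " expression row(s) with missing values rejected")
        m <- m[!bad, , drop = FALSE]
    }
    ExpressionMatrix(m)
}

#' Write a ranked prediction table
#'
#' TSV with columns `gene`, `known_flag`, `prior`, `posterior`,
#' `decision_score`, sorted by decision score descending with a
#' deterministic lexicographic tie-break on the gene symbol. Known
#' (clamped) genes are reported with posterior 1 and decision score 1.
#'
#' @param result a [SamplerResult-class].
#' @param path output file path.
#' @return The ranking data frame, invisibly.
#' @export
writeRanking <- function(result, path) {
    df <- rankingTable(result)
    con <- file(path, open = "wt")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Assemble the ranking table of a sampler result
#'
#' @inheritParams writeRanking
#' @return data.frame with gene, known_flag, prior, posterior,
#'   decision_score, ordered by decision score (desc), gene symbol (asc).
#' @export
rankingTable <- function(result) {
    g <- result@universe@genes
    score <- numeric(length(g))
    free <- !result@known
    if (any(free)) score[free] <- decisionScores(result@posterior[free])
    score[result@known] <- 1
    df <- data.frame(gene = g, known_flag = as.integer(result@known),
                     prior = result@prior, posterior = result@posterior,
                     decision_score = score, stringsAsFactors = FALSE)
    df[order(-df$decision_score, df$gene), , drop = FALSE]
}
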