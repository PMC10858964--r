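## Score-weighted network assembly and local over-representation
## enrichment. Interaction retrieval and graph layout are out of scope:
## the module consumes any 3-column edge list (gene_a, gene_b, weight).

#' Assemble a score-weighted gene network
#'
#' Nodes are the given genes weighted by final score (isolated nodes are
#' retained); edges are the input interactions with both endpoints in the
#' gene list, weighted by the mean of the two endpoints' experiment scores
#' multiplied by the supplied interaction weight.
#'
#' @param scores a \linkS4class{ScoreTable} covering \code{genes}.
#' @param genes character vector of node genes.
#' @param edges data.frame(from, to, weight) of interactions.
#' @param condition condition label.
#' @param combine how an edge weight is formed from the two endpoint
#'   experiment scores and the interaction weight (default: their mean
#'   times the interaction weight).
#' @return A \linkS4class{GeneNetwork}.
#' @export
buildNetwork <- function(scores, genes, edges, condition = "condition",
                         combine = function(expA, expB, w)
                             (expA + expB) / 2 * w) {
    stopifnot(is(scores, "ScoreTable"))
    genes <- unique(normSymbols(genes))
    fin <- finalScores(scores)
    missing <- setdiff(genes, names(fin))
    if (length(missing))
        stop("gene(s) absent from score table: ",
             paste(utils::head(missing, 3L), collapse = ", "))
    nodes <- data.frame(gene = genes, weight = unname(fin[genes]))
    exps <- experimentScores(scores)
    keep <- edges$from %in% genes & edges$to %in% genes
    ed <- edges[keep, , drop = FALSE]
    w <- if (nrow(ed))
        mapply(combine, exps[ed$from], exps[ed$to], ed$weight) else numeric()
    ed <- data.frame(from = ed$from, to = ed$to, weight = as.numeric(w))
    rownames(ed) <- NULL
    new("GeneNetwork", nodes = nodes, edges = ed, condition = condition)
}

#' Hypergeometric over-representation enrichment
#'
#' For each gene set (intersected with the universe first), the upper-tail
#' hypergeometric probability of observing at least the realized overlap
#' between the query and the set, with Benjamini-Hochberg adjustment across
#' the tested sets. Sets with zero universe overlap are skipped. The
#' adjusted value plays the role of the E-value threshold used for
#' pathway/ontology enrichment calls.
#'
#' @param query character vector of query genes (must lie in the universe).
#' @param sets named list of character vectors.
#' @param universe character vector of background genes.
#' @param adjust multiplicity adjustment method (see
#'   \code{\link[stats]{p.adjust}}).
#' @return data.frame with one row per tested set: \code{set},
#'   \code{overlap}, \code{setSize}, \code{querySize}, \code{universeSize},
#'   \code{p}, \code{adjusted}, \code{genes} (comma-separated overlap).
#' @export
oraEnrich <- function(query, sets, universe, adjust = "BH") {
    query <- unique(normSymbols(query))
    universe <- unique(normSymbols(universe))
    if (!length(query)) stop("empty query")
    if (!length(universe)) stop("empty universe")
    stray <- setdiff(query, universe)
    if (length(stray))
        stop("query gene(s) outside the universe: ",
             paste(utils::head(stray, 3L), collapse = ", "))
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(sets), function(nm) {
        s <- intersect(unique(normSymbols(sets[[nm]])), universe)
        if (!length(s)) return(NULL)
        ov <- intersect(query, s)
        k <- length(ov)
        ## P(X >= k), X ~ Hypergeom(N, |s|, n)
        p <- stats::phyper(k - 1L, length(s), N - length(s), n,
                           lower.tail = FALSE)
        data.frame(set = nm, overlap = k, setSize = length(s),
                   querySize = n, universeSize = N, p = p,
                   genes = paste(sort(ov), collapse = ","))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(set = character(), overlap = integer(),
                          setSize = integer(), querySize = integer(),
                          universeSize = integer(), p = numeric(),
                          adjusted = numeric(), genes = character()))
    res <- do.call(rbind, rows)
    res$adjusted <- stats::p.adjust(res$p, method = adjust)
    res <- res[order(res$p), c("set", "overlap", "setSize", "querySize",
                               "universeSize", "p", "adjusted", "genes")]
    rownames(res) <- NULL
    res
}

#' Write a network as node and edge TSV tables
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param nodePath,edgePath output TSV paths.
#' @return Invisibly, \code{c(nodePath, edgePath)}.
#' @export
writeNetworkTSV <- function(network, nodePath, edgePath) {
    utils::write.table(networkNodes(network), nodePath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(networkEdges(network), edgePath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(c(nodePath, edgePath))
}
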