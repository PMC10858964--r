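## Tabular IO: series-matrix-style expression TSV with a sample-metadata
## sidecar, GMT gene sets, 3-column edge lists, 2-column evidence tables.
## All files are UTF-8, tab-delimited, '.' decimal.

#' Read an expression TSV with its sample metadata sidecar
#'
#' The expression file has a header row of sample identifiers and gene
#' symbols in the first column; the metadata file maps sample identifier to
#' clinical group and batch.
#'
#' @param path expression TSV (first column gene symbol, then one numeric
#'   column per sample).
#' @param metadataPath TSV with columns \code{sample}, \code{group},
#'   \code{batch}.
#' @return An \linkS4class{ExpressionDataset}; row order is preserved.
#' @export
readExpressionTSV <- function(path, metadataPath) {
    raw <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 2L) stop("expression file needs a gene column and at least one sample")
    genes <- normSymbols(raw[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene identifiers in ", path, ": ",
             paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
    samples <- colnames(raw)[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample identifiers in ", path)
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
        v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
        bad <- which(!is.finite(v))
        if (length(bad))
            stop(sprintf("non-numeric or non-finite value for gene '%s', sample '%s' in %s",
                         genes[bad[1L]], samples[j], path))
        m[, j] <- v
    }
    meta <- utils::read.delim(metadataPath, colClasses = "character")
    need <- c("sample", "group", "batch")
    if (!all(need %in% colnames(meta)))
        stop("metadata must have columns sample, group, batch")
    if (anyDuplicated(meta$sample)) stop("duplicate sample in metadata")
    unknown <- setdiff(meta$sample, samples)
    if (length(unknown))
        stop("metadata lists unknown sample(s): ",
             paste(unknown, collapse = ", "))
    missing <- setdiff(samples, meta$sample)
    if (length(missing))
        stop("metadata is missing sample(s): ",
             paste(missing, collapse = ", "))
    meta <- meta[match(samples, meta$sample), ]
    ExpressionDataset(m, group = meta$group, batch = meta$batch)
}

#' Write an expression dataset and its sample metadata sidecar
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param path,metadataPath output TSV paths.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionTSV <- function(dataset, path, metadataPath) {
    m <- exprsValues(dataset)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- data.frame(sample = colnames(m),
                       group = unname(sampleGroups(dataset)),
                       batch = unname(sampleBatches(dataset)))
    utils::write.table(meta, metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Collapse probe-level rows to gene symbols
#'
#' Probes mapping to no symbol are dropped (their count is reported in a
#' message and in \code{attr(result, "droppedProbes")}). With
#' \code{method = "mean"} probes of one symbol are averaged per sample;
#' with \code{method = "max-variance"} the single most variable probe's row
#' is kept verbatim.
#'
#' @param dataset probe-level \linkS4class{ExpressionDataset}.
#' @param probeToGene named character vector (names = probe identifiers,
#'   values = gene symbols) or two-column data.frame(probe, symbol).
#' @param method summarization rule.
#' @return A gene-level \linkS4class{ExpressionDataset} with attribute
#'   \code{droppedProbes}.
#' @export
collapseProbes <- function(dataset, probeToGene,
                           method = c("mean", "max-variance")) {
    method <- match.arg(method)
    if (is.data.frame(probeToGene))
        probeToGene <- setNames(as.character(probeToGene[[2L]]),
                                as.character(probeToGene[[1L]]))
    if (!length(probeToGene)) stop("probe-to-gene mapping is empty")
    m <- exprsValues(dataset)
    sym <- normSymbols(probeToGene[rownames(m)])
    keep <- !is.na(sym) & nzchar(sym)
    dropped <- sum(!keep)
    if (dropped) message(dropped, " unmapped probe(s) dropped")
    m <- m[keep, , drop = FALSE]
    sym <- sym[keep]
    if (!nrow(m)) stop("no probes left after mapping")
    collapsed <- switch(method,
        "mean" = {
            rowsum(m, sym, reorder = FALSE) /
                as.vector(table(factor(sym, levels = unique(sym))))
        },
        "max-variance" = {
            pick <- vapply(split(seq_along(sym), sym)[unique(sym)],
                           function(idx) idx[which.max(
                               apply(m[idx, , drop = FALSE], 1L, stats::var))],
                           integer(1))
            out <- m[pick, , drop = FALSE]
            rownames(out) <- names(pick)
            out
        })
    res <- ExpressionDataset(collapsed,
                             group = unname(sampleGroups(dataset)),
                             batch = unname(sampleBatches(dataset)))
    attr(res, "droppedProbes") <- dropped
    res
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields tab-separated -- set name,
#' description, then member gene symbols.
#'
#' @param path GMT file.
#' @return Named list of character vectors; descriptions in
#'   \code{attr(, "descriptions")}.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list(); descs <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("malformed GMT line ", i, ": need name, description and at least one gene")
        nm <- f[1L]
        if (nm %in% names(sets)) stop("duplicate set name at line ", i, ": ", nm)
        sets[[nm]] <- unique(normSymbols(f[-(1:2)]))
        descs[nm] <- f[2L]
    }
    attr(sets, "descriptions") <- descs
    sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set descriptions.
#' @return Invisibly, \code{path}.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- setNames(rep("na", length(sets)), names(sets))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a 3-column interaction edge list
#'
#' Columns: gene_a, gene_b, weight (non-negative). Self-loops are rejected;
#' duplicate edges (in either orientation) are merged keeping the maximum
#' weight.
#'
#' @param path TSV with a header row.
#' @return data.frame(from, to, weight), one row per unordered pair.
#' @export
readEdgeTSV <- function(path) {
    df <- utils::read.delim(path)
    if (ncol(df) < 3L) stop("edge file needs 3 columns: gene_a, gene_b, weight")
    edges <- data.frame(from = normSymbols(df[[1L]]),
                        to = normSymbols(df[[2L]]),
                        weight = as.numeric(df[[3L]]))
    bad <- which(!is.finite(edges$weight) | edges$weight < 0)
    if (length(bad))
        stop("invalid edge weight at line ", bad[1L] + 1L)
    loops <- which(edges$from == edges$to)
    if (length(loops))
        stop("self-loop at line ", loops[1L] + 1L, ": ", edges$from[loops[1L]])
    mergeEdges(edges)
}

#' Merge duplicate undirected edges keeping the maximum weight
#' @param edges data.frame(from, to, weight).
#' @return data.frame with one row per unordered pair.
#' @export
mergeEdges <- function(edges) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste(a, b, sep = "\r")
    w <- tapply(edges$weight, key, max)
    parts <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    out <- data.frame(from = parts[, 1L], to = parts[, 2L],
                      weight = as.numeric(w))
    rownames(out) <- NULL
    out[order(out$from, out$to), , drop = FALSE]
}

#' Write an edge list as a 3-column TSV
#' @param edges data.frame(from, to, weight).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeTSV <- function(edges, path) {
    utils::write.table(
        data.frame(gene_a = edges$from, gene_b = edges$to,
                   weight = edges$weight),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a 2-column evidence table
#'
#' Column 1: gene symbol; column 2: non-negative value (a literature report
#' count or a DisGeNET score).
#'
#' @param path TSV with a header row.
#' @return Named numeric vector.
#' @export
readEvidenceTSV <- function(path) {
    df <- utils::read.delim(path)
    if (ncol(df) < 2L) stop("evidence file needs 2 columns: gene, value")
    g <- normSymbols(df[[1L]])
    v <- as.numeric(df[[2L]])
    if (anyDuplicated(g))
        stop("duplicate gene symbol in ", path, ": ", g[duplicated(g)][1L])
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
        stop("negative or non-numeric value at line ", bad[1L] + 1L,
             " (gene ", g[bad[1L]], ")")
    setNames(v, g)
}

#' Write an evidence table as a 2-column TSV
#' @param values named numeric vector.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEvidenceTSV <- function(values, path) {
    utils::write.table(
        data.frame(gene = names(values), value = unname(values)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
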