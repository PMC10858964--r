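## High-score gene profiles and heatmap-ready fold matrices.

#' Select a high-score gene profile
#'
#' Genes with final score strictly greater than the threshold, sorted by
#' descending score; the selection rule is recorded in the profile.
#'
#' @param scores a \linkS4class{ScoreTable} or a named numeric score
#'   vector.
#' @param threshold score threshold (strict \code{>}).
#' @param condition condition label, e.g. \code{"STEMI"}.
#' @param folds optional named per-gene folds to carry along (defaults to
#'   NA per gene).
#' @param scoreType label of the score the threshold applies to.
#' @return A \linkS4class{GeneProfile}.
#' @export
selectProfile <- function(scores, threshold, condition = "condition",
                          folds = NULL, scoreType = "final") {
    v <- if (is(scores, "ScoreTable")) finalScores(scores) else scores
    if (!is.finite(threshold) && threshold > 0)
        stop("threshold must be finite or -Inf")
    keep <- v > threshold
    if (!any(keep)) warning("no gene exceeds the score threshold")
    sel <- sort(v[keep], decreasing = TRUE)
    fv <- if (is.null(folds)) setNames(rep(NA_real_, length(sel)), names(sel))
          else folds[names(sel)]
    new("GeneProfile", condition = condition, genes = names(sel),
        scores = unname(sel), folds = unname(fv),
        rule = list(scoreType = scoreType, threshold = threshold),
        level = "")
}

#' Fold-level sub-profile of a gene profile
#'
#' Members of the profile with fold strictly greater than
#' \code{foldThreshold}; the level tag records the rule.
#'
#' @param profile a non-empty \linkS4class{GeneProfile}.
#' @param foldThreshold fold threshold (strict \code{>}).
#' @return A \linkS4class{GeneProfile} tagged
#'   \code{"fold > <threshold> sub-profile"}.
#' @export
subProfileByFold <- function(profile, foldThreshold = 0.4) {
    stopifnot(is(profile, "GeneProfile"))
    if (!length(profile@genes)) stop("profile is empty")
    keep <- !is.na(profile@folds) & profile@folds > foldThreshold
    new("GeneProfile", condition = profile@condition,
        genes = profile@genes[keep], scores = profile@scores[keep],
        folds = profile@folds[keep], rule = profile@rule,
        level = sprintf("fold > %g sub-profile", foldThreshold))
}

#' Heatmap-ready fold matrix for a high/low selection
#'
#' Rows are the high genes (descending fold in the first contrast) followed
#' by the low genes (ascending); ties break lexicographically by gene
#' symbol. Columns are the contrasts in caller order; a gene missing from a
#' fold table gives an NA cell, counted in \code{attr(, "missingCells")}.
#'
#' @param selection a \linkS4class{HighLowSelection}.
#' @param foldTables list of \linkS4class{FoldTable}s; the first is used
#'   for the row ordering.
#' @param path optional TSV export path.
#' @return Numeric matrix (genes x contrasts).
#' @export
heatmapMatrix <- function(selection, foldTables, path = NULL) {
    stopifnot(is(selection, "HighLowSelection"), length(foldTables) >= 1L)
    ref <- foldValues(foldTables[[1L]])
    ordStrict <- function(genes, decreasing) {
        f <- ref[genes]
        ## lexicographic symbol order breaks fold ties deterministically
        genes[order(f, genes, decreasing = c(decreasing, FALSE),
                    method = "radix")]
    }
    rows <- c(ordStrict(highGenes(selection), TRUE),
              ordStrict(lowGenes(selection), FALSE))
    m <- vapply(foldTables, function(ft) foldValues(ft)[rows],
                numeric(length(rows)))
    m <- matrix(m, nrow = length(rows),
                dimnames = list(rows, vapply(foldTables, contrastName,
                                             character(1))))
    attr(m, "missingCells") <- sum(is.na(m))
    if (!is.null(path)) {
        utils::write.table(data.frame(gene = rows, m, check.names = FALSE),
                           path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    m
}
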