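## The fold statistic and the three-layer score algebra.
##
## The per-gene fold for a case-vs-control contrast is
##   sum(GEV_case - mu_control)/n_case - sum(GEV_control - mu_control)/n_control
## on the log-scale merged matrix; the second term vanishes analytically
## (mu_control is the mean of the same control samples), so the fold equals
## mean(case) - mean(control). Both forms are implemented and must agree.

#' Per-gene fold for a case-vs-control contrast
#'
#' @param dataset an \linkS4class{ExpressionDataset} containing both groups.
#' @param caseGroup,controlGroup group labels.
#' @param form evaluate the centered-sum form literally
#'   (\code{"literal"}) or the algebraically equivalent difference of
#'   group means (\code{"mean-difference"}, default).
#' @return A \linkS4class{FoldTable} named \code{"<case>-vs-<control>"}.
#' @export
geneFold <- function(dataset, caseGroup, controlGroup = "control",
                     form = c("mean-difference", "literal")) {
    form <- match.arg(form)
    grp <- unname(sampleGroups(dataset))
    caseIdx <- which(grp == caseGroup)
    ctlIdx <- which(grp == controlGroup)
    if (!length(caseIdx)) stop("no samples in case group '", caseGroup, "'")
    if (!length(ctlIdx))
        stop("no samples in control group '", controlGroup, "'")
    if (length(caseIdx) < 2L || length(ctlIdx) < 2L)
        warning("a group has a single sample; folds have no replication")
    m <- exprsValues(dataset)
    if (!nrow(m)) stop("empty gene universe")
    caseM <- m[, caseIdx, drop = FALSE]
    ctlM <- m[, ctlIdx, drop = FALSE]
    folds <- if (form == "mean-difference") {
        rowMeans(caseM) - rowMeans(ctlM)
    } else {
        muCtl <- rowMeans(ctlM)
        rowSums(caseM - muCtl) / length(caseIdx) -
            rowSums(ctlM - muCtl) / length(ctlIdx)
    }
    FoldTable(setNames(as.numeric(folds), rownames(m)),
              contrast = paste0(caseGroup, "-vs-", controlGroup))
}

#' Expression score: primary fold plus average enrichment fold
#'
#' Per gene: the fold in the primary merged data plus the arithmetic mean
#' of its folds over the enrichment fold tables in which it appears (with
#' full coverage over three tables this is the primary fold + sum/3). Genes
#' absent from every enrichment table keep the primary fold and are flagged
#' \code{"none"}; partial coverage is flagged \code{"partial"}.
#'
#' @param primaryFold \linkS4class{FoldTable} from the primary merged data.
#' @param enrichmentFolds list of at least one \linkS4class{FoldTable} from
#'   the enrichment datasets.
#' @return Named numeric vector over the primary fold's gene universe, with
#'   attribute \code{coverage} (per-gene \code{"full"}/\code{"partial"}/
#'   \code{"none"}).
#' @export
expressionScore <- function(primaryFold, enrichmentFolds) {
    stopifnot(is(primaryFold, "FoldTable"))
    if (!length(enrichmentFolds))
        stop("need at least one enrichment fold table")
    genes <- names(primaryFold)
    extra <- setdiff(unique(unlist(lapply(enrichmentFolds, names))), genes)
    if (length(extra))
        message(length(extra),
                " enrichment-only gene(s) excluded (absent from primary folds)")
    hits <- vapply(enrichmentFolds, function(ft)
        foldValues(ft)[genes], numeric(length(genes)))
    hits <- matrix(hits, nrow = length(genes))
    nAvail <- rowSums(!is.na(hits))
    avg <- ifelse(nAvail > 0, rowSums(hits, na.rm = TRUE) / pmax(nAvail, 1), 0)
    score <- foldValues(primaryFold) + avg
    coverage <- ifelse(nAvail == length(enrichmentFolds), "full",
                       ifelse(nAvail > 0, "partial", "none"))
    attr(score, "coverage") <- setNames(coverage, genes)
    score
}

#' Experiment score: DisGeNET score plus normalized text-mining score
#'
#' The literature report counts are normalized onto the DisGeNET score
#' range: text-mining score = (report count / maximum report count) x
#' (maximum DisGeNET score in the table). The experiment score is the
#' DisGeNET score plus the text-mining score; a gene absent from a table
#' contributes 0 from it (union universe, flagged).
#'
#' @param reportCounts named non-negative vector of literature report
#'   counts.
#' @param disgenet named vector of DisGeNET scores in [0, 1].
#' @return Named numeric vector over the union universe, with attributes
#'   \code{textMining}, \code{disgenetScore} (the per-gene components) and
#'   \code{missing} (per-gene \code{"none"}/\code{"reports"}/
#'   \code{"disgenet"}).
#' @export
experimentScore <- function(reportCounts, disgenet) {
    if (any(reportCounts < 0)) stop("report counts must be non-negative")
    if (any(disgenet < 0 | disgenet > 1))
        stop("DisGeNET scores must lie in [0, 1]")
    names(reportCounts) <- normSymbols(names(reportCounts))
    names(disgenet) <- normSymbols(names(disgenet))
    genes <- sort(union(names(reportCounts), names(disgenet)))
    counts <- setNames(rep(0, length(genes)), genes)
    counts[names(reportCounts)] <- reportCounts
    dg <- setNames(rep(0, length(genes)), genes)
    dg[names(disgenet)] <- disgenet
    maxCount <- if (length(reportCounts)) max(reportCounts) else 0
    maxDG <- if (length(disgenet)) max(disgenet) else 0
    text <- if (maxCount > 0) counts / maxCount * maxDG
            else setNames(rep(0, length(genes)), genes)
    score <- dg + text
    missing <- ifelse(!genes %in% names(reportCounts),
                      ifelse(!genes %in% names(disgenet), "both", "reports"),
                      ifelse(!genes %in% names(disgenet), "disgenet", "none"))
    attr(score, "textMining") <- text
    attr(score, "disgenetScore") <- dg
    attr(score, "missing") <- setNames(missing, genes)
    score
}

#' Final score table: experiment score plus expression score
#'
#' Assembles the full \linkS4class{ScoreTable} over the union of the two
#' gene universes; a gene missing from one side contributes 0 from it and
#' is flagged.
#'
#' @param experiment named vector from \code{\link{experimentScore}} (its
#'   \code{textMining}/\code{disgenetScore} attributes, when present, are
#'   carried into the table).
#' @param expression named vector from \code{\link{expressionScore}}.
#' @return A \linkS4class{ScoreTable}.
#' @export
finalScore <- function(experiment, expression) {
    genes <- sort(union(names(experiment), names(expression)))
    pick <- function(v, default = 0) {
        out <- setNames(rep(default, length(genes)), genes)
        out[names(v)] <- v
        out
    }
    expMiss <- !genes %in% names(experiment)
    exprMiss <- !genes %in% names(expression)
    tm <- attr(experiment, "textMining")
    dg <- attr(experiment, "disgenetScore")
    expv <- pick(experiment)
    if (is.null(tm) || is.null(dg)) {
        tm <- expv          # component split unknown: book it as text mining
        dg <- setNames(rep(0, length(genes)), genes)
    } else {
        tm <- pick(tm); dg <- pick(dg)
    }
    exprv <- pick(expression)
    df <- data.frame(textMining = unname(tm), disgenet = unname(dg),
                     experiment = unname(expv), expression = unname(exprv),
                     final = unname(expv + exprv),
                     experimentMissing = unname(expMiss),
                     expressionMissing = unname(exprMiss),
                     row.names = genes)
    new("ScoreTable", scores = df)
}

#' Select high- and low-fold genes by percentile
#'
#' High genes have fold strictly greater than the \code{hiPct}-th
#' percentile of the fold distribution; low genes strictly below the
#' \code{loPct}-th. Percentiles use linear interpolation between closest
#' order statistics (quantile type 7); the realized cutoffs are recorded in
#' the result.
#'
#' @param folds a \linkS4class{FoldTable} (or named numeric vector).
#' @param hiPct,loPct percentile levels on the 0-100 scale.
#' @return A \linkS4class{HighLowSelection}.
#' @export
selectPercentileGenes <- function(folds, hiPct = 99.5, loPct = 0.25) {
    v <- if (is(folds, "FoldTable")) foldValues(folds) else folds
    if (length(v) < 10L) stop("need at least 10 genes")
    if (hiPct <= loPct) stop("hiPct must exceed loPct")
    hiCut <- pctCutoff(v, hiPct)
    loCut <- pctCutoff(v, loPct)
    high <- names(v)[v > hiCut]
    low <- names(v)[v < loCut]
    if (!length(high) && !length(low))
        warning("constant or degenerate fold vector: empty selection")
    new("HighLowSelection", high = high, low = low,
        hiPct = hiPct, loPct = loPct, hiCutoff = hiCut, loCutoff = loCut)
}

#' Filter genes by score centile
#'
#' Genes whose score is strictly above (or below) the given rank centile of
#' the score distribution, using the same linear-interpolation percentile
#' convention as \code{\link{selectPercentileGenes}}.
#'
#' @param scores named numeric vector (e.g. expression or final scores; the
#'   caller chooses which score the centile applies to).
#' @param centile centile level on the 0-100 scale.
#' @param side keep genes strictly above or strictly below the cutoff.
#' @return Character vector of gene symbols.
#' @export
centileFilter <- function(scores, centile = 25,
                          side = c("above", "below")) {
    side <- match.arg(side)
    if (!length(scores)) stop("empty score vector")
    ## boundary convention: nothing lies strictly beyond the extreme
    ## percentiles, so centile 0 (above) / 100 (below) keep every gene
    if ((centile <= 0 && side == "above") ||
        (centile >= 100 && side == "below"))
        return(names(scores))
    cut <- pctCutoff(scores, centile)
    keep <- if (side == "above") scores > cut else scores < cut
    if (!any(keep) && length(unique(scores)) == 1L)
        warning("all scores tied: no strict exceedance")
    names(scores)[keep]
}
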