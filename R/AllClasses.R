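#' @import methods
#' @importFrom stats quantile rnorm runif rpois sd var pnorm pt phyper p.adjust
#' @importFrom utils read.delim write.table head
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## ------------------------------------------------------------------------
## Expression containers
## ------------------------------------------------------------------------

#' Gene-by-sample log-scale expression dataset
#'
#' An \linkS4class{SummarizedExperiment} holding one assay (\code{"exprs"}) of
#' finite log-scale expression values, with the per-sample clinical group
#' (\code{control}, \code{STEMI}, \code{NSTEMI}, \code{day7}, \code{day30},
#' \code{MI}) and batch label in \code{colData}.
#'
#' @slot .. see \code{\link[SummarizedExperiment]{SummarizedExperiment}}.
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

.validExpressionDataset <- function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        m <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(m))
            msg <- c(msg, "expression values must be numeric")
        else if (any(!is.finite(m)))
            msg <- c(msg, "expression values must all be finite")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("group", "batch") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'group' and 'batch'")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionDataset", .validExpressionDataset)

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes in rows, samples in columns
#'   (log-scale expression).
#' @param group character vector, one clinical group label per sample.
#' @param batch vector, one batch label per sample.
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("MMP9", "CA1"), paste0("s", 1:3)))
#' ExpressionDataset(m, group = c("control", "control", "STEMI"), batch = 1)
#' @export
ExpressionDataset <- function(values, group, batch = 1L) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (length(batch) == 1L) batch <- rep(batch, ncol(values))
    if (length(group) != ncol(values))
        stop("'group' must have one label per sample")
    if (length(batch) != ncol(values))
        stop("'batch' must have one label per sample")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(group = as.character(group),
                                       batch = as.character(batch),
                                       row.names = colnames(values)))
    new("ExpressionDataset", se)
}

#' Merged multi-study expression dataset
#'
#' An \linkS4class{ExpressionDataset} whose batch labels identify the source
#' datasets; \code{sources} records their names in merge order.
#'
#' @slot sources character vector of source dataset names.
#' @export
setClass("MergedDataset", contains = "ExpressionDataset",
         representation(sources = "character"))

## ------------------------------------------------------------------------
## Fold and score tables
## ------------------------------------------------------------------------

#' Per-gene fold table for a named contrast
#'
#' Holds the per-gene fold statistic (difference between case and control
#' group mean expression on the log scale) for one case-vs-control contrast.
#'
#' @slot contrast single string, e.g. \code{"STEMI-vs-control"}.
#' @slot folds named numeric vector of finite fold values, one per gene.
#' @export
setClass("FoldTable",
         representation(contrast = "character", folds = "numeric"))

setValidity("FoldTable", function(object) {
    msg <- NULL
    if (length(object@contrast) != 1L)
        msg <- c(msg, "'contrast' must be a single string")
    if (is.null(names(object@folds)) || anyDuplicated(names(object@folds)))
        msg <- c(msg, "folds must be uniquely named by gene symbol")
    if (any(!is.finite(object@folds)))
        msg <- c(msg, "fold values must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Construct a FoldTable
#' @param folds named numeric vector of per-gene folds.
#' @param contrast contrast name.
#' @export
FoldTable <- function(folds, contrast = "case-vs-control") {
    new("FoldTable", contrast = contrast, folds = folds)
}

#' Per-gene evidence score table
#'
#' Per gene: the text-mining score, the DisGeNET clinical-trial score, the
#' experiment score (their sum), the expression score (primary fold plus the
#' average enrichment fold) and the final score (experiment + expression).
#' Evidence missing from a source contributes 0 and is flagged, never
#' dropped, so the table covers the union gene universe.
#'
#' @slot scores data.frame with row names = gene symbols and columns
#'   \code{textMining}, \code{disgenet}, \code{experiment},
#'   \code{expression}, \code{final}, \code{experimentMissing},
#'   \code{expressionMissing}.
#' @export
setClass("ScoreTable", representation(scores = "data.frame"))

setValidity("ScoreTable", function(object) {
    df <- object@scores
    need <- c("textMining", "disgenet", "experiment", "expression", "final",
              "experimentMissing", "expressionMissing")
    msg <- NULL
    if (!all(need %in% colnames(df)))
        msg <- c(msg, paste("score table needs columns:",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(rownames(df)))
            msg <- c(msg, "gene symbols must be unique")
        if (max(abs(df$experiment - df$textMining - df$disgenet)) > 1e-12)
            msg <- c(msg, "experiment score must equal textMining + disgenet")
        if (max(abs(df$final - df$experiment - df$expression)) > 1e-12)
            msg <- c(msg, "final score must equal experiment + expression")
    }
    if (is.null(msg)) TRUE else msg
})

#' High/low percentile gene selection
#'
#' Result of the percentile rule used for the fold heatmaps: genes with fold
#' strictly above the upper percentile cutoff and strictly below the lower
#' one, together with the percentile levels requested and the realized fold
#' cutoffs, so the selection is auditable.
#'
#' @slot high,low character vectors of selected gene symbols (disjoint).
#' @slot hiPct,loPct percentile levels requested (0-100 scale).
#' @slot hiCutoff,loCutoff realized fold cutoffs (linear-interpolation
#'   order statistics).
#' @export
setClass("HighLowSelection",
         representation(high = "character", low = "character",
                        hiPct = "numeric", loPct = "numeric",
                        hiCutoff = "numeric", loCutoff = "numeric"))

setValidity("HighLowSelection", function(object) {
    if (length(intersect(object@high, object@low)))
        "high and low selections must be disjoint" else TRUE
})

#' Ordered high-score gene profile
#'
#' An ordered, named gene list for one clinical condition, carrying the
#' per-gene final score and fold and the selection rule that produced it
#' (score type, threshold, optional fold-level tag).
#'
#' @slot condition e.g. \code{"STEMI"} or \code{"NSTEMI"}.
#' @slot genes gene symbols sorted by descending score.
#' @slot scores,folds named numeric vectors aligned with \code{genes}.
#' @slot rule list with \code{scoreType} and \code{threshold}.
#' @slot level optional tag for fold-level sub-profiles.
#' @export
setClass("GeneProfile",
         representation(condition = "character", genes = "character",
                        scores = "numeric", folds = "numeric",
                        rule = "list", level = "character"))

setValidity("GeneProfile", function(object) {
    msg <- NULL
    n <- length(object@genes)
    if (length(object@scores) != n || length(object@folds) != n)
        msg <- c(msg, "scores and folds must align with genes")
    if (n > 1L && any(diff(object@scores) > 1e-12))
        msg <- c(msg, "profile must be sorted by descending score")
    thr <- object@rule$threshold
    if (!is.null(thr) && n && any(object@scores <= thr))
        msg <- c(msg, "all member scores must satisfy the recorded rule")
    if (is.null(msg)) TRUE else msg
})

## ------------------------------------------------------------------------
## Network
## ------------------------------------------------------------------------

#' Score-weighted gene network
#'
#' Undirected network whose nodes are genes weighted by final score and
#' whose edges are weighted by the mean of the two endpoints' experiment
#' scores times the supplied interaction weight.
#'
#' @slot nodes data.frame(gene, weight).
#' @slot edges data.frame(from, to, weight).
#' @slot condition condition label.
#' @export
setClass("GeneNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        condition = "character"))

setValidity("GeneNetwork", function(object) {
    msg <- NULL
    ed <- object@edges
    if (nrow(ed) &&
        !all(c(ed$from, ed$to) %in% object@nodes$gene))
        msg <- c(msg, "every edge endpoint must be a node")
    if (any(!is.finite(object@nodes$weight)) ||
        (nrow(ed) && any(!is.finite(ed$weight))))
        msg <- c(msg, "weights must be finite")
    if (is.null(msg)) TRUE else msg
})

## ------------------------------------------------------------------------
## Sigma-metric machinery
## ------------------------------------------------------------------------

#' Sigma-metric parameters
#'
#' The laboratory quality-control parameters of the total-allowable-error
#' model: TEa = SE + RE with SE = Bias + dSE and RE = CV + dRE, so that
#' TEa = Bias + (dSE + Z) * CV at the stated false-reject probability.
#'
#' @slot tea total allowable error (fold units); may be NA when derived.
#' @slot bias systematic offset (fold units).
#' @slot cv imprecision, scalar or per-gene vector (fold units); > 0.
#' @slot z detection quantile of the false-reject rule (default 1.96,
#'   i.e. Pfr = 5\% two-sided).
#' @slot pfr probability of false reject, in (0, 1).
#' @slot dre random-error increment (default 0).
#' @slot detectionLimit control-limit quantile used for the probability of
#'   error detection Ped (default 3, a 3-SD limit).
#' @export
setClass("SigmaParams",
         representation(tea = "numeric", bias = "numeric", cv = "numeric",
                        z = "numeric", pfr = "numeric", dre = "numeric",
                        detectionLimit = "numeric"))

setValidity("SigmaParams", function(object) {
    msg <- NULL
    if (any(object@cv <= 0)) msg <- c(msg, "CV must be > 0")
    if (object@pfr <= 0 || object@pfr >= 1)
        msg <- c(msg, "Pfr must lie in (0, 1)")
    if (object@z <= 0) msg <- c(msg, "Z must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct sigma-metric parameters
#'
#' @param cv imprecision (scalar or per-gene vector), fold units.
#' @param bias systematic offset, fold units.
#' @param tea total allowable error; \code{NA} when computed from the rounds.
#' @param z detection quantile for false rejects (1.96 at Pfr = 5\%).
#' @param pfr probability of false reject.
#' @param dre random-error increment.
#' @param detectionLimit quantile of the error-detection rule (3-SD default).
#' @return A \linkS4class{SigmaParams} object.
#' @export
sigmaParams <- function(cv, bias = 0, tea = NA_real_, z = 1.96, pfr = 0.05,
                        dre = 0, detectionLimit = 3) {
    new("SigmaParams", tea = tea, bias = bias, cv = cv, z = z, pfr = pfr,
        dre = dre, detectionLimit = detectionLimit)
}

#' Time cut-off search result
#'
#' Per dSE round: the shift applied, the mean shifted fold, the t statistic
#' and two-tailed p-value of the overlap test against the reference (7-day)
#' profile. \code{kStar} is the first round whose overlap is not
#' significant; \code{ped} its probability of error detection; \code{days}
#' the mapped time after myocardial infarction.
#'
#' @slot rounds data.frame(k, shift, meanFold, t, p, significant).
#' @slot kStar integer round index, or NA if never non-significant.
#' @slot ped probability of error detection at kStar.
#' @slot days mapped time in days (NA if unmapped).
#' @slot mappingName name of the day mapping used.
#' @slot alpha significance level used.
#' @export
setClass("CutoffResult",
         representation(rounds = "data.frame", kStar = "integer",
                        ped = "numeric", days = "numeric",
                        mappingName = "character", alpha = "numeric"))

setValidity("CutoffResult", function(object) {
    msg <- NULL
    r <- object@rounds
    if (nrow(r) && !identical(r$k, seq_len(nrow(r)) - 1L))
        msg <- c(msg, "rounds must be consecutive from 0")
    if (nrow(r) && (any(r$p < 0) || any(r$p > 1)))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

## ------------------------------------------------------------------------
## Synthetic data
## ------------------------------------------------------------------------

#' Synthetic study configuration
#'
#' Parameters of the generator: batched group-labelled log-scale expression
#' with per-batch location/scale effects, i.i.d. Gaussian noise and planted
#' additive group effects of known size.
#'
#' @slot nGenes number of genes.
#' @slot groups named integer vector of samples per group; must include
#'   \code{"control"}.
#' @slot nBatches number of batches within the dataset.
#' @slot batchShiftSD SD of the additive per-batch shift (expression units).
#' @slot batchScaleRange length-2 positive range of the multiplicative
#'   per-batch scale.
#' @slot noiseSD SD of the i.i.d. Gaussian noise (expression units).
#' @slot planted data.frame(gene, group, effect): additive effects planted
#'   into samples of the matching group; \code{gene} is a 1-based index
#'   into the gene universe.
#' @slot baselineMean baseline expression level.
#' @slot seed integer RNG seed; every sub-generator derives a child seed
#'   from it.
#' @export
setClass("SynthConfig",
         representation(nGenes = "integer", groups = "integer",
                        nBatches = "integer", batchShiftSD = "numeric",
                        batchScaleRange = "numeric", noiseSD = "numeric",
                        planted = "data.frame", baselineMean = "numeric",
                        seed = "integer"))

setValidity("SynthConfig", function(object) {
    msg <- NULL
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
    if (is.null(names(object@groups)) || !"control" %in% names(object@groups))
        msg <- c(msg, "groups must be named and include 'control'")
    if (any(object@groups < 2L))
        msg <- c(msg, "every generated group needs at least 2 samples")
    if (object@nBatches < 1L) msg <- c(msg, "nBatches must be positive")
    if (length(object@batchScaleRange) != 2L ||
        object@batchScaleRange[1L] <= 0 ||
        diff(object@batchScaleRange) < 0)
        msg <- c(msg, "batchScaleRange must be an increasing positive pair")
    if (any(!is.finite(c(object@batchShiftSD, object@noiseSD,
                         object@baselineMean))) ||
        object@batchShiftSD < 0 || object@noiseSD < 0)
        msg <- c(msg, "noise/shift/baseline parameters must be finite and non-negative")
    pl <- object@planted
    if (nrow(pl)) {
        if (!all(c("gene", "group", "effect") %in% colnames(pl)))
            msg <- c(msg, "planted needs columns gene, group, effect")
        else {
            if (any(pl$gene < 1L) || any(pl$gene > object@nGenes))
                msg <- c(msg, "every planted gene index must lie in the gene universe")
            if (any(!is.finite(pl$effect)))
                msg <- c(msg, "planted effects must be finite")
            if (anyDuplicated(pl[, c("gene", "group")]))
                msg <- c(msg, "at most one planted effect per (gene, group)")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Full synthetic study bundle
#'
#' Emulates the five-dataset design of the study: one acute dataset
#' (control/STEMI/NSTEMI), one follow-up dataset (day7/day30), three
#' enrichment datasets (control/MI), plus report-count, DisGeNET-score,
#' interaction edge-list and gene-set fixtures on the same gene universe,
#' and the planted-effect truth records.
#'
#' @slot acute,followup \linkS4class{ExpressionDataset}s.
#' @slot enrichment named list of three \linkS4class{ExpressionDataset}s.
#' @slot reportCounts,disgenet named numeric vectors (evidence tables).
#' @slot edges data.frame(from, to, weight).
#' @slot geneSets named list of character vectors.
#' @slot truth data.frame(gene, group, effect) ground-truth records.
#' @slot config the \linkS4class{SynthConfig} used.
#' @export
setClass("StudyBundle",
         representation(acute = "ExpressionDataset",
                        followup = "ExpressionDataset",
                        enrichment = "list",
                        reportCounts = "numeric", disgenet = "numeric",
                        edges = "data.frame", geneSets = "list",
                        truth = "data.frame", config = "SynthConfig"))
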