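## Accessors and show methods. Slot access stays internal to the package;
## users go through these.

#' @rdname ExpressionDataset
#' @export
setMethod("exprsValues", "ExpressionDataset", function(object)
    SummarizedExperiment::assay(object, "exprs"))

#' @rdname ExpressionDataset
#' @export
setMethod("sampleGroups", "ExpressionDataset", function(object)
    setNames(SummarizedExperiment::colData(object)$group, colnames(object)))

#' @rdname ExpressionDataset
#' @export
setMethod("sampleBatches", "ExpressionDataset", function(object)
    setNames(SummarizedExperiment::colData(object)$batch, colnames(object)))

#' @export
setMethod("show", "ExpressionDataset", function(object) {
    cat(class(object), "with", nrow(object), "genes x",
        ncol(object), "samples\n")
    cat("groups:", paste(sprintf("%s=%d", names(table(sampleGroups(object))),
                                 table(sampleGroups(object))),
                         collapse = ", "), "\n")
    cat("batches:", paste(unique(sampleBatches(object)), collapse = ", "),
        "\n")
})

#' @rdname MergedDataset
#' @param object a \linkS4class{MergedDataset}.
#' @description \code{mergeSources()} returns the names of the source
#'   datasets in merge order.
#' @export
mergeSources <- function(object) {
    stopifnot(is(object, "MergedDataset"))
    object@sources
}

#' @rdname FoldTable
#' @export
setMethod("foldValues", "FoldTable", function(object) object@folds)

#' @rdname FoldTable
#' @export
setMethod("contrastName", "FoldTable", function(object) object@contrast)

#' @rdname FoldTable
#' @export
setMethod("length", "FoldTable", function(x) length(x@folds))

#' @rdname FoldTable
#' @export
setMethod("names", "FoldTable", function(x) names(x@folds))

#' @export
setMethod("show", "FoldTable", function(object) {
    cat("FoldTable [", object@contrast, "]: ", length(object@folds),
        " genes, fold range [", sprintf("%.3g", min(object@folds)), ", ",
        sprintf("%.3g", max(object@folds)), "]\n", sep = "")
})

#' @rdname ScoreTable
#' @export
setMethod("scoreFrame", "ScoreTable", function(object) object@scores)

#' @rdname ScoreTable
#' @export
setMethod("finalScores", "ScoreTable", function(object)
    setNames(object@scores$final, rownames(object@scores)))

#' @rdname ScoreTable
#' @export
setMethod("experimentScores", "ScoreTable", function(object)
    setNames(object@scores$experiment, rownames(object@scores)))

#' @rdname ScoreTable
#' @export
setMethod("expressionScores", "ScoreTable", function(object)
    setNames(object@scores$expression, rownames(object@scores)))

#' @export
setMethod("show", "ScoreTable", function(object) {
    cat("ScoreTable:", nrow(object@scores), "genes\n")
    cat("final score range [",
        sprintf("%.3g", min(object@scores$final)), ", ",
        sprintf("%.3g", max(object@scores$final)), "]\n", sep = "")
})

#' @rdname HighLowSelection
#' @export
setMethod("highGenes", "HighLowSelection", function(object) object@high)

#' @rdname HighLowSelection
#' @export
setMethod("lowGenes", "HighLowSelection", function(object) object@low)

#' @rdname HighLowSelection
#' @description \code{selectionCutoffs()} returns the percentile levels
#'   requested and the realized fold cutoffs.
#' @param object a \linkS4class{HighLowSelection}.
#' @export
selectionCutoffs <- function(object) {
    stopifnot(is(object, "HighLowSelection"))
    c(hiPct = object@hiPct, loPct = object@loPct,
      hiCutoff = object@hiCutoff, loCutoff = object@loCutoff)
}

#' @export
setMethod("show", "HighLowSelection", function(object) {
    cat("HighLowSelection: ", length(object@high), " high (fold > ",
        sprintf("%.4g", object@hiCutoff), " = P", object@hiPct, "), ",
        length(object@low), " low (fold < ",
        sprintf("%.4g", object@loCutoff), " = P", object@loPct, ")\n",
        sep = "")
})

#' @rdname GeneProfile
#' @export
setMethod("profileGenes", "GeneProfile", function(object) object@genes)

#' @rdname GeneProfile
#' @export
setMethod("profileFolds", "GeneProfile", function(object)
    setNames(object@folds, object@genes))

#' @rdname GeneProfile
#' @export
setMethod("profileScores", "GeneProfile", function(object)
    setNames(object@scores, object@genes))

#' @rdname GeneProfile
#' @export
setMethod("length", "GeneProfile", function(x) length(x@genes))

#' @rdname GeneProfile
#' @description \code{profileRule()} returns the recorded selection rule.
#' @export
profileRule <- function(object) {
    stopifnot(is(object, "GeneProfile"))
    c(object@rule, level = object@level)
}

#' @export
setMethod("show", "GeneProfile", function(object) {
    cat("GeneProfile [", object@condition, "]: ", length(object@genes),
        " genes (", object@rule$scoreType, " > ", object@rule$threshold,
        if (nzchar(object@level)) paste0("; ", object@level) else "",
        ")\n", sep = "")
    if (length(object@genes))
        cat(paste(utils::head(object@genes, 15L), collapse = ", "),
            if (length(object@genes) > 15L) ", ..." else "", "\n", sep = "")
})

#' @rdname GeneNetwork
#' @export
setMethod("networkNodes", "GeneNetwork", function(object) object@nodes)

#' @rdname GeneNetwork
#' @export
setMethod("networkEdges", "GeneNetwork", function(object) object@edges)

#' @export
setMethod("show", "GeneNetwork", function(object) {
    cat("GeneNetwork [", object@condition, "]: ", nrow(object@nodes),
        " nodes, ", nrow(object@edges), " edges\n", sep = "")
})

#' @rdname CutoffResult
#' @export
setMethod("cutoffRounds", "CutoffResult", function(object) object@rounds)

#' @rdname CutoffResult
#' @export
setMethod("cutoffRound", "CutoffResult", function(object) object@kStar)

#' @rdname CutoffResult
#' @export
setMethod("cutoffDays", "CutoffResult", function(object) object@days)

#' @rdname CutoffResult
#' @export
setMethod("cutoffPed", "CutoffResult", function(object) object@ped)

#' @export
setMethod("show", "CutoffResult", function(object) {
    if (is.na(object@kStar)) {
        cat("CutoffResult: no non-significant overlap within",
            nrow(object@rounds) - 1L, "rounds\n")
    } else {
        cat("CutoffResult: dSE round k* = ", object@kStar,
            " (Ped = ", sprintf("%.0f%%", 100 * object@ped), ")", sep = "")
        if (!is.na(object@days))
            cat(" -> ", object@days, " day(s) after MI [",
                object@mappingName, "]", sep = "")
        cat("\n")
    }
})

#' @export
setMethod("show", "SynthConfig", function(object) {
    cat("SynthConfig:", object@nGenes, "genes;",
        paste(sprintf("%s=%d", names(object@groups), object@groups),
              collapse = ", "),
        "; batches:", object@nBatches,
        "; planted:", nrow(object@planted), "effects; seed:", object@seed,
        "\n")
})

#' @export
setMethod("show", "StudyBundle", function(object) {
    cat("StudyBundle:", nrow(object@acute), "genes\n")
    cat(" acute:", ncol(object@acute), "samples; followup:",
        ncol(object@followup), "samples;",
        length(object@enrichment), "enrichment datasets\n")
    cat(" evidence:", length(object@reportCounts), "report counts,",
        length(object@disgenet), "DisGeNET scores,",
        nrow(object@edges), "edges,",
        length(object@geneSets), "gene sets\n")
    cat(" truth:", nrow(object@truth), "planted effects\n")
})

## Convenience extractors for StudyBundle slots

#' Extract components of a StudyBundle
#'
#' @param bundle a \linkS4class{StudyBundle}.
#' @param what which component: one of \code{"acute"}, \code{"followup"},
#'   \code{"enrichment"}, \code{"reportCounts"}, \code{"disgenet"},
#'   \code{"edges"}, \code{"geneSets"}, \code{"truth"}, \code{"config"}.
#' @return The requested component.
#' @export
bundleComponent <- function(bundle,
                            what = c("acute", "followup", "enrichment",
                                     "reportCounts", "disgenet", "edges",
                                     "geneSets", "truth", "config")) {
    stopifnot(is(bundle, "StudyBundle"))
    slot(bundle, match.arg(what))
}
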