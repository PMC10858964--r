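#' @rdname ExpressionDataset
#' @param object,x an object of the documented class.
#' @export
setGeneric("exprsValues", function(object) standardGeneric("exprsValues"))

#' @rdname ExpressionDataset
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname ExpressionDataset
#' @export
setGeneric("sampleBatches", function(object) standardGeneric("sampleBatches"))

#' @rdname FoldTable
#' @export
setGeneric("foldValues", function(object) standardGeneric("foldValues"))

#' @rdname FoldTable
#' @export
setGeneric("contrastName", function(object) standardGeneric("contrastName"))

#' @rdname ScoreTable
#' @export
setGeneric("scoreFrame", function(object) standardGeneric("scoreFrame"))

#' @rdname ScoreTable
#' @export
setGeneric("finalScores", function(object) standardGeneric("finalScores"))

#' @rdname ScoreTable
#' @export
setGeneric("experimentScores",
           function(object) standardGeneric("experimentScores"))

#' @rdname ScoreTable
#' @export
setGeneric("expressionScores",
           function(object) standardGeneric("expressionScores"))

#' @rdname HighLowSelection
#' @export
setGeneric("highGenes", function(object) standardGeneric("highGenes"))

#' @rdname HighLowSelection
#' @export
setGeneric("lowGenes", function(object) standardGeneric("lowGenes"))

#' @rdname GeneProfile
#' @export
setGeneric("profileGenes", function(object) standardGeneric("profileGenes"))

#' @rdname GeneProfile
#' @export
setGeneric("profileFolds", function(object) standardGeneric("profileFolds"))

#' @rdname GeneProfile
#' @export
setGeneric("profileScores", function(object) standardGeneric("profileScores"))

#' @rdname GeneNetwork
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname GeneNetwork
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname CutoffResult
#' @export
setGeneric("cutoffRounds", function(object) standardGeneric("cutoffRounds"))

#' @rdname CutoffResult
#' @export
setGeneric("cutoffRound", function(object) standardGeneric("cutoffRound"))

#' @rdname CutoffResult
#' @export
setGeneric("cutoffDays", function(object) standardGeneric("cutoffDays"))

#' @rdname CutoffResult
#' @export
setGeneric("cutoffPed", function(object) standardGeneric("cutoffPed"))
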