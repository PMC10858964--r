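## Multi-study merge and batch-effect harmonization.
##
## The harmonization is a control-anchored per-gene location-scale
## transform: within each batch, values are shifted and scaled so that the
## batch's control mean matches the pooled control mean and the batch's
## control SD matches the pooled within-batch control SD. Anchoring on
## controls (not all samples) keeps group-composition differences between
## batches from being absorbed as batch effect.

#' Merge expression datasets on their common gene universe
#'
#' Rows are the sorted intersection of the source gene universes; columns
#' are the concatenated samples, each keeping its original group label;
#' batch labels identify the source datasets.
#'
#' @param sources list of at least two \linkS4class{ExpressionDataset}s.
#' @param names optional source names (defaults to list names or
#'   \code{ds1}, \code{ds2}, ...).
#' @return A \linkS4class{MergedDataset}.
#' @export
mergeDatasets <- function(sources, names = NULL) {
    if (length(sources) < 2L)
        stop("need at least 2 source datasets to merge")
    if (is.null(names))
        names <- if (!is.null(base::names(sources)))
            base::names(sources) else paste0("ds", seq_along(sources))
    common <- Reduce(intersect, lapply(sources, rownames))
    if (!length(common)) stop("gene universes have empty intersection")
    common <- sort(common)
    allSamples <- unlist(lapply(sources, colnames))
    if (anyDuplicated(allSamples))
        stop("duplicate sample identifiers across sources: ",
             paste(unique(allSamples[duplicated(allSamples)])[1:3],
                   collapse = ", "))
    m <- do.call(cbind, lapply(sources, function(s)
        exprsValues(s)[common, , drop = FALSE]))
    group <- unlist(lapply(sources, function(s) unname(sampleGroups(s))))
    batch <- unlist(lapply(seq_along(sources), function(i)
        rep(names[i], ncol(sources[[i]]))))
    ds <- ExpressionDataset(m, group = group, batch = batch)
    new("MergedDataset", ds, sources = names)
}

#' Remove batch effects by control-anchored location-scale harmonization
#'
#' Per gene, each batch's values are affinely transformed so the batch-wise
#' anchor mean equals the pooled anchor mean and the batch-wise anchor SD
#' equals the pooled within-batch anchor SD. The anchor samples are the
#' control group (\code{anchored = TRUE}; every batch must contain at least
#' one) or all samples (\code{anchored = FALSE}, for batches without a
#' control arm). Genes with zero within-batch anchor variance pass through
#' shift-only correction. The operation is idempotent and preserves matrix
#' shape, sample order and group labels.
#'
#' @param merged a \linkS4class{MergedDataset} (or any
#'   \linkS4class{ExpressionDataset} with >= 2 samples per batch).
#' @param method correction method; only \code{"location-scale"} is
#'   implemented (the slot exists so an SVA-like estimator could be plugged
#'   in).
#' @param anchored anchor the transform on control samples (default) or on
#'   all samples.
#' @param controlGroup label of the anchor group.
#' @return Dataset of the same class with harmonized values.
#' @export
correctBatch <- function(merged, method = "location-scale",
                         anchored = TRUE, controlGroup = "control") {
    method <- match.arg(method, "location-scale")
    m <- exprsValues(merged)
    batch <- unname(sampleBatches(merged))
    group <- unname(sampleGroups(merged))
    batches <- unique(batch)
    anchorCols <- lapply(batches, function(b) {
        idx <- which(batch == b)
        if (length(idx) < 2L)
            stop("batch '", b, "' has fewer than 2 samples")
        if (anchored) {
            ctl <- idx[group[idx] == controlGroup]
            if (!length(ctl))
                stop("batch '", b, "' has no '", controlGroup,
                     "' samples; rerun with anchored = FALSE")
            ctl
        } else idx
    })
    ## per gene x batch anchor means/SDs
    mu <- matrix(vapply(anchorCols, function(cols)
        rowMeans(m[, cols, drop = FALSE]), numeric(nrow(m))),
        nrow = nrow(m))
    sdv <- matrix(vapply(anchorCols, function(cols) {
        if (length(cols) < 2L) rep(0, nrow(m))
        else apply(m[, cols, drop = FALSE], 1L, stats::sd)
    }, numeric(nrow(m))), nrow = nrow(m))
    nAnchor <- lengths(anchorCols)
    wMean <- as.vector(mu %*% nAnchor) / sum(nAnchor)
    ## pooled within-batch anchor SD (idempotence requires this target,
    ## not the grand SD)
    dfree <- pmax(nAnchor - 1L, 0L)
    pooledSD <- if (sum(dfree) > 0)
        sqrt(as.vector(sdv^2 %*% dfree) / sum(dfree)) else rep(0, nrow(m))
    out <- m
    for (i in seq_along(batches)) {
        idx <- which(batch == batches[i])
        scale <- ifelse(sdv[, i] > 1e-12 & pooledSD > 1e-12,
                        pooledSD / sdv[, i], 1)
        out[, idx] <- (m[, idx, drop = FALSE] - mu[, i]) * scale + wMean
    }
    res <- ExpressionDataset(out, group = group, batch = batch)
    if (is(merged, "MergedDataset"))
        res <- new("MergedDataset", res, sources = merged@sources)
    res
}

#' Batch sum of squares of the control samples
#'
#' One-way decomposition of the control-sample values by batch, summed over
#' genes: the between-batch sum of squares, used to quantify how much
#' batch-driven variation a correction removed.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param controlGroup label of the control group.
#' @return Single number, the between-batch sum of squares.
#' @export
batchSumOfSquares <- function(dataset, controlGroup = "control") {
    m <- exprsValues(dataset)
    keep <- unname(sampleGroups(dataset)) == controlGroup
    m <- m[, keep, drop = FALSE]
    b <- factor(unname(sampleBatches(dataset))[keep])
    grand <- rowMeans(m)
    ss <- 0
    for (lev in levels(b)) {
        idx <- which(b == lev)
        ss <- ss + length(idx) *
            sum((rowMeans(m[, idx, drop = FALSE]) - grand)^2)
    }
    ss
}
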