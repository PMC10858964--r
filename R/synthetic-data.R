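## Synthetic study generator. Emulates the statistical structure the
## analysis assumes: batched, group-labelled log-scale expression with
## per-batch location/scale effects, i.i.d. Gaussian noise and planted
## additive group effects of known size, plus evidence tables coupled to
## the planted truth.

#' Create a synthetic study configuration
#'
#' @param nGenes number of genes in the universe.
#' @param groups named vector of samples per group; must include
#'   \code{"control"}; at least 2 samples per group.
#' @param nBatches batches within the dataset; samples of each group are
#'   dealt to batches round-robin so every batch keeps control samples.
#' @param batchShiftSD SD of the additive per-batch location shift.
#' @param batchScaleRange range of the multiplicative per-batch scale
#'   (drawn uniformly); lower bound must be positive.
#' @param noiseSD SD of the i.i.d. Gaussian measurement noise.
#' @param planted data.frame(gene, group, effect) of additive effects
#'   (gene = 1-based index into the universe).
#' @param baselineMean baseline log-scale expression level.
#' @param seed integer seed; one global seed drives the generator and every
#'   sub-generator derives a child seed from it.
#' @return A \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(nGenes = 50, groups = c(control = 4, STEMI = 4),
#'                    planted = data.frame(gene = 1, group = "STEMI",
#'                                         effect = 2))
#' @export
synthConfig <- function(nGenes = 2000,
                        groups = c(control = 7, STEMI = 7, NSTEMI = 10),
                        nBatches = 1,
                        batchShiftSD = 0,
                        batchScaleRange = c(1, 1),
                        noiseSD = 0.3,
                        planted = data.frame(gene = integer(),
                                             group = character(),
                                             effect = numeric()),
                        baselineMean = 8,
                        seed = 1L) {
    grp <- as.integer(groups)
    names(grp) <- names(groups)
    planted <- as.data.frame(planted)
    if (nrow(planted)) planted$gene <- as.integer(planted$gene)
    new("SynthConfig", nGenes = as.integer(nGenes), groups = grp,
        nBatches = as.integer(nBatches),
        batchShiftSD = as.numeric(batchShiftSD),
        batchScaleRange = as.numeric(batchScaleRange),
        noiseSD = as.numeric(noiseSD), planted = planted,
        baselineMean = as.numeric(baselineMean), seed = as.integer(seed))
}

.geneUniverse <- function(nGenes) sprintf("G%05d", seq_len(nGenes))

#' Generate one synthetic expression dataset
#'
#' Each matrix entry is (baseline + batch shift + planted effect + Gaussian
#' noise) scaled by the batch scale factor. Deterministic for a fixed seed.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param batchLabel prefix for batch labels (batches are
#'   \code{<batchLabel>.1}, ... when \code{nBatches > 1}, else just
#'   \code{<batchLabel>}).
#' @return A list with elements \code{dataset}
#'   (\linkS4class{ExpressionDataset}) and \code{truth}
#'   (data.frame(gene, group, effect) of planted effects, gene symbols).
#' @export
generateExpressionDataset <- function(config, batchLabel = "b") {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    genes <- .geneUniverse(config@nGenes)
    groups <- rep(names(config@groups), config@groups)
    nS <- length(groups)
    samples <- unlist(lapply(names(config@groups), function(g)
        sprintf("%s_%s_%02d", batchLabel, g, seq_len(config@groups[[g]]))))
    ## round-robin batch assignment within each group
    batchIdx <- unlist(lapply(config@groups, function(n)
        rep_len(seq_len(config@nBatches), n)), use.names = FALSE)
    batch <- if (config@nBatches > 1L)
        sprintf("%s.%d", batchLabel, batchIdx) else rep(batchLabel, nS)

    effects <- matrix(0, config@nGenes, nS)
    pl <- config@planted
    if (nrow(pl)) {
        for (i in seq_len(nrow(pl))) {
            cols <- which(groups == pl$group[i])
            if (length(cols))
                effects[pl$gene[i], cols] <- effects[pl$gene[i], cols] +
                    pl$effect[i]
        }
    }

    m <- withSeed(config@seed, {
        shift <- stats::rnorm(config@nBatches, 0, config@batchShiftSD)
        scale <- stats::runif(config@nBatches, config@batchScaleRange[1L],
                              config@batchScaleRange[2L])
        noise <- matrix(stats::rnorm(config@nGenes * nS, 0, config@noiseSD),
                        config@nGenes, nS)
        base <- config@baselineMean +
            matrix(shift[batchIdx], config@nGenes, nS, byrow = TRUE) +
            effects + noise
        base * matrix(scale[batchIdx], config@nGenes, nS, byrow = TRUE)
    })
    dimnames(m) <- list(genes, samples)
    truth <- pl
    if (nrow(truth)) truth$gene <- genes[truth$gene]
    list(dataset = ExpressionDataset(m, group = groups, batch = batch),
         truth = truth)
}

#' Default planted-effect table for a study bundle
#'
#' Plants \code{nHigh} up-regulated and \code{nLow} down-regulated genes for
#' each of STEMI and NSTEMI (disjoint gene blocks), with decayed echoes of
#' the same effects in the follow-up groups (x0.4 at day 7, x0.1 at day 30)
#' and a pooled MI effect (x0.5) carried by the enrichment datasets.
#'
#' @param nGenes size of the gene universe.
#' @param effect additive effect size (expression units) of the acute
#'   planted genes.
#' @param nHigh,nLow planted genes per direction per condition.
#' @return data.frame(gene, group, effect).
#' @export
plantedEffects <- function(nGenes = 2000, effect = 1.2,
                           nHigh = 10, nLow = 6) {
    stopifnot(nGenes >= 2 * (nHigh + nLow))
    stemiHi <- seq_len(nHigh)
    stemiLo <- nHigh + seq_len(nLow)
    nstemiHi <- nHigh + nLow + seq_len(nHigh)
    nstemiLo <- 2 * nHigh + nLow + seq_len(nLow)
    acute <- rbind(
        data.frame(gene = stemiHi, group = "STEMI", effect = effect),
        data.frame(gene = stemiLo, group = "STEMI", effect = -effect),
        data.frame(gene = nstemiHi, group = "NSTEMI", effect = effect),
        data.frame(gene = nstemiLo, group = "NSTEMI", effect = -effect))
    echoes <- do.call(rbind, lapply(
        list(c("day7", 0.4), c("day30", 0.1), c("MI", 0.5)),
        function(e) data.frame(gene = acute$gene, group = e[[1L]],
                               effect = acute$effect * as.numeric(e[[2L]]))))
    ## one planted (gene, group) pair each
    rbind(acute, echoes[!duplicated(echoes[, c("gene", "group")]), ])
}

.subConfig <- function(config, groups, seed, nBatches = 1L,
                       batchShiftSD = NULL) {
    synthConfig(nGenes = config@nGenes, groups = groups,
                nBatches = nBatches,
                batchShiftSD = if (is.null(batchShiftSD))
                    config@batchShiftSD else batchShiftSD,
                batchScaleRange = config@batchScaleRange,
                noiseSD = config@noiseSD, planted = config@planted,
                baselineMean = config@baselineMean, seed = seed)
}

#' Generate a full synthetic study bundle
#'
#' Emulates the five-dataset study design: an acute dataset
#' (control/STEMI/NSTEMI), a follow-up dataset (control/day7/day30), and
#' three enrichment datasets (control/MI) of unequal size, each carrying a
#' distinct batch label, all on one gene universe. Evidence tables (report
#' counts, DisGeNET scores), an interaction edge list and a gene-set
#' collection are generated coupled to the planted truth: for a fraction
#' \code{evidenceCoupling} of planted genes the evidence grows with the
#' planted effect magnitude, and a fraction \code{edgeCoupling} of planted
#' genes is wired together in the edge list.
#'
#' @param config a \linkS4class{SynthConfig}; its \code{groups} define the
#'   acute dataset and must include the acute groups (control and at least
#'   one of STEMI/NSTEMI).
#' @param followupGroups samples per follow-up group.
#' @param enrichmentGroups list of three named vectors, samples per group in
#'   each enrichment dataset (defaults mirror the study's three enrichment
#'   set sizes).
#' @param evidenceCoupling fraction of planted genes whose report counts and
#'   DisGeNET scores scale with the planted effect magnitude.
#' @param edgeCoupling fraction of planted genes connected in the edge list.
#' @return A \linkS4class{StudyBundle}.
#' @export
generateStudyBundle <- function(config = synthConfig(
                                    planted = plantedEffects()),
                                followupGroups = c(control = 6, day7 = 18,
                                                   day30 = 18),
                                enrichmentGroups = list(
                                    enr1 = c(control = 48, MI = 49),
                                    enr2 = c(control = 11, MI = 6),
                                    enr3 = c(control = 3, MI = 3)),
                                evidenceCoupling = 0.8,
                                edgeCoupling = 0.8) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    if (!"control" %in% names(config@groups) ||
        !any(c("STEMI", "NSTEMI") %in% names(config@groups)))
        stop("config must request the acute groups (control and STEMI and/or NSTEMI)")
    genes <- .geneUniverse(config@nGenes)

    acute <- generateExpressionDataset(
        .subConfig(config, config@groups, childSeed(config@seed, 1L),
                   nBatches = config@nBatches),
        batchLabel = "acute")
    followup <- generateExpressionDataset(
        .subConfig(config, followupGroups, childSeed(config@seed, 2L)),
        batchLabel = "followup")
    enrichment <- lapply(seq_along(enrichmentGroups), function(i)
        generateExpressionDataset(
            .subConfig(config, enrichmentGroups[[i]],
                       childSeed(config@seed, 2L + i)),
            batchLabel = names(enrichmentGroups)[i])$dataset)
    names(enrichment) <- names(enrichmentGroups)

    truth <- acute$truth
    planted <- unique(truth$gene)
    plantedMag <- if (length(planted))
        vapply(planted, function(g)
            max(abs(truth$effect[truth$gene == g])), numeric(1)) else numeric()

    ev <- withSeed(childSeed(config@seed, 6L), {
        coupled <- if (length(planted))
            stats::runif(length(planted)) < evidenceCoupling else logical()
        nBg <- min(50L, config@nGenes)
        bg <- setdiff(sample(genes, nBg), planted)
        counts <- c(
            setNames(ifelse(coupled,
                            round(3 + 15 * plantedMag) + stats::rpois(length(planted), 2),
                            1 + stats::rpois(length(planted), 3)), planted),
            setNames(1 + stats::rpois(length(bg), 3), bg))
        dg <- c(
            setNames(pmin(1, pmax(0.01, ifelse(coupled,
                            0.2 + 0.2 * plantedMag + stats::rnorm(length(planted), 0, 0.05),
                            stats::runif(length(planted), 0.01, 0.4)))), planted),
            setNames(stats::runif(length(bg), 0.01, 0.4), bg))
        list(counts = counts, dg = dg)
    })

    edges <- withSeed(childSeed(config@seed, 7L), {
        wired <- if (length(planted))
            planted[stats::runif(length(planted)) < edgeCoupling] else character()
        e <- NULL
        if (length(wired) >= 2L) {
            ## chain plus random extra pairs among the wired planted genes
            chain <- cbind(wired[-length(wired)], wired[-1L])
            pairs <- t(utils::combn(wired, 2L))
            extra <- pairs[stats::runif(nrow(pairs)) < 0.25, , drop = FALSE]
            e <- rbind(chain, extra)
        }
        nBgE <- min(100L, config@nGenes * 2L)
        bgE <- cbind(sample(genes, nBgE, replace = TRUE),
                     sample(genes, nBgE, replace = TRUE))
        e <- rbind(e, bgE[bgE[, 1L] != bgE[, 2L], , drop = FALSE])
        key <- apply(e, 1L, function(r) paste(sort(r), collapse = "\r"))
        e <- e[!duplicated(key), , drop = FALSE]
        data.frame(from = e[, 1L], to = e[, 2L],
                   weight = round(stats::runif(nrow(e), 0.15, 0.99), 3))
    })

    geneSets <- withSeed(childSeed(config@seed, 8L), {
        up <- unique(truth$gene[truth$effect > 0])
        down <- unique(truth$gene[truth$effect < 0])
        sets <- list()
        if (length(up) >= 2L)
            sets$PLANTED_UP <- unique(c(up, sample(genes, 5L)))
        if (length(down) >= 2L)
            sets$PLANTED_DOWN <- unique(c(down, sample(genes, 5L)))
        for (i in seq_len(8L)) {
            sets[[sprintf("RANDOM_SET_%02d", i)]] <-
                sample(genes, min(sample(20:50, 1L), config@nGenes))
        }
        sets
    })

    new("StudyBundle", acute = acute$dataset, followup = followup$dataset,
        enrichment = enrichment, reportCounts = ev$counts,
        disgenet = ev$dg, edges = edges, geneSets = geneSets,
        truth = truth, config = config)
}

#' Write a study bundle to a directory of plain-text files
#'
#' Expression matrices as TSV (genes in rows, sample-ID header) with
#' sidecar sample metadata TSVs, evidence tables as 2-column TSV, the edge
#' list as 3-column TSV, gene sets as GMT, truth records as TSV.
#'
#' @param bundle a \linkS4class{StudyBundle}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
writeStudyBundle <- function(bundle, dir) {
    stopifnot(is(bundle, "StudyBundle"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c()
    wrt <- function(ds, name) {
        p <- file.path(dir, paste0(name, ".tsv"))
        m <- file.path(dir, paste0(name, "_samples.tsv"))
        writeExpressionTSV(ds, p, m)
        c(setNames(p, name), setNames(m, paste0(name, "_samples")))
    }
    paths <- c(paths, wrt(bundle@acute, "acute"),
               wrt(bundle@followup, "followup"))
    for (nm in names(bundle@enrichment))
        paths <- c(paths, wrt(bundle@enrichment[[nm]], nm))
    p <- file.path(dir, "report_counts.tsv")
    writeEvidenceTSV(bundle@reportCounts, p); paths <- c(paths, reports = p)
    p <- file.path(dir, "disgenet_scores.tsv")
    writeEvidenceTSV(bundle@disgenet, p); paths <- c(paths, disgenet = p)
    p <- file.path(dir, "edges.tsv")
    writeEdgeTSV(bundle@edges, p); paths <- c(paths, edges = p)
    p <- file.path(dir, "gene_sets.gmt")
    writeGMT(bundle@geneSets, p); paths <- c(paths, geneSets = p)
    p <- file.path(dir, "truth.tsv")
    utils::write.table(bundle@truth, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth = p)
    invisible(paths)
}
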