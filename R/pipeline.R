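## End-to-end orchestration: merge -> batch correction -> folds -> scores
## -> percentile selection -> profiles -> network + enrichment -> time
## cut-off, writing every intermediate as TSV/JSON plus a manifest with
## checksums so a rerun under the same configuration is verifiably
## identical.

#' Assemble a pipeline configuration
#'
#' Inputs come either from a \linkS4class{StudyBundle} (e.g. from
#' \code{\link{generateStudyBundle}}) or from files: a named \code{paths}
#' list with entries \code{acute}, \code{acuteSamples}, \code{followup},
#' \code{followupSamples}, \code{enrichment} (character vector),
#' \code{enrichmentSamples}, \code{reports}, \code{disgenet}, \code{edges},
#' \code{geneSets}.
#'
#' @param bundle optional \linkS4class{StudyBundle}.
#' @param paths named list of input file paths (used when \code{bundle} is
#'   NULL).
#' @param hiPct,loPct fold-selection percentiles (0-100).
#' @param centile network-membership score centile.
#' @param profileThresholds named numeric, score threshold per condition;
#'   NULL uses the 75th centile of each condition's final scores.
#' @param foldThreshold fold-level sub-profile threshold.
#' @param alpha significance level (= Pfr of the sigma model).
#' @param maxRounds maximum dSE round of the cut-off search.
#' @param anchored anchor batch correction on control samples.
#' @param seed integer seed (drives nothing unless a stage is stochastic;
#'   recorded in the manifest).
#' @return A list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(bundle = NULL, paths = list(), hiPct = 99.5,
                           loPct = 0.25, centile = 25,
                           profileThresholds = NULL, foldThreshold = 0.4,
                           alpha = 0.05, maxRounds = 10, anchored = TRUE,
                           seed = 1L) {
    structure(list(bundle = bundle, paths = paths, hiPct = hiPct,
                   loPct = loPct, centile = centile,
                   profileThresholds = profileThresholds,
                   foldThreshold = foldThreshold, alpha = alpha,
                   maxRounds = maxRounds, anchored = anchored,
                   seed = as.integer(seed)),
              class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the \code{paths} entries and any threshold fields of
#' \code{\link{pipelineConfig}}.
#'
#' @param path YAML file.
#' @return A \code{pipelineConfig} list.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- y[setdiff(names(y), "paths")]
    args$paths <- y$paths %||% list()
    do.call(pipelineConfig, args)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.needPath <- function(paths, key) {
    p <- paths[[key]]
    if (is.null(p) || !all(file.exists(p)))
        stop("missing input path '", key, "'",
             if (!is.null(p)) paste0(" (", paste(p, collapse = ", "), ")"))
    p
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes all
#' intermediates plus \code{manifest.json} (package version, seed,
#' thresholds, per-file MD5 checksums) to \code{outDir}. Rerunning with the
#' same configuration reproduces byte-identical outputs.
#'
#' @param config a \code{pipelineConfig}, a \linkS4class{StudyBundle}, or
#'   the path to a YAML configuration.
#' @param outDir output directory.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) config <- readPipelineConfig(config)
    if (is(config, "StudyBundle")) config <- pipelineConfig(bundle = config)
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    bundle <- config$bundle
    paths <- config$paths
    outputs <- list()
    emit <- function(stage, file) {
        outputs[[stage]] <<- c(outputs[[stage]], file)
        file.path(outDir, file)
    }

    ## -- stage 1: merge + batch correction ------------------------------
    corrected <- .stage("integrate", {
        if (!is.null(bundle)) {
            acute <- bundle@acute; followup <- bundle@followup
        } else {
            acute <- readExpressionTSV(.needPath(paths, "acute"),
                                       .needPath(paths, "acuteSamples"))
            followup <- readExpressionTSV(.needPath(paths, "followup"),
                                          .needPath(paths, "followupSamples"))
        }
        merged <- mergeDatasets(list(acute = acute, followup = followup))
        cb <- correctBatch(merged, anchored = config$anchored)
        writeExpressionTSV(cb, emit("integrate", "merged.tsv"),
                           emit("integrate", "merged_samples.tsv"))
        cb
    })
    conditions <- intersect(c("STEMI", "NSTEMI"),
                            unique(sampleGroups(corrected)))
    timeGroups <- intersect(c("day7", "day30"),
                            unique(sampleGroups(corrected)))

    ## -- stage 2: primary folds -----------------------------------------
    folds <- .stage("fold", {
        ft <- lapply(c(conditions, timeGroups), function(g)
            geneFold(corrected, g, "control"))
        names(ft) <- c(conditions, timeGroups)
        df <- data.frame(gene = names(ft[[1L]]),
                         vapply(ft, foldValues, numeric(length(ft[[1L]]))),
                         check.names = FALSE)
        utils::write.table(df, emit("fold", "folds.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        ft
    })

    ## -- stage 3: enrichment-dataset folds ------------------------------
    enrFolds <- .stage("enrichment_folds", {
        dss <- if (!is.null(bundle)) bundle@enrichment else {
            ep <- .needPath(paths, "enrichment")
            em <- .needPath(paths, "enrichmentSamples")
            stopifnot(length(ep) == length(em))
            setNames(lapply(seq_along(ep), function(i)
                readExpressionTSV(ep[i], em[i])),
                paste0("enr", seq_along(ep)))
        }
        ef <- lapply(names(dss), function(nm) {
            ds <- dss[[nm]]
            caseGrp <- setdiff(unique(sampleGroups(ds)), "control")[1L]
            ft <- geneFold(ds, caseGrp, "control")
            FoldTable(foldValues(ft), contrast = paste0(nm, ":",
                                                        contrastName(ft)))
        })
        df <- data.frame(gene = names(ef[[1L]]),
                         vapply(ef, foldValues, numeric(length(ef[[1L]]))),
                         check.names = FALSE)
        colnames(df)[-1L] <- vapply(ef, contrastName, character(1))
        utils::write.table(df, emit("enrichment_folds",
                                    "enrichment_folds.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ef
    })

    ## -- stage 4: evidence + score algebra ------------------------------
    scores <- .stage("score", {
        if (!is.null(bundle)) {
            reports <- bundle@reportCounts; dg <- bundle@disgenet
        } else {
            reports <- readEvidenceTSV(.needPath(paths, "reports"))
            dg <- readEvidenceTSV(.needPath(paths, "disgenet"))
        }
        expSc <- experimentScore(reports, dg)
        st <- lapply(conditions, function(g) {
            exprSc <- expressionScore(folds[[g]], enrFolds)
            finalScore(expSc, exprSc)
        })
        names(st) <- conditions
        for (g in conditions) {
            df <- scoreFrame(st[[g]])
            utils::write.table(
                data.frame(gene = rownames(df), df),
                emit("score", paste0("scores_", g, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
        st
    })

    ## -- stage 5: percentile selection + heatmap matrices ---------------
    selections <- .stage("select", {
        sel <- lapply(conditions, function(g) {
            s <- selectPercentileGenes(folds[[g]], config$hiPct,
                                       config$loPct)
            other <- setdiff(conditions, g)
            heatmapMatrix(s, folds[c(g, other, timeGroups)],
                          path = emit("select",
                                      paste0("heatmap_", g, ".tsv")))
            s
        })
        names(sel) <- conditions
        sel
    })

    ## -- stage 6: gene profiles -----------------------------------------
    profiles <- .stage("profile", {
        pr <- lapply(conditions, function(g) {
            fin <- finalScores(scores[[g]])
            thr <- config$profileThresholds[[g]] %||%
                pctCutoff(fin, 75)
            p <- selectProfile(scores[[g]], thr, condition = g,
                              folds = foldValues(folds[[g]]))
            sub <- subProfileByFold(p, config$foldThreshold)
            df <- data.frame(gene = profileGenes(p),
                             score = unname(profileScores(p)),
                             fold = unname(profileFolds(p)),
                             inFoldSubProfile =
                                 profileGenes(p) %in% profileGenes(sub))
            utils::write.table(df, emit("profile",
                                        paste0("profile_", g, ".tsv")),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            list(profile = p, sub = sub, threshold = thr)
        })
        names(pr) <- conditions
        pr
    })

    ## -- stage 7: network + enrichment ----------------------------------
    networks <- .stage("network", {
        edges <- if (!is.null(bundle)) bundle@edges
                 else readEdgeTSV(.needPath(paths, "edges"))
        sets <- if (!is.null(bundle)) bundle@geneSets
                else readGMT(.needPath(paths, "geneSets"))
        nw <- lapply(conditions, function(g) {
            exprSc <- expressionScores(scores[[g]])
            members <- centileFilter(exprSc, config$centile, "above")
            net <- buildNetwork(scores[[g]], members, edges, condition = g)
            writeNetworkTSV(net,
                            emit("network", paste0("network_", g,
                                                   "_nodes.tsv")),
                            emit("network", paste0("network_", g,
                                                   "_edges.tsv")))
            enr <- oraEnrich(profileGenes(profiles[[g]]$profile), sets,
                             universe = rownames(scoreFrame(scores[[g]])))
            utils::write.table(enr,
                               emit("network", paste0("enrichment_", g,
                                                      ".tsv")),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            list(network = net, enrichment = enr)
        })
        names(nw) <- conditions
        nw
    })

    ## -- stage 8: time cut-off ------------------------------------------
    cutoffs <- .stage("cutoff", {
        if (!"day7" %in% timeGroups) return(NULL)
        m <- exprsValues(corrected)
        grp <- unname(sampleGroups(corrected))
        res <- lapply(conditions, function(g) {
            genes <- profileGenes(profiles[[g]]$profile)
            if (length(genes) < 2L) return(NULL)
            caseM <- m[genes, grp == g, drop = FALSE]
            ## per-gene CV = SE of the fold under the case-group spread
            cv <- apply(caseM, 1L, stats::sd) / sqrt(ncol(caseM))
            cv[cv <= 0] <- min(cv[cv > 0], 1e-6)
            acuteF <- foldValues(folds[[g]])[genes]
            refF <- foldValues(folds[["day7"]])[genes]
            ## the CV increments are additive, so shift the lower-lying
            ## profile toward the other (two-tailed test: label-symmetric)
            if (mean(acuteF) > mean(refF)) {
                tmp <- acuteF; acuteF <- refF; refF <- tmp
            }
            cfg <- sigmaParams(cv = cv, pfr = config$alpha)
            findCutoff(acuteF, refF, cv, cfg,
                       maxRounds = config$maxRounds,
                       mapping = dayMapping("reported"))
        })
        names(res) <- conditions
        keep <- !vapply(res, is.null, logical(1))
        out <- lapply(res[keep], function(r)
            list(kStar = cutoffRound(r), ped = cutoffPed(r),
                 days = cutoffDays(r), alpha = r@alpha,
                 rounds = cutoffRounds(r)))
        jsonlite::write_json(out, emit("cutoff", "cutoff.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", na = "null")
        res[keep]
    })

    ## -- manifest --------------------------------------------------------
    files <- unlist(outputs, use.names = FALSE)
    manifest <- list(
        package = "stemiProfiles",
        version = as.character(utils::packageVersion("stemiProfiles")),
        seed = config$seed,
        thresholds = list(hiPct = config$hiPct, loPct = config$loPct,
                          centile = config$centile,
                          profileThresholds = lapply(profiles, `[[`,
                                                     "threshold"),
                          foldThreshold = config$foldThreshold,
                          alpha = config$alpha),
        stages = lapply(outputs, as.list),
        checksums = as.list(tools::md5sum(file.path(outDir, files))))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
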