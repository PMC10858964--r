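test_that("noiseless degenerate configuration yields a constant matrix", {
    cfg <- synthConfig(nGenes = 20, groups = c(control = 3, STEMI = 3),
                       noiseSD = 0, batchShiftSD = 0,
                       batchScaleRange = c(1, 1), baselineMean = 8,
                       seed = 1)
    out <- generateExpressionDataset(cfg)
    expect_true(all(exprsValues(out$dataset) == 8))
    expect_identical(nrow(out$truth), 0L)
})

test_that("planted effects pass through exactly without noise", {
    cfg <- synthConfig(nGenes = 10, groups = c(control = 3, STEMI = 4),
                       noiseSD = 0, batchShiftSD = 0,
                       batchScaleRange = c(1, 1),
                       planted = data.frame(gene = 1, group = "STEMI",
                                            effect = 2.0),
                       seed = 3)
    out <- generateExpressionDataset(cfg)
    m <- exprsValues(out$dataset)
    grp <- sampleGroups(out$dataset)
    expect_equal(unique(m[1, grp == "STEMI"] - m[1, grp == "control"][1]),
                 2.0)
    ## estimated fold equals the planted effect exactly
    ft <- geneFold(out$dataset, "STEMI")
    expect_identical(unname(foldValues(ft)[out$truth$gene]), 2.0)
    expect_true(all(foldValues(ft)[-1] == 0))
})

test_that("generation is deterministic for a fixed seed", {
    cfg <- synthConfig(nGenes = 30, groups = c(control = 3, STEMI = 3),
                       nBatches = 2, batchShiftSD = 1,
                       batchScaleRange = c(0.8, 1.2), seed = 7)
    a <- generateExpressionDataset(cfg)
    b <- generateExpressionDataset(cfg)
    expect_identical(exprsValues(a$dataset), exprsValues(b$dataset))
    bu1 <- generateStudyBundle(synthConfig(nGenes = 60,
                                           planted = plantedEffects(60, nHigh = 3, nLow = 2),
                                           seed = 7))
    bu2 <- generateStudyBundle(synthConfig(nGenes = 60,
                                           planted = plantedEffects(60, nHigh = 3, nLow = 2),
                                           seed = 7))
    expect_identical(exprsValues(bundleComponent(bu1, "acute")),
                     exprsValues(bundleComponent(bu2, "acute")))
    expect_identical(bundleComponent(bu1, "reportCounts"),
                     bundleComponent(bu2, "reportCounts"))
    expect_identical(bundleComponent(bu1, "edges"),
                     bundleComponent(bu2, "edges"))
})

test_that("invalid configurations are rejected", {
    expect_error(synthConfig(groups = c(control = 1, STEMI = 3)),
                 "at least 2 samples")
    expect_error(synthConfig(nGenes = 5,
                             planted = data.frame(gene = 9, group = "STEMI",
                                                  effect = 1)),
                 "gene universe")
    expect_error(synthConfig(noiseSD = NaN), "finite")
    expect_error(synthConfig(batchScaleRange = c(0, 2)), "positive")
})

test_that("study bundle has the five-dataset, four-evidence-table design", {
    b <- generateStudyBundle(synthConfig(nGenes = 80,
                                         planted = plantedEffects(80, nHigh = 4, nLow = 2),
                                         seed = 5))
    expect_s4_class(bundleComponent(b, "acute"), "ExpressionDataset")
    expect_s4_class(bundleComponent(b, "followup"), "ExpressionDataset")
    expect_length(bundleComponent(b, "enrichment"), 3)
    ## common gene universe, distinct batch labels
    allDs <- c(list(b@acute, b@followup), b@enrichment)
    expect_length(unique(lapply(allDs, rownames)), 1)
    expect_length(unique(unlist(lapply(allDs, function(d)
        unique(sampleBatches(d))))), 5)
    expect_true(all(bundleComponent(b, "reportCounts") >= 0))
    expect_true(all(bundleComponent(b, "disgenet") >= 0 &
                    bundleComponent(b, "disgenet") <= 1))
    expect_gt(nrow(bundleComponent(b, "edges")), 0)
    expect_gt(length(bundleComponent(b, "geneSets")), 0)
})

test_that("a bundle without planted effects has empty truth and clean nulls", {
    b <- generateStudyBundle(synthConfig(nGenes = 200, seed = 9))
    expect_identical(nrow(bundleComponent(b, "truth")), 0L)
    expect_true(all(bundleComponent(b, "reportCounts") >= 0))
    ## null calibration: folds over genes average to 0 within 3 SE
    ft <- foldValues(geneFold(bundleComponent(b, "acute"), "STEMI"))
    se <- sd(ft) / sqrt(length(ft))
    expect_lt(abs(mean(ft)), 3 * se)
})

test_that("bundle round-trips through its plain-text directory format", {
    b <- generateStudyBundle(synthConfig(nGenes = 40,
                                         planted = plantedEffects(40, nHigh = 2, nLow = 2),
                                         seed = 13))
    dir <- withr::local_tempdir()
    paths <- writeStudyBundle(b, dir)
    back <- readExpressionTSV(paths[["acute"]], paths[["acute_samples"]])
    expect_equal(exprsValues(back), exprsValues(b@acute))
    expect_identical(unname(sampleGroups(back)),
                     unname(sampleGroups(b@acute)))
    counts <- readEvidenceTSV(paths[["reports"]])
    expect_equal(counts[names(b@reportCounts)], b@reportCounts)
    sets <- readGMT(paths[["geneSets"]])
    expect_identical(sets[[1]], b@geneSets[[1]])
})
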