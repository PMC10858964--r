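mkDs <- function(genes, n = 4, group = NULL, seed = 1, shift = 0) {
    set.seed(seed)
    m <- matrix(rnorm(length(genes) * n, 8 + shift), length(genes), n,
                dimnames = list(genes,
                                sprintf("d%d_s%d", seed, seq_len(n))))
    if (is.null(group)) group <- rep(c("control", "STEMI"), length.out = n)
    ExpressionDataset(m, group = group)
}

test_that("merging intersects gene universes and concatenates samples", {
    d1 <- mkDs(c("A", "B", "C"), seed = 1)
    d2 <- mkDs(c("B", "C", "D"), seed = 2)
    mg <- mergeDatasets(list(x = d1, y = d2))
    expect_identical(rownames(mg), c("B", "C"))
    expect_identical(ncol(mg), 8L)
    expect_identical(mergeSources(mg), c("x", "y"))
    expect_error(mergeDatasets(list(d1)), "at least 2")
    expect_error(mergeDatasets(list(mkDs("A", seed = 1),
                                    mkDs("B", seed = 2))),
                 "empty intersection")
    ## batch labels follow source order
    mg3 <- mergeDatasets(list(mkDs(c("A", "B"), seed = 1),
                              mkDs(c("A", "B"), seed = 2),
                              mkDs(c("A", "B"), seed = 3)))
    expect_identical(unname(sampleBatches(mg3)),
                     rep(c("ds1", "ds2", "ds3"), each = 4))
})

test_that("duplicate sample identifiers across sources are an error", {
    d1 <- mkDs(c("A", "B"), seed = 1)
    expect_error(mergeDatasets(list(d1, d1)), "duplicate sample")
})

test_that("correction equalizes batch control means and is idempotent", {
    ## gene with control means 10 and 12 in the two batches
    m <- rbind(g1 = c(10.2, 9.8, 11, 12.3, 11.7, 13),
               g2 = c(5, 6, 7, 8, 9, 10))
    colnames(m) <- paste0("s", 1:6)
    ds <- ExpressionDataset(m, group = rep(c("control", "control", "STEMI"), 2),
                            batch = rep(c("b1", "b2"), each = 3))
    mg <- mergeDatasets(list(a = ds[, 1:3], b = ds[, 4:6]))
    cb <- correctBatch(mg)
    mm <- exprsValues(cb)
    grp <- sampleGroups(cb); bat <- sampleBatches(cb)
    for (g in rownames(mm)) {
        ctl <- mm[g, grp == "control"]
        pooled <- mean(ctl)
        for (b in unique(bat)) {
            expect_lt(abs(mean(mm[g, grp == "control" & bat == b]) - pooled),
                      1e-9)
        }
    }
    ## idempotence
    cb2 <- correctBatch(cb)
    expect_lt(max(abs(exprsValues(cb2) - exprsValues(cb))), 1e-9)
    ## shape and ordering preserved
    expect_identical(dimnames(exprsValues(cb)), dimnames(exprsValues(mg)))
    expect_identical(sampleGroups(cb), sampleGroups(mg))
})

test_that("a batch-homogeneous matrix passes through unchanged", {
    set.seed(4)
    block <- matrix(rnorm(20, 8), 5, 4,
                    dimnames = list(paste0("g", 1:5), NULL))
    m <- cbind(block, block)  # second batch repeats the first exactly
    colnames(m) <- paste0("s", 1:8)
    ds <- ExpressionDataset(m, group = rep(c("control", "control",
                                             "STEMI", "STEMI"), 2),
                            batch = rep(c("b1", "b2"), each = 4))
    cb <- correctBatch(ds)
    expect_lt(max(abs(exprsValues(cb) - m)), 1e-9)
})

test_that("anchored correction demands control samples in every batch", {
    m <- matrix(rnorm(16, 8), 2, 8,
                dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
    ds <- ExpressionDataset(m, group = c(rep("control", 2), rep("STEMI", 2),
                                         rep("day7", 4)),
                            batch = rep(c("b1", "b2"), each = 4))
    expect_error(correctBatch(ds), "anchored = FALSE")
    expect_s4_class(correctBatch(ds, anchored = FALSE),
                    "ExpressionDataset")
})

test_that("correction removes nearly all batch-driven control variation", {
    cfg <- synthConfig(nGenes = 300, batchShiftSD = 2,
                       planted = plantedEffects(300, nHigh = 4, nLow = 2),
                       seed = 31)
    b <- generateStudyBundle(cfg)
    mg <- mergeDatasets(c(list(acute = b@acute, followup = b@followup),
                          b@enrichment))
    before <- batchSumOfSquares(mg)
    after <- batchSumOfSquares(correctBatch(mg))
    expect_gt(before, 0)
    expect_lt(after / before, 0.01)
})

test_that("planted group effects survive a noiseless shift-only correction", {
    mk <- function(seed, shift) {
        cfg <- synthConfig(nGenes = 20, groups = c(control = 3, STEMI = 3),
                           noiseSD = 0, batchShiftSD = 0,
                           batchScaleRange = c(1, 1), baselineMean = 8 + shift,
                           planted = data.frame(gene = 1:2, group = "STEMI",
                                                effect = c(1.5, -0.7)),
                           seed = seed)
        generateExpressionDataset(cfg, batchLabel = paste0("b", seed))$dataset
    }
    mg <- mergeDatasets(list(a = mk(1, 0), b = mk(2, 3)))
    cb <- correctBatch(mg)
    ft <- foldValues(geneFold(cb, "STEMI"))
    expect_lt(abs(ft[["G00001"]] - 1.5), 1e-9)
    expect_lt(abs(ft[["G00002"]] + 0.7), 1e-9)
    expect_lt(max(abs(ft[-(1:2)])), 1e-9)
})
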