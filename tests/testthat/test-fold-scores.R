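test_that("the fold is the difference of group means", {
    ds <- edsTwoGroup(caseVals = matrix(c(3, 5), 1),
                      controlVals = matrix(c(1, 3), 1), genes = "G")
    expect_equal(unname(foldValues(geneFold(ds, "STEMI"))), 2.0)
    ## case identical to control: fold 0
    ds0 <- edsTwoGroup(caseVals = matrix(c(1, 3), 1),
                       controlVals = matrix(c(1, 3), 1), genes = "G")
    expect_equal(unname(foldValues(geneFold(ds0, "STEMI"))), 0)
    expect_error(geneFold(ds, "NSTEMI"), "no samples")
})

test_that("literal centered-sum form agrees with the mean difference", {
    set.seed(42)
    m <- matrix(rnorm(50 * 12, 8, 2), 50, 12,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("s%02d", 1:12)))
    ds <- edsFromMatrix(m, group = rep(c("control", "STEMI"), each = 6))
    lit <- foldValues(geneFold(ds, "STEMI", form = "literal"))
    mdiff <- foldValues(geneFold(ds, "STEMI", form = "mean-difference"))
    expect_lt(max(abs(lit - mdiff)), 1e-12)
})

test_that("folds are translation invariant and case-shift equivariant", {
    set.seed(11)
    m <- matrix(rnorm(40, 8), 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
    grp <- c("control", "control", "STEMI", "STEMI")
    f0 <- foldValues(geneFold(edsFromMatrix(m, grp), "STEMI"))
    f1 <- foldValues(geneFold(edsFromMatrix(m + 5, grp), "STEMI"))
    expect_equal(f0, f1)
    mShift <- m
    mShift[, grp == "STEMI"] <- mShift[, grp == "STEMI"] + 1.25
    f2 <- foldValues(geneFold(edsFromMatrix(mShift, grp), "STEMI"))
    expect_equal(f2, f0 + 1.25)
})

test_that("expression score adds the mean enrichment fold with coverage flags", {
    primary <- FoldTable(c(A = 0.5, B = 0.2, C = -0.1))
    e1 <- FoldTable(c(A = 0.1, B = 0.4))
    e2 <- FoldTable(c(A = 0.2, B = 0.8))
    e3 <- FoldTable(c(A = 0.3))
    s <- expressionScore(primary, list(e1, e2, e3))
    expect_equal(unname(s["A"]), 0.5 + mean(c(0.1, 0.2, 0.3)))
    ## partial coverage: mean over the available tables only
    expect_equal(unname(s["B"]), 0.2 + mean(c(0.4, 0.8)))
    expect_equal(unname(s["C"]), -0.1)
    cov <- attr(s, "coverage")
    expect_identical(unname(cov[c("A", "B", "C")]),
                     c("full", "partial", "none"))
    ## all-zero enrichment leaves the primary fold unchanged
    z <- expressionScore(primary,
                         list(FoldTable(c(A = 0, B = 0, C = 0))))
    expect_equal(as.numeric(z), unname(foldValues(primary)))
})

test_that("experiment score applies the max-count/max-score normalization", {
    s <- experimentScore(c(A = 10, B = 5), c(A = 0.4, B = 0.8))
    expect_equal(unname(attr(s, "textMining")[c("A", "B")]), c(0.8, 0.4))
    expect_equal(unname(s[c("A", "B")]), c(1.2, 1.2))
    ## gene present only in DisGeNET keeps its score
    s2 <- experimentScore(c(A = 10), c(A = 0.4, B = 0.3))
    expect_equal(unname(s2["B"]), 0.3)
    expect_identical(unname(attr(s2, "missing")["B"]), "reports")
    ## equal counts: every text score equals the max DisGeNET score
    s3 <- experimentScore(c(A = 4, B = 4, C = 4), c(A = 0.6, B = 0.2))
    expect_true(all(attr(s3, "textMining") == 0.6))
    ## all-zero counts are fine; negative input is not
    s4 <- experimentScore(c(A = 0, B = 0), c(A = 0.5))
    expect_true(all(attr(s4, "textMining") == 0))
    expect_error(experimentScore(c(A = -1), c(A = 0.5)), "non-negative")
    expect_error(experimentScore(c(A = 1), c(A = 1.5)), "\\[0, 1\\]")
})

test_that("final score is the exact sum of its layers on the union universe", {
    exp <- experimentScore(c(A = 10, B = 5), c(A = 0.4, B = 0.8))
    expr <- c(A = 0.7, C = 0.3)
    st <- finalScore(exp, expr)
    df <- scoreFrame(st)
    expect_equal(df["A", "final"], 1.2 + 0.7)
    expect_equal(df["B", "final"], 1.2)       # expression missing
    expect_true(df["B", "expressionMissing"])
    expect_equal(df["C", "final"], 0.3)       # experiment missing
    expect_true(df["C", "experimentMissing"])
    ## algebraic identity on random tables
    set.seed(99)
    g <- sprintf("g%03d", 1:200)
    e1 <- setNames(runif(200, 0, 3), g)
    e2 <- setNames(rnorm(150), sample(g, 150))
    df2 <- scoreFrame(finalScore(e1, e2))
    expect_lt(max(abs(df2$final - df2$experiment - df2$expression)), 1e-12)
    expect_lt(max(abs(df2$experiment - df2$textMining - df2$disgenet)),
              1e-12)
})

test_that("percentile selection matches the interpolated order statistics", {
    folds <- setNames(as.numeric(1:1000), sprintf("g%04d", 1:1000))
    sel <- selectPercentileGenes(folds)
    expect_identical(sort(highGenes(sel)), sprintf("g%04d", 996:1000))
    expect_identical(sort(lowGenes(sel)), sprintf("g%04d", 1:3))
    cuts <- selectionCutoffs(sel)
    expect_equal(unname(cuts["hiCutoff"]), 995.005)
    expect_equal(unname(cuts["loCutoff"]), 3.4975)
    expect_warning(selectPercentileGenes(setNames(rep(1, 20),
                                                  paste0("g", 1:20))),
                   "empty selection")
})

test_that("selection membership equals the brute-force sort oracle", {
    set.seed(123)
    for (i in 1:200) {
        n <- sample(20:400, 1)
        v <- setNames(rnorm(n), paste0("g", seq_len(n)))
        sel <- selectPercentileGenes(v)
        hiCut <- bfPercentile(v, 99.5)
        loCut <- bfPercentile(v, 0.25)
        expect_identical(sort(highGenes(sel)), sort(names(v)[v > hiCut]))
        expect_identical(sort(lowGenes(sel)), sort(names(v)[v < loCut]))
        ## size bounds for distinct-valued inputs
        expect_lte(length(highGenes(sel)), ceiling(0.005 * n) + 1)
        expect_lte(length(lowGenes(sel)), ceiling(0.0025 * n) + 1)
    }
})

test_that("centile filtering uses strict exceedance of the rank percentile", {
    scores <- setNames(as.numeric(1:100), sprintf("g%03d", 1:100))
    up <- centileFilter(scores, 25, "above")
    expect_identical(sort(up), sprintf("g%03d", 26:100))
    expect_length(up, 75)
    down <- centileFilter(scores, 25, "below")
    expect_identical(sort(down), sprintf("g%03d", 1:25))
    expect_warning(tied <- centileFilter(setNames(rep(2, 5), letters[1:5]),
                                         25, "above"),
                   "tied")
    expect_length(tied, 0)
    expect_length(centileFilter(scores, 0, "above"), 100)
    ## strict-median semantics on a symmetric 4-value vector
    sym <- c(a = -2, b = -1, c = 1, d = 2)
    expect_identical(sort(centileFilter(sym, 50, "above")), c("c", "d"))
})
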