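# Small in-code fixture builders shared across test files.

# expression dataset from an explicit matrix
edsFromMatrix <- function(m, group, batch = 1) {
    ExpressionDataset(m, group = group, batch = batch)
}

# two-group dataset with given per-group column values for a few genes
edsTwoGroup <- function(caseVals, controlVals,
                        genes = sprintf("G%02d", seq_len(nrow(caseVals)))) {
    m <- cbind(controlVals, caseVals)
    rownames(m) <- genes
    colnames(m) <- c(sprintf("c%02d", seq_len(ncol(controlVals))),
                     sprintf("s%02d", seq_len(ncol(caseVals))))
    ExpressionDataset(m, group = c(rep("control", ncol(controlVals)),
                                   rep("STEMI", ncol(caseVals))))
}

# independent brute-force linear-interpolation order statistic
# (sort-based; deliberately not stats::quantile)
bfPercentile <- function(v, pct) {
    s <- sort(v)
    n <- length(s)
    h <- (n - 1) * pct / 100 + 1
    lo <- floor(h)
    if (lo >= n) return(s[n])
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# independent pooled-variance two-sample t test
bfPooledT <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# exhaustive upper-tail hypergeometric probability via binomial coefficients
bfHyperTail <- function(overlap, setSize, querySize, universeSize) {
    ks <- overlap:min(setSize, querySize)
    sum(choose(setSize, ks) *
        choose(universeSize - setSize, querySize - ks)) /
        choose(universeSize, querySize)
}
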