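test_that("total allowable error follows Bias + (dSE + Z) * CV", {
    expect_equal(allowableTotalError(sigmaParams(cv = 1, bias = 0), 0),
                 1.96)
    expect_equal(allowableTotalError(sigmaParams(cv = 2, bias = 0.5), 2),
                 0.5 + 3.96 * 2)
    ## dSE = -Z zeroes the CV term
    expect_equal(allowableTotalError(sigmaParams(cv = 2, bias = 0.5),
                                     -1.96), 0.5)
    expect_error(sigmaParams(cv = 0), "CV")
    expect_error(sigmaParams(cv = 1, pfr = 1.2), "Pfr")
})

test_that("sigma metric inverts the total-error formula exactly", {
    expect_equal(sigmaMetric(3, 0, 1), 3)
    expect_equal(sigmaMetric(5, 5, 2), 0)
    expect_error(sigmaMetric(3, 0, 0), "CV")
    cfg <- sigmaParams(cv = 0.37, bias = 1.1)
    for (d in seq(-1, 6, by = 0.5)) {
        expect_lt(abs(sigmaMetric(allowableTotalError(cfg, d), 1.1, 0.37) -
                      (d + 1.96)), 1e-12)
    }
})

test_that("error-detection probability follows the normal model", {
    expect_equal(ped(3), 0.5)
    expect_equal(ped(2), pnorm(-1))
    expect_equal(round(100 * ped(2)), 16)
    expect_equal(ped(4), pnorm(1))
    expect_equal(round(100 * ped(4)), 84)
    ## monotone nondecreasing, and exactly 1/2 at the detection limit
    d <- seq(0, 6, by = 0.25)
    expect_true(all(diff(ped(d)) >= 0))
    expect_equal(ped(2.5, detectionLimit = 2.5), 0.5)
    expect_error(ped(-1), "non-negative")
})

test_that("profile shifting is additive and broadcasts the CV", {
    f <- c(A = 0.4, B = 0.6)
    expect_identical(shiftProfile(f, 0.1, 0), f)
    expect_equal(shiftProfile(f, 0.1, 2), c(A = 0.6, B = 0.8))
    expect_equal(shiftProfile(f, 0.1, 3),
                 shiftProfile(f, c(0.1, 0.1), 3))
    expect_error(shiftProfile(f, c(0.1, 0.1, 0.1), 1), "length")
    expect_error(shiftProfile(f, 0.1, -1), ">= 0")
})

test_that("overlap test matches a textbook t computation", {
    expect_identical(overlapTest(rep(1, 5), rep(1, 5)),
                     list(t = 0, p = 1, significant = FALSE))
    sep <- overlapTest(rnorm(10, 0, 0.01) + 10, rnorm(10, 0, 0.01))
    expect_lt(sep$p, 0.05)
    set.seed(77)
    a <- rnorm(13, 0.5, 0.2); b <- rnorm(13, 0.4, 0.3)
    got <- overlapTest(a, b)
    want <- bfPooledT(a, b)
    expect_lt(abs(got$t - want$t), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
    ## Welch variant agrees with stats::t.test default
    gotW <- overlapTest(a, b, welch = TRUE)
    ref <- t.test(a, b)
    expect_equal(gotW$p, ref$p.value)
    expect_error(overlapTest(1, 1:3), "at least 2")
})

test_that("the cut-off search recovers a constructed compensation round", {
    set.seed(101)
    acute <- rnorm(13, 0.5, 0.02)
    cv <- 0.1
    ref <- acute + 3 * cv + rnorm(13, 0, 0.005)
    res <- findCutoff(acute, ref, cv, sigmaParams(cv = cv),
                      mapping = dayMapping("reported"))
    expect_identical(cutoffRound(res), 3L)
    expect_equal(cutoffPed(res), 0.5)
    expect_equal(cutoffDays(res), 3)
    tab <- cutoffRounds(res)
    expect_identical(tab$k, 0:10)
    expect_true(all(tab$significant[1:3]))
    ## identical profiles overlap immediately
    expect_identical(cutoffRound(findCutoff(acute, acute, cv)), 0L)
    ## vanishing CV never compensates a real difference
    expect_warning(none <- findCutoff(acute, acute + 1, 1e-9,
                                      sigmaParams(cv = 1e-9)),
                   "no non-significant")
    expect_true(is.na(cutoffRound(none)))
})

test_that("scaling the CV up never delays the cut-off round", {
    set.seed(55)
    acute <- rnorm(13, 0.5, 0.02)
    ref <- acute + 0.3
    ks <- vapply(c(0.075, 0.1, 0.15, 0.3), function(cv)
        cutoffRound(findCutoff(acute, ref, cv, sigmaParams(cv = cv))),
        integer(1))
    expect_true(all(diff(ks) <= 0))
})

test_that("under the null the cut-off is round zero at about 1 - alpha", {
    set.seed(202)
    hits <- replicate(200, {
        a <- rnorm(13, 0.5, 0.05)
        b <- rnorm(13, 0.5, 0.05)
        cutoffRound(suppressWarnings(
            findCutoff(a, b, 0.05, sigmaParams(cv = 0.05),
                       maxRounds = 3))) == 0L
    })
    mcse <- sqrt(0.95 * 0.05 / 200)
    expect_gte(mean(hits, na.rm = TRUE), 0.95 - 3 * mcse)
})

test_that("fold trends match the closed-form simple regression", {
    tr <- profileTrend(c(2, 1, 0), times = c(0, 7, 30))
    expect_lt(tr$slope, 0)
    flat <- profileTrend(rep(1.3, 4), times = c(0, 7, 14, 30))
    expect_identical(c(flat$slope, flat$p), c(0, 1))
    set.seed(9)
    y <- matrix(rnorm(15), 3, 5,
                dimnames = list(paste0("g", 1:3), NULL))
    times <- c(0, 3, 7, 14, 30)
    got <- profileTrend(y, times)
    for (i in 1:3) {
        fit <- summary(lm(y[i, ] ~ times))$coefficients
        expect_lt(abs(got$slope[i] - fit["times", "Estimate"]), 1e-10)
        expect_lt(abs(got$p[i] - fit["times", "Pr(>|t|)"]), 1e-10)
    }
    expect_error(profileTrend(c(1, 2), times = c(0, 7)), "3 time points")
})
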