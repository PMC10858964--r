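## Sigma-metric machinery and the dSE-round overlap procedure that yields
## the time cut-off for measuring a gene profile after myocardial
## infarction.
##
## Model: TEa = SE + RE with SE = Bias + dSE and RE = CV + dRE. With
## normally distributed data, Pfr = 5% and dRE = 0 this collapses to
## TEa = Bias + (dSE + 1.96) * CV, and Sigma = (TE - Bias)/CV, so
## Sigma(TEa(d)) = d + Z identically. The probability of error detection
## Ped uses a separate detection-limit quantile: under a standard-normal
## error model a systematic shift of dSE (in CV units) is detected with
## probability P(Z > limit - dSE). The default limit of 3 (a 3-SD control
## rule) yields Ped = 16%, 50%, 84% at dSE = 2, 3, 4.

#' Total allowable error at a given systematic-error increment
#'
#' \code{TEa = Bias + (dSE + Z) * CV}.
#'
#' @param cfg a \linkS4class{SigmaParams}.
#' @param dse systematic-error increment in CV units.
#' @return Numeric (scalar CV) or per-gene vector.
#' @export
allowableTotalError <- function(cfg, dse) {
    stopifnot(is(cfg, "SigmaParams"))
    validObject(cfg)
    cfg@bias + (dse + cfg@z) * cfg@cv
}

#' Sigma metric of a measurement procedure
#'
#' \code{Sigma = (TE - Bias) / CV}: the process capability in SD units.
#'
#' @param te total (allowable) error.
#' @param bias systematic offset.
#' @param cv imprecision; must be > 0.
#' @return Numeric.
#' @export
sigmaMetric <- function(te, bias, cv) {
    if (any(cv <= 0)) stop("CV must be > 0")
    (te - bias) / cv
}

#' Probability of error detection
#'
#' Probability that a result carrying a systematic shift of \code{dse} CV
#' units exceeds the detection limit under a standard normal error model:
#' \code{Ped = P(Z > detectionLimit - dse)}. Monotone increasing in
#' \code{dse}; equals 0.5 exactly at \code{dse = detectionLimit}.
#'
#' @param dse systematic-error increment in CV units (>= 0).
#' @param detectionLimit control-limit quantile (default 3, a 3-SD rule).
#' @return Probability in [0, 1].
#' @export
ped <- function(dse, detectionLimit = 3) {
    if (any(dse < 0)) stop("dse must be non-negative")
    stats::pnorm(dse - detectionLimit)
}

#' Shift a fold profile by k CV-sized increments
#'
#' Per gene: \code{fold + k * cv} (cv scalar or per-gene, broadcast).
#'
#' @param folds numeric fold vector.
#' @param cv positive scalar or vector matching \code{folds}.
#' @param k round index (>= 0).
#' @return Shifted fold vector.
#' @export
shiftProfile <- function(folds, cv, k) {
    if (k < 0) stop("round index k must be >= 0")
    if (any(cv <= 0)) stop("cv must be positive")
    if (length(cv) != 1L && length(cv) != length(folds))
        stop("cv must be scalar or match the fold vector length")
    folds + k * cv
}

#' Two-tailed t test of profile overlap
#'
#' Two-sample two-tailed t test between two fold vectors on the same gene
#' panel. Pooled-variance Student test by default, Welch by flag.
#' Identical vectors (zero variance, zero mean difference) return p = 1 by
#' convention.
#'
#' @param profileA,profileB numeric fold vectors (length >= 2).
#' @param alpha significance level.
#' @param welch use the Welch (unequal-variance) test.
#' @return list(t, p, significant).
#' @export
overlapTest <- function(profileA, profileB, alpha = 0.05, welch = FALSE) {
    if (length(profileA) < 2L || length(profileB) < 2L)
        stop("both profiles need at least 2 values")
    if (stats::var(profileA) + stats::var(profileB) < .Machine$double.eps) {
        if (abs(mean(profileA) - mean(profileB)) < .Machine$double.eps^0.5)
            return(list(t = 0, p = 1, significant = FALSE))
        return(list(t = Inf, p = 0, significant = TRUE))
    }
    ht <- stats::t.test(profileA, profileB, var.equal = !welch)
    list(t = unname(ht$statistic), p = ht$p.value,
         significant = ht$p.value < alpha)
}

#' Day mapping presets for dSE rounds
#'
#' The dSE round at which the shifted acute profile first overlaps the
#' 7-day profile is mapped to a time after myocardial infarction. The
#' \code{"reported"} preset is the empirical mapping established for the
#' STEMI/NSTEMI blood panels (dSE 2 -> 1 day, 3 -> 3 days, 4 -> 2 days);
#' it is not monotone, so no formula-based default is offered.
#'
#' @param name preset name.
#' @return Named numeric vector: names are dSE rounds, values days.
#' @export
dayMapping <- function(name = c("reported")) {
    name <- match.arg(name)
    structure(c(`2` = 1, `3` = 3, `4` = 2), mappingName = name)
}

#' Find the time cut-off by iterated CV-shift and overlap testing
#'
#' Iterates rounds k = 0, 1, ..., \code{maxRounds}: shifts the acute fold
#' profile by \code{k * cv} and t-tests it against the reference (7-day)
#' profile. The cut-off round \code{k*} is the first k whose overlap is not
#' significant (p >= alpha); the result carries Ped(k*) and, when a day
#' mapping covers k*, the mapped time after MI. Before searching, the
#' caller should confirm that the reference and the 30-day profile do not
#' differ significantly (see \code{\link{overlapTest}}); the search itself
#' only compares against the reference.
#'
#' @param acuteFolds,referenceFolds numeric fold vectors on the same gene
#'   panel.
#' @param cv positive scalar or per-gene CV added per round.
#' @param cfg a \linkS4class{SigmaParams} (supplies alpha via
#'   \code{pfr} and the Ped detection limit).
#' @param maxRounds maximum dSE round.
#' @param mapping optional named day mapping (see \code{\link{dayMapping}}).
#' @param welch use the Welch test.
#' @return A \linkS4class{CutoffResult}.
#' @export
findCutoff <- function(acuteFolds, referenceFolds, cv,
                       cfg = sigmaParams(cv = if (length(cv) == 1L) cv else
                                             mean(cv)),
                       maxRounds = 10, mapping = NULL, welch = FALSE) {
    stopifnot(is(cfg, "SigmaParams"))
    alpha <- cfg@pfr
    rounds <- lapply(0:maxRounds, function(k) {
        shifted <- shiftProfile(acuteFolds, cv, k)
        ht <- overlapTest(shifted, referenceFolds, alpha = alpha,
                          welch = welch)
        data.frame(k = as.integer(k), shift = k * mean(cv),
                   meanFold = mean(shifted), t = ht$t, p = ht$p,
                   significant = ht$significant)
    })
    tab <- do.call(rbind, rounds)
    hit <- which(!tab$significant)
    kStar <- if (length(hit)) tab$k[hit[1L]] else NA_integer_
    if (is.na(kStar))
        warning("no non-significant overlap within ", maxRounds, " rounds")
    days <- NA_real_
    mapName <- "none"
    if (!is.null(mapping) && !is.na(kStar) &&
        as.character(kStar) %in% names(mapping)) {
        days <- unname(mapping[[as.character(kStar)]])
        mapName <- attr(mapping, "mappingName") %||% "custom"
    }
    new("CutoffResult", rounds = tab, kStar = kStar,
        ped = if (is.na(kStar)) NA_real_ else
            ped(kStar, cfg@detectionLimit),
        days = days, mappingName = mapName, alpha = alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene linear trend of folds over time
#'
#' Ordinary least-squares slope of fold versus time per gene, with the
#' two-tailed t test of the slope. Constant series return slope 0 and
#' p = 1 by convention.
#'
#' @param foldSeries numeric matrix, genes x time points (or a vector for
#'   one gene).
#' @param times numeric time points (days), length >= 3.
#' @return data.frame(gene, slope, intercept, t, p).
#' @export
profileTrend <- function(foldSeries, times) {
    if (is.null(dim(foldSeries)))
        foldSeries <- matrix(foldSeries, nrow = 1L,
                             dimnames = list("gene1", NULL))
    if (length(times) < 3L) stop("need at least 3 time points")
    if (ncol(foldSeries) != length(times))
        stop("foldSeries columns must match times")
    n <- length(times)
    tc <- times - mean(times)
    sxx <- sum(tc^2)
    res <- t(apply(foldSeries, 1L, function(y) {
        slope <- sum(tc * y) / sxx
        intercept <- mean(y) - slope * mean(times)
        resid <- y - (intercept + slope * times)
        s2 <- sum(resid^2) / (n - 2L)
        if (s2 < .Machine$double.eps) {
            if (abs(slope) < .Machine$double.eps^0.5)
                return(c(slope = 0, intercept = mean(y), t = 0, p = 1))
            return(c(slope = slope, intercept = intercept, t = Inf, p = 0))
        }
        tval <- slope / sqrt(s2 / sxx)
        c(slope = slope, intercept = intercept, t = tval,
          p = 2 * stats::pt(-abs(tval), df = n - 2L))
    }))
    data.frame(gene = rownames(foldSeries), res, row.names = NULL)
}
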