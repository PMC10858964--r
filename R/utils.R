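## Internal helpers.

## Derive a child seed from a parent seed and a stream index, so each
## sub-generator is reproducible in isolation. Kept strictly below 2^31 - 1.
childSeed <- function(seed, stream) {
    as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(stream) * 1000003) %% 2147483646) + 1L
}

## Evaluate expr under a local RNG state.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Uppercase HGNC-style symbol normalization; matching across evidence
## tables is case-insensitive exact string match.
normSymbols <- function(x) toupper(trimws(as.character(x)))

## Linear-interpolation percentile (quantile type 7) of v at pct (0-100).
pctCutoff <- function(v, pct) {
    unname(stats::quantile(v, pct / 100, type = 7, names = FALSE))
}
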