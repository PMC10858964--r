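## Packaged gene panels.
##
## The gene SYMBOLS are the published high-score STEMI and NSTEMI blood
## panels (selected at final score > 12 and > 8 respectively, with the
## fold > 0.4 sub-profile {IPO11, CA1, XK, ACOX2} inside the NSTEMI
## panel), together with the text-mining comparator genes. The per-gene
## score and fold VALUES are synthetic: only the thresholds were
## published, so the fixtures carry values consistent with them, not
## measured ones (hence the "_synthetic_" file names).

#' Packaged STEMI/NSTEMI panel score fixtures
#'
#' @param condition which panel.
#' @return data.frame(gene, score, fold). Scores above the panel's
#'   published selection threshold (12 for STEMI, 8 for NSTEMI) mark the
#'   panel members; lower-scoring rows are the text-mining comparator
#'   genes.
#' @examples
#' p <- panelScores("STEMI")
#' selectProfile(setNames(p$score, p$gene), 12, condition = "STEMI")
#' @export
panelScores <- function(condition = c("STEMI", "NSTEMI")) {
    condition <- match.arg(condition)
    f <- system.file("extdata",
                     paste0(tolower(condition),
                            "_panel_synthetic_scores.tsv"),
                     package = "stemiProfiles", mustWork = TRUE)
    utils::read.delim(f, colClasses = c("character", "numeric", "numeric"))
}
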