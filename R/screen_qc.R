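## Per-screen quality control: F-measure at BF = 5 and essential-gene count.

#' Evaluate one screen's quality
#'
#' Computes the precision-recall F-measure at `bf_threshold` against the
#' reference sets and counts genes called essential (`BF > bf_threshold`)
#' across all scored genes. Unscorable screens yield `scorable = FALSE` and
#' never pass.
#'
#' @param bf named numeric vector of one cell line's Bayes factors, or NULL
#'   for an unscorable screen.
#' @param essentials,nonessentials reference symbol vectors.
#' @param cell_line screen label.
#' @param bf_threshold Bayes-factor threshold (default 5).
#' @param f_min,max_essential pass thresholds; kept iff
#'   `f_measure > f_min` and `n_essential < max_essential` (strict
#'   inequalities).
#' @return one-row data.frame: cell_line, f_measure, n_essential, scorable,
#'   pass.
#' @export
evaluateScreen <- function(bf, essentials, nonessentials,
                           cell_line = "screen", bf_threshold = 5,
                           f_min = 0.85, max_essential = 2000) {
    if (is.null(bf) || !length(bf)) {
        return(data.frame(cell_line = cell_line, f_measure = NA_real_,
                          n_essential = NA_integer_, scorable = FALSE,
                          pass = FALSE))
    }
    pr <- precisionRecall(bf, essentials, nonessentials)
    f <- fMeasure(pr, bf_threshold)
    n_ess <- sum(bf > bf_threshold)
    data.frame(cell_line = cell_line, f_measure = f, n_essential = n_ess,
               scorable = TRUE,
               pass = f > f_min && n_ess < max_essential)
}

#' QC records for every column of an EssentialityMatrix
#'
#' @param bf an [EssentialityMatrix-class].
#' @inheritParams evaluateScreen
#' @return data.frame with one row per cell line (input column order).
#' @export
screenQC <- function(bf, essentials = NULL, nonessentials = NULL,
                     bf_threshold = 5, f_min = 0.85, max_essential = 2000) {
    md <- S4Vectors::metadata(bf)
    if (is.null(essentials)) essentials <- md$essentials
    if (is.null(nonessentials)) nonessentials <- md$nonessentials
    m <- bfMatrix(bf)
    do.call(rbind, lapply(colnames(m), function(cl)
        evaluateScreen(setNames(m[, cl], rownames(m)), essentials,
                       nonessentials, cell_line = cl,
                       bf_threshold = bf_threshold, f_min = f_min,
                       max_essential = max_essential)))
}

#' Select screens passing quality control
#'
#' Strict-inequality semantics: a screen is kept iff `f_measure > f_min` and
#' `n_essential < max_essential`. Thresholds are overridable for other
#' libraries (e.g. `f_min = 0.80`).
#'
#' @param records data.frame from [screenQC()] / [evaluateScreen()].
#' @param f_min minimum F-measure, exclusive (default 0.85).
#' @param max_essential maximum essential-gene count, exclusive (default
#'   2000).
#' @return character vector of passing cell lines, in input order.
#' @export
filterScreens <- function(records, f_min = 0.85, max_essential = 2000) {
    if (!nrow(records)) stop("no QC records supplied")
    keep <- records$scorable & !is.na(records$f_measure) &
        records$f_measure > f_min & records$n_essential < max_essential
    if (!any(keep))
        stop(sprintf(
            "no screens pass QC (f_min > %g, n_essential < %d); best F = %g",
            f_min, max_essential, suppressWarnings(max(records$f_measure,
                                                       na.rm = TRUE))))
    records$cell_line[keep]
}
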