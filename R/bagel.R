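## Bayes-factor essentiality scoring: reference-distribution log-ratios with
## a linear-regression extension of the dynamic range, trained on
## gold-standard essential / nonessential gene sets under gene-level
## cross-validation.

#' FoldChangeSet: guide x cell-line log2 fold changes
#'
#' One `fc` assay (guides x cell lines), rowData carries the target gene.
#' Values may be NA for guides dropped by the minimum-read filter in a given
#' screen.
#' @export
setClass("FoldChangeSet", contains = "SummarizedExperiment")

#' Compute normalized log2 fold changes versus matched controls
#'
#' Each sample column is scaled to a common library size (default 10 million
#' reads), then `fc = log2((sample + pseudocount) / (control + pseudocount))`
#' against the sample's designated control from the same batch. Guides whose
#' raw control reads fall below `min_reads` are set NA for that screen.
#' Samples with zero total reads are skipped with a warning.
#'
#' @param counts a [ScreenCounts-class].
#' @param pseudocount added to scaled counts before the ratio (default 5).
#' @param min_reads minimum raw control reads for a guide to be scored
#'   (default 0, i.e. keep all).
#' @param lib_size common library size for per-column scaling (default 1e7).
#' @return a [FoldChangeSet-class] with one column per non-control sample,
#'   named by cell line.
#' @export
computeFoldChanges <- function(counts, pseudocount = 5, min_reads = 0,
                               lib_size = 1e7) {
    cts <- SummarizedExperiment::assay(counts, "counts")
    cd <- SummarizedExperiment::colData(counts)
    tot <- colSums(cts)
    dead <- tot == 0
    if (any(dead & cd$is_control))
        stop("control sample(s) with zero total reads: ",
             paste(colnames(cts)[dead & cd$is_control], collapse = ", "))
    scaled <- sweep(cts, 2L, ifelse(tot > 0, tot, 1), "/") * lib_size
    samples <- colnames(cts)[!cd$is_control]
    keep <- logical(length(samples))
    fc <- matrix(NA_real_, nrow(cts), length(samples),
                 dimnames = list(rownames(cts), samples))
    for (i in seq_along(samples)) {
        s <- samples[i]
        if (tot[s] == 0) {
            warning("sample ", s, " has zero total reads; screen skipped")
            next
        }
        ctl <- cd[s, "control"]
        fc[, i] <- log2((scaled[, s] + pseudocount) /
                        (scaled[, ctl] + pseudocount))
        if (min_reads > 0) fc[cts[, ctl] < min_reads, i] <- NA_real_
        keep[i] <- TRUE
    }
    fc <- fc[, keep, drop = FALSE]
    cl <- cd[samples[keep], "cell_line"]
    if (anyDuplicated(cl))
        stop("duplicate cell-line names among scored samples")
    colnames(fc) <- cl
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fc = fc),
        rowData = SummarizedExperiment::rowData(counts))
    methods::new("FoldChangeSet", se)
}

#' Fit the reference fold-change evidence model for one screen
#'
#' Kernel density estimates (Gaussian kernel, Scott-rule bandwidth by
#' default) of the guide-level fold changes of the core-essential and
#' nonessential reference genes, the log2 density ratio on a shared grid,
#' and a linear fit of that ratio against fold change over the interval
#' where both densities exceed `support_floor` of their maxima. The linear
#' fit extends the classifier's dynamic range beyond the data support;
#' extrapolated branches are anchored at the fit-range boundaries so the
#' curve is continuous.
#'
#' @param fc numeric vector of guide-level fold changes for one screen.
#' @param genes character, target gene per element of `fc`.
#' @param essentials,nonessentials character vectors of reference symbols.
#' @param bw bandwidth rule passed to [stats::density()] (default `"nrd"`,
#'   Scott's rule).
#' @param grid_n grid size (default 1024).
#' @param support_floor fraction of each density's maximum below which the
#'   density is considered unsupported (default `2^-7`).
#' @param min_ref minimum observed reference genes per class (default 10).
#' @return a [ReferenceModel-class]; `@scorable` is FALSE when the two
#'   reference distributions are indistinguishable (non-negative slope or
#'   empty fit range), mirroring screens that fail to score.
#' @export
fitReferenceModel <- function(fc, genes, essentials, nonessentials,
                              bw = "nrd", grid_n = 1024,
                              support_floor = 2^-7, min_ref = 10) {
    ok <- is.finite(fc)
    fc <- fc[ok]; genes <- genes[ok]
    e_fc <- fc[genes %in% essentials]
    n_fc <- fc[genes %in% nonessentials]
    if (length(unique(genes[genes %in% essentials])) < min_ref ||
        length(unique(genes[genes %in% nonessentials])) < min_ref)
        stop("need >= ", min_ref, " observed reference genes per class")
    lo <- min(e_fc, n_fc) - 1; hi <- max(e_fc, n_fc) + 1
    de <- density(e_fc, bw = bw, n = grid_n, from = lo, to = hi)
    dn <- density(n_fc, bw = bw, n = grid_n, from = lo, to = hi)
    grid <- de$x
    renorm <- function(y) {
        dx <- diff(grid)
        y / sum((y[-1] + y[-length(y)]) / 2 * dx)
    }
    fe <- renorm(de$y); fn <- renorm(dn$y)
    eps <- .Machine$double.xmin
    logRatio <- log2(pmax(fe, eps)) - log2(pmax(fn, eps))
    supE <- fe > support_floor * max(fe)
    supN <- fn > support_floor * max(fn)
    supported <- supE & supN
    unscorable <- function() methods::new("ReferenceModel",
        grid = grid, essDensity = fe, nonessDensity = fn, logRatio = logRatio,
        fitRange = numeric(2), slope = NA_real_, interceptLo = NA_real_,
        interceptHi = NA_real_, scorable = FALSE)
    if (sum(supported) < 3L) {
        ## No joint support: either the classes are indistinguishable, or they
        ## are so well separated that the densities never overlap above the
        ## floor. The latter is maximal evidence, not failure: fit over the
        ## union support with floored densities (the log ratio then runs from
        ## strongly positive through ~0 to strongly negative, still monotone).
        if (!any(supE) || !any(supN) ||
            median(grid[supE]) >= median(grid[supN]))
            return(unscorable())
        logRatio <- log2(pmax(fe, support_floor * max(fe))) -
                    log2(pmax(fn, support_floor * max(fn)))
        supported <- supE | supN
    }
    idx <- range(which(supported))
    sel <- seq(idx[1], idx[2])
    fit <- lm(logRatio[sel] ~ grid[sel])
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) return(unscorable())
    fr <- c(grid[idx[1]], grid[idx[2]])
    yLo <- logRatio[idx[1]]; yHi <- logRatio[idx[2]]
    methods::new("ReferenceModel",
        grid = grid, essDensity = fe, nonessDensity = fn, logRatio = logRatio,
        fitRange = fr, slope = slope,
        interceptLo = yLo - slope * fr[1],
        interceptHi = yHi - slope * fr[2],
        scorable = TRUE)
}

#' Log2 evidence for a fold-change value under a reference model
#'
#' Inside the fit range the smoothed log2 density ratio is interpolated;
#' outside, the linear extension `intercept + slope * fc` (anchored at the
#' nearer boundary, hence continuous there) is used.
#'
#' @param fc numeric vector of fold changes (must be finite).
#' @param model a scorable [ReferenceModel-class].
#' @return numeric vector of log2 evidence values.
#' @export
guideLogRatio <- function(fc, model) {
    if (!model@scorable) stop("model is not scorable")
    if (any(!is.finite(fc))) stop("non-finite fold change")
    fr <- model@fitRange
    sel <- model@grid >= fr[1] & model@grid <= fr[2]
    out <- numeric(length(fc))
    inr <- fc >= fr[1] & fc <= fr[2]
    if (any(inr))
        out[inr] <- approx(model@grid[sel], model@logRatio[sel],
                           xout = fc[inr], rule = 2)$y
    below <- fc < fr[1]
    if (any(below)) out[below] <- model@interceptLo + model@slope * fc[below]
    above <- fc > fr[2]
    if (any(above)) out[above] <- model@interceptHi + model@slope * fc[above]
    out
}

## deterministic stratified fold assignment over reference genes
assignFolds <- function(ess, noness, n_folds, seed) {
    set.seed(seed)
    f <- integer(0)
    nm <- character(0)
    for (cls in list(ess, noness)) {
        cls <- sort(cls)
        k <- sample(rep_len(seq_len(n_folds), length(cls)))
        f <- c(f, k); nm <- c(nm, cls)
    }
    setNames(f, nm)
}

#' Gene-level log2 Bayes factors across screens
#'
#' For each screen, reference genes are split into `n_folds` cross-validation
#' folds; each fold's model is trained on the remaining reference genes. A
#' gene's Bayes factor is the sum over its guides of the guide log2 evidence,
#' averaged over folds; reference genes are scored only by the fold in which
#' they were held out, so no gene is scored by a model trained on itself.
#' Screens whose reference classes are indistinguishable are marked
#' unscorable and dropped with a warning.
#'
#' @param fc a [FoldChangeSet-class].
#' @param essentials,nonessentials reference gene symbol vectors.
#' @param n_folds cross-validation folds over reference genes (default 10).
#' @param seed integer seed controlling fold assignment (default 42).
#' @param ... passed to [fitReferenceModel()].
#' @return an [EssentialityMatrix-class]; `metadata()` carries the cached
#'   per-guide log-ratio matrix (`guide_log_ratios`), the guide-to-gene map,
#'   fold scheme, seed, and any unscorable cell lines.
#' @export
geneBayesFactors <- function(fc, essentials, nonessentials, n_folds = 10,
                             seed = 42, ...) {
    fcm <- SummarizedExperiment::assay(fc, "fc")
    genes <- SummarizedExperiment::rowData(fc)$gene
    is_ref <- genes %in% c(essentials, nonessentials)
    glr <- matrix(NA_real_, nrow(fcm), ncol(fcm), dimnames = dimnames(fcm))
    unscorable <- character(0)
    for (j in seq_len(ncol(fcm))) {
        v <- fcm[, j]
        ok <- is.finite(v)
        ess_obs <- intersect(essentials, genes[ok])
        non_obs <- intersect(nonessentials, genes[ok])
        folds <- assignFolds(ess_obs, non_obs, n_folds, seed)
        acc <- matrix(0, sum(ok), 2L)  # sum of LR, number of folds counted
        vi <- v[ok]; gi <- genes[ok]
        failed <- FALSE
        for (k in seq_len(n_folds)) {
            held <- names(folds)[folds == k]
            train <- ok & is_ref & !(genes %in% held)
            model <- tryCatch(
                fitReferenceModel(v[train], genes[train], essentials,
                                  nonessentials, ...),
                error = function(e) NULL)
            if (is.null(model) || !model@scorable) { failed <- TRUE; break }
            lr <- guideLogRatio(vi, model)
            ref_gene <- gi %in% names(folds)
            use <- !ref_gene | gi %in% held
            acc[use, 1L] <- acc[use, 1L] + lr[use]
            acc[use, 2L] <- acc[use, 2L] + 1L
        }
        if (failed) {
            unscorable <- c(unscorable, colnames(fcm)[j])
            next
        }
        glr[ok, j] <- ifelse(acc[, 2L] > 0, acc[, 1L] / acc[, 2L], NA_real_)
    }
    keep_col <- !(colnames(fcm) %in% unscorable)
    if (length(unscorable))
        warning("unscorable screen(s) dropped (reference classes ",
                "indistinguishable): ", paste(unscorable, collapse = ", "))
    if (!any(keep_col)) stop("no scorable screens")
    glr <- glr[, keep_col, drop = FALSE]
    scored <- rowSums(is.finite(glr)) > 0
    bf <- rowsum(ifelse(is.finite(glr[scored, , drop = FALSE]), glr[scored, , drop = FALSE], 0),
                 group = genes[scored])
    ## genes lacking any scored guide in some screen get the sum over scored
    ## guides there; genes with zero scored guides anywhere were dropped above
    se <- SummarizedExperiment::SummarizedExperiment(assays = list(bf = bf))
    S4Vectors::metadata(se) <- list(
        normalized = FALSE, n_folds = n_folds, seed = seed,
        guide_log_ratios = glr, guide_gene = setNames(genes, rownames(fcm)),
        unscorable = unscorable,
        essentials = essentials, nonessentials = nonessentials)
    methods::new("EssentialityMatrix", se)
}

#' Precision-recall curve of a screen against the reference sets
#'
#' Thresholds sweep the observed reference-gene Bayes factors in descending
#' order; at each threshold genes with `BF >= threshold` are called
#' essential. Precision and recall are computed among reference genes only.
#'
#' @param bf named numeric vector: one cell line's Bayes factors.
#' @param essentials,nonessentials reference symbol vectors.
#' @return data.frame with columns threshold, tp, fp, precision, recall.
#' @export
precisionRecall <- function(bf, essentials, nonessentials) {
    ess <- intersect(names(bf), essentials)
    non <- intersect(names(bf), nonessentials)
    if (!length(ess) || !length(non))
        stop("both reference classes must be present in the scored genes")
    ref_bf <- bf[c(ess, non)]
    is_ess <- c(rep(TRUE, length(ess)), rep(FALSE, length(non)))
    thr <- sort(unique(ref_bf), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(is_ess & ref_bf >= t), 0L)
    fp <- vapply(thr, function(t) sum(!is_ess & ref_bf >= t), 0L)
    data.frame(threshold = thr, tp = tp, fp = fp,
               precision = ifelse(tp + fp > 0, tp / (tp + fp), 1),
               recall = tp / length(ess))
}

#' F-measure at a Bayes-factor threshold
#'
#' Harmonic mean of precision and recall at the nearest observed threshold at
#' or above `bf_threshold` (default BF = 5). Returns 0 when no observed
#' threshold reaches `bf_threshold` or when precision + recall is zero.
#'
#' @param pr data.frame from [precisionRecall()].
#' @param bf_threshold numeric (default 5).
#' @return numeric F-measure in \[0, 1\].
#' @export
fMeasure <- function(pr, bf_threshold = 5) {
    if (!nrow(pr)) stop("empty precision-recall curve")
    cand <- which(pr$threshold >= bf_threshold)
    if (!length(cand)) return(0)
    i <- cand[which.min(pr$threshold[cand])]
    p <- pr$precision[i]; r <- pr$recall[i]
    if (p + r == 0) return(0)
    2 * p * r / (p + r)
}
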