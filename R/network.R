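## Coessentiality network construction: quantile normalization, essentiality
## mask, all-pairs Pearson correlation, genomic-proximity filter, strict
## (Bonferroni) / extended (Benjamini-Hochberg) thresholding, and
## off-target-suspect flagging.

#' Quantile-normalize an essentiality matrix across cell lines
#'
#' Each column's values are replaced by the per-rank mean of the
#' column-sorted values (the shared reference distribution); ties receive the
#' mean of the tied reference values. Genes missing in any screen are dropped
#' first with a message.
#'
#' @param bf an [EssentialityMatrix-class] (raw).
#' @return an [EssentialityMatrix-class] with `metadata()$normalized = TRUE`
#'   and the reference distribution in `metadata()$reference_distribution`.
#' @export
quantileNormalize <- function(bf) {
    m <- bfMatrix(bf)
    if (ncol(m) < 2L) stop("quantile normalization needs >= 2 cell lines")
    drop <- rowSums(!is.finite(m)) > 0
    if (any(drop)) {
        message(sum(drop), " gene(s) missing in >= 1 screen dropped before ",
                "normalization")
        m <- m[!drop, , drop = FALSE]
    }
    if (any(apply(m, 2L, function(x) diff(range(x)) == 0)))
        stop("all-constant column cannot be quantile-normalized")
    qn <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(qn) <- dimnames(m)
    se <- SummarizedExperiment::SummarizedExperiment(assays = list(bf = qn))
    md <- S4Vectors::metadata(bf)
    md$normalized <- TRUE
    md$reference_distribution <- rowMeans(apply(m, 2L, sort))
    S4Vectors::metadata(se) <- md
    methods::new("EssentialityMatrix", se)
}

#' Genes essential in at least `min_lines` cell lines
#'
#' Variation in never-essential genes is noise, and genes essential in only
#' one or two lines cannot support a correlation; both are removed before
#' network construction.
#'
#' @param bf an [EssentialityMatrix-class].
#' @param bf_threshold Bayes factor above which a gene counts as essential in
#'   a line (default 5).
#' @param min_lines minimum number of lines (default 3); genes essential in
#'   fewer than `min_lines` lines are discarded.
#' @return character vector of retained genes.
#' @export
essentialityMask <- function(bf, bf_threshold = 5, min_lines = 3) {
    m <- bfMatrix(bf)
    keep <- rowSums(m > bf_threshold, na.rm = TRUE) >= min_lines
    if (!any(keep))
        stop("no genes essential in >= ", min_lines, " cell lines")
    rownames(m)[keep]
}

#' All-pairs Pearson correlation of essentiality profiles
#'
#' Two-sided p-values via the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Zero-variance profiles are excluded with a warning.
#'
#' @param bf an [EssentialityMatrix-class] (normally quantile-normalized).
#' @param genes genes to correlate (default: all rows).
#' @return data.frame with columns gene_a, gene_b (canonical order), pcc,
#'   p_value, n_obs, proximity_removed (all FALSE).
#' @export
pairwiseCorrelation <- function(bf, genes = NULL) {
    m <- bfMatrix(bf)
    if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
    n <- ncol(m)
    if (n < 3L) stop("need >= 3 cell lines for correlation p-values")
    v <- apply(m, 1L, sd)
    if (any(v == 0)) {
        warning(sum(v == 0), " zero-variance gene profile(s) excluded")
        m <- m[v > 0, , drop = FALSE]
    }
    if (nrow(m) < 2L) stop("fewer than 2 variable gene profiles")
    cc <- cor(t(m))
    ut <- which(upper.tri(cc), arr.ind = TRUE)
    r <- cc[ut]
    r <- pmin(1, pmax(-1, r))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
    p <- 2 * pt(-abs(tt), df = n - 2)
    g <- rownames(m)
    ed <- data.frame(gene_a = g[ut[, 1L]], gene_b = g[ut[, 2L]],
                     pcc = r, p_value = p, n_obs = n,
                     proximity_removed = FALSE, stringsAsFactors = FALSE)
    swap <- ed$gene_a > ed$gene_b
    tmp <- ed$gene_a[swap]; ed$gene_a[swap] <- ed$gene_b[swap]
    ed$gene_b[swap] <- tmp
    ed[order(-abs(ed$pcc), ed$gene_a, ed$gene_b), , drop = FALSE]
}

#' Flag same-chromosome pairs closer than a window
#'
#' Copy-number segments depress counts of all guides they cover, so nearby
#' genes correlate for reasons unrelated to function. Same-chromosome pairs
#' with `|pos_a - pos_b| < window_bp` are marked `proximity_removed` and
#' excluded from thresholding. Pairs with a gene missing from the location
#' map are kept with a warning.
#'
#' @param pairs data.frame from [pairwiseCorrelation()].
#' @param locations data.frame with columns gene, chromosome, position.
#' @param window_bp window size in base pairs (default 2e7 = 20 Mb).
#' @return `pairs` with `proximity_removed` updated.
#' @export
proximityFilter <- function(pairs, locations, window_bp = 2e7) {
    ia <- match(pairs$gene_a, locations$gene)
    ib <- match(pairs$gene_b, locations$gene)
    miss <- is.na(ia) | is.na(ib)
    if (any(miss))
        warning(sum(miss), " pair(s) kept: gene(s) missing from location map")
    near <- !miss &
        locations$chromosome[ia] == locations$chromosome[ib] &
        abs(locations$position[ia] - locations$position[ib]) < window_bp
    pairs$proximity_removed <- pairs$proximity_removed | near
    pairs
}

#' Threshold correlated pairs into a network
#'
#' Strict mode keeps positive correlations at Bonferroni-corrected p < alpha
#' (family size m = pairs surviving the mask and proximity filters); extended
#' mode keeps both signs at Benjamini-Hochberg adjusted p < q.
#'
#' @param pairs data.frame from [pairwiseCorrelation()] (possibly after
#'   [proximityFilter()]).
#' @param mode `"strict"` or `"extended"`.
#' @param alpha family-wise level for strict mode (default 0.05).
#' @param q FDR level for extended mode (default 0.01).
#' @return a [CoessentialityNetwork-class].
#' @export
thresholdNetwork <- function(pairs, mode = c("strict", "extended"),
                             alpha = 0.05, q = 0.01) {
    mode <- match.arg(mode)
    tested <- pairs[!pairs$proximity_removed, , drop = FALSE]
    m <- nrow(tested)
    if (!m) stop("no pairs survive the filters")
    if (mode == "strict") {
        keep <- tested$pcc > 0 & tested$p_value < alpha / m
    } else {
        keep <- p.adjust(tested$p_value, method = "BH") < q
    }
    if (!any(keep)) stop("no significant pairs at the ", mode, " threshold")
    ed <- tested[keep, , drop = FALSE]
    ed$tier <- mode
    ed$sign <- ifelse(ed$pcc >= 0, "+", "-")
    ed$offtarget_suspect <- FALSE
    ed <- canonicalEdges(ed[, c("gene_a", "gene_b", "pcc", "p_value", "n_obs",
                                "tier", "sign", "proximity_removed",
                                "offtarget_suspect")])
    methods::new("CoessentialityNetwork", edges = ed, mode = mode,
                 provenance = list(mode = mode, alpha = alpha, q = q,
                                   m_tested = m,
                                   n_input_pairs = nrow(pairs)))
}

## integer-coded sequence matrix for Hamming comparisons
.seqMatrix <- function(seqs) {
    t(vapply(seqs, function(s) utf8ToInt(s), integer(nchar(seqs[1]))))
}

## which of seqs A are within Hamming distance <= d of any seq in B
.crossMatch <- function(A, B, d = 1L) {
    hitsA <- logical(nrow(A)); hitsB <- logical(nrow(B))
    for (i in seq_len(nrow(A))) {
        h <- rowSums(B != matrix(A[i, ], nrow(B), ncol(A), byrow = TRUE)) <= d
        if (any(h)) { hitsA[i] <- TRUE; hitsB <- hitsB | h }
    }
    list(a = unname(hitsA), b = unname(hitsB))
}

#' Flag edges suspected to be driven by off-target guide activity
#'
#' For each edge (A, B), guides of A whose spacer is within Hamming distance
#' `max_mismatch` of any guide targeting B (and vice versa) are removed, both
#' genes' Bayes-factor profiles are recomputed from the cached per-guide
#' log-ratios, and the pair's correlation is re-tested. If the recomputed
#' pair no longer meets the network's tier threshold, the edge is marked
#' `offtarget_suspect`. Re-scoring uses the raw (unnormalized) profiles of
#' the two genes.
#'
#' @param network a [CoessentialityNetwork-class].
#' @param bf the raw [EssentialityMatrix-class] from [geneBayesFactors()]
#'   (its metadata carries the cached guide log-ratios).
#' @param library data.frame from [readLibraryAnnotation()] (guide,
#'   sequence, gene). If sequences are unavailable the operation is skipped
#'   with a warning and all flags stay FALSE.
#' @param max_mismatch Hamming tolerance (default 1).
#' @return the network with `offtarget_suspect` set.
#' @export
flagOfftargetEdges <- function(network, bf, library, max_mismatch = 1L) {
    ed <- networkEdges(network)
    if (is.null(library) || !nrow(library) || !"sequence" %in% colnames(library)) {
        warning("guide sequences unavailable; off-target flagging skipped")
        return(network)
    }
    md <- S4Vectors::metadata(bf)
    glr <- md$guide_log_ratios
    gg <- md$guide_gene
    lib <- library[library$guide %in% rownames(glr), , drop = FALSE]
    seqm <- .seqMatrix(lib$sequence)
    rownames(seqm) <- lib$guide
    byGene <- split(lib$guide, lib$gene)
    prov <- network@provenance
    n <- ncol(glr)
    pass <- function(r, p) {
        if (!is.finite(r) || !is.finite(p)) return(FALSE)
        if (network@mode == "strict")
            r > 0 && p < prov$alpha / prov$m_tested
        else p < prov$q  # conservative re-test at the nominal FDR level
    }
    geneProfile <- function(guides) {
        if (!length(guides)) return(rep(NA_real_, n))
        colSums(glr[guides, , drop = FALSE], na.rm = TRUE)
    }
    for (i in seq_len(nrow(ed))) {
        ga <- byGene[[ed$gene_a[i]]]; gb <- byGene[[ed$gene_b[i]]]
        if (is.null(ga) || is.null(gb)) next
        hit <- .crossMatch(seqm[ga, , drop = FALSE], seqm[gb, , drop = FALSE],
                           max_mismatch)
        if (!any(hit$a) && !any(hit$b)) next
        pa <- geneProfile(ga[!hit$a]); pb <- geneProfile(gb[!hit$b])
        if (all(is.na(pa)) || all(is.na(pb)) || sd(pa) == 0 || sd(pb) == 0) {
            ed$offtarget_suspect[i] <- TRUE
            next
        }
        r <- cor(pa, pb)
        tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.xmin))
        p <- 2 * pt(-abs(tt), df = n - 2)
        if (!pass(r, p)) ed$offtarget_suspect[i] <- TRUE
    }
    methods::new("CoessentialityNetwork", edges = ed, mode = network@mode,
                 provenance = c(prov, list(offtarget_checked = TRUE)))
}
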