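## Cluster annotation: tissue specificity (rank-sum), molecular associations
## (t-test on expression, Fisher on discretized copy number and binary
## mutations), drug-sensitivity correlations, and amplification-artifact
## labeling.

#' Assemble a molecular data bundle
#'
#' Validates and intersects the per-cell-line molecular layers. Expression is
#' expected on the log2(FPKM + 0.5) scale; copy number as log ratios
#' (discretized downstream at +/-0.4); mutations as a binary matrix with
#' silent mutations already coded as wild-type (0).
#'
#' @param expression,cnv,mutation gene x cell-line matrices (any may be
#'   NULL).
#' @param tissue named character vector: cell line -> tissue label.
#' @param drugs drug x cell-line matrix of log(IC50) (may be NULL).
#' @return a list of class `molecular_bundle`.
#' @export
molecularBundle <- function(expression = NULL, cnv = NULL, mutation = NULL,
                            tissue = NULL, drugs = NULL) {
    layers <- list(expression = expression, cnv = cnv, mutation = mutation,
                   drugs = drugs)
    lines <- lapply(Filter(Negate(is.null), layers), colnames)
    if (!is.null(tissue)) lines <- c(lines, list(names(tissue)))
    if (length(lines) && any(vapply(lines, is.null, logical(1))))
        stop("all molecular layers need cell-line column names")
    if (!is.null(mutation) && !all(mutation %in% c(0, 1)))
        stop("mutation layer must be binary (silent mutations coded 0)")
    structure(c(layers, list(tissue = tissue)), class = "molecular_bundle")
}

#' Per-cluster essentiality profiles and case/control splits
#'
#' For each cluster, the mean Bayes factor of member genes per cell line; a
#' line is a "case" for the cluster when the median member-gene BF exceeds
#' `case_threshold`.
#'
#' @param bf an [EssentialityMatrix-class] (normally quantile-normalized).
#' @param cl a [ClusterSet-class].
#' @param case_threshold median member BF above which a line is a case
#'   (default 5).
#' @return list with `mean_bf` (cluster x line matrix), `case` (logical
#'   cluster x line matrix), and `clusters` (the member lists actually used).
#' @export
clusterProfiles <- function(bf, cl, case_threshold = 5) {
    m <- bfMatrix(bf)
    cls <- lapply(clusters(cl), intersect, x = rownames(m))
    ## clusters() built the list from network genes; keep members present in
    ## the matrix and drop clusters left without any
    cls <- lapply(clusters(cl), function(g) intersect(g, rownames(m)))
    keep <- lengths(cls) >= 1L
    if (!any(keep)) stop("no cluster has genes in the matrix")
    cls <- cls[keep]
    mean_bf <- t(vapply(cls, function(g)
        colMeans(m[g, , drop = FALSE]), numeric(ncol(m))))
    med_bf <- t(vapply(cls, function(g)
        apply(m[g, , drop = FALSE], 2L, median), numeric(ncol(m))))
    list(mean_bf = mean_bf, case = med_bf > case_threshold, clusters = cls)
}

#' Tissue-specific essentiality of a cluster
#'
#' For each tissue, a two-sided Wilcoxon rank-sum test of the cluster's mean
#' essentiality in that tissue's lines versus all other lines, Bonferroni
#' corrected over the tissues tested. Tissues with fewer than `min_lines`
#' lines on either side are skipped.
#'
#' @param profile output of [clusterProfiles()].
#' @param cluster_id cluster name (row of `profile$mean_bf`).
#' @param tissue named character vector: cell line -> tissue.
#' @param min_lines minimum group size (default 2).
#' @return data.frame with tissue, n_lines, p_value, p_adjusted (Bonferroni),
#'   sorted by adjusted p.
#' @export
tissueSpecificity <- function(profile, cluster_id, tissue, min_lines = 2) {
    x <- profile$mean_bf[cluster_id, ]
    tis <- tissue[names(x)]
    levels <- sort(unique(tis[!is.na(tis)]))
    rows <- lapply(levels, function(tt) {
        inT <- !is.na(tis) & tis == tt
        if (sum(inT) < min_lines || sum(!inT, na.rm = TRUE) < min_lines)
            return(NULL)
        p <- suppressWarnings(
            wilcox.test(x[inT], x[!inT & !is.na(tis)])$p.value)
        data.frame(tissue = tt, n_lines = sum(inT), p_value = p)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no tissue with enough lines to test")
    out$p_adjusted <- pmin(1, out$p_value * nrow(out))
    out[order(out$p_adjusted, out$p_value), , drop = FALSE]
}

#' Case-control expression association (Welch t-test)
#'
#' Two-sided two-sample t-test of a gene's log2(FPKM + 0.5) expression
#' between a cluster's case and control lines. When both groups are constant
#' with equal means the test is degenerate and p = 1 is returned.
#'
#' @param profile output of [clusterProfiles()].
#' @param cluster_id cluster name.
#' @param expression gene x line matrix, log2(FPKM + 0.5).
#' @param gene gene symbol (row of `expression`).
#' @return two-sided p-value.
#' @export
expressionAssociation <- function(profile, cluster_id, expression, gene) {
    lines <- intersect(colnames(profile$mean_bf), colnames(expression))
    if (!gene %in% rownames(expression)) stop("gene not in expression matrix")
    case <- profile$case[cluster_id, lines]
    x <- expression[gene, lines][case]
    y <- expression[gene, lines][!case]
    if (length(x) < 2L || length(y) < 2L)
        stop("need >= 2 case and >= 2 control lines with expression")
    if (sd(x) == 0 && sd(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
    t.test(x, y)$p.value
}

#' Case-control association for discretized copy number or binary mutation
#'
#' Two-sided Fisher exact test on the 2x2 table of case/control versus
#' feature present/absent. Copy number is discretized at
#' `logCN >= cnv_cut` (amplified) / `<= -cnv_cut` (deleted); amplifications
#' and deletions are tested separately. Mutation layers are taken as binary
#' with silent mutations already coded wild-type. An empty table margin
#' yields p = 1 with a warning.
#'
#' @param profile output of [clusterProfiles()].
#' @param cluster_id cluster name.
#' @param layer one of `"cnv_amp"`, `"cnv_del"`, `"mutation"`.
#' @param data gene x line matrix for that layer (log ratios or 0/1).
#' @param gene gene symbol.
#' @param cnv_cut discretization threshold (default 0.4).
#' @return two-sided p-value.
#' @export
discreteAssociation <- function(profile, cluster_id,
                                layer = c("cnv_amp", "cnv_del", "mutation"),
                                data, gene, cnv_cut = 0.4) {
    layer <- match.arg(layer)
    lines <- intersect(colnames(profile$mean_bf), colnames(data))
    if (!gene %in% rownames(data)) stop("gene not in ", layer, " matrix")
    v <- data[gene, lines]
    feature <- switch(layer,
        cnv_amp = v >= cnv_cut,
        cnv_del = v <= -cnv_cut,
        mutation = v > 0)
    case <- profile$case[cluster_id, lines]
    tab <- table(factor(case, c(FALSE, TRUE)),
                 factor(feature, c(FALSE, TRUE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("empty margin in 2x2 table for ", gene, " (", layer, ")")
        return(1)
    }
    fisher.test(tab)$p.value
}

#' Drug-sensitivity correlates of a cluster
#'
#' Pearson correlation of the cluster's mean BF against each drug's log(IC50)
#' across overlapping lines. Only negative correlations (higher essentiality,
#' lower IC50, i.e. greater sensitivity) with p below `p_max` are reported.
#' Drugs with fewer than `min_pairs` overlapping lines or zero IC50 variance
#' are skipped.
#'
#' @param profile output of [clusterProfiles()].
#' @param cluster_id cluster name.
#' @param drugs drug x line matrix of log(IC50).
#' @param min_pairs minimum overlapping lines (default 34).
#' @param p_max p-value cutoff (default 1e-4).
#' @return data.frame with drug, r, p_value, n (possibly 0 rows).
#' @export
drugCorrelation <- function(profile, cluster_id, drugs, min_pairs = 34,
                            p_max = 1e-4) {
    x <- profile$mean_bf[cluster_id, ]
    rows <- lapply(rownames(drugs), function(d) {
        y <- drugs[d, ]
        common <- intersect(names(x)[is.finite(x)],
                            colnames(drugs)[is.finite(y)])
        if (length(common) < min_pairs) return(NULL)
        yy <- y[common]
        if (sd(yy) == 0 || sd(x[common]) == 0) return(NULL)
        ct <- cor.test(x[common], yy)
        data.frame(drug = d, r = unname(ct$estimate), p_value = ct$p.value,
                   n = length(common))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(drug = character(), r = numeric(),
                          p_value = numeric(), n = integer()))
    out <- out[out$r < 0 & out$p_value < p_max, , drop = FALSE]
    rownames(out) <- NULL
    out[order(out$p_value), , drop = FALSE]
}

#' Label a cluster as amplification artifact, expression-driven, or neither
#'
#' A member gene whose essentiality tracks its own copy number
#' (Bonferroni-adjusted self-CNV p < alpha) but not its own expression is a
#' copy-number cutting artifact; one significant for both is
#' expression-driven. The cluster label is the majority label of its
#' significant genes (ties: `cnv_artifact`); with no significant genes the
#' label is `none`.
#'
#' @param self_cnv_p,self_expr_p named numeric vectors of per-member-gene
#'   p-values (same genes).
#' @param alpha significance level applied to Bonferroni-adjusted p-values
#'   (default 1e-4).
#' @return list with `label` and per-gene `gene_label` vector.
#' @export
labelArtifacts <- function(self_cnv_p, self_expr_p, alpha = 1e-4) {
    genes <- names(self_cnv_p)
    stopifnot(identical(genes, names(self_expr_p)))
    n <- length(genes)
    cnv_sig <- pmin(1, self_cnv_p * n) < alpha
    expr_sig <- pmin(1, self_expr_p * n) < alpha
    gl <- rep("none", n)
    gl[cnv_sig & !expr_sig] <- "cnv_artifact"
    gl[cnv_sig & expr_sig] <- "expression_driven"
    names(gl) <- genes
    sig <- gl != "none"
    label <- if (!any(sig)) "none"
             else if (sum(gl == "cnv_artifact") >= sum(gl == "expression_driven"))
                 "cnv_artifact" else "expression_driven"
    list(label = label, gene_label = gl)
}

#' Annotate all clusters with tissue, molecular, drug, and artifact calls
#'
#' Convenience wrapper running [tissueSpecificity()], self-gene
#' [expressionAssociation()] / [discreteAssociation()], [drugCorrelation()],
#' and [labelArtifacts()] for every cluster with at least `min_size` genes.
#'
#' @param bf a (quantile-normalized) [EssentialityMatrix-class].
#' @param cl a [ClusterSet-class].
#' @param bundle a `molecular_bundle` from [molecularBundle()].
#' @param min_size smallest cluster annotated (default 3).
#' @param alpha artifact-label significance level (default 1e-4).
#' @param drug_p drug-correlation p cutoff (default 1e-4).
#' @param min_pairs minimum lines for drug correlations (default 34).
#' @return data.frame, one row per cluster: top tissue and adjusted p, number
#'   of drug hits plus the top drug, artifact label.
#' @export
annotateClusters <- function(bf, cl, bundle, min_size = 3, alpha = 1e-4,
                             drug_p = 1e-4, min_pairs = 34) {
    prof <- clusterProfiles(bf, cl)
    ids <- names(prof$clusters)[lengths(prof$clusters) >= min_size]
    rows <- lapply(ids, function(id) {
        top_tissue <- NA_character_; tissue_p <- NA_real_
        if (!is.null(bundle$tissue)) {
            ts <- tryCatch(tissueSpecificity(prof, id, bundle$tissue),
                           error = function(e) NULL)
            if (!is.null(ts)) { top_tissue <- ts$tissue[1]
                                tissue_p <- ts$p_adjusted[1] }
        }
        n_drug <- NA_integer_; top_drug <- NA_character_
        if (!is.null(bundle$drugs)) {
            dh <- drugCorrelation(prof, id, bundle$drugs,
                                  min_pairs = min_pairs, p_max = drug_p)
            n_drug <- nrow(dh)
            top_drug <- if (nrow(dh)) dh$drug[1] else NA_character_
        }
        art <- "none"
        if (!is.null(bundle$cnv) && !is.null(bundle$expression)) {
            genes <- intersect(prof$clusters[[id]],
                               intersect(rownames(bundle$cnv),
                                         rownames(bundle$expression)))
            if (length(genes)) {
                cp <- vapply(genes, function(g) tryCatch(
                    discreteAssociation(prof, id, "cnv_amp", bundle$cnv, g),
                    error = function(e) 1), numeric(1))
                ep <- vapply(genes, function(g) tryCatch(
                    expressionAssociation(prof, id, bundle$expression, g),
                    error = function(e) 1), numeric(1))
                art <- labelArtifacts(cp, ep, alpha = alpha)$label
            }
        }
        data.frame(cluster_id = id, n_genes = length(prof$clusters[[id]]),
                   top_tissue = top_tissue, tissue_p = tissue_p,
                   n_drug_hits = n_drug, top_drug = top_drug,
                   artifact_label = art, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
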