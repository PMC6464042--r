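#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx coef cor density fisher.test lm median p.adjust pt
#'   quantile rbinom rnbinom rnorm runif sd setNames t.test wilcox.test
#'   cor.test
#' @importFrom utils read.delim write.table head combn
NULL

#' ScreenCounts: raw guide-level read counts from pooled CRISPR screens
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one `counts` assay
#' (guides in rows, samples in columns). Row data carry the target gene of
#' each guide; column data carry the cell line name, the batch, the matched
#' control sample, and a control indicator. Control samples (T0 / plasmid)
#' are ordinary columns flagged with `is_control = TRUE`.
#'
#' Validity: counts are non-negative and integral; every non-control sample
#' names an existing control column; guide identifiers (rownames) are unique;
#' each guide targets exactly one gene.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(cts) || any(cts < 0) || any(cts != round(cts)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "guide identifiers (rownames) must be unique")
    rd <- SummarizedExperiment::rowData(object)
    if (!"gene" %in% colnames(rd))
        msg <- c(msg, "rowData must contain a 'gene' column")
    cd <- SummarizedExperiment::colData(object)
    need <- c("cell_line", "batch", "control", "is_control")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
    else {
        noncontrol <- colnames(object)[!cd$is_control]
        ctrl_of <- cd$control[!cd$is_control]
        if (any(is.na(ctrl_of)) ||
            !all(ctrl_of %in% colnames(object)[cd$is_control]))
            msg <- c(msg, "every non-control sample must map to a control column")
    }
    if (length(msg)) msg else TRUE
})

#' EssentialityMatrix: gene x cell-line log2 Bayes factors
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `bf` assay (genes
#' in rows, cell lines in columns). Positive values indicate a knockout
#' fitness defect. `metadata()` records the cross-validation scheme, seed,
#' whether the matrix has been quantile-normalized
#' (`metadata(x)$normalized`), and cached per-guide log-ratios used for
#' off-target re-scoring.
#'
#' @export
setClass("EssentialityMatrix", contains = "SummarizedExperiment")

setValidity("EssentialityMatrix", function(object) {
    msg <- character()
    if (!"bf" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'bf' is required")
    else if (any(!is.finite(SummarizedExperiment::assay(object, "bf"))))
        msg <- c(msg, "Bayes factors must be finite")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene rownames must be unique")
    if (length(msg)) msg else TRUE
})

#' ReferenceModel: fold-change evidence model for one screen
#'
#' Smoothed empirical densities of guide-level log2 fold changes for the
#' core-essential and nonessential reference classes, the log2 density ratio
#' evaluated on a grid, the fit range where both densities are supported, and
#' the linear fit (slope, boundary-anchored intercepts) of the log2 ratio
#' against fold change used to extrapolate beyond the fit range.
#'
#' @slot grid numeric, evaluation grid over fold change.
#' @slot essDensity,nonessDensity numeric densities on `grid`, each
#'   integrating to 1 over the grid.
#' @slot logRatio numeric, log2(essDensity/nonessDensity) on `grid`.
#' @slot fitRange numeric(2), interval where both densities exceed the
#'   support floor.
#' @slot slope numeric, OLS slope of logRatio ~ grid over `fitRange`
#'   (negative: deeper depletion means stronger essentiality evidence).
#' @slot interceptLo,interceptHi numeric, intercepts anchored so that the
#'   extrapolated line is continuous with the in-range curve at each
#'   boundary.
#' @slot scorable logical, FALSE when the reference classes are
#'   indistinguishable (slope >= 0 or empty fit range).
#' @export
setClass("ReferenceModel",
    representation(grid = "numeric", essDensity = "numeric",
                   nonessDensity = "numeric", logRatio = "numeric",
                   fitRange = "numeric", slope = "numeric",
                   interceptLo = "numeric", interceptHi = "numeric",
                   scorable = "logical"))

setValidity("ReferenceModel", function(object) {
    msg <- character()
    if (length(object@grid) < 2L) msg <- c(msg, "grid too short")
    dx <- diff(object@grid)
    for (nm in c("essDensity", "nonessDensity")) {
        d <- slot(object, nm)
        if (length(d) != length(object@grid)) {
            msg <- c(msg, paste(nm, "must match grid length"))
        } else {
            mass <- sum((d[-1] + d[-length(d)]) / 2 * dx)
            if (abs(mass - 1) > 1e-6)
                msg <- c(msg, paste(nm, "must integrate to 1 over the grid"))
        }
    }
    if (object@scorable) {
        if (length(object@fitRange) != 2L || diff(object@fitRange) <= 0)
            msg <- c(msg, "fitRange must be a nonempty interval")
        if (!length(object@slope) || object@slope >= 0)
            msg <- c(msg, "slope must be negative for a scorable model")
    }
    if (length(msg)) msg else TRUE
})

#' CoessentialityNetwork: significant gene-pair coessentiality edges
#'
#' Edges are stored canonically (gene_a < gene_b lexicographically, sorted by
#' descending |pcc| with ties broken by gene_a then gene_b) with their Pearson
#' correlation, two-sided p-value, number of observations, significance tier
#' (`strict` or `extended`), correlation sign, and proximity / off-target
#' flags. `provenance` records thresholds, the Bonferroni family size, and
#' input fingerprints.
#'
#' @slot edges data.frame of edge records.
#' @slot mode character, "strict" or "extended".
#' @slot provenance list of thresholds and filter settings.
#' @export
setClass("CoessentialityNetwork",
    representation(edges = "data.frame", mode = "character",
                   provenance = "list"))

setValidity("CoessentialityNetwork", function(object) {
    msg <- character()
    ed <- object@edges
    need <- c("gene_a", "gene_b", "pcc", "p_value", "n_obs", "tier", "sign",
              "proximity_removed", "offtarget_suspect")
    if (!all(need %in% colnames(ed)))
        msg <- c(msg, paste("edges must contain columns:",
                            paste(setdiff(need, colnames(ed)), collapse = ", ")))
    else if (nrow(ed)) {
        if (any(ed$gene_a == ed$gene_b)) msg <- c(msg, "self-edges not allowed")
        if (any(ed$gene_a > ed$gene_b))
            msg <- c(msg, "edges must be in canonical order (gene_a < gene_b)")
        if (anyDuplicated(paste(ed$gene_a, ed$gene_b)))
            msg <- c(msg, "duplicate gene pairs not allowed")
        if (any(abs(ed$pcc) > 1 + 1e-12)) msg <- c(msg, "pcc out of [-1, 1]")
    }
    if (!object@mode %in% c("strict", "extended"))
        msg <- c(msg, "mode must be 'strict' or 'extended'")
    if (length(msg)) msg else TRUE
})

#' ClusterSet: a disjoint partition of network genes into modules
#'
#' Clusters are ordered by decreasing size and named `C1`, `C2`, ... Every
#' clustered gene belongs to exactly one cluster.
#'
#' @slot clusters named list of character vectors (gene symbols).
#' @slot inflation numeric, MCL inflation used.
#' @slot converged logical.
#' @export
setClass("ClusterSet",
    representation(clusters = "list", inflation = "numeric",
                   converged = "logical"))

setValidity("ClusterSet", function(object) {
    genes <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(genes))
        return("clusters must be pairwise disjoint")
    sizes <- lengths(object@clusters)
    if (length(sizes) > 1 && is.unsorted(rev(sizes)))
        return("clusters must be ordered by decreasing size")
    TRUE
})

setMethod("show", "ScreenCounts", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("ScreenCounts:", nrow(object), "guides x", ncol(object), "samples (",
        sum(cd$is_control), "control )\n")
    cat("  genes:", length(unique(SummarizedExperiment::rowData(object)$gene)),
        " batches:", length(unique(cd$batch)), "\n")
})

setMethod("show", "EssentialityMatrix", function(object) {
    norm <- isTRUE(S4Vectors::metadata(object)$normalized)
    cat("EssentialityMatrix:", nrow(object), "genes x", ncol(object),
        "cell lines", if (norm) "(quantile-normalized)" else "(raw)", "\n")
})

setMethod("show", "ReferenceModel", function(object) {
    if (object@scorable)
        cat(sprintf(
            "ReferenceModel: fit range [%.3g, %.3g], slope %.4g (log2/unit fc)\n",
            object@fitRange[1], object@fitRange[2], object@slope))
    else cat("ReferenceModel: unscorable (reference classes indistinguishable)\n")
})

setMethod("show", "CoessentialityNetwork", function(object) {
    cat(sprintf("CoessentialityNetwork (%s): %d genes, %d edges\n",
                object@mode, length(networkGenes(object)),
                nrow(object@edges)))
})

setMethod("show", "ClusterSet", function(object) {
    sz <- lengths(object@clusters)
    cat(sprintf("ClusterSet: %d clusters (inflation %.2f), %d with >= 3 genes\n",
                length(sz), object@inflation, sum(sz >= 3)))
})

#' Accessors for coessnet containers
#'
#' `bfMatrix()` returns the gene x cell-line Bayes-factor matrix;
#' `networkEdges()` the edge table of a network; `networkGenes()` the node
#' set (union of edge endpoints); `clusters()` the list of gene modules.
#'
#' @param x a coessnet object.
#' @return see details per generic.
#' @export
#' @rdname accessors
setGeneric("bfMatrix", function(x) standardGeneric("bfMatrix"))

#' @export
#' @rdname accessors
setMethod("bfMatrix", "EssentialityMatrix", function(x)
    SummarizedExperiment::assay(x, "bf"))

#' @export
#' @rdname accessors
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
#' @rdname accessors
setMethod("networkEdges", "CoessentialityNetwork", function(x) x@edges)

#' @export
#' @rdname accessors
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @export
#' @rdname accessors
setMethod("networkGenes", "CoessentialityNetwork", function(x)
    sort(unique(c(x@edges$gene_a, x@edges$gene_b))))

#' @export
#' @rdname accessors
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @export
#' @rdname accessors
setMethod("clusters", "ClusterSet", function(x) x@clusters)
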