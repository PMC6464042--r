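## Log-likelihood-score benchmarking of ranked gene pairs against a pathway
## standard. The pair universe is annotated genes only: a pair is a true
## positive if the genes share a surviving pathway, a false positive if both
## are annotated but share none; pairs with an unannotated gene are unlabeled
## and excluded from numerator and denominator alike.

#' Build a filtered pathway standard
#'
#' Pathways larger than `max_size` genes (large generic machinery such as the
#' ribosome, spliceosome and proteasome dominates enrichment statistics) and
#' any explicitly excluded names are discarded; pathways with fewer than 2
#' genes cannot contribute a pair and are dropped too.
#'
#' @param annotations named list of character vectors (e.g. from
#'   [readGMT()]).
#' @param max_size maximum pathway size (default 200).
#' @param exclusions character, pathway names (or regular expressions when
#'   `fixed = FALSE`) to drop regardless of size.
#' @param fixed treat `exclusions` as literal names (default) or patterns.
#' @return object of class `pathway_standard`: list with `pathways`, the
#'   gene universe, and a genes x pathways sparse membership matrix.
#' @export
buildStandard <- function(annotations, max_size = 200, exclusions = NULL,
                          fixed = TRUE) {
    pw <- annotations
    if (!is.null(exclusions)) {
        drop <- if (fixed) names(pw) %in% exclusions
                else Reduce(`|`, lapply(exclusions, grepl, x = names(pw)))
        pw <- pw[!drop]
    }
    pw <- lapply(pw, unique)
    pw <- pw[lengths(pw) >= 2L & lengths(pw) <= max_size]
    if (length(pw) < 2L) stop("fewer than 2 pathways survive filtering")
    genes <- sort(unique(unlist(pw, use.names = FALSE)))
    memb <- Matrix::sparseMatrix(
        i = match(unlist(pw, use.names = FALSE), genes),
        j = rep(seq_along(pw), lengths(pw)),
        x = 1, dims = c(length(genes), length(pw)),
        dimnames = list(genes, names(pw)))
    structure(list(pathways = pw, genes = genes, membership = memb),
              class = "pathway_standard")
}

## label pairs: +1 shared pathway, 0 annotated-no-share, NA unlabeled
labelPairs <- function(standard, gene_a, gene_b) {
    ia <- match(gene_a, standard$genes)
    ib <- match(gene_b, standard$genes)
    out <- rep(NA_real_, length(gene_a))
    ok <- !is.na(ia) & !is.na(ib)
    if (any(ok)) {
        ma <- standard$membership[ia[ok], , drop = FALSE]
        mb <- standard$membership[ib[ok], , drop = FALSE]
        shared <- Matrix::rowSums(ma * mb) > 0
        out[ok] <- as.numeric(shared)
    }
    out
}

## background odds P_total / N_total over all pairs of annotated genes in
## `universe` (default: the standard's whole gene universe)
backgroundOdds <- function(standard, universe = NULL) {
    genes <- standard$genes
    if (!is.null(universe)) genes <- intersect(genes, universe)
    if (length(genes) < 2L) stop("background universe has < 2 annotated genes")
    memb <- standard$membership[genes, , drop = FALSE]
    co <- Matrix::tcrossprod(memb)
    pos <- (sum(co > 0) - length(genes)) / 2  # off-diagonal sharing pairs
    total <- choose(length(genes), 2)
    neg <- total - pos
    if (pos == 0 || neg == 0) stop("degenerate pathway standard")
    pos / neg
}

#' Log-likelihood-score curve over ranked gene pairs
#'
#' Labeled pairs (both genes annotated) are taken in rank order and grouped
#' into bins of `bin_size`; each bin's LLS is
#' `log((TP_bin / FP_bin) / (P_total / N_total))` (natural log by default),
#' where the background odds come from all possible pairs of annotated genes.
#' Bins with no false positives carry an `Inf` sentinel. A cumulative variant
#' over the first k bins is also returned.
#'
#' @param ranked_pairs data.frame with gene_a, gene_b, ordered by decreasing
#'   correlation (e.g. output of [pairwiseCorrelation()]).
#' @param standard a `pathway_standard` from [buildStandard()].
#' @param bin_size pairs per bin (default 1000).
#' @param log_base base of the log (default `exp(1)`).
#' @return data.frame with columns bin, rank_lo, rank_hi, tp, fp, lls,
#'   cum_lls.
#' @export
llsCurve <- function(ranked_pairs, standard, bin_size = 1000,
                     log_base = exp(1)) {
    lab <- labelPairs(standard, ranked_pairs$gene_a, ranked_pairs$gene_b)
    lab <- lab[!is.na(lab)]
    if (!length(lab)) stop("no labeled pairs (is the standard relevant?)")
    bg <- backgroundOdds(standard)
    nb <- ceiling(length(lab) / bin_size)
    bin <- rep(seq_len(nb), each = bin_size)[seq_along(lab)]
    tp <- as.vector(rowsum(lab, bin))
    nlab <- as.vector(rowsum(rep(1, length(lab)), bin))
    fp <- nlab - tp
    lls <- ifelse(fp == 0, Inf,
                  ifelse(tp == 0, -Inf,
                         log((tp / fp) / bg, base = log_base)))
    ctp <- cumsum(tp); cfp <- cumsum(fp)
    cum <- ifelse(cfp == 0, Inf,
                  ifelse(ctp == 0, -Inf, log((ctp / cfp) / bg, base = log_base)))
    data.frame(bin = seq_len(nb),
               rank_lo = (seq_len(nb) - 1L) * bin_size + 1L,
               rank_hi = pmin(seq_len(nb) * bin_size, length(lab)),
               tp = tp, fp = fp, lls = lls, cum_lls = cum)
}

#' Functional coherence of a clustering, as the LLS of within-cluster pairs
#'
#' All pairs within clusters of at most `max_cluster` genes form the test
#' set; the standard is re-filtered at `max_term` (plus named exclusions such
#' as ribosome/proteasome/spliceosome terms). The score is the natural-log
#' LLS of the test set against the background odds over the filtered
#' standard's whole gene universe.
#'
#' @param cl a [ClusterSet-class].
#' @param annotations named list of pathway gene sets.
#' @param max_cluster clusters larger than this contribute no pairs
#'   (default 50).
#' @param max_term pathway size cap (default 200).
#' @param exclusions pathway name patterns always dropped (default
#'   ribosome/proteasome/spliceosome).
#' @return numeric LLS (natural log).
#' @export
scoreClusteringLLS <- function(cl, annotations, max_cluster = 50,
                               max_term = 200,
                               exclusions = c("(?i)ribosom", "(?i)proteasom",
                                              "(?i)spliceosom")) {
    std <- buildStandard(annotations, max_size = max_term,
                         exclusions = exclusions, fixed = FALSE)
    cls <- clusters(cl)
    cls <- cls[lengths(cls) <= max_cluster & lengths(cls) >= 2L]
    if (!length(cls)) stop("no clusters of evaluable size")
    pairs <- do.call(rbind, lapply(cls, function(g) {
        g <- sort(g)
        if (length(g) < 2L) return(NULL)
        cb <- combn(g, 2L)
        data.frame(gene_a = cb[1L, ], gene_b = cb[2L, ],
                   stringsAsFactors = FALSE)
    }))
    lab <- labelPairs(std, pairs$gene_a, pairs$gene_b)
    lab <- lab[!is.na(lab)]
    if (!length(lab)) stop("no evaluable within-cluster pairs")
    bg <- backgroundOdds(std)
    tp <- sum(lab); fp <- length(lab) - tp
    if (fp == 0) return(Inf)
    if (tp == 0) return(-Inf)
    log((tp / fp) / bg)
}

#' Select the MCL inflation maximizing clustering functional coherence
#'
#' Runs [runMCL()] over an inflation grid and scores each partition with
#' [scoreClusteringLLS()].
#'
#' @param network a [CoessentialityNetwork-class].
#' @param annotations pathway gene sets.
#' @param inflations numeric grid (default `c(1.5, 2, 2.5, 3, 4)`).
#' @param ... passed to [scoreClusteringLLS()].
#' @return list with `inflation` (best), and `scores` data.frame.
#' @export
selectInflation <- function(network, annotations,
                            inflations = c(1.5, 2, 2.5, 3, 4), ...) {
    scores <- vapply(inflations, function(I) {
        cs <- runMCL(network, inflation = I)
        tryCatch(scoreClusteringLLS(cs, annotations, ...),
                 error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(scores))) stop("no inflation produced an evaluable score")
    list(inflation = inflations[which.max(scores)],
         scores = data.frame(inflation = inflations, lls = scores))
}
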