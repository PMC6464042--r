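# Independent oracles used to validate the package implementations. These are
# deliberately written as naive, direct translations of the definitions, with
# no code shared with R/.

# Naive MCL: explicit column normalization loops, attractor-based cluster
# extraction with union-find merging of overlapping attractor systems.
naiveMCL <- function(adj, inflation = 2, max_iter = 200, tol = 1e-8) {
    n <- nrow(adj)
    A <- adj
    for (i in seq_len(n)) {
        mx <- max(A[i, ])
        A[i, i] <- if (mx > 0) mx else 1
    }
    M <- A
    for (j in seq_len(n)) M[, j] <- A[, j] / sum(A[, j])
    for (it in seq_len(max_iter)) {
        prev <- M
        M <- M %*% M
        M <- M ^ inflation
        for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
        if (max(abs(M - prev)) < tol) break
    }
    # attractors: rows with nonzero diagonal mass; each attractor row's
    # support is one cluster; overlapping supports merged via union-find
    eps <- 1e-9
    attractors <- which(diag(M) > eps)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    union_ <- function(x, y) {
        rx <- find(x); ry <- find(y)
        if (rx != ry) parent[rx] <<- ry
    }
    for (a in attractors) {
        memb <- which(M[a, ] > eps)
        for (m in c(memb, a)) union_(a, m)
    }
    # nodes not reached by any attractor become singletons
    roots <- vapply(seq_len(n), find, integer(1))
    labels <- rownames(adj)
    cl <- split(labels, roots)
    unname(lapply(cl, sort))
}

# canonical form of a partition for comparison
partitionKey <- function(cl) {
    sets <- lapply(cl, function(g) paste(sort(g), collapse = ","))
    paste(sort(unlist(sets)), collapse = ";")
}

# brute-force pairwise Pearson correlation with cor.test, double loop
bruteCorrelation <- function(m) {
    g <- rownames(m)
    out <- list()
    k <- 0L
    for (i in seq_len(nrow(m) - 1L)) {
        for (j in (i + 1L):nrow(m)) {
            ct <- cor.test(m[i, ], m[j, ])
            k <- k + 1L
            out[[k]] <- data.frame(
                gene_a = min(g[i], g[j]), gene_b = max(g[i], g[j]),
                pcc = unname(ct$estimate), p_value = ct$p.value)
        }
    }
    do.call(rbind, out)
}

# exact two-sided Wilcoxon rank-sum p by exhaustive enumeration (no ties)
enumWilcoxonP <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[seq_along(x)])
    combos <- combn(length(pooled), length(x))
    w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
    mu <- length(x) * (length(pooled) + 1) / 2
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
enumFisherP <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    support <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
    probs <- vapply(support, function(a)
        choose(cs[1], a) * choose(cs[2], rs[1] - a) / choose(n, rs[1]),
        numeric(1))
    p_obs <- probs[match(tab[1, 1], support)]
    sum(probs[probs <= p_obs + 1e-9])
}

# pathway standard whose background odds are exactly 1/99: 66 disjoint
# triples plus one pair over 200 genes (199 positive / 19701 negative pairs)
standardOdds99 <- function() {
    genes <- sprintf("G%03d", 1:200)
    pw <- lapply(1:66, function(i) genes[(3 * i - 2):(3 * i)])
    pw <- c(pw, list(genes[199:200]))
    names(pw) <- sprintf("PW%02d", seq_along(pw))
    list(pathways = pw, genes = genes)
}

# construct an EssentialityMatrix directly from a plain matrix
asBF <- function(m, normalized = FALSE) {
    se <- SummarizedExperiment::SummarizedExperiment(assays = list(bf = m))
    S4Vectors::metadata(se) <- list(normalized = normalized)
    methods::new("EssentialityMatrix", se)
}

# run the pipeline stages from simulation output up to the strict network
simToStrict <- function(sim, ...) {
    fc <- computeFoldChanges(sim$counts)
    bf <- suppressWarnings(
        geneBayesFactors(fc, sim$truth$core, sim$truth$noness))
    nbf <- quantileNormalize(bf)
    mask <- essentialityMask(nbf)
    pairs <- proximityFilter(pairwiseCorrelation(nbf, mask), sim$locations)
    list(bf = bf, nbf = nbf, mask = mask, pairs = pairs,
         strict = thresholdNetwork(pairs, "strict", ...))
}
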