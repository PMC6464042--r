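## Markov Cluster Algorithm on the coessentiality network. Flow simulation on
## the column-stochastic edge-weight matrix: expansion (matrix squaring)
## spreads flow, inflation (elementwise power + column renormalization)
## strengthens strong currents, and the process converges to a doubly
## idempotent matrix whose connected components are the clusters.

#' Run the Markov Cluster Algorithm on a network
#'
#' Edge weights are the correlation coefficients (absolute value in extended
#' mode); self-loops are added with each node's maximum incident weight.
#' Iterates expansion (matrix power `expansion`) then inflation (elementwise
#' power `inflation`, column renormalization), pruning entries below
#' `prune_threshold`, until the maximum column change drops below `tol` or
#' `max_iter` is reached (non-convergence returns the current partition with
#' `converged = FALSE` and a warning). Clusters are the connected components
#' of the converged flow matrix; nodes attracted by several overlapping
#' attractor systems are thereby assigned deterministically. Cluster ids are
#' ordered by decreasing size, ties by lexicographically smallest member.
#'
#' @param network a [CoessentialityNetwork-class] (or a symmetric weighted
#'   adjacency matrix with dimnames).
#' @param inflation inflation exponent (default 2.0).
#' @param expansion expansion power (default 2).
#' @param prune_threshold entries below this are zeroed each iteration
#'   (default 1e-5; 0 disables pruning).
#' @param max_iter iteration cap (default 200).
#' @param tol convergence tolerance on the max absolute column change
#'   (default 1e-8).
#' @return a [ClusterSet-class].
#' @export
runMCL <- function(network, inflation = 2.0, expansion = 2,
                   prune_threshold = 1e-5, max_iter = 200, tol = 1e-8) {
    A <- if (is(network, "CoessentialityNetwork")) {
        ed <- networkEdges(network)
        if (!nrow(ed)) stop("network has no edges")
        g <- networkGenes(network)
        M <- matrix(0, length(g), length(g), dimnames = list(g, g))
        w <- abs(ed$pcc)
        M[cbind(ed$gene_a, ed$gene_b)] <- w
        M[cbind(ed$gene_b, ed$gene_a)] <- w
        M
    } else {
        stopifnot(is.matrix(network), isSymmetric(unname(network)),
                  !is.null(rownames(network)))
        network
    }
    n <- nrow(A)
    loops <- apply(A, 1L, max)  # self-loops at max incident weight
    loops[loops == 0] <- 1      # isolated nodes keep their own flow
    diag(A) <- loops
    M <- sweep(A, 2L, colSums(A), "/")
    converged <- FALSE
    for (it in seq_len(max_iter)) {
        prev <- M
        for (e in seq_len(expansion - 1L)) M <- M %*% M
        M <- M ^ inflation
        if (prune_threshold > 0) M[M < prune_threshold] <- 0
        cs <- colSums(M)
        if (any(cs == 0)) stop("pruning emptied a column; lower prune_threshold")
        M <- sweep(M, 2L, cs, "/")
        if (max(abs(M - prev)) < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("MCL did not converge in ", max_iter, " iterations")
    ## clusters = connected components of the nonzero structure
    eps <- 1e-9
    adj <- (M > eps) | (t(M) > eps)
    comp <- .connectedComponents(adj)
    cl <- split(rownames(A), comp)
    cl <- cl[order(-lengths(cl),
                   vapply(cl, function(g) min(g), character(1)))]
    names(cl) <- paste0("C", seq_along(cl))
    methods::new("ClusterSet", clusters = lapply(cl, sort),
                 inflation = inflation, converged = converged)
}

## BFS connected components of a logical adjacency matrix
.connectedComponents <- function(adj) {
    n <- nrow(adj)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        cur <- cur + 1L
        queue <- s
        comp[s] <- cur
        while (length(queue)) {
            v <- queue[[1L]]; queue <- queue[-1L]
            nb <- which(adj[v, ] & comp == 0L)
            comp[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    comp
}
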