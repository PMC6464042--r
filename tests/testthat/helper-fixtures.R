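# Build a ScreenCounts object in memory
makeCounts <- function(cts, genes, controls = "T0") {
    storage.mode(cts) <- "double"
    cd <- S4Vectors::DataFrame(
        cell_line = ifelse(colnames(cts) %in% controls,
                           paste0(colnames(cts), "_CONTROL"), colnames(cts)),
        batch = "batch1",
        control = ifelse(colnames(cts) %in% controls, NA_character_,
                         controls[1]),
        is_control = colnames(cts) %in% controls,
        row.names = colnames(cts))
    methods::new("ScreenCounts",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = cts),
            rowData = S4Vectors::DataFrame(gene = genes,
                                           row.names = rownames(cts)),
            colData = cd))
}

# guide-level fold changes drawn from two normals (essential mean mu_e,
# nonessential mean mu_n), n_genes per class x guides_per_gene guides
twoNormalFC <- function(n_genes = 200, guides_per_gene = 4, mu_e = -3,
                        mu_n = 0, sd = 1) {
    ess <- sprintf("ESS%04d", seq_len(n_genes))
    non <- sprintf("NON%04d", seq_len(n_genes))
    genes <- c(rep(ess, each = guides_per_gene),
               rep(non, each = guides_per_gene))
    fc <- c(rnorm(n_genes * guides_per_gene, mu_e, sd),
            rnorm(n_genes * guides_per_gene, mu_n, sd))
    list(fc = fc, genes = genes, ess = ess, non = non)
}

# small clean cluster fixture: named list -> ClusterSet
makeClusterSet <- function(cl, inflation = 2) {
    cl <- cl[order(-lengths(cl))]
    names(cl) <- paste0("C", seq_along(cl))
    methods::new("ClusterSet", clusters = lapply(cl, sort),
                 inflation = inflation, converged = TRUE)
}
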