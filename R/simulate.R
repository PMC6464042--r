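## Synthetic screen compendia with planted ground truth: negative-binomial
## read counts, core-essential and nonessential backgrounds, context-specific
## essential modules, copy-number-artifact genes, and 1-bp-mismatch
## promiscuous guides. Everything downstream of the sequencer is emulated so
## every pipeline stage is testable without external data.

#' Simulation configuration
#'
#' Defaults describe the standard benchmark compendium: 60 cell lines over 4
#' tissues; 6 planted modules of 8 genes each, depleted by a log2
#' fold-change shift of -4 in their context lines with penetrance 0.9
#' (modules 1-4 are tissue-specific, modules 5-6 hit random line subsets so
#' no two modules share a context); 200 core-essential and 600 nonessential
#' background genes; 4 guides per gene at a mean depth of 500 reads per
#' guide (negative binomial, size 10); 10 copy-number-artifact genes whose
#' depletion tracks an amplified log copy ratio while their expression stays
#' independent of essentiality.
#'
#' @param n_lines cell lines (default 60).
#' @param n_tissues tissues, lines split evenly (default 4).
#' @param n_modules,module_size planted modules (default 6 x 8 genes).
#' @param module_shift log2 fold-change shift of module genes in context
#'   lines (default -4).
#' @param penetrance probability a module gene is depleted in a given context
#'   line (default 0.9).
#' @param n_core,core_shift core-essential genes, depleted everywhere
#'   (default 200 at shift -4).
#' @param n_noness nonessential genes (default 600).
#' @param guides_per_gene default 4.
#' @param reads_mean,nb_size negative-binomial mean and size for counts
#'   (default 500, 10).
#' @param n_cnv_genes copy-number-artifact genes (default 10).
#' @param cnv_slope fold-change per unit log copy ratio in amplified lines
#'   (default -3).
#' @param cnv_line_frac fraction of lines amplified per artifact gene
#'   (default 0.25).
#' @param n_offtarget planted promiscuous guides: a nonessential gene
#'   receives one guide within 1 mismatch of a module gene's guide and
#'   inherits that gene's depletion through it (default 0).
#' @param n_drugs drug log(IC50) profiles; drug 1 is planted to track module
#'   1's context (default 5).
#' @param guide_length spacer length (default 20).
#' @param seed integer seed (default 42).
#' @return list of class `sim_config`.
#' @export
simulationConfig <- function(n_lines = 60, n_tissues = 4, n_modules = 6,
                             module_size = 8, module_shift = -4,
                             penetrance = 0.9, n_core = 200, core_shift = -4,
                             n_noness = 600, guides_per_gene = 4,
                             reads_mean = 500, nb_size = 10,
                             n_cnv_genes = 10, cnv_slope = -3,
                             cnv_line_frac = 0.25, n_offtarget = 0,
                             n_drugs = 5, guide_length = 20, seed = 42) {
    cfg <- as.list(environment())
    if (module_size < 3) stop("module size must be >= 3")
    if (penetrance <= 0 || penetrance > 1) stop("penetrance must be in (0, 1]")
    if (n_lines < 2 * n_tissues) stop("need >= 2 lines per tissue")
    if (n_offtarget > min(n_core, n_modules * module_size))
        stop("more planted off-target guides than available genes")
    if (min(reads_mean, nb_size, guides_per_gene) <= 0)
        stop("counts parameters must be positive")
    structure(cfg, class = "sim_config")
}

.randomSeqs <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
}

.mutateOneBase <- function(seq) {
    pos <- sample(nchar(seq), 1)
    old <- substr(seq, pos, pos)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    paste0(substr(seq, 1, pos - 1), new, substr(seq, pos + 1, nchar(seq)))
}

#' Simulate a pooled CRISPR screen compendium with planted truth
#'
#' Control (T0) counts are negative binomial; treated counts have their mean
#' scaled by `2^fc` where `fc` combines the planted gene effects (core
#' essentials everywhere; module genes in their context lines with the
#' configured penetrance; artifact genes proportionally to a generated
#' amplified log copy ratio). Planted promiscuous guides carry their
#' partner's depletion. Gene positions are laid out so one pair per module
#' falls inside the 20 Mb proximity window and all other pairs fall outside
#' it. Fully reproducible from the seed.
#'
#' @param config a `sim_config` from [simulationConfig()].
#' @return list with `counts` ([ScreenCounts-class]), `library` (guide
#'   annotation data.frame), `locations` (gene location data.frame),
#'   `bundle` (`molecular_bundle`), and `truth` (gene classes, line tissues,
#'   planted module pairs, planted off-target records, context lines).
#' @export
simulateScreens <- function(config) {
    stopifnot(inherits(config, "sim_config"))
    c_ <- config
    set.seed(c_$seed)
    lines <- sprintf("LINE%03d", seq_len(c_$n_lines))
    tissue <- setNames(
        sprintf("TISSUE%d", rep_len(seq_len(c_$n_tissues), c_$n_lines)),
        lines)

    mod_names <- lapply(seq_len(c_$n_modules), function(m)
        sprintf("M%02dG%02d", m, seq_len(c_$module_size)))
    core <- sprintf("CORE%04d", seq_len(c_$n_core))
    noness <- sprintf("NONE%04d", seq_len(c_$n_noness))
    cnvg <- if (c_$n_cnv_genes) sprintf("CNVG%03d", seq_len(c_$n_cnv_genes))
            else character(0)
    genes <- c(unlist(mod_names), core, noness, cnvg)
    if (anyDuplicated(genes)) stop("gene name collision")

    ## context lines per module: tissues first, then random disjoint-looking
    ## subsets of the same typical size
    ctx_size <- max(2L, round(c_$n_lines / c_$n_tissues))
    context <- lapply(seq_len(c_$n_modules), function(m) {
        if (m <= c_$n_tissues) lines[tissue == sprintf("TISSUE%d", m)]
        else sort(sample(lines, ctx_size))
    })

    ## gene-level fold-change effects
    fc_gene <- matrix(0, length(genes), c_$n_lines,
                      dimnames = list(genes, lines))
    fc_gene[core, ] <- c_$core_shift
    for (m in seq_len(c_$n_modules)) {
        for (g in mod_names[[m]]) {
            hit <- rbinom(length(context[[m]]), 1, c_$penetrance) == 1
            fc_gene[g, context[[m]][hit]] <- c_$module_shift
        }
    }
    cnv <- matrix(0, length(genes), c_$n_lines,
                  dimnames = list(genes, lines))
    for (g in cnvg) {
        amp <- sample(lines, max(2L, round(c_$cnv_line_frac * c_$n_lines)))
        logcn <- runif(length(amp), 0.5, 1.2)
        cnv[g, amp] <- logcn
        fc_gene[g, amp] <- c_$cnv_slope * logcn
    }

    ## guide library; per-guide knockout efficiency scales the planted shift,
    ## as in real libraries where spacer potency varies widely
    gpg <- c_$guides_per_gene
    guide_gene <- rep(genes, each = gpg)
    guide_id <- sprintf("%s_g%d", guide_gene, rep(seq_len(gpg), length(genes)))
    seqs <- .randomSeqs(length(guide_id), c_$guide_length)
    names(seqs) <- guide_id
    efficiency <- runif(length(guide_id), 0.4, 1)
    fc_guide <- fc_gene[guide_gene, , drop = FALSE] * efficiency
    rownames(fc_guide) <- guide_id

    offtarget <- data.frame(guide = character(), gene = character(),
                            partner_guide = character(),
                            partner_gene = character())
    if (c_$n_offtarget > 0) {
        ## promiscuous guide in a core-essential gene: the host's profile is
        ## flat on its own, so the partner's context depletion transmitted
        ## through the shared cut site creates a strong spurious edge
        for (k in seq_len(c_$n_offtarget)) {
            host <- core[k]
            m <- ((k - 1L) %% c_$n_modules) + 1L
            partner <- mod_names[[m]][1L]
            hg <- sprintf("%s_g1", host)
            pg <- sprintf("%s_g1", partner)
            seqs[hg] <- .mutateOneBase(seqs[pg])
            ## the guide cuts both loci: depletions add in log space
            fc_guide[hg, ] <- fc_gene[host, ] + fc_gene[partner, ]
            offtarget <- rbind(offtarget, data.frame(
                guide = hg, gene = host, partner_guide = pg,
                partner_gene = partner))
        }
    }

    ## counts: control NB(mean), treated NB(mean * 2^fc)
    t0 <- rnbinom(length(guide_id), mu = c_$reads_mean, size = c_$nb_size)
    treated <- matrix(
        rnbinom(length(guide_id) * c_$n_lines,
                mu = c_$reads_mean * 2^as.vector(fc_guide),
                size = c_$nb_size),
        nrow = length(guide_id), dimnames = list(guide_id, lines))
    cts <- cbind(T0 = t0, treated)
    storage.mode(cts) <- "double"

    cd <- S4Vectors::DataFrame(
        cell_line = c("T0_CONTROL", lines),
        batch = "batch1",
        control = c(NA_character_, rep("T0", c_$n_lines)),
        is_control = c(TRUE, rep(FALSE, c_$n_lines)),
        row.names = colnames(cts))
    counts <- methods::new("ScreenCounts",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = cts),
            rowData = S4Vectors::DataFrame(gene = guide_gene,
                                           row.names = guide_id),
            colData = cd))

    ## genomic layout: one pair per module inside the proximity window, every
    ## other pair of genes > 20 Mb apart or on different chromosomes
    slot_chrom <- sprintf("chr%d", rep_len(seq_len(40), length(genes)))
    slot_pos <- 1e6 + 3e7 * (seq_along(genes) %/% 40)
    locations <- data.frame(gene = genes, chromosome = slot_chrom,
                            position = as.integer(slot_pos))
    for (m in seq_len(c_$n_modules)) {
        i1 <- match(mod_names[[m]][1], locations$gene)
        i2 <- match(mod_names[[m]][2], locations$gene)
        locations$chromosome[i2] <- locations$chromosome[i1]
        locations$position[i2] <- locations$position[i1] + 5e6L
    }

    library_annot <- data.frame(guide = guide_id, sequence = unname(seqs),
                                gene = guide_gene,
                                chromosome = locations$chromosome[
                                    match(guide_gene, locations$gene)],
                                position = locations$position[
                                    match(guide_gene, locations$gene)])

    expression <- matrix(rnorm(length(genes) * c_$n_lines, 5, 1),
                         length(genes), c_$n_lines,
                         dimnames = list(genes, lines))
    mutation <- matrix(rbinom(length(genes) * c_$n_lines, 1, 0.05),
                       length(genes), c_$n_lines,
                       dimnames = list(genes, lines))
    drugs <- NULL
    if (c_$n_drugs > 0) {
        drugs <- matrix(rnorm(c_$n_drugs * c_$n_lines), c_$n_drugs, c_$n_lines,
                        dimnames = list(sprintf("DRUG%02d", seq_len(c_$n_drugs)),
                                        lines))
        drugs[1, ] <- rnorm(c_$n_lines, 0, 0.5) -
            2 * (lines %in% context[[1]])  # planted sensitivity to module 1
    }
    bundle <- molecularBundle(expression = expression, cnv = cnv,
                              mutation = mutation, tissue = tissue,
                              drugs = drugs)

    cls <- c(setNames(rep(sprintf("module_%d", seq_len(c_$n_modules)),
                          each = c_$module_size), unlist(mod_names)),
             setNames(rep("core", c_$n_core), core),
             setNames(rep("noness", c_$n_noness), noness),
             setNames(rep("cnv_artifact", length(cnvg)), cnvg))
    module_pairs <- do.call(rbind, lapply(mod_names, function(g) {
        cb <- combn(sort(g), 2L)
        data.frame(gene_a = cb[1L, ], gene_b = cb[2L, ])
    }))
    truth <- list(class = cls, tissue = tissue, module_pairs = module_pairs,
                  offtarget = offtarget, context = context,
                  core = core, noness = noness, cnv_genes = cnvg)

    list(counts = counts, library = library_annot, locations = locations,
         bundle = bundle, truth = truth)
}

## adjusted Rand index of two label vectors over the same elements
.ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    expected <- si * sj / n2
    mx <- (si + sj) / 2
    if (mx == expected) return(0)
    (sij - expected) / (mx - expected)
}

#' Score recovery of planted structure
#'
#' `metric = "ari"`: adjusted Rand index between the predicted clustering
#' and the planted module labels, restricted to planted-module genes (genes
#' the clustering did not place form singletons). `metric = "edge_f1"`: F1 of
#' the predicted network's edges among planted-module genes against the
#' planted within-module pairs.
#'
#' @param predicted a [ClusterSet-class] (ari) or
#'   [CoessentialityNetwork-class] (edge_f1).
#' @param truth the `truth` element of [simulateScreens()] output.
#' @param metric `"ari"` or `"edge_f1"`.
#' @return numeric score (empty predictions score 0).
#' @export
recoveryScore <- function(predicted, truth, metric = c("ari", "edge_f1")) {
    metric <- match.arg(metric)
    mod_genes <- names(truth$class)[startsWith(truth$class, "module")]
    if (metric == "ari") {
        cls <- clusters(predicted)
        if (!length(cls)) return(0)
        pred <- setNames(rep(names(cls), lengths(cls)),
                         unlist(cls, use.names = FALSE))
        lab_pred <- pred[mod_genes]
        lab_pred[is.na(lab_pred)] <-
            paste0("singleton_", seq_len(sum(is.na(lab_pred))))
        .ari(lab_pred, truth$class[mod_genes])
    } else {
        ed <- networkEdges(predicted)
        ed <- ed[ed$gene_a %in% mod_genes & ed$gene_b %in% mod_genes, ,
                 drop = FALSE]
        predKeys <- paste(ed$gene_a, ed$gene_b)
        trueKeys <- paste(truth$module_pairs$gene_a, truth$module_pairs$gene_b)
        tp <- sum(predKeys %in% trueKeys)
        if (tp == 0) return(0)
        fp <- length(predKeys) - tp
        fn <- length(trueKeys) - tp
        2 * tp / (2 * tp + fp + fn)
    }
}

#' Write a simulated compendium to disk in the pipeline's input formats
#'
#' @param sim output of [simulateScreens()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedInputs <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeReadCounts(sim$counts, file.path(dir, "readcounts.tsv"))
    write.table(sim$library, file.path(dir, "library.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$locations, file.path(dir, "gene_locations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    truth_class <- sim$truth$class
    writeLines(sim$truth$core, file.path(dir, "core_essentials.txt"))
    writeLines(sim$truth$noness, file.path(dir, "nonessentials.txt"))
    write.table(data.frame(gene = names(truth_class), class = truth_class),
                file.path(dir, "truth_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
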