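test_that("fold changes follow the pseudocount log-ratio with library scaling", {
    ## column totals equal lib_size so scaled counts equal raw counts
    cts <- matrix(c(45, 40, 15,
                    15, 40, 45), ncol = 2,
                  dimnames = list(c("g1", "g2", "g3"), c("T0", "LINE1")))
    sc <- makeCounts(cts, genes = c("A", "B", "C"))
    fc <- computeFoldChanges(sc, pseudocount = 5, lib_size = 100)
    m <- SummarizedExperiment::assay(fc, "fc")
    expect_equal(m["g1", "LINE1"], log2(20 / 50), tolerance = 1e-12)
    expect_equal(m["g1", "LINE1"], -1.32193, tolerance = 1e-5)
    expect_identical(m["g2", "LINE1"], 0)  # equal scaled counts
    ## defaults: pseudocount 5, minimum reads 0
    expect_identical(eval(formals(computeFoldChanges)$pseudocount), 5)
    expect_identical(eval(formals(computeFoldChanges)$min_reads), 0)
})

test_that("fold changes respect the minimum-read filter and scaling", {
    cts <- matrix(c(0, 100, 400,
                    10, 100, 800), ncol = 2,
                  dimnames = list(c("g1", "g2", "g3"), c("T0", "LINE1")))
    sc <- makeCounts(cts, genes = c("A", "B", "C"))
    fc <- computeFoldChanges(sc, min_reads = 1)
    m <- SummarizedExperiment::assay(fc, "fc")
    expect_true(is.na(m["g1", "LINE1"]))  # control reads below min_reads
    ## scaling: library size normalization makes equal-proportion guides fc 0
    expect_equal(m["g2", "LINE1"],
                 log2((100 / 910 * 1e7 + 5) / (100 / 500 * 1e7 + 5)),
                 tolerance = 1e-12)
})

test_that("reference model recovers the analytic two-normal log ratio", {
    set.seed(101)
    d <- twoNormalFC(n_genes = 400, guides_per_gene = 10)
    model <- fitReferenceModel(d$fc, d$genes, d$ess, d$non)
    expect_true(model@scorable)
    expect_lt(model@slope, 0)
    ## the densities cross at fc = -1.5 where the log ratio is 0
    expect_equal(guideLogRatio(-1.5, model), 0, tolerance = 0.1)
    ## monotone non-increasing within tolerance across the whole line
    x <- seq(-8, 4, length.out = 400)
    y <- guideLogRatio(x, model)
    expect_lt(max(diff(y)), 0.2)
    expect_error(guideLogRatio(NaN, model), "finite")
})

test_that("extrapolation is linear and continuous at the fit boundary", {
    set.seed(102)
    d <- twoNormalFC(n_genes = 300, guides_per_gene = 8)
    model <- fitReferenceModel(d$fc, d$genes, d$ess, d$non)
    lo <- model@fitRange[1]; hi <- model@fitRange[2]
    expect_equal(guideLogRatio(lo - 2, model),
                 model@interceptLo + model@slope * (lo - 2), tolerance = 0)
    ## continuity at both boundaries
    expect_equal(guideLogRatio(lo - 1e-9, model), guideLogRatio(lo, model),
                 tolerance = 1e-6)
    expect_equal(guideLogRatio(hi + 1e-9, model), guideLogRatio(hi, model),
                 tolerance = 1e-6)
})

test_that("indistinguishable reference classes are unscorable", {
    set.seed(103)
    d <- twoNormalFC(n_genes = 100, mu_e = 0, mu_n = 0)  # identical classes
    model <- fitReferenceModel(d$fc, d$genes, d$ess, d$non)
    expect_false(model@scorable)
    expect_error(guideLogRatio(0, model), "not scorable")
    expect_error(
        fitReferenceModel(d$fc[1:20], d$genes[1:20], d$ess, d$non),
        ">= 10")
})

test_that("gene Bayes factors are additive over guides and permutation-invariant", {
    set.seed(104)
    cfg <- simulationConfig(n_lines = 8, n_tissues = 4, n_modules = 2,
                            module_size = 3, n_core = 40, n_noness = 120,
                            n_cnv_genes = 0, n_drugs = 0, seed = 5)
    sim <- simulateScreens(cfg)
    fc <- computeFoldChanges(sim$counts)
    bf <- suppressWarnings(
        geneBayesFactors(fc, sim$truth$core, sim$truth$noness, n_folds = 5))
    glr <- S4Vectors::metadata(bf)$guide_log_ratios
    gg <- S4Vectors::metadata(bf)$guide_gene
    m <- bfMatrix(bf)
    ## BF = sum over a gene's guides of the cached per-guide evidence
    gene <- "M01G01"
    expect_equal(unname(m[gene, ]),
                 unname(colSums(glr[names(gg)[gg == gene], , drop = FALSE])),
                 tolerance = 1e-9)

    ## permuting guide rows of the input leaves the BF matrix unchanged
    perm <- sample(nrow(sim$counts))
    counts2 <- makeCounts(
        SummarizedExperiment::assay(sim$counts, "counts")[perm, ],
        SummarizedExperiment::rowData(sim$counts)$gene[perm])
    bf2 <- suppressWarnings(
        geneBayesFactors(computeFoldChanges(counts2), sim$truth$core,
                         sim$truth$noness, n_folds = 5))
    expect_equal(bfMatrix(bf2)[rownames(m), colnames(m)], m,
                 tolerance = 1e-9)

    ## fixed seed => bit-reproducible
    bf3 <- suppressWarnings(
        geneBayesFactors(fc, sim$truth$core, sim$truth$noness, n_folds = 5))
    expect_identical(bfMatrix(bf3), m)
})

test_that("planted essential genes reach high Bayes factors end to end", {
    cfg <- simulationConfig(n_lines = 6, n_tissues = 3, n_modules = 2,
                            module_size = 3, n_core = 40, n_noness = 120,
                            n_cnv_genes = 0, n_drugs = 0, seed = 9)
    sim <- simulateScreens(cfg)
    fc <- computeFoldChanges(sim$counts)
    bf <- suppressWarnings(
        geneBayesFactors(fc, sim$truth$core, sim$truth$noness, n_folds = 5))
    m <- bfMatrix(bf)
    core <- intersect(sim$truth$core, rownames(m))
    expect_gt(median(m[core, ]), 5)
    non <- intersect(sim$truth$noness, rownames(m))
    expect_lt(median(m[non, ]), 1)
})

test_that("precision-recall sweep matches hand enumeration", {
    bf <- c(E1 = 10, E2 = 8, E3 = -2, N1 = -5, N2 = -6, N3 = 6)
    pr <- precisionRecall(bf, essentials = c("E1", "E2", "E3"),
                          nonessentials = c("N1", "N2", "N3"))
    ## at the nearest observed threshold at or above BF = 5 (here 6):
    i <- which(pr$threshold == 6)
    expect_equal(pr$precision[i], 2 / 3)
    expect_equal(pr$recall[i], 2 / 3)
    ## recall non-increasing as the threshold rises
    expect_true(all(diff(pr$recall) >= 0))  # rows are descending thresholds
    expect_true(all(pr$precision >= 0 & pr$precision <= 1))
    expect_error(precisionRecall(bf, "E1", "ABSENT"), "reference")

    ## perfectly separated references: precision 1 until full recall
    bf2 <- c(E1 = 9, E2 = 7, E3 = 5, N1 = -1, N2 = -3)
    pr2 <- precisionRecall(bf2, c("E1", "E2", "E3"), c("N1", "N2"))
    first_full <- min(which(pr2$recall == 1))
    expect_true(all(pr2$precision[seq_len(first_full)] == 1))
})

test_that("F-measure is the harmonic mean at the BF-5 point", {
    pr <- data.frame(threshold = c(7, 5, 2), tp = c(3, 4, 5), fp = c(0, 1, 4),
                     precision = c(1, 0.8, 0.5), recall = c(0.4, 0.6, 1))
    expect_equal(fMeasure(pr), 2 * 0.8 * 0.6 / (0.8 + 0.6))
    expect_equal(fMeasure(pr), 0.685714, tolerance = 1e-6)
    expect_identical(eval(formals(fMeasure)$bf_threshold), 5)
    pr1 <- data.frame(threshold = 5, precision = 1, recall = 1)
    expect_identical(fMeasure(pr1), 1)
    pr0 <- data.frame(threshold = 5, precision = 0, recall = 0)
    expect_identical(fMeasure(pr0), 0)
    expect_identical(fMeasure(data.frame(threshold = 2, precision = 1,
                                         recall = 1)), 0)
})
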