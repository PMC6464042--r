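smallCfg <- function(seed = 7, ...) simulationConfig(
    n_lines = 12, n_tissues = 3, n_modules = 2, module_size = 3,
    n_core = 30, n_noness = 90, n_cnv_genes = 2, n_drugs = 2, seed = seed, ...)

test_that("simulation is byte-reproducible from the seed", {
    a <- simulateScreens(smallCfg())
    b <- simulateScreens(smallCfg())
    expect_identical(SummarizedExperiment::assay(a$counts, "counts"),
                     SummarizedExperiment::assay(b$counts, "counts"))
    expect_identical(a$library, b$library)
    expect_identical(a$bundle$expression, b$bundle$expression)
    expect_identical(a$truth, b$truth)
    c_ <- simulateScreens(smallCfg(seed = 8))
    expect_false(identical(SummarizedExperiment::assay(a$counts, "counts"),
                           SummarizedExperiment::assay(c_$counts, "counts")))
})

test_that("planted classes shape the count distributions as configured", {
    sim <- simulateScreens(smallCfg())
    fc <- SummarizedExperiment::assay(computeFoldChanges(sim$counts), "fc")
    genes <- SummarizedExperiment::rowData(sim$counts)$gene
    core_fc <- fc[genes %in% sim$truth$core, ]
    non_fc <- fc[genes %in% sim$truth$noness, ]
    ## core essentials depleted everywhere; mean efficiency 0.7 on shift -4
    expect_lt(mean(core_fc), mean(non_fc) - 1.5)
    expect_lt(abs(mean(non_fc)), 0.5)  # small compositional shift only

    ## module genes depleted only in their context lines
    m1 <- rownames(fc)[genes == "M01G01"]
    ctx <- sim$truth$context[[1]]
    expect_lt(mean(fc[m1, ctx]), mean(fc[m1, setdiff(colnames(fc), ctx)]) - 1)

    ## CNV-artifact genes depleted in amplified lines, expression independent
    g <- sim$truth$cnv_genes[1]
    amp <- colnames(fc)[sim$bundle$cnv[g, colnames(fc)] >= 0.4]
    expect_gt(length(amp), 0)
    gfc <- colMeans(fc[genes == g, , drop = FALSE])
    expect_lt(mean(gfc[amp]), mean(gfc[setdiff(names(gfc), amp)]) - 0.5)

    ## planted off-target guides are within one mismatch of their partner
    sim2 <- simulateScreens(smallCfg(n_offtarget = 1))
    ot <- sim2$truth$offtarget
    s1 <- sim2$library$sequence[sim2$library$guide == ot$guide]
    s2 <- sim2$library$sequence[sim2$library$guide == ot$partner_guide]
    mm <- sum(utf8ToInt(s1) != utf8ToInt(s2))
    expect_identical(mm, 1L)
})

test_that("genomic layout plants one proximal pair per module", {
    sim <- simulateScreens(smallCfg())
    loc <- sim$locations
    pairs <- sim$truth$module_pairs
    ia <- match(pairs$gene_a, loc$gene); ib <- match(pairs$gene_b, loc$gene)
    near <- loc$chromosome[ia] == loc$chromosome[ib] &
        abs(loc$position[ia] - loc$position[ib]) < 2e7
    expect_identical(sum(near), 2L)  # one per module
    expect_gt(sum(!near), 0L)
})

test_that("infeasible configurations are rejected", {
    expect_error(simulationConfig(module_size = 2), ">= 3")
    expect_error(simulationConfig(penetrance = 0), "penetrance")
    expect_error(simulationConfig(n_lines = 4, n_tissues = 4), "lines per")
    expect_error(simulationConfig(n_core = 2, n_offtarget = 5), "off-target")
})

test_that("recovery scores behave at the extremes and match mclust", {
    sim <- simulateScreens(smallCfg())
    truth <- sim$truth
    mod_genes <- names(truth$class)[startsWith(truth$class, "module")]
    perfect <- makeClusterSet(split(mod_genes, truth$class[mod_genes]))
    expect_equal(recoveryScore(perfect, truth, "ari"), 1)

    ## agreement with the reference ARI implementation on random partitions
    set.seed(71)
    for (rep in 1:10) {
        a <- sample(3, length(mod_genes), TRUE)
        b <- sample(3, length(mod_genes), TRUE)
        expect_equal(coessnet:::.ari(a, b),
                     mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }

    ## random partitions of the same sizes average near zero
    big <- simulateScreens(simulationConfig(
        n_lines = 12, n_tissues = 3, n_modules = 3, module_size = 8,
        n_core = 30, n_noness = 90, n_cnv_genes = 0, n_drugs = 0,
        seed = 19))$truth
    bg <- names(big$class)[startsWith(big$class, "module")]
    aris <- replicate(100, {
        g <- sample(bg)
        cs <- makeClusterSet(split(g, rep(1:3, each = 8)))
        recoveryScore(cs, big, "ari")
    })
    expect_lt(abs(mean(aris)), 0.05)

    ## perfect edge recovery
    net <- methods::new("CoessentialityNetwork",
        edges = coessnet:::canonicalEdges(cbind(
            truth$module_pairs,
            data.frame(pcc = 0.9, p_value = 1e-9, n_obs = 12, tier = "strict",
                       sign = "+", proximity_removed = FALSE,
                       offtarget_suspect = FALSE))),
        mode = "strict", provenance = list())
    expect_equal(recoveryScore(net, truth, "edge_f1"), 1)
    empty <- methods::new("CoessentialityNetwork",
        edges = networkEdges(net)[0, ], mode = "strict", provenance = list())
    expect_identical(recoveryScore(empty, truth, "edge_f1"), 0)
})

test_that("nonessential genes score far below the essential threshold", {
    cfg <- simulationConfig(n_lines = 10, n_tissues = 2, n_modules = 2,
                            module_size = 3, n_core = 50, n_noness = 150,
                            n_cnv_genes = 0, n_drugs = 0, seed = 12)
    sim <- simulateScreens(cfg)
    bf <- suppressWarnings(geneBayesFactors(
        computeFoldChanges(sim$counts), sim$truth$core, sim$truth$noness))
    non <- intersect(sim$truth$noness, rownames(bfMatrix(bf)))
    core <- intersect(sim$truth$core, rownames(bfMatrix(bf)))
    ## evidence is a density log-ratio: nonessentials sit deep in negative
    ## territory, far from the BF > 5 essential call
    expect_lt(median(bfMatrix(bf)[non, ]), -5)
    expect_gt(median(bfMatrix(bf)[core, ]), 5)
    expect_lt(mean(bfMatrix(bf)[non, ] > 5), 0.01)
})

test_that("simulated inputs round-trip through the readers", {
    sim <- simulateScreens(smallCfg())
    d <- withr::local_tempdir()
    writeSimulatedInputs(sim, d)
    sc <- readReadCounts(file.path(d, "readcounts.tsv"), "T0")
    expect_identical(SummarizedExperiment::assay(sc, "counts"),
                     SummarizedExperiment::assay(sim$counts, "counts"))
    lib <- readLibraryAnnotation(file.path(d, "library.tsv"))
    expect_identical(lib$sequence, sim$library$sequence)
    loc <- readGeneLocations(file.path(d, "gene_locations.tsv"))
    expect_identical(loc$position, sim$locations$position)
    ceg <- readGeneList(file.path(d, "core_essentials.txt"))
    expect_setequal(ceg, sim$truth$core)
})
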