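profileFrom <- function(mean_bf, case) {
    list(mean_bf = mean_bf, case = case, clusters = list())
}

test_that("cluster profiles average members and call cases by median", {
    m <- rbind(G1 = c(2, 6, 0), G2 = c(4, 7, 0), G3 = c(9, 1, 0))
    colnames(m) <- paste0("L", 1:3)
    cs <- makeClusterSet(list(c("G1", "G2", "G3")))
    prof <- clusterProfiles(asBF(m), cs)
    expect_equal(unname(prof$mean_bf["C1", ]), c(5, 14 / 3, 0))
    ## member BFs {9, 2, 4} in L1: median 4 -> control; {6, 7, 1}: median 6 -> case
    expect_identical(unname(prof$case["C1", ]), c(FALSE, TRUE, FALSE))
    ## mean of {2, 4} = 3 for a two-gene cluster
    prof2 <- clusterProfiles(asBF(m), makeClusterSet(list(c("G1", "G2"),
                                                          c("G3", "ZZ"))))
    expect_equal(unname(prof2$mean_bf["C1", 1]), 3)
})

test_that("tissue specificity reproduces the exact rank-sum p-value", {
    mean_bf <- matrix(c(10, 11, 12, 1, 2, 3), 1,
                      dimnames = list("C1", paste0("L", 1:6)))
    tissue <- setNames(c(rep("LUNG", 3), rep("SKIN", 3)), paste0("L", 1:6))
    ts <- tissueSpecificity(profileFrom(mean_bf, mean_bf > 5), "C1", tissue)
    expect_equal(ts$p_value[ts$tissue == "LUNG"], 0.1, tolerance = 1e-12)
    expect_equal(ts$p_value[ts$tissue == "LUNG"],
                 enumWilcoxonP(c(10, 11, 12), c(1, 2, 3)), tolerance = 1e-12)
    ## Bonferroni over the 2 tissues tested
    expect_equal(ts$p_adjusted[ts$tissue == "LUNG"], 0.2, tolerance = 1e-12)

    ## identical distributions in both groups: p = 1
    mb2 <- matrix(rep(c(1, 2, 3), 2), 1,
                  dimnames = list("C1", paste0("L", 1:6)))
    ts2 <- suppressWarnings(
        tissueSpecificity(profileFrom(mb2, mb2 > 5), "C1", tissue))
    expect_equal(ts2$p_value, rep(1, 2), tolerance = 1e-9)
})

test_that("rank-sum p-values match enumeration for small groups", {
    set.seed(61)
    for (rep in 1:8) {
        n1 <- sample(3:5, 1); n2 <- sample(3:6, 1)
        x <- sample(100, n1); y <- sample(200:300, n2)
        got <- suppressWarnings(wilcox.test(x, y)$p.value)
        expect_equal(got, enumWilcoxonP(x, y), tolerance = 1e-9)
    }
})

test_that("expression association is a two-sided Welch test on log2 FPKM", {
    lines <- paste0("L", 1:8)
    mean_bf <- matrix(0, 1, 8, dimnames = list("C1", lines))
    case <- matrix(rep(c(TRUE, FALSE), each = 4), 1,
                   dimnames = list("C1", lines))
    prof <- profileFrom(mean_bf, case)
    set.seed(62)
    expr <- matrix(rnorm(8), 1, dimnames = list("GENE", lines))
    expect_equal(expressionAssociation(prof, "C1", expr, "GENE"),
                 t.test(expr[1, 1:4], expr[1, 5:8])$p.value)

    ## equal group means and variances: t = 0, p = 1
    expr2 <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 1,
                    dimnames = list("GENE", lines))
    expect_equal(expressionAssociation(prof, "C1", expr2, "GENE"), 1)

    ## strong separation with epsilon jitter is significant
    expr3 <- matrix(c(2, 2, 2, 2, 0, 0, 0, 0) +
                    c(1e-3, -1e-3, 2e-3, -2e-3, 1e-3, -1e-3, 2e-3, -2e-3),
                    1, dimnames = list("GENE", lines))
    expect_lt(expressionAssociation(prof, "C1", expr3, "GENE"), 0.01)

    ## zero variance in both groups with equal means
    expr4 <- matrix(rep(5, 8), 1, dimnames = list("GENE", lines))
    expect_identical(expressionAssociation(prof, "C1", expr4, "GENE"), 1)
})

test_that("discrete associations discretize CNV at 0.4 and use Fisher", {
    lines <- paste0("L", 1:6)
    case <- matrix(rep(c(TRUE, FALSE), each = 3), 1,
                   dimnames = list("C1", lines))
    prof <- profileFrom(matrix(0, 1, 6, dimnames = list("C1", lines)), case)
    ## perfectly concordant 3/3 table: two-sided p = 0.1 (2 of 20 tables)
    cnv <- matrix(c(0.8, 0.9, 1.2, 0, 0, 0), 1,
                  dimnames = list("GENE", lines))
    p <- discreteAssociation(prof, "C1", "cnv_amp", cnv, "GENE")
    expect_equal(p, 0.1, tolerance = 1e-12)
    expect_equal(p, enumFisherP(matrix(c(3, 0, 0, 3), 2)), tolerance = 1e-12)

    ## logCN = 0.39 is neutral, not amplified (empty margin -> p = 1)
    cnv2 <- matrix(c(0.39, 0.39, 0.39, 0, 0, 0), 1,
                   dimnames = list("GENE", lines))
    expect_warning(p2 <- discreteAssociation(prof, "C1", "cnv_amp", cnv2,
                                             "GENE"), "margin")
    expect_identical(p2, 1)
    ## boundary 0.4 is amplified; deletions cut at -0.4
    cnv3 <- matrix(c(0.4, 0.41, 0.5, 0, 0, 0), 1,
                   dimnames = list("GENE", lines))
    expect_lt(discreteAssociation(prof, "C1", "cnv_amp", cnv3, "GENE"), 1)
    del <- matrix(c(-0.5, -0.6, -0.4, 0, 0.2, -0.39), 1,
                  dimnames = list("GENE", lines))
    expect_equal(discreteAssociation(prof, "C1", "cnv_del", del, "GENE"),
                 0.1, tolerance = 1e-12)

    ## binary mutations (silent already coded wild-type = 0)
    mut <- matrix(c(1, 1, 1, 0, 0, 0), 1, dimnames = list("GENE", lines))
    expect_equal(discreteAssociation(prof, "C1", "mutation", mut, "GENE"),
                 0.1, tolerance = 1e-12)
})

test_that("Fisher p is symmetric under transposing the 2x2 table", {
    set.seed(63)
    for (rep in 1:6) {
        tab <- matrix(sample(0:6, 4, TRUE) + c(1, 0, 0, 1), 2)
        expect_equal(fisher.test(tab)$p.value, fisher.test(t(tab))$p.value,
                     tolerance = 1e-12)
    }
})

test_that("drug hits require negative correlation below the p cutoff", {
    lines <- paste0("L", 1:40)
    set.seed(64)
    x <- c(rep(20, 12), rep(0, 28)) + rnorm(40, 0, 0.5)
    mean_bf <- matrix(x, 1, dimnames = list("C1", lines))
    prof <- profileFrom(mean_bf, mean_bf > 5)
    drugs <- rbind(
        SENSITIZER = -0.2 * x + rnorm(40, 0, 0.3),  # IC50 drops as BF rises
        RESISTOR = 0.2 * x + rnorm(40, 0, 0.3),
        NOISE = rnorm(40))
    colnames(drugs) <- lines
    hits <- drugCorrelation(prof, "C1", drugs, min_pairs = 10)
    expect_identical(hits$drug, "SENSITIZER")
    expect_lt(hits$r, 0)
    expect_lt(hits$p_value, 1e-4)
    ## anti-monotone toy vectors give r = -1
    mb <- matrix(c(1, 2, 3), 1, dimnames = list("C1", paste0("L", 1:3)))
    pr2 <- profileFrom(mb, mb > 5)
    d2 <- matrix(c(3, 2, 1), 1, dimnames = list("D", paste0("L", 1:3)))
    h2 <- drugCorrelation(pr2, "C1", d2, min_pairs = 3, p_max = 1.1)
    expect_equal(h2$r, -1, tolerance = 1e-12)
    ## min_pairs enforced
    expect_identical(nrow(drugCorrelation(pr2, "C1", d2, min_pairs = 10)), 0L)
})

test_that("artifact labels split copy-number from expression drivers", {
    cnv_p <- c(A = 1e-8, B = 1e-9, C = 0.4)
    expr_p <- c(A = 0.4, B = 1e-9, C = 0.5)
    out <- labelArtifacts(cnv_p, expr_p, alpha = 1e-4)
    expect_identical(unname(out$gene_label),
                     c("cnv_artifact", "expression_driven", "none"))
    expect_identical(out$label, "cnv_artifact")  # tie broken to cnv_artifact
    out2 <- labelArtifacts(c(A = 0.5), c(A = 0.9))
    expect_identical(out2$label, "none")
    out3 <- labelArtifacts(c(A = 1e-9, B = 1e-9), c(A = 1e-9, B = 1e-9))
    expect_identical(out3$label, "expression_driven")
})

test_that("a planted tissue-specific module tops the tissue ranking", {
    set.seed(65)
    tiss <- setNames(rep(sprintf("T%02d", 1:19), length.out = 50),
                     sprintf("L%02d", 1:50))
    target <- names(tiss)[tiss == "T01"]  # becomes 8 lines below
    tiss[sprintf("L%02d", 44:50)] <- "T01"
    target <- names(tiss)[tiss == "T01"]
    expect_gte(length(target), 8)
    hits <- 0
    for (rep in 1:100) {
        x <- rnorm(50, 0, 1)
        x[names(tiss) %in% target] <- x[names(tiss) %in% target] + 8
        mb <- matrix(x, 1, dimnames = list("C1", names(tiss)))
        ts <- suppressWarnings(
            tissueSpecificity(profileFrom(mb, mb > 5), "C1", tiss))
        if (ts$tissue[1] == "T01") hits <- hits + 1
    }
    expect_gte(hits, 95)
})
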