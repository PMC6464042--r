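## End-to-end orchestration: bf -> qc -> normalize -> mask -> correlate ->
## proximity -> threshold -> offtarget -> cluster -> benchmark -> annotate,
## with a JSON run manifest for provenance.

pipelineDefaults <- function() list(
    controls = "T0",
    pseudocount = 5, min_reads = 0, lib_size = 1e7,
    n_folds = 10, seed = 42,
    bf_threshold = 5, f_min = 0.85, max_essential = 2000,
    min_lines = 3, window_bp = 2e7,
    strict_alpha = 0.05, extended_q = 0.01,
    inflation = 2.0, lls_bin = 1000, pathway_max = 200,
    drug_p = 1e-4, min_drug_pairs = 34, cnv_cut = 0.4,
    artifact_alpha = 1e-4,
    proximity_filter = TRUE,  # disable for shRNA-derived networks
    offtarget = TRUE, cluster = TRUE, benchmark = TRUE, annotate = TRUE)

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys fall back to the documented defaults (pseudocount 5,
#' BF threshold 5, F-measure floor 0.85, essential-gene cap 2000, >= 3
#' essential lines, 20 Mb proximity window, Bonferroni 0.05 strict /
#' BH 0.01 extended, inflation 2.0, LLS bin 1000, pathway cap 200, drug p
#' 1e-4, CNV cut 0.4).
#'
#' @param path YAML file.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    utils::modifyList(pipelineDefaults(), cfg)
}

.readMatrixTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' Run the full coessentiality-network pipeline
#'
#' Executes every stage in order and writes the artifact directory: Bayes
#' factor matrix, QC report, strict and extended edge tables, cluster table,
#' LLS benchmark curve, cluster annotations, and a JSON manifest with input
#' and output fingerprints. A stage failure aborts with a stage-tagged
#' message; artifacts from completed stages remain on disk. Re-running with
#' identical inputs and seed reproduces identical outputs.
#'
#' @param config named list (see [readPipelineConfig()]); file inputs:
#'   `counts`, `essentials`, `nonessentials`, optionally `locations`,
#'   `library`, `gmt`, `expression`, `cnv`, `mutation`, `tissue`, `drugs`,
#'   `batch_map`.
#' @param out_dir artifact directory (created).
#' @return invisible list of in-memory results (bf, qc, networks, clusters,
#'   lls, annotations, manifest path).
#' @export
runPipeline <- function(config, out_dir) {
    cfg <- utils::modifyList(pipelineDefaults(), config)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("[stage:", name, "] ", conditionMessage(e), call. = FALSE))
    }
    inputs <- Filter(Negate(is.null), cfg[c(
        "counts", "essentials", "nonessentials", "locations", "library",
        "gmt", "expression", "cnv", "mutation", "tissue", "drugs",
        "batch_map")])

    bm <- if (!is.null(cfg$batch_map)) read.delim(cfg$batch_map) else NULL
    counts <- stage("read", readReadCounts(cfg$counts, cfg$controls,
                                           batch_map = bm))
    ess <- stage("read", readGeneList(cfg$essentials))
    non <- stage("read", readGeneList(cfg$nonessentials))

    fc <- stage("foldchange",
                computeFoldChanges(counts, pseudocount = cfg$pseudocount,
                                   min_reads = cfg$min_reads,
                                   lib_size = cfg$lib_size))
    bf <- stage("bf", geneBayesFactors(fc, ess, non, n_folds = cfg$n_folds,
                                       seed = cfg$seed))
    bfm <- bfMatrix(bf)
    write.table(data.frame(GENE = rownames(bfm), bfm, check.names = FALSE),
                file.path(out_dir, "bf.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    qc <- stage("qc", screenQC(bf, ess, non, bf_threshold = cfg$bf_threshold,
                               f_min = cfg$f_min,
                               max_essential = cfg$max_essential))
    write.table(qc, file.path(out_dir, "qc_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    passing <- stage("qc", filterScreens(qc, f_min = cfg$f_min,
                                         max_essential = cfg$max_essential))
    bf_pass <- methods::new("EssentialityMatrix",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(bf = bfm[, passing, drop = FALSE])))
    S4Vectors::metadata(bf_pass) <- S4Vectors::metadata(bf)
    S4Vectors::metadata(bf_pass)$guide_log_ratios <-
        S4Vectors::metadata(bf)$guide_log_ratios[, passing, drop = FALSE]

    nbf <- stage("normalize", quantileNormalize(bf_pass))
    mask <- stage("mask", essentialityMask(nbf, cfg$bf_threshold,
                                           cfg$min_lines))
    pairs <- stage("correlate", pairwiseCorrelation(nbf, mask))

    if (isTRUE(cfg$proximity_filter)) {
        pairs <- stage("proximity", {
            if (is.null(cfg$locations))
                stop("gene-location file required when the proximity ",
                     "filter is enabled")
            loc <- readGeneLocations(cfg$locations)
            proximityFilter(pairs, loc, window_bp = cfg$window_bp)
        })
    }

    strict <- stage("threshold",
                    thresholdNetwork(pairs, "strict", alpha = cfg$strict_alpha))
    extended <- stage("threshold",
                      thresholdNetwork(pairs, "extended", q = cfg$extended_q))

    if (isTRUE(cfg$offtarget) && !is.null(cfg$library)) {
        lib <- stage("offtarget", readLibraryAnnotation(cfg$library))
        strict <- stage("offtarget", flagOfftargetEdges(strict, bf_pass, lib))
        extended <- stage("offtarget", flagOfftargetEdges(extended, bf_pass, lib))
    }
    writeEdgeTable(strict, file.path(out_dir, "network_strict.tsv"))
    writeEdgeTable(extended, file.path(out_dir, "network_extended.tsv"))

    cl <- NULL
    if (isTRUE(cfg$cluster)) {
        cl <- stage("cluster", runMCL(strict, inflation = cfg$inflation))
        writeClusterTable(cl, file.path(out_dir, "clusters.tsv"))
    }

    lls <- NULL
    if (isTRUE(cfg$benchmark) && !is.null(cfg$gmt)) {
        lls <- stage("benchmark", {
            std <- buildStandard(readGMT(cfg$gmt), max_size = cfg$pathway_max)
            llsCurve(pairs[!pairs$proximity_removed, ], std,
                     bin_size = cfg$lls_bin)
        })
        write.table(lls, file.path(out_dir, "lls_strict.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }

    ann <- NULL
    if (isTRUE(cfg$annotate) && !is.null(cl)) {
        ann <- stage("annotate", {
            tissue <- NULL
            if (!is.null(cfg$tissue)) {
                td <- read.delim(cfg$tissue, colClasses = "character")
                tissue <- setNames(td[[2]], td[[1]])
            }
            bundle <- molecularBundle(
                expression = if (!is.null(cfg$expression))
                    .readMatrixTSV(cfg$expression) else NULL,
                cnv = if (!is.null(cfg$cnv)) .readMatrixTSV(cfg$cnv) else NULL,
                mutation = if (!is.null(cfg$mutation))
                    .readMatrixTSV(cfg$mutation) else NULL,
                tissue = tissue,
                drugs = if (!is.null(cfg$drugs))
                    .readMatrixTSV(cfg$drugs) else NULL)
            annotateClusters(nbf, cl, bundle, alpha = cfg$artifact_alpha,
                             drug_p = cfg$drug_p,
                             min_pairs = cfg$min_drug_pairs)
        })
        write.table(ann, file.path(out_dir, "annotations.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }

    manifest <- list(
        package_version = as.character(utils::packageVersion("coessnet")),
        seed = cfg$seed,
        config = cfg[setdiff(names(cfg), names(inputs))],
        input_md5 = as.list(tools::md5sum(unlist(inputs))),
        output_md5 = as.list(tools::md5sum(
            list.files(out_dir, full.names = TRUE, pattern = "\\.tsv$"))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(bf = bf, qc = qc, passing = passing, normalized = nbf,
                   pairs = pairs, strict = strict, extended = extended,
                   clusters = cl, lls = lls, annotations = ann,
                   manifest = file.path(out_dir, "manifest.json")))
}
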