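## I/O for every external format the pipeline touches. All tables are
## tab-delimited with a header row, UTF-8, "." decimal.

normalizeSymbols <- function(x, aliases = NULL) {
    x <- toupper(trimws(x))
    if (!is.null(aliases)) {
        hit <- match(x, toupper(trimws(names(aliases))))
        x[!is.na(hit)] <- toupper(trimws(unname(aliases)))[hit[!is.na(hit)]]
    }
    x
}

#' Read a raw read-count table from a pooled CRISPR screen
#'
#' Expects a TSV whose first two columns identify the guide and its target
#' gene, followed by one column of integer read counts per sample. Guides
#' annotated to multiple genes (comma/semicolon-separated annotation) are
#' removed before any scoring, since a shared guide would induce covariation
#' between its targets.
#'
#' @param path TSV file.
#' @param control_names character, sample columns that are T0/plasmid
#'   controls. Every other sample is matched to a control via `batch_map`.
#' @param multi_target_policy `"drop"` (default) removes guides annotated to
#'   more than one gene; `"error"` aborts when one is seen.
#' @param batch_map optional data.frame with columns `sample`, `cell_line`,
#'   `batch`, `control`; defaults to a single batch in which every sample is
#'   matched to the first control.
#' @param guide_col,gene_col column names for guide id and target gene;
#'   default the first and second column.
#' @param aliases optional named character vector mapping old symbols to
#'   current ones (applied after uppercase normalization).
#' @return a [ScreenCounts-class] object.
#' @export
readReadCounts <- function(path, control_names,
                           multi_target_policy = c("drop", "error"),
                           batch_map = NULL, guide_col = NULL,
                           gene_col = NULL, aliases = NULL) {
    multi_target_policy <- match.arg(multi_target_policy)
    raw <- read.delim(path, check.names = FALSE, colClasses = "character")
    if (ncol(raw) < 4L)
        stop("read-count file needs guide, gene and >= 2 sample columns")
    if (is.null(guide_col)) guide_col <- colnames(raw)[1]
    if (is.null(gene_col)) gene_col <- colnames(raw)[2]
    sample_cols <- setdiff(colnames(raw), c(guide_col, gene_col))
    missing_ctl <- setdiff(control_names, sample_cols)
    if (length(missing_ctl))
        stop("control column(s) not found: ", paste(missing_ctl, collapse = ", "))

    cts <- suppressWarnings(
        vapply(raw[sample_cols], as.numeric, numeric(nrow(raw))))
    if (nrow(raw) == 1L) cts <- matrix(cts, nrow = 1L,
                                       dimnames = list(NULL, sample_cols))
    bad <- which(rowSums(is.na(cts) | cts < 0 | cts != round(cts)) > 0)
    if (length(bad))
        stop("negative or non-numeric counts in row(s): ",
             paste(head(bad + 1L, 5L), collapse = ", "),
             " (guide ", raw[[guide_col]][bad[1]], ")")

    multi <- grepl("[,;]", raw[[gene_col]])
    if (any(multi) && multi_target_policy == "error")
        stop(sum(multi), " guide(s) target multiple genes")
    keep <- !multi
    if (!any(keep)) stop("zero guides remaining after multi-target removal")
    guides <- raw[[guide_col]][keep]
    if (anyDuplicated(guides))
        stop("duplicate guide identifiers: ",
             paste(head(unique(guides[duplicated(guides)]), 3L), collapse = ", "))
    genes <- normalizeSymbols(raw[[gene_col]][keep], aliases)
    cts <- cts[keep, , drop = FALSE]
    storage.mode(cts) <- "double"
    rownames(cts) <- guides

    if (is.null(batch_map)) {
        batch_map <- data.frame(sample = sample_cols,
                                cell_line = sample_cols,
                                batch = "batch1",
                                control = control_names[1],
                                stringsAsFactors = FALSE)
    }
    m <- match(sample_cols, batch_map$sample)
    if (anyNA(m)) stop("batch_map missing sample(s): ",
                       paste(sample_cols[is.na(m)], collapse = ", "))
    cd <- S4Vectors::DataFrame(
        cell_line = batch_map$cell_line[m],
        batch = batch_map$batch[m],
        control = batch_map$control[m],
        is_control = sample_cols %in% control_names,
        row.names = sample_cols)
    cd$control[cd$is_control] <- NA_character_

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cts),
        rowData = S4Vectors::DataFrame(gene = genes, row.names = guides),
        colData = cd)
    methods::new("ScreenCounts", se)
}

#' Write a ScreenCounts object back to TSV (round-trip inverse of
#' readReadCounts)
#' @param x a [ScreenCounts-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReadCounts <- function(x, path) {
    df <- data.frame(GUIDE = rownames(x),
                     GENE = SummarizedExperiment::rowData(x)$gene,
                     SummarizedExperiment::assay(x, "counts"),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a reference gene list (one symbol per line)
#'
#' Blank lines and `#` comments are tolerated; symbols are uppercased,
#' trimmed and deduplicated.
#'
#' @param path text file.
#' @param aliases optional named character alias map.
#' @return character vector of unique gene symbols.
#' @export
readGeneList <- function(path, aliases = NULL) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    genes <- unique(normalizeSymbols(lines, aliases))
    if (!length(genes)) stop("gene list is empty after parsing: ", path)
    genes
}

#' Read a guide library annotation
#'
#' TSV with columns `guide`, `sequence`, `gene`, `chromosome`, `position`
#' (1-based). Sequences must be same-length ACGT strings.
#'
#' @param path TSV file.
#' @param aliases optional alias map.
#' @return data.frame with columns guide, sequence, gene, chromosome,
#'   position.
#' @export
readLibraryAnnotation <- function(path, aliases = NULL) {
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    need <- c("guide", "sequence", "gene", "chromosome", "position")
    if (!all(need %in% colnames(df)))
        stop("library annotation must have columns: ",
             paste(need, collapse = ", "))
    df$sequence <- toupper(df$sequence)
    if (any(grepl("[^ACGT]", df$sequence)))
        stop("guide sequences must contain only A/C/G/T")
    if (length(unique(nchar(df$sequence))) != 1L)
        stop("guide sequences must have a single fixed length")
    if (anyDuplicated(df$guide)) stop("duplicate guide ids in annotation")
    df$gene <- normalizeSymbols(df$gene, aliases)
    df$position <- as.integer(df$position)
    df[need]
}

#' Read gene genomic locations
#'
#' Accepts either a TSV with columns `gene`, `chromosome`, `position`
#' (1-based representative coordinate — callers choose start, midpoint or
#' TSS) or a BED file (`format = "bed"`: chrom, start, end, name; 0-based
#' half-open, converted to the 1-based start coordinate).
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`.
#' @param aliases optional alias map.
#' @return data.frame with columns gene, chromosome, position.
#' @export
readGeneLocations <- function(path, format = c("tsv", "bed"), aliases = NULL) {
    format <- match.arg(format)
    if (format == "bed") {
        df <- read.delim(path, header = FALSE, colClasses = "character")
        if (ncol(df) < 4L) stop("BED needs chrom, start, end, name")
        out <- data.frame(gene = normalizeSymbols(df[[4]], aliases),
                          chromosome = df[[1]],
                          position = as.integer(df[[2]]) + 1L,
                          stringsAsFactors = FALSE)
    } else {
        df <- read.delim(path, colClasses = "character")
        need <- c("gene", "chromosome", "position")
        if (!all(need %in% colnames(df)))
            stop("gene location table must have columns: ",
                 paste(need, collapse = ", "))
        out <- data.frame(gene = normalizeSymbols(df$gene, aliases),
                          chromosome = df$chromosome,
                          position = as.integer(df$position),
                          stringsAsFactors = FALSE)
    }
    if (anyDuplicated(out$gene)) stop("one location entry per gene required")
    if (any(is.na(out$position) | out$position <= 0))
        stop("positions must be positive integers")
    out
}

#' Read pathway gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @param aliases optional alias map.
#' @return named list of character vectors.
#' @export
readGMT <- function(path, aliases = NULL) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file: ", path)
    out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
        if (length(f) < 3L) stop("GMT line needs name, description, >=1 gene")
        unique(normalizeSymbols(f[-(1:2)]))
    })
    names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
    out
}

#' Write / read a coessentiality edge table
#'
#' Canonical TSV with columns geneA, geneB, pcc, p_value, tier, sign,
#' offtarget_flag; geneA < geneB lexicographically, rows sorted by descending
#' |pcc| (ties by geneA then geneB). `readEdgeTable(writeEdgeTable(x))`
#' reproduces the network's retained edges exactly.
#'
#' @param network a [CoessentialityNetwork-class] with >= 1 edge.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeEdgeTable <- function(network, path) {
    ed <- networkEdges(network)
    if (!nrow(ed)) stop("network has no edges to write")
    df <- data.frame(geneA = ed$gene_a, geneB = ed$gene_b,
                     pcc = ed$pcc, p_value = ed$p_value,
                     n_obs = ed$n_obs, tier = ed$tier, sign = ed$sign,
                     offtarget_flag = as.integer(ed$offtarget_suspect),
                     stringsAsFactors = FALSE)
    o <- order(-abs(df$pcc), df$geneA, df$geneB)
    df <- df[o, , drop = FALSE]
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = "\t"), con)
    body <- apply(cbind(df$geneA, df$geneB,
                        formatC(df$pcc, format = "g", digits = 17),
                        formatC(df$p_value, format = "g", digits = 17),
                        df$n_obs, df$tier, df$sign, df$offtarget_flag),
                  1L, paste, collapse = "\t")
    writeLines(body, con)
    invisible(path)
}

#' @rdname writeEdgeTable
#' @param mode network mode recorded on read-back.
#' @export
readEdgeTable <- function(path, mode = c("strict", "extended")) {
    mode <- match.arg(mode)
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ed <- data.frame(gene_a = df$geneA, gene_b = df$geneB, pcc = df$pcc,
                     p_value = df$p_value, n_obs = as.integer(df$n_obs),
                     tier = df$tier, sign = df$sign,
                     proximity_removed = FALSE,
                     offtarget_suspect = df$offtarget_flag == 1L,
                     stringsAsFactors = FALSE)
    methods::new("CoessentialityNetwork", edges = canonicalEdges(ed),
                 mode = mode, provenance = list(source = path))
}

## canonical edge ordering used throughout: gene_a < gene_b within a row,
## rows by descending |pcc| then lexicographic pair
canonicalEdges <- function(ed) {
    if (!nrow(ed)) return(ed)
    swap <- ed$gene_a > ed$gene_b
    if (any(swap)) {
        tmp <- ed$gene_a[swap]
        ed$gene_a[swap] <- ed$gene_b[swap]
        ed$gene_b[swap] <- tmp
    }
    ed <- ed[order(-abs(ed$pcc), ed$gene_a, ed$gene_b), , drop = FALSE]
    rownames(ed) <- NULL
    ed
}

#' Write a ClusterSet as a two-column TSV (cluster_id, gene)
#' @param x a [ClusterSet-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeClusterTable <- function(x, path) {
    cl <- clusters(x)
    df <- data.frame(cluster_id = rep(names(cl), lengths(cl)),
                     gene = unlist(cl, use.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
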