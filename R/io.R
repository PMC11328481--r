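#' Read and write the package's plain-text artifacts
#'
#' The pipeline exchanges tab-separated files throughout: a sample table
#' (columns `sample_id`, `group`, `p_low`, optional `pair_id`), a
#' gene-by-sample count matrix (first column gene id, header = sample ids),
#' peaks as BED6+1 (chrom, start, end, name, score, strand, enrichment;
#' 0-based half-open coordinates) and result tables mirroring the analysis
#' outputs.
#'
#' @param path File path.
#' @return `readSampleTable`: a `data.frame`; `readCountMatrix`: an integer
#'   matrix; `readPeaksBed`: a `GRanges` with an `enrichment` column.
#'   Writers return their `path` invisibly.
#' @name qimbalance-io
NULL

#' @rdname qimbalance-io
#' @export
readSampleTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "p_low")
    if (!all(need %in% colnames(df)))
        stop("sample table needs columns sample_id, group, p_low")
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
    if (any(df$p_low < 0 | df$p_low > 1)) stop("p_low outside [0, 1]")
    df
}

#' @rdname qimbalance-io
#' @param x Object to write (sample-table `data.frame`, count matrix,
#'   per-sample `GRanges`/`GRangesList`, ...).
#' @export
writeSampleTable <- function(x, path) {
    if (is(x, "QualityExperiment")) x <- sampleTable(x)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname qimbalance-io
#' @export
readCountMatrix <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (any(m < 0) || any(m != floor(m)))
        stop("counts must be non-negative integers")
    storage.mode(m) <- "integer"
    m
}

#' @rdname qimbalance-io
#' @export
writeCountMatrix <- function(x, path) {
    if (is(x, "QualityExperiment")) x <- counts(x)
    df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname qimbalance-io
#' @export
writePeaksBed <- function(x, path) {
    stopifnot(is(x, "GRanges"), "enrichment" %in% colnames(
        S4Vectors::mcols(x)))
    nm <- if ("name" %in% colnames(S4Vectors::mcols(x))) x$name
          else sprintf("peak%04d", seq_along(x))
    df <- data.frame(chrom = as.character(seqnames(x)),
                     start = start(x) - 1L, end = end(x), name = nm,
                     score = 0L, strand = ".",
                     enrichment = x$enrichment)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname qimbalance-io
#' @export
readPeaksBed <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                     col.names = c("chrom", "start", "end", "name",
                                   "score", "strand", "enrichment"))
    if (any(df$start >= df$end))
        stop("malformed BED interval: start must be < end")
    gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end))
    gr$name <- df$name
    gr$enrichment <- df$enrichment
    gr
}

#' @rdname qimbalance-io
#' @param result Differential result `DataFrame` from [runDE()].
#' @export
writeDEResult <- function(result, path) {
    df <- data.frame(gene = rownames(result), as.data.frame(result),
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname qimbalance-io
#' @param catalog A [MarkerCatalog-class].
#' @export
writeMarkerCatalog <- function(catalog, path) {
    tab <- as.data.frame(catalog@table)
    rv <- catalog@rvalues
    if (nrow(tab) > 0 && nrow(rv) > 0) {
        rstr <- apply(rv[tab$feature, , drop = FALSE], 1, function(z)
            paste(ifelse(is.na(z), "", sprintf("%.4f", z)),
                  collapse = ","))
        tab$r_per_dataset <- unname(rstr)
    }
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
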