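#' Differential expression between disease and control
#'
#' Fits the standard per-gene negative-binomial generalized linear model
#' (DESeq2, median-of-ratios size factors) and Wald-tests the group
#' coefficient, disease versus control.  The design is `~ group`, optionally
#' extended by the pairing factor (`~ pair + group`) and/or the continuous
#' quality covariate `1 - p_low` (`~ quality + group`), the
#' covariate form of quality-imbalance mitigation: higher-quality samples
#' get the larger covariate value.
#'
#' Genes with all-zero counts are marked untested and excluded from the
#' Benjamini-Hochberg adjustment, which is otherwise applied across all
#' tested genes (no independent filtering, no outlier-based p-value
#' zeroing, no fold-change shrinkage: the selection downstream is on the
#' plain Wald results).
#'
#' @param x A [QualityExperiment-class].
#' @param useQualityCovariate Add `1 - p_low` as a continuous covariate.
#' @param usePairing Add the pairing factor (requires complete `pair_id`).
#' @return A [S4Vectors::DataFrame] with one row per gene: `log2fc` (disease
#'   vs control), `p`, `padj` (BH across tested genes) and `tested`.
#'   Untested genes carry `NA` statistics.
#' @examples
#' qe <- simulateQualityDataset(nGenes = 300, nLowMarkers = 0,
#'                              nHighMarkers = 0, nDiseaseGenes = 30,
#'                              qiTarget = 0, seed = 7)
#' res <- runDE(qe)
#' head(significantGenes(res))
#' @export
runDE <- function(x, useQualityCovariate = FALSE, usePairing = FALSE) {
    stopifnot(is(x, "QualityExperiment"))
    k <- counts(x)
    if (all(k == 0)) stop("all-zero count matrix")
    cd <- data.frame(group = sampleGroup(x), row.names = colnames(x))
    terms <- "group"
    if (useQualityCovariate) {
        cd$quality <- 1 - pLow(x)
        if (length(unique(cd$quality)) < 2L)
            stop("quality covariate requested but p_low is constant")
        terms <- c("quality", terms)
    }
    if (usePairing) {
        pid <- pairId(x)
        if (is.null(pid) || anyNA(pid))
            stop("pairing requested but pair_id missing or incomplete")
        cd$pair <- factor(pid)
        terms <- c("pair", terms)
    }
    design <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(k, cd, design))
    dds <- suppressWarnings(suppressMessages(
        DESeq2::DESeq(dds, quiet = TRUE)))
    res <- DESeq2::results(dds, name = "group_disease_vs_control",
                           independentFiltering = FALSE,
                           cooksCutoff = FALSE)
    tested <- !is.na(res$pvalue) & rowSums(k) > 0
    out <- DataFrame(log2fc = res$log2FoldChange,
                     p = res$pvalue,
                     padj = NA_real_,
                     tested = tested,
                     row.names = rownames(k))
    out$padj[tested] <- p.adjust(out$p[tested], method = "BH")
    out
}

#' Select significant genes from a differential result
#'
#' Strict thresholds, matching the usual reporting convention: adjusted
#' p-value strictly below `fdr` and, when `useLfc` is `TRUE`, absolute log2
#' fold change strictly above `lfc`.  The FDR-only selection is therefore
#' always a superset of the FDR + fold-change selection.
#'
#' @param result `DataFrame` from [runDE()].
#' @param fdr Adjusted p-value cutoff (default 0.05).
#' @param lfc Absolute log2 fold-change cutoff (default 1).
#' @param useLfc Apply the fold-change cutoff (default `TRUE`).
#' @return Character vector of significant gene ids.
#' @export
significantGenes <- function(result, fdr = 0.05, lfc = 1, useLfc = TRUE) {
    stopifnot(nrow(result) >= 0, all(c("padj", "log2fc") %in%
                                     colnames(result)))
    keep <- !is.na(result$padj) & result$padj < fdr
    if (useLfc) keep <- keep & !is.na(result$log2fc) &
        abs(result$log2fc) > lfc
    rownames(result)[keep]
}

#' Top-ranked genes of a differential result
#'
#' Tested genes ordered by adjusted p-value ascending, ties broken by
#' absolute log2 fold change descending, then by gene id; truncated to `n`
#' entries (fewer if fewer genes were tested).
#'
#' @param result `DataFrame` from [runDE()].
#' @param n Number of genes to return (default 500).
#' @return Ordered character vector of gene ids.
#' @export
topGenes <- function(result, n = 500) {
    stopifnot(nrow(result) > 0)
    res <- result[result$tested & !is.na(result$padj), , drop = FALSE]
    ord <- order(res$padj, -abs(res$log2fc), rownames(res))
    head(rownames(res)[ord], n)
}
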