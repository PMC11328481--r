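#' Per-gene correlation between expression and low-quality probability
#'
#' For each gene, the Pearson correlation between its transformed expression
#' and the per-sample `p_low`.  The default transform is
#' `log2(count / sizeFactor + 1)` with median-of-ratios size factors; raw or
#' normalized (unlogged) scales are available since the correlation scale is
#' a modelling choice rather than a fixed convention.  Genes with zero
#' expression variance are flagged `excluded` (their correlation is
#' undefined) and carry `NA` rather than 0.
#'
#' @param x A [QualityExperiment-class] with at least 4 samples.
#' @param transform `"log"` (default), `"normalized"` or `"raw"`.
#' @return `data.frame` with columns `gene`, `r`, `excluded`.
#' @export
geneQualityCorrelations <- function(x,
                                    transform = c("log", "normalized",
                                                  "raw")) {
    transform <- match.arg(transform)
    stopifnot(is(x, "QualityExperiment"))
    if (ncol(x) < 4L) stop("need at least 4 samples")
    p <- pLow(x)
    if (length(unique(p)) < 2L) stop("p_low is constant")
    k <- counts(x)
    expr <- switch(transform,
        raw = k,
        normalized = {
            sf <- DESeq2::estimateSizeFactorsForMatrix(k)
            sweep(k, 2, sf, "/")
        },
        log = {
            sf <- DESeq2::estimateSizeFactorsForMatrix(k)
            log2(sweep(k, 2, sf, "/") + 1)
        })
    v <- apply(expr, 1, stats::var)
    excluded <- v == 0 | !is.finite(v)
    r <- rep(NA_real_, nrow(k))
    if (any(!excluded))
        r[!excluded] <- as.vector(cor(t(expr[!excluded, , drop = FALSE]), p))
    data.frame(gene = rownames(k), r = r, excluded = excluded,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Call low- and high-quality marker features in one dataset
#'
#' A feature is a low-quality marker candidate if its quality correlation is
#' strictly above `threshold` (expression higher in lower-quality samples),
#' a high-quality marker candidate if strictly below `-threshold`.  The
#' default threshold 0.4 is the gene-level convention; bin-level calls use
#' 0.3 (see [binQualityCorrelations()]).
#'
#' @param rTable `data.frame` with columns `gene` (or `feature`) and `r`,
#'   e.g. from [geneQualityCorrelations()].
#' @param threshold Absolute-correlation cutoff (strict inequality).
#' @return List with elements `low`, `high` (character vectors of feature
#'   ids) and `r` (named correlation vector over all non-excluded features).
#' @export
callMarkers <- function(rTable, threshold = 0.4) {
    stopifnot(nrow(rTable) > 0)
    idcol <- if ("gene" %in% colnames(rTable)) "gene" else "feature"
    stopifnot(idcol %in% colnames(rTable), "r" %in% colnames(rTable))
    ids <- as.character(rTable[[idcol]])
    r <- rTable$r
    ok <- !is.na(r)
    list(low = ids[ok & r > threshold],
         high = ids[ok & r < -threshold],
         r = setNames(r[ok], ids[ok]),
         threshold = threshold)
}

#' MarkerCatalog: recurrent quality markers across datasets
#'
#' Aggregation of per-dataset marker calls: for each feature and direction,
#' `n_datasets` (`N`) counts the datasets in which the feature was called
#' with that direction; the catalog keeps features with `N >=` the
#' `minDatasets` used at construction.  Per-dataset correlation values are
#' retained for the catalog features.
#'
#' @slot table `DataFrame` with columns `feature`, `direction`
#'   (`low`/`high`), `n_datasets`.
#' @slot rvalues numeric matrix, catalog features x datasets, `NA` where
#'   the feature was not called in that dataset.
#' @slot featureKind `"gene"` or `"bin"`.
#' @slot nDatasets total number of datasets aggregated.
#' @slot minDatasets recurrence cutoff used.
#' @seealso [markerRecurrence()], [markerFeatures()], [recurrenceTable()]
#' @export
setClass("MarkerCatalog",
         representation(table = "DataFrame", rvalues = "matrix",
                        featureKind = "character", nDatasets = "integer",
                        minDatasets = "integer"))

setMethod("show", "MarkerCatalog", function(object) {
    tab <- object@table
    cat(sprintf("MarkerCatalog (%s-level): %d features with N >= %d over %d datasets\n",
                object@featureKind, nrow(tab), object@minDatasets,
                object@nDatasets))
    cat(sprintf("  low-quality markers: %d; high-quality markers: %d\n",
                sum(tab$direction == "low"), sum(tab$direction == "high")))
})

#' @describeIn MarkerCatalog Feature ids in the catalog, optionally
#'   restricted by direction and a stronger recurrence cutoff.
#' @param x A `MarkerCatalog`.
#' @param direction `"both"`, `"low"` or `"high"`.
#' @param minDatasets Recurrence cutoff (defaults to the catalog's).
#' @export
markerFeatures <- function(x, direction = c("both", "low", "high"),
                           minDatasets = NULL) {
    direction <- match.arg(direction)
    if (is.null(minDatasets)) minDatasets <- x@minDatasets
    tab <- x@table
    keep <- tab$n_datasets >= minDatasets
    if (direction != "both") keep <- keep & tab$direction == direction
    unique(as.character(tab$feature[keep]))
}

#' @describeIn MarkerCatalog Cumulative recurrence table: for each `k` from
#'   the catalog cutoff up to the number of datasets, how many features per
#'   direction were called in at least `k` datasets (non-increasing in `k`).
#' @export
recurrenceTable <- function(x) {
    tab <- x@table
    ks <- seq(x@minDatasets, x@nDatasets)
    do.call(rbind, lapply(ks, function(k) {
        data.frame(k = k,
                   low = sum(tab$direction == "low" & tab$n_datasets >= k),
                   high = sum(tab$direction == "high" & tab$n_datasets >= k))
    }))
}

#' Aggregate marker calls across datasets into a recurrence catalog
#'
#' For every feature and direction, counts the datasets in which the
#' feature was called a marker with that direction (recurrence `N`).  A
#' feature called low-quality in some datasets and high-quality in others
#' accrues separate counts per direction; only directions reaching
#' `minDatasets` enter the catalog.
#'
#' @param calls List of per-dataset call objects from [callMarkers()] (or
#'   bare lists with `low`/`high` character elements and optionally `r`).
#' @param minDatasets Minimum recurrence to enter the catalog (default 2).
#' @param featureKind `"gene"` or `"bin"`.
#' @return A [MarkerCatalog-class].
#' @export
markerRecurrence <- function(calls, minDatasets = 2,
                             featureKind = c("gene", "bin")) {
    featureKind <- match.arg(featureKind)
    stopifnot(length(calls) >= 2)
    nD <- length(calls)
    dsNames <- if (!is.null(names(calls)) && all(nzchar(names(calls))))
        names(calls) else sprintf("dataset%02d", seq_len(nD))
    cnt <- list(low = table(unlist(lapply(calls, `[[`, "low"))),
                high = table(unlist(lapply(calls, `[[`, "high"))))
    rows <- do.call(rbind, lapply(c("low", "high"), function(d) {
        tb <- cnt[[d]]
        tb <- tb[tb >= minDatasets]
        if (length(tb) == 0) return(NULL)
        data.frame(feature = names(tb), direction = d,
                   n_datasets = as.integer(tb),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(rows))
        rows <- data.frame(feature = character(), direction = character(),
                           n_datasets = integer())
    rows <- rows[order(-rows$n_datasets, rows$feature), , drop = FALSE]
    feats <- unique(rows$feature)
    rv <- matrix(NA_real_, length(feats), nD,
                 dimnames = list(feats, dsNames))
    for (i in seq_len(nD)) {
        r <- calls[[i]]$r
        if (!is.null(r)) {
            hit <- intersect(feats, names(r))
            rv[hit, i] <- r[hit]
        }
    }
    new("MarkerCatalog",
        table = DataFrame(rows, row.names = NULL), rvalues = rv,
        featureKind = featureKind, nDatasets = as.integer(nD),
        minDatasets = as.integer(minDatasets))
}

#' Assign peaks to fixed-width genomic bins
#'
#' Tiles each chromosome into `binWidth`-bp bins and assigns every peak to
#' every bin it overlaps (half-open interval overlap: a peak ending exactly
#' at a bin boundary does not enter the next bin).  Per bin and sample the
#' peak count and the min, max and mean enrichment of the contributing
#' peaks are recorded; bins without peaks hold count 0 and `NA` enrichment.
#'
#' @param peaks Named list or [GenomicRanges::GRangesList] of per-sample
#'   peak sets, each a `GRanges` with an `enrichment` metadata column.
#' @param binWidth Bin width in bp (default 500).
#' @param seqlengths Named vector of chromosome lengths; defaults to the
#'   seqlengths of the first sample, which must then be set.
#' @return A `RangedSummarizedExperiment` (bins x samples) with assays
#'   `count`, `min`, `max`, `mean`; bin ids are `chrom:start-end`
#'   (0-based half-open).
#' @export
binPeaks <- function(peaks, binWidth = 500, seqlengths = NULL) {
    stopifnot(length(peaks) >= 1)
    if (is.null(seqlengths)) {
        seqlengths <- GenomeInfoDb::seqlengths(peaks[[1]])
        if (anyNA(seqlengths))
            stop("seqlengths must be provided or set on the peaks")
    }
    bins <- GenomicRanges::tileGenome(seqlengths, tilewidth = binWidth,
                                      cut.last.tile.in.chrom = TRUE)
    binIds <- sprintf("%s:%d-%d", as.character(seqnames(bins)),
                      start(bins) - 1L, end(bins))
    nSamp <- length(peaks)
    ids <- if (!is.null(names(peaks))) names(peaks) else
        sprintf("S%03d", seq_len(nSamp))
    mk <- function() matrix(NA_real_, length(bins), nSamp,
                            dimnames = list(binIds, ids))
    cntM <- matrix(0L, length(bins), nSamp, dimnames = list(binIds, ids))
    minM <- mk(); maxM <- mk(); meanM <- mk()
    for (i in seq_len(nSamp)) {
        gr <- peaks[[i]]
        if (any(width(gr) < 1)) stop("malformed peak interval (width < 1)")
        hits <- findOverlaps(bins, gr)
        if (length(hits) == 0) next
        bi <- S4Vectors::queryHits(hits)
        enr <- gr$enrichment[S4Vectors::subjectHits(hits)]
        if (any(!is.finite(enr))) stop("non-finite enrichment value")
        cntM[, i] <- tabulate(bi, nbins = length(bins))
        agg <- function(f) tapply(enr, bi, f)
        for (nm in c("min", "max", "mean")) {
            a <- agg(get(nm))
            m <- switch(nm, min = minM, max = maxM, mean = meanM)
            m[as.integer(names(a)), i] <- a
            assign(paste0(nm, "M"), m)
        }
    }
    SummarizedExperiment(
        assays = list(count = cntM, min = minM, max = maxM, mean = meanM),
        rowRanges = setNames(bins, binIds))
}

#' Quality-marker bins from a binned peak matrix
#'
#' Restricted to bins with peaks in at least `minSamplesWithPeak` samples,
#' computes the Pearson correlation between the per-sample mean peak
#' enrichment (0 where the sample has no peak in the bin) and `p_low`, and
#' calls marker bins at the stricter-than-gene-level threshold 0.3 (the
#' binning and subsequent nearest-gene annotation add noise, so a lower
#' cutoff is used).
#'
#' @param bins `RangedSummarizedExperiment` from [binPeaks()].
#' @param samples Sample table `data.frame` (columns `sample_id`, `p_low`)
#'   or [QualityExperiment-class]; sample ids must match the bin matrix
#'   columns.
#' @param minSamplesWithPeak Eligibility cutoff (default 3).
#' @param threshold Absolute-correlation cutoff (default 0.3, strict).
#' @param summary Which per-bin enrichment summary to correlate
#'   (default `"mean"`).
#' @return List as from [callMarkers()], plus `table` with per-bin `r` and
#'   eligibility.
#' @export
binQualityCorrelations <- function(bins, samples, minSamplesWithPeak = 3,
                                   threshold = 0.3,
                                   summary = c("mean", "min", "max")) {
    summary <- match.arg(summary)
    p <- if (is(samples, "QualityExperiment")) {
        setNames(pLow(samples), colnames(samples))
    } else setNames(samples$p_low, samples$sample_id)
    stopifnot(all(colnames(bins) %in% names(p)))
    p <- p[colnames(bins)]
    if (length(unique(p)) < 2L) stop("p_low is constant")
    cnt <- assay(bins, "count")
    enr <- assay(bins, summary)
    enr[cnt == 0L] <- 0          # absent peak treated as zero enrichment
    eligible <- rowSums(cnt > 0L) >= minSamplesWithPeak
    r <- rep(NA_real_, nrow(bins))
    if (any(eligible)) {
        e <- enr[eligible, , drop = FALSE]
        v <- apply(e, 1, stats::var)
        r[eligible][v > 0] <-
            as.vector(cor(t(e[v > 0, , drop = FALSE]), p))
    }
    tab <- data.frame(feature = rownames(bins), r = r,
                      eligible = eligible, row.names = NULL,
                      stringsAsFactors = FALSE)
    c(callMarkers(tab[tab$eligible & !is.na(tab$r), , drop = FALSE],
                  threshold = threshold),
      list(table = tab))
}

#' Map bins to their nearest gene by TSS distance
#'
#' Each bin is annotated with the gene whose transcription start site is
#' closest to the bin midpoint on the same chromosome; ties are broken by
#' the smaller TSS coordinate, then by lexicographic gene id.  Bins on
#' chromosomes absent from the annotation remain unmapped (`NA`) and are
#' flagged.
#'
#' @param bins `RangedSummarizedExperiment` from [binPeaks()], or a
#'   `GRanges` of bins.
#' @param tss `data.frame` with columns `gene_id`, `chrom`, `tss` (1-based
#'   position); gene ids must be unique.
#' @return `data.frame` with columns `bin`, `gene`, `distance`, `mapped`.
#' @export
annotateBinsToGenes <- function(bins, tss) {
    gr <- if (is(bins, "RangedSummarizedExperiment")) rowRanges(bins)
          else bins
    stopifnot(all(c("gene_id", "chrom", "tss") %in% colnames(tss)),
              !anyDuplicated(tss$gene_id))
    binId <- if (!is.null(names(gr))) names(gr) else
        sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L,
                end(gr))
    mid <- floor((start(gr) + end(gr)) / 2)
    chrom <- as.character(seqnames(gr))
    gene <- rep(NA_character_, length(gr))
    dist <- rep(NA_real_, length(gr))
    for (ch in unique(chrom)) {
        cand <- tss[tss$chrom == ch, , drop = FALSE]
        sel <- which(chrom == ch)
        if (nrow(cand) == 0) next
        # deterministic tie-breaks: distance, then TSS coordinate, then id
        cand <- cand[order(cand$tss, cand$gene_id), , drop = FALSE]
        for (i in sel) {
            d <- abs(cand$tss - mid[i])
            j <- which.min(d)     # first minimum = smaller coord / id
            gene[i] <- cand$gene_id[j]
            dist[i] <- d[j]
        }
    }
    data.frame(bin = binId, gene = gene, distance = dist,
               mapped = !is.na(gene), row.names = NULL,
               stringsAsFactors = FALSE)
}
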