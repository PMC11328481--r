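test_that("gene-quality correlation recovers exact linear dependence", {
    # constant library: size factors 1; one gene's normalized expression
    # is proportional to p_low, so its Pearson r is exactly 1
    p <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.8)
    k <- matrix(100L, nrow = 5, ncol = 6,
                dimnames = list(paste0("G", 1:5), paste0("S", 1:6)))
    k[1, ] <- as.integer(1000 * p)
    k[2, ] <- 55L                      # zero variance
    qe <- QualityExperiment(k, group = rep(c(0, 1), each = 3), pLow = p)
    rt <- geneQualityCorrelations(qe, transform = "normalized")
    expect_equal(rt$r[rt$gene == "G1"], 1, tolerance = 1e-9)
    expect_true(rt$excluded[rt$gene == "G2"])
    expect_true(is.na(rt$r[rt$gene == "G2"]))
})

test_that("marker calls use a strict absolute threshold with sign rule", {
    rt <- data.frame(gene = paste0("g", 1:5),
                     r = c(0.4, 0.41, -0.41, -0.4, 0.1))
    calls <- callMarkers(rt, threshold = 0.4)
    expect_equal(calls$low, "g2")
    expect_equal(calls$high, "g3")
    none <- callMarkers(data.frame(gene = "a", r = 0.39))
    expect_length(none$low, 0)
    expect_length(none$high, 0)
})

test_that("recurrence counts datasets per direction with sign consistency", {
    calls <- list(
        d1 = list(low = c("gA", "gB"), high = "gX"),
        d2 = list(low = "gA", high = c("gX", "gB")),
        d3 = list(low = c("gA", "gC"), high = "gY"))
    cat <- markerRecurrence(calls, minDatasets = 2)
    tab <- as.data.frame(cat@table)
    expect_equal(tab$n_datasets[tab$feature == "gA" &
                                tab$direction == "low"], 3L)
    expect_equal(tab$n_datasets[tab$feature == "gX" &
                                tab$direction == "high"], 2L)
    # gB: low once, high once -- below the cutoff in both directions
    expect_false("gB" %in% tab$feature)
    expect_setequal(markerFeatures(cat, "low"), "gA")
    rec <- recurrenceTable(cat)
    expect_true(all(diff(rec$low) <= 0) && all(diff(rec$high) <= 0))
})

test_that("null collections produce marker counts near the binomial rate", {
    # two datasets with no planted effects: a gene enters the catalog only
    # if |r| > 0.4 with the same sign twice; compare to the per-dataset
    # false-call rate measured from the same data
    coll <- simulateQualityCollection(nDatasets = 2, nControl = 8,
                                      nDisease = 8, nGenes = 400,
                                      nLowMarkers = 0, nHighMarkers = 0,
                                      nDiseaseGenes = 0,
                                      qualityEffect = 0, qiTarget = 0,
                                      seed = 5)
    calls <- lapply(coll, function(qe)
        callMarkers(geneQualityCorrelations(qe)))
    rate <- mean(vapply(calls, function(cl)
        (length(cl$low) + length(cl$high)) / 400, numeric(1)))
    cat2 <- markerRecurrence(calls, minDatasets = 2)
    nRecur <- nrow(cat2@table)
    expectedRecur <- 400 * 2 * (rate / 2)^2   # same sign twice
    expect_lte(nRecur, expectedRecur + 3 * sqrt(expectedRecur) + 3)
})

test_that("peaks are assigned to every overlapped bin with summaries", {
    gr <- GRanges("chrS", IRanges(start = c(101, 151), end = c(700, 300)),
                  seqinfo = GenomeInfoDb::Seqinfo("chrS", 2000))
    gr$enrichment <- c(4, 8)
    bm <- binPeaks(list(S1 = gr), binWidth = 500)
    cnt <- assay(bm, "count")[, 1]
    # peak [100, 700) spans bins [0,500) and [500,1000); second peak only
    # the first bin
    expect_equal(unname(cnt), c(2L, 0L, 0L, 0L) + c(0L, 1L, 0L, 0L))
    expect_equal(assay(bm, "mean")["chrS:0-500", 1], 6)
    expect_equal(assay(bm, "min")["chrS:0-500", 1], 4)
    expect_equal(assay(bm, "max")["chrS:0-500", 1], 8)
    expect_equal(assay(bm, "mean")["chrS:500-1000", 1], 4)
    # a peak ending exactly on a boundary stays out of the next bin
    gr2 <- GRanges("chrS", IRanges(start = 1, end = 500),
                   seqinfo = GenomeInfoDb::Seqinfo("chrS", 2000))
    gr2$enrichment <- 1
    expect_equal(unname(assay(binPeaks(list(S1 = gr2), 500), "count")[, 1]),
                 c(1L, 0L, 0L, 0L))
})

test_that("random peak sets match a brute-force overlap oracle", {
    set.seed(9)
    L <- 5000
    st <- sample.int(L - 400, 40)
    gr <- GRanges("chrS", IRanges(start = st, width = sample(50:400, 40,
                                                             TRUE)),
                  seqinfo = GenomeInfoDb::Seqinfo("chrS", L))
    gr <- gr[end(gr) <= L]
    gr$enrichment <- runif(length(gr), 1, 10)
    bm <- binPeaks(list(S1 = gr), binWidth = 500)
    binStarts <- seq(0, L - 500, by = 500)
    oracle <- vapply(binStarts, function(b0)
        sum(start(gr) - 1 < b0 + 500 & end(gr) > b0), integer(1))
    expect_equal(unname(assay(bm, "count")[, 1]), oracle)
})

test_that("bin eligibility and thresholds follow the bin-level rules", {
    cnt <- matrix(c(1, 1, 0, 0, 0,
                    1, 1, 1, 0, 0), nrow = 2, byrow = TRUE)
    enr <- matrix(c(5, 6, NA, NA, NA,
                    2, 4, 6, NA, NA), nrow = 2, byrow = TRUE)
    rn <- c("chrS:0-500", "chrS:500-1000")
    cn <- paste0("S", 1:5)
    dimnames(cnt) <- dimnames(enr) <- list(rn, cn)
    bins <- GRanges("chrS", IRanges(c(1, 501), width = 500))
    names(bins) <- rn
    se <- SummarizedExperiment(assays = list(count = cnt, min = enr,
                                             max = enr, mean = enr),
                               rowRanges = bins)
    colnames(se) <- cn
    samp <- data.frame(sample_id = cn, p_low = c(0.1, 0.3, 0.5, 0.7, 0.9))
    res <- binQualityCorrelations(se, samp, minSamplesWithPeak = 3,
                                  threshold = 0.3)
    expect_false(res$table$eligible[1])   # peaks in only 2 samples
    expect_true(res$table$eligible[2])
    # second bin: enrichment (2,4,6,0,0) vs p_low -- compute expected call
    rexp <- cor(c(2, 4, 6, 0, 0), samp$p_low)
    expect_equal(res$table$r[2], rexp)
    if (rexp > 0.3) expect_true(rn[2] %in% res$low)
})

test_that("bins map to the nearest TSS with deterministic tie-breaks", {
    tss <- data.frame(gene_id = c("gB", "gA"), chrom = "chrS",
                      tss = c(1000, 2000))
    bins <- GRanges("chrS", IRanges(start = c(1, 1701, 1201), width = 100))
    names(bins) <- c("b1", "b2", "b3")
    ann <- annotateBinsToGenes(bins, tss)
    expect_equal(ann$gene[ann$bin == "b1"], "gB")
    expect_equal(ann$gene[ann$bin == "b2"], "gA")   # midpoint 1750
    expect_equal(ann$gene[ann$bin == "b3"], "gB")   # midpoint 1250
    # exact equidistance resolves to the smaller coordinate
    mid <- GRanges("chrS", IRanges(start = 1451, width = 99))  # mid 1500
    names(mid) <- "bm"
    expect_equal(annotateBinsToGenes(mid, tss)$gene, "gB")
    # chromosome absent from the annotation: unmapped, flagged
    off <- GRanges("chrX", IRanges(start = 1, width = 100))
    names(off) <- "bx"
    annOff <- annotateBinsToGenes(off, tss)
    expect_false(annOff$mapped)

    # random layout vs exhaustive scan
    set.seed(12)
    tss2 <- data.frame(gene_id = sprintf("g%02d", 1:15), chrom = "chrS",
                       tss = sample.int(10000, 15))
    b <- GRanges("chrS", IRanges(start = sample.int(9900, 25), width = 80))
    names(b) <- sprintf("b%02d", 1:25)
    ann2 <- annotateBinsToGenes(b, tss2)
    for (i in seq_along(b)) {
        m <- floor((start(b)[i] + end(b)[i]) / 2)
        d <- abs(tss2$tss - m)
        best <- tss2[d == min(d), ]
        best <- best[order(best$tss, best$gene_id), ][1, ]
        expect_equal(ann2$gene[i], best$gene_id)
    }
})
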