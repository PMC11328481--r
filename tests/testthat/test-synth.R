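smallCfg <- function(...) {
    simulateQualityDataset(nControl = 10, nDisease = 10, nGenes = 50,
                           nLowMarkers = 0, nHighMarkers = 0,
                           nDiseaseGenes = 0, qualityEffect = 0,
                           diseaseEffect = 0, ...)
}

test_that("simulated datasets have the requested shape and valid truth", {
    qe <- smallCfg(qiTarget = 0, seed = 1)
    expect_s4_class(qe, "QualityExperiment")
    expect_equal(dim(qe), c(50L, 20L))
    expect_equal(as.vector(table(sampleGroup(qe))), c(10L, 10L))
    expect_true(all(counts(qe) >= 0))
    expect_true(all(colData(qe)$size_factor > 0))
    expect_true(all(pLow(qe) >= 0 & pLow(qe) <= 1))
    # p_low is the latent quality itself
    expect_identical(pLow(qe), colData(qe)$quality)

    qe2 <- simulateQualityDataset(nGenes = 100, nLowMarkers = 10,
                                  nHighMarkers = 10, nDiseaseGenes = 5,
                                  seed = 3)
    rd <- rowData(qe2)
    expect_true(all(rd$beta_quality[rd$role == "low_marker"] > 0))
    expect_true(all(rd$beta_quality[rd$role == "high_marker"] < 0))
    expect_true(all(rd$beta_quality[!rd$role %in%
                                    c("low_marker", "high_marker")] == 0))
    expect_true(realizedQI(qe2) >= 0 && realizedQI(qe2) <= 1)
})

test_that("identical configuration and seed reproduce the dataset exactly", {
    a <- simulateQualityDataset(nGenes = 80, seed = 42, nLowMarkers = 10,
                                nHighMarkers = 10, nDiseaseGenes = 10)
    b <- simulateQualityDataset(nGenes = 80, seed = 42, nLowMarkers = 10,
                                nHighMarkers = 10, nDiseaseGenes = 10)
    expect_identical(counts(a), counts(b))
    expect_identical(pLow(a), pLow(b))
    c <- simulateQualityDataset(nGenes = 80, seed = 43, nLowMarkers = 10,
                                nHighMarkers = 10, nDiseaseGenes = 10)
    expect_false(identical(counts(a), counts(c)))
})

test_that("paired simulation links one control to one disease sample", {
    qe <- smallCfg(qiTarget = 0, paired = TRUE, seed = 2)
    expect_false(is.null(pairId(qe)))
    tab <- table(pairId(qe), sampleGroup(qe))
    expect_true(all(tab == 1L))
    expect_error(simulateQualityDataset(nControl = 4, nDisease = 6,
                                        nGenes = 20, nLowMarkers = 0,
                                        nHighMarkers = 0,
                                        nDiseaseGenes = 0, paired = TRUE),
                 "equal group sizes")
})

test_that("QI calibration hits its targets in expectation", {
    for (target in c(0.2, 0.5, 0.8)) {
        rq <- vapply(1:20, function(k)
            realizedQI(smallCfg(qiTarget = target, seed = 100 + k)),
            numeric(1))
        expect_lt(abs(mean(rq) - target), 0.1)
    }
})

test_that("with independent quality the realized QI sits at the null floor", {
    # E|r| under independence for n samples: 2 / ((n-2) B(1/2, (n-2)/2))
    n <- 20
    floorE <- 2 / ((n - 2) * beta(0.5, (n - 2) / 2))
    rq <- vapply(1:50, function(k)
        realizedQI(smallCfg(qiTarget = 0, seed = 200 + k)), numeric(1))
    expect_lt(abs(mean(rq) - floorE), 0.05)
    expect_lt(mean(rq), 0.25)
})

test_that("unreachable QI targets error with the achievable bound", {
    expect_error(simulateQualityDataset(nGenes = 20, nLowMarkers = 0,
                                        nHighMarkers = 0,
                                        nDiseaseGenes = 0, qiTarget = 0.999,
                                        qualityConcentration = 0.5),
                 "maximum achievable")
})

test_that("planted low markers correlate positively with p_low", {
    qe <- simulateQualityDataset(nGenes = 500, nLowMarkers = 100,
                                 nHighMarkers = 0, nDiseaseGenes = 0,
                                 qualityEffect = 2, qiTarget = 0.2,
                                 seed = 9)
    rt <- geneQualityCorrelations(qe)
    low <- rownames(qe)[rowData(qe)$role == "low_marker"]
    expect_gt(mean(rt$r[rt$gene %in% low] > 0, na.rm = TRUE), 0.5)
})

test_that("collections share marker identities but not disease genes", {
    coll <- simulateQualityCollection(nDatasets = 3, nControl = 6,
                                      nDisease = 6, nGenes = 200,
                                      nLowMarkers = 20, nHighMarkers = 20,
                                      nDiseaseGenes = 20, seed = 77)
    roles <- lapply(coll, function(qe)
        rownames(qe)[rowData(qe)$role %in% c("low_marker", "high_marker")])
    expect_identical(roles[[1]], roles[[2]])
    expect_identical(roles[[1]], roles[[3]])
    dis <- lapply(coll, function(qe)
        rownames(qe)[rowData(qe)$role == "disease"])
    expect_false(identical(dis[[1]], dis[[2]]))
    # deterministic from the base seed
    coll2 <- simulateQualityCollection(nDatasets = 3, nControl = 6,
                                       nDisease = 6, nGenes = 200,
                                       nLowMarkers = 20, nHighMarkers = 20,
                                       nDiseaseGenes = 20, seed = 77)
    expect_identical(counts(coll[[2]]), counts(coll2[[2]]))
})

test_that("simulated peaks are deterministic and carry the planted signal", {
    a <- simulatePeakDataset(nBins = 50, nLowMarkerBins = 5,
                             nHighMarkerBins = 5, seed = 3)
    b <- simulatePeakDataset(nBins = 50, nLowMarkerBins = 5,
                             nHighMarkerBins = 5, seed = 3)
    expect_identical(as.list(a$peaks), as.list(b$peaks))
    expect_equal(nrow(a$samples), 16)

    # strong planted effect is recovered from the emitted data
    pk <- simulatePeakDataset(nBins = 60, nLowMarkerBins = 10,
                              nHighMarkerBins = 0, enrichmentEffect = 4,
                              markerPresenceProb = 1, seed = 5)
    bm <- binPeaks(pk$peaks, binWidth = 500,
                   seqlengths = pk$seqlengths)
    res <- binQualityCorrelations(bm, pk$samples)
    lowBins <- rownames(bm)[seq_len(10)]
    expect_gt(length(intersect(res$low, lowBins)), 5)

    # zero effect: bin-quality correlations center on 0
    pk0 <- simulatePeakDataset(nBins = 60, nLowMarkerBins = 0,
                               nHighMarkerBins = 0, seed = 6)
    bm0 <- binPeaks(pk0$peaks, binWidth = 500,
                    seqlengths = pk0$seqlengths)
    res0 <- binQualityCorrelations(bm0, pk0$samples)
    expect_lt(abs(mean(res0$table$r, na.rm = TRUE)), 0.15)
})
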