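test_that("differential result satisfies the BH contracts", {
    qe <- simulateQualityDataset(nGenes = 300, nLowMarkers = 0,
                                 nHighMarkers = 0, nDiseaseGenes = 30,
                                 diseaseEffect = 2, qiTarget = 0, seed = 4)
    res <- runDE(qe)
    tested <- res$tested
    expect_true(all(res$padj[tested] >= res$p[tested]))
    expect_true(all(res$padj[tested] >= 0 & res$padj[tested] <= 1))
    # BH preserves the p-value ordering
    o <- order(res$p[tested])
    expect_true(all(diff(res$padj[tested][o]) >= -1e-12))
    # equals the textbook step-up procedure
    expect_equal(res$padj[tested], bhStepUp(res$p[tested]),
                 tolerance = 1e-12)
})

test_that("planted disease genes are recovered at large effect", {
    qe <- simulateQualityDataset(nGenes = 800, nLowMarkers = 0,
                                 nHighMarkers = 0, nDiseaseGenes = 60,
                                 diseaseEffect = 2, qiTarget = 0, seed = 8)
    res <- runDE(qe)
    sig <- significantGenes(res, useLfc = FALSE)
    dis <- rownames(qe)[rowData(qe)$role == "disease"]
    expect_gte(mean(dis %in% sig), 0.8)
})

test_that("a dataset duplicated as both groups yields no significant genes", {
    set.seed(21)
    half <- matrix(rnbinom(200 * 6, mu = 50, size = 10), nrow = 200,
                   dimnames = list(sprintf("G%03d", 1:200), NULL))
    k <- cbind(half, half)
    colnames(k) <- sprintf("S%02d", 1:12)
    qe <- QualityExperiment(k, group = rep(c(0, 1), each = 6),
                            pLow = runif(12))
    res <- runDE(qe)
    expect_length(significantGenes(res, useLfc = FALSE), 0)
})

test_that("significance selection uses strict thresholds and nests", {
    res <- S4Vectors::DataFrame(
        log2fc = c(2, 0.5, -3, 1.5, 0.2),
        p = c(0.001, 0.002, 0.003, 0.04, 0.2),
        padj = c(0.01, 0.05, 0.02, 0.049, 0.6),
        tested = TRUE,
        row.names = paste0("g", 1:5))
    expect_setequal(significantGenes(res, useLfc = FALSE),
                    c("g1", "g3", "g4"))
    # padj exactly at the cutoff is excluded
    expect_false("g2" %in% significantGenes(res, fdr = 0.05,
                                            useLfc = FALSE))
    both <- significantGenes(res)
    expect_true(all(both %in% significantGenes(res, useLfc = FALSE)))
    expect_setequal(both, c("g1", "g3", "g4"))
    # lfc exactly at the cutoff is excluded
    res2 <- res; res2$log2fc[1] <- 1
    expect_false("g1" %in% significantGenes(res2))
})

test_that("top gene ranking follows padj, |lfc|, then gene id", {
    res <- S4Vectors::DataFrame(
        log2fc = c(1, 2, -2, 0.5),
        p = c(0.01, 0.02, 0.02, 0.03),
        padj = c(0.01, 0.02, 0.02, 0.03),
        tested = TRUE,
        row.names = c("gD", "gB", "gA", "gC"))
    expect_equal(topGenes(res, 10), c("gD", "gA", "gB", "gC"))
    expect_equal(topGenes(res, 2), c("gD", "gA"))

    # random instance against an independent sort oracle
    set.seed(33)
    n <- 60
    r <- S4Vectors::DataFrame(
        log2fc = round(rnorm(n), 2),
        p = round(runif(n), 3), padj = round(runif(n), 2),
        tested = TRUE, row.names = sprintf("g%02d", sample(n)))
    oracle <- rownames(r)[order(r$padj, -abs(r$log2fc), rownames(r))]
    expect_equal(topGenes(r, n), oracle)
})

test_that("design options validate their inputs", {
    qe <- simulateQualityDataset(nGenes = 30, nLowMarkers = 0,
                                 nHighMarkers = 0, nDiseaseGenes = 0,
                                 seed = 2)
    expect_error(runDE(qe, usePairing = TRUE), "pair")
    k <- counts(qe) * 0L
    qe0 <- QualityExperiment(k, group = sampleGroup(qe), pLow = pLow(qe))
    expect_error(runDE(qe0), "all-zero")
})
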