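test_that("dataset eligibility uses inclusive boundaries", {
    df <- data.frame(dataset = c("a", "b", "c", "d"),
                     n_samples = c(50, 51, 20, 20),
                     n_degs = c(500, 600, 499, 700),
                     n_disease_genes = c(50, 60, 70, 49))
    keep <- eligibleDatasets(df)
    expect_equal(keep$dataset, "a")
})

test_that("marker and disease-gene proportions count overlaps", {
    calls <- list(d1 = list(low = c("g1", "g2"), high = "g9"),
                  d2 = list(low = c("g1", "g2"), high = "g9"))
    cat2 <- markerRecurrence(calls, minDatasets = 2)

    top <- paste0("x", 1:500)
    expect_equal(markerProportionInDegs(top, cat2)$proportion, 0)

    top[1:110] <- paste0("m", 1:110)
    calls110 <- list(d1 = list(low = paste0("m", 1:110), high = character()),
                     d2 = list(low = paste0("m", 1:110), high = character()))
    cat110 <- markerRecurrence(calls110, minDatasets = 2)
    pr <- markerProportionInDegs(top, cat110)
    expect_equal(pr$numerator, 110)
    expect_equal(pr$proportion, 0.22)

    dis <- paste0("d", 1:60)
    expect_equal(diseaseGeneProportion(top, dis)$proportion, 0)
    top2 <- c(paste0("d", 1:50), paste0("x", 1:450))
    expect_equal(diseaseGeneProportion(top2, dis)$proportion, 1)
    expect_error(diseaseGeneProportion(top2, paste0("d", 1:30)),
                 "30 entries")
})

test_that("proportion regression is flat for constant proportions", {
    df <- data.frame(proportion = rep(0.2, 6),
                     qi_value = seq(0.1, 0.6, 0.1),
                     paired = FALSE)
    # lm warns about the (intended) perfect fit of a constant response
    fit <- suppressWarnings(qiProportionRegression(df))
    expect_equal(fit$slope, 0)
    expect_error(qiProportionRegression(df[1:2, ]), "degenerate")
})

test_that("deg-count regression stratifies by QI class", {
    df <- data.frame(n_samples = rep(c(10, 20, 30, 40), 2),
                     deg_count = c(100, 200, 300, 400,
                                   100, 400, 700, 1000),
                     qi_value = rep(c(0.1, 0.6), each = 4))
    fit <- degCountVsSizeRegression(df)
    expect_equal(unname(fit$slopes["low"]), 10)
    expect_equal(unname(fit$slopes["high"]), 30)
    expect_equal(fit$ratio, 3)
    df$deg_count <- 10
    expect_error(degCountVsSizeRegression(df), "degenerate")
})

test_that("marker enrichment in disease genes matches the exact Fisher tail", {
    calls <- list(d1 = list(low = paste0("g", 1:10), high = paste0("h", 1:5)),
                  d2 = list(low = paste0("g", 1:10), high = paste0("h", 1:5)))
    cat2 <- markerRecurrence(calls, minDatasets = 2)
    uni <- c(paste0("g", 1:10), paste0("h", 1:5), paste0("u", 1:10))
    dis <- c(paste0("g", 1:4), paste0("u", 1:4))
    res <- markerEnrichmentInDiseaseGenes(dis, cat2, uni)
    expect_equal(res$overlap[res$direction == "low"], 4L)
    # exact enumeration oracle for the low direction
    pOracle <- hyperTailOracle(4, 10, 25, 8)
    expect_equal(res$p[res$direction == "low"], pOracle,
                 tolerance = 1e-10)
    # disjoint markers: tail at overlap 0 is 1
    disOnly <- paste0("u", 1:8)
    res0 <- markerEnrichmentInDiseaseGenes(disOnly, cat2, uni)
    expect_equal(res0$p, c(1, 1))
})

test_that("the 15% verdict rule follows the relative-change definition", {
    expect_equal(qimbalance:::.mitigationVerdict(10, 8, 3), "better")
    expect_equal(qimbalance:::.mitigationVerdict(10, 12, 3), "worse")
    expect_equal(qimbalance:::.mitigationVerdict(10, 9, 3), "no_change")
    expect_equal(qimbalance:::.mitigationVerdict(10, 8.5, 3), "better")
    expect_equal(qimbalance:::.mitigationVerdict(0, 5, 0), "excluded")
})

test_that("mitigation evaluation excludes baselines with no contamination", {
    qe <- simulateQualityDataset(nGenes = 400, nLowMarkers = 0,
                                 nHighMarkers = 0, nDiseaseGenes = 40,
                                 diseaseEffect = 2, qiTarget = 0, seed = 18)
    sets <- simulateGeneSets(qe, nLowSets = 0, nDiseaseSets = 5,
                             nNullSets = 5, seed = 18)
    rep <- evaluateMitigation(qe, lowQualityPathwaySet = "LOWQ_SET_01",
                              geneSets = sets, strategy = "covariate",
                              useLfc = FALSE)
    expect_true(all(rep$verdict == "excluded"))
    expect_equal(rep$qi_before, rep$qi_after)
})
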