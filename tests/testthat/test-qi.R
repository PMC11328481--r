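test_that("pearson QI matches the definition and the point-biserial form", {
    tab <- makeSampleTab(c(0.1, 0.1, 0.9, 0.9),
                         c("control", "control", "disease", "disease"))
    expect_equal(qiValue(qiIndex(tab)), 1)

    tab <- makeSampleTab(c(0.3, 0.3, 0.7, 0.7),
                         c("control", "disease", "control", "disease"))
    expect_equal(qiValue(qiIndex(tab)), 0)

    tab <- makeSampleTab(c(0.2, 0.4, 0.3, 0.9),
                         c("control", "control", "disease", "disease"))
    g <- as.integer(tab$group == "disease")
    expect_equal(qiValue(qiIndex(tab)),
                 abs(bruteForcePearson(tab$p_low, g)), tolerance = 1e-12)
    expect_equal(qiValue(qiIndex(tab)),
                 abs(pointBiserial(tab$p_low, g)), tolerance = 1e-12)
})

test_that("spearman QI is rank-based and monotone-invariant", {
    # perfect rank separation of 2+2: with midrank ties on the binary
    # group the rank correlation attains its maximum sqrt(4/5), not 1
    tab <- makeSampleTab(c(0.1, 0.2, 0.8, 0.9),
                         c("control", "control", "disease", "disease"))
    expect_equal(qiValue(qiIndex(tab, "spearman")), sqrt(4 / 5),
                 tolerance = 1e-12)

    set.seed(11)
    tab <- randomQIInstance()
    v1 <- qiValue(qiIndex(tab, "spearman"))
    tab2 <- tab; tab2$p_low <- tab$p_low^3
    expect_equal(qiValue(qiIndex(tab2, "spearman")), v1)
    # rank-then-Pearson oracle with midrank ties
    g <- as.integer(tab$group == "disease")
    expect_equal(v1, abs(bruteForcePearson(rank(tab$p_low), rank(g))),
                 tolerance = 1e-12)
})

test_that("ctdiff QI equals the all-pairs enumeration and is scale-free", {
    tab <- makeSampleTab(c(0.2, 0.4, 0.2, 0.4),
                         c("control", "control", "disease", "disease"))
    expect_equal(qiValue(qiIndex(tab, "ctdiff")), 0)

    tab <- makeSampleTab(c(0, 0, 1, 1),
                         c("control", "control", "disease", "disease"))
    g <- as.integer(tab$group == "disease")
    expect_equal(qiValue(qiIndex(tab, "ctdiff")),
                 ctdiffOracle(tab$p_low, g))
    # scale cancels exactly in the ratio
    tab2 <- tab; tab2$p_low <- tab$p_low * 0.37
    expect_equal(qiValue(qiIndex(tab2, "ctdiff")),
                 qiValue(qiIndex(tab, "ctdiff")))
})

test_that("all metrics are invariant under swapping the group coding", {
    set.seed(5)
    for (i in 1:20) {
        tab <- randomQIInstance()
        swapped <- tab
        swapped$group <- ifelse(tab$group == "control", "disease",
                                "control")
        for (m in c("pearson", "spearman", "ctdiff"))
            expect_equal(qiValue(qiIndex(swapped, m)),
                         qiValue(qiIndex(tab, m)), tolerance = 1e-12)
    }
})

test_that("degenerate inputs raise errors instead of silent zeros", {
    tab <- makeSampleTab(rep(0.5, 6), rep(c("control", "disease"), 3))
    expect_error(qiIndex(tab), "constant")
    expect_error(qiIndex(tab, "ctdiff"), "identical")
    one <- makeSampleTab(c(0.1, 0.5, 0.9),
                         c("control", "disease", "disease"))
    expect_error(qiIndex(one), "2 samples")
})

test_that("QI classification uses strict cutoffs per metric", {
    expect_equal(classifyQI(0.31, "pearson"), "high")
    expect_equal(classifyQI(0.30, "pearson"), "intermediate")
    expect_equal(classifyQI(0.17, "spearman"), "low")
    expect_equal(classifyQI(0.18, "spearman"), "intermediate")
    expect_equal(classifyQI(0.75, "ctdiff"), "intermediate")
    expect_equal(classifyQI(0.49, "ctdiff"), "low")
    expect_equal(classifyQI(1.01, "ctdiff"), "high")
    expect_error(classifyQI(0.5, "mad"))
})

test_that("IQR outlier detection matches hand-computed fences", {
    p <- c(0.10, 0.11, 0.12, 0.13, 0.90)
    names(p) <- sprintf("S%02d", 1:5)
    # type-7 quartiles: Q1 = 0.11, Q3 = 0.13, fence = 0.13 + 1.5 * 0.02
    expect_equal(detectQualityOutliers(p), "S05")

    expect_equal(detectQualityOutliers(rep(0.4, 6)), character(0))

    # uniform spread, no extremes: independent fence computation
    p <- seq(0.1, 0.9, length.out = 9)
    q <- quantile(p, c(.25, .75), type = 7, names = FALSE)
    expect_true(all(p <= q[2] + 1.5 * diff(q) & p >= q[1] - 1.5 * diff(q)))
    expect_equal(detectQualityOutliers(p), character(0))

    expect_error(detectQualityOutliers(c(0.1, 0.2, 0.9)), "4 samples")
})
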