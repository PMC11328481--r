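#' Filter datasets eligible for the proportion analyses
#'
#' The reproducibility analyses compare marker and disease-gene content of
#' the top differential genes across datasets; they are restricted to
#' datasets small enough for the top-500 list to be informative and with
#' enough signal: at most `maxSamples` samples, at least `minDegs`
#' differential genes and a disease with at least `minDiseaseGenes` known
#' genes (all boundaries inclusive).
#'
#' @param datasets `data.frame` with columns `dataset`, `n_samples`,
#'   `n_degs`, `n_disease_genes`.
#' @param maxSamples,minDegs,minDiseaseGenes Filter bounds (defaults 50,
#'   500, 50).
#' @return The eligible rows of `datasets`.
#' @export
eligibleDatasets <- function(datasets, maxSamples = 50, minDegs = 500,
                             minDiseaseGenes = 50) {
    stopifnot(all(c("n_samples", "n_degs", "n_disease_genes") %in%
                  colnames(datasets)))
    datasets[datasets$n_samples <= maxSamples &
             datasets$n_degs >= minDegs &
             datasets$n_disease_genes >= minDiseaseGenes, , drop = FALSE]
}

.proportionResult <- function(numerator, denominator, kind, dataset = NA,
                              qiValue = NA, paired = NA) {
    data.frame(dataset = dataset, qi_value = qiValue, paired = paired,
               kind = kind, numerator = numerator,
               denominator = denominator,
               proportion = numerator / denominator,
               stringsAsFactors = FALSE)
}

#' Proportion of quality markers among the top differential genes
#'
#' Shares the top differential genes of a dataset against the recurrent
#' quality markers (both directions) of a catalog: the fraction of the top
#' list that is a known quality marker.  Under quality imbalance this
#' proportion inflates — quality markers masquerade as disease biology.
#'
#' @param topDegs Ordered gene list, e.g. `topGenes(res, 500)`.
#' @param catalog A [MarkerCatalog-class].
#' @param minDatasets Recurrence cutoff for the marker list (default the
#'   catalog's own).
#' @param dataset,qiValue,paired Optional annotation copied to the result.
#' @return One-row `data.frame` (see [ProportionResult][qiProportionRegression]):
#'   `numerator`, `denominator`, `proportion`, `kind = "marker_in_deg"`.
#' @export
markerProportionInDegs <- function(topDegs, catalog, minDatasets = NULL,
                                   dataset = NA, qiValue = NA,
                                   paired = NA) {
    if (length(topDegs) == 0) stop("empty top gene list")
    markers <- markerFeatures(catalog, "both", minDatasets)
    if (length(markers) == 0) stop("empty marker catalog")
    .proportionResult(length(intersect(topDegs, markers)),
                      length(topDegs), "marker_in_deg",
                      dataset, qiValue, paired)
}

#' Proportion of known disease genes recovered in the top differential genes
#'
#' The fraction of the `topK` top-ranked known disease genes that appear in
#' the dataset's top differential genes.  Under quality imbalance this
#' proportion drops: genuine disease genes are crowded out.
#'
#' @param topDegs Ordered gene list (top 500 by default convention).
#' @param diseaseGenes Ranked character vector of known disease genes
#'   (at least `topK` entries).
#' @param topK How many top disease genes to look for (default 50).
#' @inheritParams markerProportionInDegs
#' @return One-row `data.frame` with `kind = "disease_in_deg"`.
#' @export
diseaseGeneProportion <- function(topDegs, diseaseGenes, topK = 50,
                                  dataset = NA, qiValue = NA, paired = NA) {
    if (length(topDegs) == 0) stop("empty top gene list")
    if (length(diseaseGenes) < topK)
        stop(sprintf("disease gene list has %d entries, need %d",
                     length(diseaseGenes), topK))
    top <- head(diseaseGenes, topK)
    .proportionResult(length(intersect(topDegs, top)), topK,
                      "disease_in_deg", dataset, qiValue, paired)
}

.olsSummary <- function(df) {
    fit <- lm(proportion ~ qi_value, data = df)
    s <- summary(fit)
    data.frame(slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = s$r.squared, n = nrow(df))
}

#' Regression of proportions on the QI index, per pairing stratum
#'
#' Ordinary least squares of a proportion (marker-in-DEG or
#' disease-gene-in-DEG) on the dataset QI index, fitted separately for
#' paired and unpaired datasets when both strata are present (pairing
#' dampens the quality confounding, so the strata differ in slope).
#'
#' @param results `data.frame` of stacked proportion rows
#'   (from [markerProportionInDegs()]/[diseaseGeneProportion()]) with
#'   `qi_value` and `paired` filled in.
#' @return `data.frame` with one row per stratum: `paired`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
qiProportionRegression <- function(results) {
    stopifnot(all(c("proportion", "qi_value") %in% colnames(results)))
    if (!"paired" %in% colnames(results) || all(is.na(results$paired)))
        results$paired <- FALSE
    strata <- split(results, results$paired)
    out <- lapply(names(strata), function(s) {
        df <- strata[[s]]
        if (nrow(df) < 3 || length(unique(df$qi_value)) < 2)
            stop(sprintf("degenerate stratum (paired = %s)", s))
        cbind(paired = as.logical(s), .olsSummary(df))
    })
    do.call(rbind, out)
}

#' Differential-gene count versus dataset size, by QI class
#'
#' Regresses the number of differential genes on the number of samples,
#' separately for low- and high-imbalance datasets (split at QI index 0.3),
#' after dropping datasets with fewer than `minDegs` differential genes.
#' With quality-responsive genes, the high-QI slope exceeds the low-QI
#' slope under FDR-only selection: imbalance converts added samples into
#' added (spurious) discoveries.
#'
#' @param datasets `data.frame` with columns `n_samples`, `deg_count`, and
#'   either `qi_class` (`"low"`/`"high"`) or `qi_value` (classified at
#'   `classCutoff`).
#' @param minDegs Minimum differential genes to enter the regression
#'   (default 50).
#' @param classCutoff QI split point when classifying from `qi_value`
#'   (default 0.3; low is `<=` the cutoff).
#' @return List with `slopes` (named numeric, `low`/`high`), `ratio`
#'   (`high / low`), and the per-class fits.
#' @export
degCountVsSizeRegression <- function(datasets, minDegs = 50,
                                     classCutoff = 0.3) {
    stopifnot(all(c("n_samples", "deg_count") %in% colnames(datasets)))
    if (!"qi_class" %in% colnames(datasets)) {
        stopifnot("qi_value" %in% colnames(datasets))
        datasets$qi_class <- ifelse(datasets$qi_value > classCutoff,
                                    "high", "low")
    }
    datasets <- datasets[datasets$deg_count >= minDegs, , drop = FALSE]
    fits <- lapply(c("low", "high"), function(cl) {
        df <- datasets[datasets$qi_class == cl, , drop = FALSE]
        if (nrow(df) < 3 || length(unique(df$n_samples)) < 2)
            stop(sprintf("degenerate class '%s' after the min_degs filter",
                         cl))
        lm(deg_count ~ n_samples, data = df)
    })
    names(fits) <- c("low", "high")
    slopes <- vapply(fits, function(f) unname(coef(f)[2]), numeric(1))
    list(slopes = slopes, ratio = unname(slopes["high"] / slopes["low"]),
         fits = fits)
}

#' Over-representation of quality markers among known disease genes
#'
#' One-sided Fisher test of the 2x2 table disease-gene membership by
#' marker membership over a gene universe, per marker direction: are
#' quality markers over-represented among the top-ranked known disease
#' genes?
#'
#' @param diseaseGenes Character vector of top-ranked known disease genes
#'   (conventionally the top 300).
#' @param catalog A [MarkerCatalog-class].
#' @param universe Background gene ids (must contain the disease genes and
#'   markers).
#' @return `data.frame` with one row per direction: `direction`, `overlap`,
#'   `n_markers`, `n_disease_genes`, `p`.
#' @export
markerEnrichmentInDiseaseGenes <- function(diseaseGenes, catalog,
                                           universe) {
    universe <- unique(as.character(universe))
    if (length(universe) == 0) stop("empty universe")
    diseaseGenes <- intersect(unique(diseaseGenes), universe)
    out <- lapply(c("low", "high"), function(d) {
        markers <- intersect(markerFeatures(catalog, d), universe)
        ov <- length(intersect(markers, diseaseGenes))
        tab <- matrix(c(ov,
                        length(diseaseGenes) - ov,
                        length(markers) - ov,
                        length(universe) - length(diseaseGenes) -
                            length(markers) + ov), nrow = 2)
        p <- fisher.test(tab, alternative = "greater")$p.value
        data.frame(direction = d, overlap = ov,
                   n_markers = length(markers),
                   n_disease_genes = length(diseaseGenes), p = p,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

# verdict rule: relative change of the low-quality-pathway percentage;
# excluded when the baseline has nothing to mitigate
.mitigationVerdict <- function(basePct, mitigatedPct, baselineLowCount,
                               changeThreshold = 0.15) {
    if (baselineLowCount == 0) return("excluded")
    rel <- (mitigatedPct - basePct) / basePct
    if (rel <= -changeThreshold) "better"
    else if (rel >= changeThreshold) "worse"
    else "no_change"
}

#' Evaluate a quality-imbalance mitigation strategy on one dataset
#'
#' Runs the differential analysis without and with a mitigation strategy —
#' the quality covariate (`1 - p_low` in the model), removal of IQR-defined
#' quality-outlier samples, or both — and scores the change in
#' quality-driven pathway contamination.  Significant genes are split by
#' fold-change sign; each sign list is tested for pathway
#' over-representation; the contamination of a run is the percentage of
#' low-quality pathways among its differential pathways.  Per sign, the
#' verdict is `better` when the contamination decreased by at least
#' `changeThreshold` (relative change, default 15%), `worse` when it
#' increased as much, `no_change` otherwise, and `excluded` when the
#' baseline has no low-quality pathway among its differential pathways
#' (nothing to mitigate).
#'
#' @param x A [QualityExperiment-class].
#' @param lowQualityPathwaySet Character vector of pathway names previously
#'   derived from the low-quality markers (see [lowQualityPathways()]).
#' @param geneSets Gene-set collection for the differential-pathway ORA.
#' @param strategy `"outlier_removal"` (default), `"covariate"` or
#'   `"both"`.
#' @param fdr,lfc,useLfc Differential-gene selection (see
#'   [significantGenes()]).
#' @param oraAlpha Adjusted-p cutoff for differential pathways.
#' @param adjust,minSize,maxSize Passed to [ora()].
#' @param changeThreshold Relative-change verdict threshold (default 0.15).
#' @return `data.frame`, one row per `deg_sign` (`pos`, `neg`): baseline
#'   and mitigated contamination percentages and counts, the verdict, and
#'   the realized QI index before and after mitigation (QI changes only
#'   under outlier removal).
#' @export
evaluateMitigation <- function(x, lowQualityPathwaySet, geneSets,
                               strategy = c("outlier_removal", "covariate",
                                            "both"),
                               fdr = 0.05, lfc = 1, useLfc = TRUE,
                               oraAlpha = 0.05,
                               adjust = c("bonferroni", "BH"),
                               minSize = 15, maxSize = 500,
                               changeThreshold = 0.15) {
    strategy <- match.arg(strategy)
    adjust <- match.arg(adjust)
    stopifnot(is(x, "QualityExperiment"))

    removeOutliers <- function(qe) {
        out <- detectQualityOutliers(qe)
        keep <- setdiff(colnames(qe), out)
        qe2 <- qe[, keep]
        if (any(table(sampleGroup(qe2)) < 2))
            stop("outlier removal leaves fewer than 2 samples in a group")
        qe2
    }
    mitigated <- switch(strategy,
        covariate = list(qe = x, covariate = TRUE),
        outlier_removal = list(qe = removeOutliers(x), covariate = FALSE),
        both = list(qe = removeOutliers(x), covariate = TRUE))

    contamination <- function(qe, covariate) {
        res <- runDE(qe, useQualityCovariate = covariate)
        sig <- significantGenes(res, fdr = fdr, lfc = lfc, useLfc = useLfc)
        uni <- rownames(res)[res$tested]
        perSign <- lapply(c(pos = 1, neg = -1), function(sgn) {
            genes <- sig[sign(res[sig, "log2fc"]) == sgn]
            if (length(genes) == 0)
                return(list(nPath = 0L, nLow = 0L, pct = 0))
            hit <- ora(genes, geneSets, uni, minSize = minSize,
                       maxSize = maxSize, adjust = adjust)
            diffPaths <- hit$set[hit$padj < oraAlpha]
            nLow <- length(intersect(diffPaths, lowQualityPathwaySet))
            list(nPath = length(diffPaths), nLow = nLow,
                 pct = if (length(diffPaths) == 0) 0
                       else 100 * nLow / length(diffPaths))
        })
        perSign
    }
    base <- contamination(x, covariate = FALSE)
    mit <- contamination(mitigated$qe, covariate = mitigated$covariate)

    qiBefore <- qiValue(qiIndex(x))
    qiAfter <- qiValue(qiIndex(mitigated$qe))

    rows <- lapply(c("pos", "neg"), function(sg) {
        b <- base[[sg]]; m <- mit[[sg]]
        verdict <- .mitigationVerdict(b$pct, m$pct, b$nLow,
                                      changeThreshold)
        data.frame(deg_sign = sg, strategy = strategy,
                   baseline_pct = b$pct, mitigated_pct = m$pct,
                   baseline_n_pathways = b$nPath,
                   baseline_n_lowq = b$nLow,
                   mitigated_n_pathways = m$nPath,
                   mitigated_n_lowq = m$nLow,
                   qi_before = qiBefore, qi_after = qiAfter,
                   verdict = verdict, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
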