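#' Replicated ground-truth experiments
#'
#' The functions on this page run the package's analyses on replicated
#' synthetic datasets with known ground truth and summarize the outcome.
#' They define the package's reference study conditions (sample sizes,
#' planted effect sizes, replicate counts — documented with defaults below
#' and in the methods vignette) and are what the acceptance script and the
#' calibration tests execute.  All randomness derives from the single
#' `seed` argument; per-replicate seeds are `seed * 1000 + k`.
#'
#' @name qi-experiments
NULL

.derivedSeed <- function(seed, k) as.integer(seed * 1000 + k)

#' @describeIn qi-experiments False-positive calibration of the
#'   differential engine under the generator's null: datasets with no
#'   planted effects and no quality-group confounding.  Returns the
#'   per-replicate fraction of tested genes significant at BH < `fdr` and
#'   its mean (which should sit at or below the nominal rate).
#' @param nReplicates Number of replicate datasets.
#' @param nControl,nDisease,nGenes Dataset dimensions.
#' @param nDiseaseGenes,diseaseEffect Planted disease genes and their log2
#'   effect, where the experiment plants them.
#' @param fdr BH cutoff for the null calibration (default 0.05).
#' @param seed Master seed.
#' @export
runNullCalibration <- function(nReplicates = 10, nControl = 10,
                               nDisease = 10, nGenes = 2000, fdr = 0.05,
                               seed = 1) {
    frac <- vapply(seq_len(nReplicates), function(k) {
        qe <- simulateQualityDataset(
            nControl = nControl, nDisease = nDisease, nGenes = nGenes,
            nLowMarkers = 0, nHighMarkers = 0, nDiseaseGenes = 0,
            qualityEffect = 0, diseaseEffect = 0, qiTarget = 0,
            seed = .derivedSeed(seed, k))
        res <- runDE(qe)
        mean(res$padj[res$tested] < fdr)
    }, numeric(1))
    list(fractions = frac, mean_fraction = mean(frac))
}

#' @describeIn qi-experiments Differential-gene inflation across a ladder
#'   of target QI values: 20-sample datasets with quality-responsive genes
#'   only (no disease effect), differential genes counted with the FDR-only
#'   and the FDR + fold-change selections.  Under confounding the FDR-only
#'   count grows with the QI target; the fold-change cutoff shrinks the
#'   gap.  Returns the per-run table and per-level means.
#' @param qiTargets Target QI ladder.
#' @param nQualityGenes Planted quality-responsive genes (half low-, half
#'   high-quality markers).
#' @param qualityEffect Log2 quality effect magnitude.
#' @export
runInflationExperiment <- function(qiTargets = c(0, 0.5, 0.9),
                                   nReplicates = 10, nControl = 10,
                                   nDisease = 10, nGenes = 1500,
                                   nQualityGenes = 300, qualityEffect = 2,
                                   seed = 1) {
    nl <- nQualityGenes %/% 2
    grid <- expand.grid(rep = seq_len(nReplicates),
                        qi_target = qiTargets)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        qe <- simulateQualityDataset(
            nControl = nControl, nDisease = nDisease, nGenes = nGenes,
            nLowMarkers = nl, nHighMarkers = nQualityGenes - nl,
            nDiseaseGenes = 0, qualityEffect = qualityEffect,
            diseaseEffect = 0, qiTarget = grid$qi_target[i],
            seed = .derivedSeed(seed, i))
        res <- runDE(qe)
        data.frame(qi_target = grid$qi_target[i], rep = grid$rep[i],
                   realized_qi = realizedQI(qe),
                   deg_fdr = length(significantGenes(res, useLfc = FALSE)),
                   deg_fdr_lfc = length(significantGenes(res)))
    })
    tab <- do.call(rbind, rows)
    means <- aggregate(cbind(deg_fdr, deg_fdr_lfc) ~ qi_target, tab, mean)
    list(table = tab, means = means,
         gap_fdr = diff(range(means$deg_fdr)),
         gap_fdr_lfc = diff(range(means$deg_fdr_lfc)))
}

#' @describeIn qi-experiments Marker recovery across a collection of
#'   low-imbalance datasets sharing planted marker identities: per-dataset
#'   quality correlations, marker calls at `threshold`, recurrence
#'   aggregation, then sensitivity (fraction of planted markers recovered
#'   with the right direction at recurrence >= 2) and precision (fraction
#'   of catalog features at recurrence >= `precisionAt` that are planted
#'   markers of the right direction).
#' @param nDatasets Datasets in the collection.
#' @param nLowMarkers,nHighMarkers Planted shared markers.
#' @param qiTarget Target QI of the derivation datasets (low).
#' @param threshold Marker-call correlation cutoff.
#' @param precisionAt Recurrence level at which precision is evaluated.
#' @export
runMarkerRecoveryExperiment <- function(nDatasets = 13, nControl = 10,
                                        nDisease = 10, nGenes = 2000,
                                        nLowMarkers = 200,
                                        nHighMarkers = 200,
                                        nDiseaseGenes = 100,
                                        qualityEffect = 2,
                                        qiTarget = 0.1, threshold = 0.4,
                                        precisionAt = 4, seed = 1) {
    coll <- simulateQualityCollection(
        nDatasets = nDatasets, nControl = nControl, nDisease = nDisease,
        nGenes = nGenes, nLowMarkers = nLowMarkers,
        nHighMarkers = nHighMarkers, nDiseaseGenes = nDiseaseGenes,
        qualityEffect = qualityEffect, qiTarget = qiTarget,
        seed = seed * 1000)
    calls <- lapply(coll, function(qe)
        callMarkers(geneQualityCorrelations(qe), threshold = threshold))
    catalog <- markerRecurrence(calls, minDatasets = 2)
    truth <- rowData(coll[[1]])
    trueLow <- rownames(coll[[1]])[truth$role == "low_marker"]
    trueHigh <- rownames(coll[[1]])[truth$role == "high_marker"]
    gotLow <- markerFeatures(catalog, "low")
    gotHigh <- markerFeatures(catalog, "high")
    sens <- (length(intersect(gotLow, trueLow)) +
             length(intersect(gotHigh, trueHigh))) /
        (length(trueLow) + length(trueHigh))
    gotLowK <- markerFeatures(catalog, "low", minDatasets = precisionAt)
    gotHighK <- markerFeatures(catalog, "high", minDatasets = precisionAt)
    nAtK <- length(gotLowK) + length(gotHighK)
    prec <- if (nAtK == 0) NA_real_ else
        (length(intersect(gotLowK, trueLow)) +
         length(intersect(gotHighK, trueHigh))) / nAtK
    list(catalog = catalog, collection = coll,
         sensitivity = sens, precision = prec,
         recurrence = recurrenceTable(catalog))
}

#' @describeIn qi-experiments Quality-stratified subset analysis on one
#'   wide-quality-spread source dataset: builds the `4 x nIterations`
#'   subsets, runs the differential engine on each, and regresses the
#'   differential-gene count on the subset QI index (FDR-only selection).
#' @param nIterations Subset iterations (4 subsets each).
#' @export
runSubsetExperiment <- function(nControl = 40, nDisease = 40,
                                nGenes = 1500, nLowMarkers = 150,
                                nHighMarkers = 150, nDiseaseGenes = 50,
                                qualityEffect = 2, diseaseEffect = 1,
                                nIterations = 3, seed = 1) {
    qe <- simulateQualityDataset(
        nControl = nControl, nDisease = nDisease, nGenes = nGenes,
        nLowMarkers = nLowMarkers, nHighMarkers = nHighMarkers,
        nDiseaseGenes = nDiseaseGenes, qualityEffect = qualityEffect,
        diseaseEffect = diseaseEffect, qiTarget = 0,
        seed = seed * 1000)
    subs <- buildQualitySubsets(qe, nIterations = nIterations,
                                seed = seed * 1000 + 500)
    curve <- subsetResponseCurve(qe, subs, useLfc = FALSE)
    list(source = qe, subsets = subs, curve = curve,
         qi_range = diff(range(subs$qi_value)))
}

#' @describeIn qi-experiments Outlier-removal mitigation on replicated
#'   datasets with planted extreme-quality outliers in the disease group:
#'   tight low quality for most samples, a few forced to `outlierPLow`.
#'   Low-quality pathways are derived from the planted low markers by ORA;
#'   the replicate verdict is the one for positively-changed genes (the
#'   direction the planted low markers contaminate).  Returns per-replicate
#'   verdicts, the fraction `better`, and the fraction of replicates where
#'   mitigation reduced the realized QI index.
#' @param nQualityOutliers,outlierPLow Planted outliers per dataset.
#' @param strategy Mitigation strategy to evaluate.
#' @export
runMitigationExperiment <- function(nReplicates = 10, nControl = 10,
                                    nDisease = 10, nGenes = 2000,
                                    nLowMarkers = 150, nHighMarkers = 150,
                                    nDiseaseGenes = 100,
                                    qualityEffect = 4, diseaseEffect = 2,
                                    nQualityOutliers = 4,
                                    outlierPLow = 0.95,
                                    strategy = "outlier_removal",
                                    seed = 1) {
    rows <- lapply(seq_len(nReplicates), function(k) {
        qe <- simulateQualityDataset(
            nControl = nControl, nDisease = nDisease, nGenes = nGenes,
            nLowMarkers = nLowMarkers, nHighMarkers = nHighMarkers,
            nDiseaseGenes = nDiseaseGenes,
            qualityEffect = qualityEffect, diseaseEffect = diseaseEffect,
            qiTarget = 0, qualityCenter = 0.2, qualityConcentration = 30,
            nQualityOutliers = nQualityOutliers,
            outlierPLow = outlierPLow, seed = .derivedSeed(seed, k))
        sets <- simulateGeneSets(qe, seed = .derivedSeed(seed, k) + 1)
        lowMarkers <- rownames(qe)[rowData(qe)$role == "low_marker"]
        lowPaths <- lowQualityPathways(lowMarkers, sets, rownames(qe))
        rep <- evaluateMitigation(qe, lowPaths, sets, strategy = strategy,
                                  useLfc = FALSE)
        pos <- rep[rep$deg_sign == "pos", , drop = FALSE]
        data.frame(rep = k, verdict = pos$verdict,
                   baseline_pct = pos$baseline_pct,
                   mitigated_pct = pos$mitigated_pct,
                   qi_before = pos$qi_before, qi_after = pos$qi_after,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    list(table = tab,
         better_fraction = mean(tab$verdict == "better"),
         qi_reduced_fraction = mean(tab$qi_after < tab$qi_before))
}

#' @describeIn qi-experiments Marker and disease-gene proportions in the
#'   top differential genes across a QI ladder.  A small derivation
#'   collection (sharing the planted marker identities) provides the
#'   recurrence catalog; then, for each ladder level and replicate, the
#'   top differential genes are intersected with the catalog markers and
#'   with the top `topK` planted disease genes.  Returns the per-run table
#'   and the Spearman correlations of both proportions with the QI level.
#' @param qiLevels Target QI ladder for the evaluation datasets.
#' @param nDerivationDatasets Low-QI datasets used to derive the marker
#'   catalog before the ladder runs.
#' @param nTop Size of the top differential-gene list.
#' @param topK Top known disease genes looked up.
#' @export
runProportionLadder <- function(qiLevels = c(0, 0.2, 0.4, 0.6, 0.8),
                                nReplicates = 5, nControl = 10,
                                nDisease = 10, nGenes = 2000,
                                nLowMarkers = 300, nHighMarkers = 300,
                                nDiseaseGenes = 100,
                                qualityEffect = 2.5, diseaseEffect = 1,
                                nDerivationDatasets = 6, nTop = 500,
                                topK = 50, seed = 1) {
    deriv <- simulateQualityCollection(
        nDatasets = nDerivationDatasets, nControl = nControl,
        nDisease = nDisease, nGenes = nGenes,
        nLowMarkers = nLowMarkers, nHighMarkers = nHighMarkers,
        nDiseaseGenes = nDiseaseGenes, qualityEffect = qualityEffect,
        qiTarget = 0.1, seed = seed * 1000 + 900)
    calls <- lapply(deriv, function(qe)
        callMarkers(geneQualityCorrelations(qe)))
    catalog <- markerRecurrence(calls, minDatasets = 2)

    grid <- expand.grid(rep = seq_len(nReplicates), level = qiLevels)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        qe <- simulateQualityDataset(
            nControl = nControl, nDisease = nDisease, nGenes = nGenes,
            nLowMarkers = nLowMarkers, nHighMarkers = nHighMarkers,
            nDiseaseGenes = nDiseaseGenes,
            qualityEffect = qualityEffect, diseaseEffect = diseaseEffect,
            qiTarget = grid$level[i], seed = .derivedSeed(seed, i))
        res <- runDE(qe)
        top <- topGenes(res, nTop)
        disRanked <- rownames(qe)[rowData(qe)$role == "disease"]
        mp <- markerProportionInDegs(top, catalog,
                                     qiValue = realizedQI(qe))
        dp <- diseaseGeneProportion(top, disRanked, topK = topK,
                                    qiValue = realizedQI(qe))
        data.frame(level = grid$level[i], rep = grid$rep[i],
                   realized_qi = realizedQI(qe),
                   marker_prop = mp$proportion,
                   disease_prop = dp$proportion)
    })
    tab <- do.call(rbind, rows)
    list(table = tab, catalog = catalog,
         marker_spearman = cor(tab$level, tab$marker_prop,
                               method = "spearman"),
         disease_spearman = cor(tab$level, tab$disease_prop,
                                method = "spearman"))
}
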