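#' Run the full synthetic quality-imbalance pipeline
#'
#' Orchestrates the stages end to end on simulated data and writes every
#' artifact as plain TSV to `outdir`: a marker-derivation collection (counts
#' and sample tables), per-dataset QI indices under all three metrics, the
#' recurrence catalog, pathway enrichment of the low-quality markers,
#' quality-stratified subsets with their differential-gene response, and a
#' mitigation report on an outlier dataset.  Re-running with the same
#' configuration reproduces the artifacts bit-identically (no timestamps
#' are embedded).
#'
#' @param outdir Output directory (created if needed).
#' @param config Named list overriding pipeline defaults; see
#'   `pipelineDefaults()`.  All stage tunables (QI cutoffs, marker
#'   thresholds, FDR/LFC, pool sizes) live here.
#' @param seed Master seed for every stochastic stage.
#' @return Invisibly, the manifest `data.frame` of written artifacts.
#' @export
runPipeline <- function(outdir, config = list(), seed = 1) {
    cfg <- utils::modifyList(pipelineDefaults(), config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    emit <- function(name, writer) {
        path <- file.path(outdir, name)
        writer(path)
        written <<- c(written, name)
        path
    }

    coll <- simulateQualityCollection(
        nDatasets = cfg$n_datasets, nControl = cfg$n_control,
        nDisease = cfg$n_disease, nGenes = cfg$n_genes,
        nLowMarkers = cfg$n_low_markers, nHighMarkers = cfg$n_high_markers,
        nDiseaseGenes = cfg$n_disease_genes,
        qualityEffect = cfg$quality_effect,
        diseaseEffect = cfg$disease_effect, qiTarget = cfg$qi_target,
        seed = seed)
    names(coll) <- sprintf("dataset%02d", seq_along(coll))

    qiRows <- do.call(rbind, lapply(names(coll), function(nm) {
        do.call(rbind, lapply(c("pearson", "spearman", "ctdiff"),
            function(m) {
                r <- qiIndex(coll[[nm]], metric = m)
                data.frame(dataset = nm, metric = m, value = qiValue(r),
                           qi_class = qiClass(r), n_samples = r@nSamples)
            }))
    }))
    emit("qi_results.tsv", function(p)
        write.table(qiRows, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))
    for (nm in names(coll)) {
        emit(sprintf("%s_counts.tsv", nm), function(p)
            writeCountMatrix(coll[[nm]], p))
        emit(sprintf("%s_samples.tsv", nm), function(p)
            writeSampleTable(coll[[nm]], p))
    }

    calls <- lapply(coll, function(qe)
        callMarkers(geneQualityCorrelations(qe),
                    threshold = cfg$marker_threshold))
    catalog <- markerRecurrence(calls, minDatasets = cfg$min_datasets)
    emit("marker_catalog.tsv", function(p) writeMarkerCatalog(catalog, p))
    emit("recurrence_table.tsv", function(p)
        write.table(recurrenceTable(catalog), p, sep = "\t",
                    quote = FALSE, row.names = FALSE))

    sets <- simulateGeneSets(coll[[1]], seed = seed + 400)
    emit("gene_sets.gmt", function(p) writeGMT(sets, p))
    lowPaths <- lowQualityPathways(catalog, sets, rownames(coll[[1]]),
                                   adjust = cfg$ora_adjust)
    oraTab <- ora(markerFeatures(catalog, "low"), sets,
                  rownames(coll[[1]]), minSize = cfg$ora_min_size,
                  maxSize = cfg$ora_max_size, adjust = cfg$ora_adjust)
    emit("lowq_marker_enrichment.tsv", function(p)
        write.table(oraTab, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))

    src <- simulateQualityDataset(
        nControl = cfg$subset_group_size, nDisease = cfg$subset_group_size,
        nGenes = cfg$n_genes, nLowMarkers = cfg$n_low_markers,
        nHighMarkers = cfg$n_high_markers,
        nDiseaseGenes = cfg$n_disease_genes,
        qualityEffect = cfg$quality_effect,
        diseaseEffect = cfg$disease_effect, qiTarget = 0,
        seed = seed + 600)
    subs <- buildQualitySubsets(src, nIterations = cfg$subset_iterations,
                                poolSize = cfg$pool_size,
                                seed = seed + 601)
    curve <- subsetResponseCurve(src, subs, fdr = cfg$fdr, lfc = cfg$lfc,
                                 useLfc = FALSE)
    emit("subsets.tsv", function(p)
        write.table(curve$table, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))
    emit("subset_regression.tsv", function(p)
        write.table(data.frame(slope = curve$slope,
                               intercept = curve$intercept,
                               r_squared = curve$r_squared), p,
                    sep = "\t", quote = FALSE, row.names = FALSE))

    outQe <- simulateQualityDataset(
        nControl = cfg$n_control, nDisease = cfg$n_disease,
        nGenes = cfg$n_genes, nLowMarkers = cfg$n_low_markers,
        nHighMarkers = cfg$n_high_markers,
        nDiseaseGenes = cfg$n_disease_genes,
        qualityEffect = cfg$outlier_quality_effect,
        diseaseEffect = cfg$disease_effect, qiTarget = 0,
        qualityCenter = 0.2, qualityConcentration = 30,
        nQualityOutliers = cfg$n_quality_outliers, seed = seed + 700)
    outSets <- simulateGeneSets(outQe, seed = seed + 701)
    outLow <- lowQualityPathways(
        rownames(outQe)[rowData(outQe)$role == "low_marker"],
        outSets, rownames(outQe))
    mit <- evaluateMitigation(outQe, outLow, outSets,
                              strategy = cfg$mitigation_strategy,
                              fdr = cfg$fdr, lfc = cfg$lfc,
                              useLfc = FALSE)
    emit("mitigation_report.tsv", function(p)
        write.table(mit, p, sep = "\t", quote = FALSE, row.names = FALSE))

    de <- runDE(coll[[1]])
    emit("dataset01_de.tsv", function(p) writeDEResult(de, p))

    log <- c(sprintf("qimbalance version: %s",
                     as.character(packageVersion("qimbalance"))),
             sprintf("seed: %d", seed),
             sprintf("%s: %s", names(cfg),
                     vapply(cfg, function(v) paste(format(v),
                                                   collapse = ","),
                            character(1))))
    emit("run_log.txt", function(p) writeLines(log, p))

    manifest <- data.frame(artifact = written, stringsAsFactors = FALSE)
    write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(manifest)
}

#' @describeIn runPipeline Default pipeline configuration: every tunable of
#'   the analysis stages with the package's standard values (QI cutoffs
#'   0.18/0.30 via [qiCutoffs()], marker threshold 0.4, recurrence >= 2,
#'   FDR 0.05, |log2 FC| 1, pool size 15, 3 subset iterations,
#'   Bonferroni-adjusted ORA with set sizes 15-500).
#' @export
pipelineDefaults <- function() {
    list(n_datasets = 6, n_control = 8, n_disease = 8, n_genes = 600,
         n_low_markers = 60, n_high_markers = 60, n_disease_genes = 40,
         quality_effect = 2, disease_effect = 2, qi_target = 0.1,
         marker_threshold = 0.4, min_datasets = 2,
         fdr = 0.05, lfc = 1,
         ora_min_size = 15, ora_max_size = 500,
         ora_adjust = "bonferroni",
         pool_size = 15, subset_iterations = 3, subset_group_size = 30,
         n_quality_outliers = 4, outlier_quality_effect = 4,
         mitigation_strategy = "outlier_removal")
}

#' Write a miniature fixture bundle
#'
#' Generates a small deterministic collection (six datasets of 16 samples
#' by 500 genes, one peak dataset, a gene-set collection and a TSS table)
#' and writes it in the package's plain-text formats.  Used by the test
#' suite; fixture QI values span the low and high classes.
#'
#' @param dir Output directory.
#' @param seed RNG seed (default 50).
#' @return Invisibly, the paths written.
#' @export
makeFixtures <- function(dir, seed = 50) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    qis <- c(0.05, 0.1, 0.15, 0.5, 0.7, 0.85)
    paths <- character()
    for (i in seq_along(qis)) {
        qe <- simulateQualityDataset(
            nControl = 8, nDisease = 8, nGenes = 500, nLowMarkers = 50,
            nHighMarkers = 50, nDiseaseGenes = 30, qiTarget = qis[i],
            seed = seed + i)
        p1 <- file.path(dir, sprintf("fixture%02d_counts.tsv", i))
        p2 <- file.path(dir, sprintf("fixture%02d_samples.tsv", i))
        writeCountMatrix(qe, p1); writeSampleTable(qe, p2)
        paths <- c(paths, p1, p2)
    }
    pk <- simulatePeakDataset(nControl = 6, nDisease = 6, nBins = 100,
                              seed = seed + 50)
    for (sid in names(pk$peaks)) {
        p <- file.path(dir, sprintf("peaks_%s.bed", sid))
        writePeaksBed(pk$peaks[[sid]], p)
        paths <- c(paths, p)
    }
    p <- file.path(dir, "peak_samples.tsv")
    writeSampleTable(pk$samples, p); paths <- c(paths, p)

    qe1 <- simulateQualityDataset(nControl = 8, nDisease = 8,
                                  nGenes = 500, nLowMarkers = 50,
                                  nHighMarkers = 50, nDiseaseGenes = 30,
                                  seed = seed + 1)
    sets <- simulateGeneSets(qe1, nLowSets = 3, nDiseaseSets = 3,
                             nNullSets = 4, setSize = 30, seed = seed)
    p <- file.path(dir, "gene_sets.gmt")
    writeGMT(sets, p); paths <- c(paths, p)

    set.seed(seed)
    tss <- data.frame(gene_id = sprintf("TG%03d", 1:40),
                      chrom = "chrS",
                      tss = sort(sample.int(100 * 500, 40)),
                      strand = "+")
    p <- file.path(dir, "tss_annotation.tsv")
    write.table(tss, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    invisible(paths)
}
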