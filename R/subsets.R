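#' Top- and bottom-quality sample pools per group
#'
#' Within each group, the `poolSize` samples with the lowest `p_low` form
#' the top-quality pool and the `poolSize` with the highest `p_low` the
#' bottom-quality pool.  The pools overlap when a group has fewer than
#' `2 * poolSize` samples.  Ties in `p_low` are broken by lexicographic
#' sample id, so pools are deterministic.
#'
#' @param x A [QualityExperiment-class] or sample-table `data.frame`.
#' @param poolSize Samples per pool (default 15).
#' @return List with character elements `control_top`, `control_bottom`,
#'   `disease_top`, `disease_bottom`.
#' @export
buildQualityPools <- function(x, poolSize = 15) {
    tab <- if (is(x, "QualityExperiment")) sampleTable(x) else x
    pools <- list()
    for (g in c("control", "disease")) {
        sub <- tab[tab$group == g, , drop = FALSE]
        if (nrow(sub) < poolSize)
            stop(sprintf("group '%s' has %d samples, fewer than poolSize %d",
                         g, nrow(sub), poolSize))
        ordAsc <- sub$sample_id[order(sub$p_low, sub$sample_id)]
        ordDesc <- sub$sample_id[order(-sub$p_low, sub$sample_id)]
        pools[[paste0(g, "_top")]] <- head(ordAsc, poolSize)
        pools[[paste0(g, "_bottom")]] <- head(ordDesc, poolSize)
    }
    pools
}

#' Build quality-stratified 20-sample subsets
#'
#' Reproduces the fixed-size subset design used to isolate the effect of
#' quality imbalance from sample size: per iteration, one 10-sample group
#' is drawn without replacement from each of the four pools (bottom/top
#' quality within control/disease), and the two control draws are paired
#' with the two disease draws to form the four combos `BB`, `BT`, `TB`,
#' `TT` (control-pool letter first, `B` = bottom quality).  Each drawn
#' group is therefore reused in exactly two combos.  Three iterations give
#' 12 subsets; each subset's realized QI index (`qi_pearson`) is recorded.
#'
#' Within an iteration the bottom draw of a group side is taken first and
#' the top draw from the remaining samples, so no sample appears in both
#' draws of the same side even when the pools overlap.
#'
#' @param x A [QualityExperiment-class] or sample-table `data.frame`.
#' @param nIterations Iterations (default 3; total subsets `4 * nIterations`).
#' @param groupSize Samples drawn per group (default 10).
#' @param poolSize Pool size (default 15).
#' @param seed RNG seed; identical seeds give identical subsets.
#' @return `data.frame`, one row per subset: `iteration`, `combo`,
#'   `control_ids`, `disease_ids` (comma-joined), `qi_value`.
#' @export
buildQualitySubsets <- function(x, nIterations = 3, groupSize = 10,
                                poolSize = 15, seed = 1) {
    tab <- if (is(x, "QualityExperiment")) sampleTable(x) else x
    pools <- buildQualityPools(tab, poolSize)
    if (poolSize < groupSize)
        stop("poolSize smaller than the 10-sample draw: pool exhausted")
    pl <- setNames(tab$p_low, tab$sample_id)
    set.seed(seed)
    out <- list()
    for (it in seq_len(nIterations)) {
        draw <- list()
        for (g in c("control", "disease")) {
            bottom <- sample(pools[[paste0(g, "_bottom")]], groupSize)
            topPool <- setdiff(pools[[paste0(g, "_top")]], bottom)
            if (length(topPool) < groupSize)
                stop(sprintf(
                    "pool exhausted for group '%s': %d samples left for the top draw",
                    g, length(topPool)))
            draw[[paste0(g, "_B")]] <- bottom
            draw[[paste0(g, "_T")]] <- sample(topPool, groupSize)
        }
        for (combo in c("BB", "BT", "TB", "TT")) {
            cIds <- draw[[paste0("control_", substr(combo, 1, 1))]]
            dIds <- draw[[paste0("disease_", substr(combo, 2, 2))]]
            sub <- data.frame(
                sample_id = c(cIds, dIds),
                group = rep(c("control", "disease"), each = groupSize),
                p_low = pl[c(cIds, dIds)], stringsAsFactors = FALSE)
            out[[length(out) + 1L]] <- data.frame(
                iteration = it, combo = combo,
                control_ids = paste(cIds, collapse = ","),
                disease_ids = paste(dIds, collapse = ","),
                qi_value = qiValue(qiIndex(sub)),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

.splitIds <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]

#' Differential-gene response to subset quality imbalance
#'
#' Runs the differential engine on every subset, counts significant genes,
#' and fits the ordinary least-squares regression of the count on the
#' subset QI index.  With quality-responsive genes in the source data the
#' slope is positive: more imbalance, more (spurious) differential genes.
#'
#' @param x The source [QualityExperiment-class] the subsets were drawn
#'   from.
#' @param subsets `data.frame` from [buildQualitySubsets()].
#' @param fdr,lfc,useLfc Selection thresholds (see [significantGenes()]).
#' @return List with `slope`, `intercept`, `r_squared` and `table` (the
#'   per-subset QI and DEG count).
#' @export
subsetResponseCurve <- function(x, subsets, fdr = 0.05, lfc = 1,
                                useLfc = FALSE) {
    stopifnot(is(x, "QualityExperiment"), nrow(subsets) >= 3)
    if (length(unique(round(subsets$qi_value, 10))) < 2)
        stop("degenerate regression: all subsets have the same QI value")
    degs <- vapply(seq_len(nrow(subsets)), function(i) {
        ids <- c(.splitIds(subsets$control_ids[i]),
                 .splitIds(subsets$disease_ids[i]))
        sub <- x[, ids]
        res <- tryCatch(runDE(sub), error = function(e)
            stop(sprintf("differential engine failed on subset %d (%s): %s",
                         i, subsets$combo[i], conditionMessage(e))))
        length(significantGenes(res, fdr = fdr, lfc = lfc,
                                useLfc = useLfc))
    }, numeric(1))
    tab <- data.frame(subsets, deg_count = degs)
    fit <- lm(deg_count ~ qi_value, data = tab)
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, table = tab)
}
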