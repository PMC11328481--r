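#' QIResult: a quality-imbalance index with its classification
#'
#' Value container returned by [qiIndex()]: the metric used (`"pearson"`,
#' `"spearman"` or `"ctdiff"`), the index value, its class under the metric's
#' cutoffs (`"low"`, `"intermediate"`, `"high"`) and the number of samples.
#'
#' @slot metric character(1), one of `pearson`, `spearman`, `ctdiff`.
#' @slot value numeric(1), the index; in `[0, 1]` for the correlation
#'   metrics, unbounded above for `ctdiff`.
#' @slot qiClass character(1), `low`/`intermediate`/`high`.
#' @slot nSamples integer(1).
#' @export
setClass("QIResult",
         representation(metric = "character", value = "numeric",
                        qiClass = "character", nSamples = "integer"))

#' @describeIn QIResult Numeric index value.
#' @param x A `QIResult`.
#' @export
qiValue <- function(x) x@value

#' @describeIn QIResult Imbalance class under the metric's cutoffs.
#' @export
qiClass <- function(x) x@qiClass

setMethod("show", "QIResult", function(object) {
    cat(sprintf("QI index (%s): %.4f [%s], n = %d samples\n",
                object@metric, object@value, object@qiClass,
                object@nSamples))
})

#' Default QI cutoffs per metric
#'
#' Correlation-based indices (Pearson point-biserial and Spearman) classify a
#' dataset as low-imbalance below 0.18 and high-imbalance above 0.30; the
#' central tendency difference uses the more stringent 0.5 and 1.
#'
#' @param metric One of `"pearson"`, `"spearman"`, `"ctdiff"`.
#' @return Numeric vector `c(low, high)` of class boundaries.
#' @export
qiCutoffs <- function(metric = c("pearson", "spearman", "ctdiff")) {
    metric <- match.arg(metric)
    if (metric == "ctdiff") c(low = 0.5, high = 1) else
        c(low = 0.18, high = 0.30)
}

#' Classify a QI index value
#'
#' Strict inequalities at both boundaries: a value below the low cutoff is
#' `"low"`, above the high cutoff `"high"`, anything else (boundaries
#' included) `"intermediate"`.
#'
#' @param value Non-negative index value.
#' @param metric Metric the value was computed under (selects default
#'   cutoffs).
#' @param cutoffs Numeric `c(low, high)`; defaults to [qiCutoffs()] for the
#'   metric.
#' @return `"low"`, `"intermediate"` or `"high"`.
#' @export
classifyQI <- function(value, metric = c("pearson", "spearman", "ctdiff"),
                       cutoffs = qiCutoffs(metric)) {
    metric <- match.arg(metric)
    stopifnot(is.numeric(value), length(value) == 1L, value >= 0,
              length(cutoffs) == 2L, cutoffs[1] <= cutoffs[2])
    if (value < cutoffs[1]) "low"
    else if (value > cutoffs[2]) "high"
    else "intermediate"
}

.qiCheckInput <- function(pLow, group, metric) {
    if (anyNA(pLow) || anyNA(group))
        stop("p_low and group must not contain NA")
    if (any(pLow < 0 | pLow > 1))
        stop("p_low values must lie in [0, 1]")
    n0 <- sum(group == 0); n1 <- sum(group == 1)
    if (n0 == 0L || n1 == 0L)
        stop("both groups must be non-empty")
    if (metric %in% c("pearson", "spearman")) {
        if (n0 < 2L || n1 < 2L)
            stop("correlation-based QI needs at least 2 samples per group")
        if (length(unique(pLow)) < 2L)
            stop("p_low is constant: the QI index is undefined, not 0")
    } else {
        if (length(unique(pLow)) < 2L)
            stop("all p_low identical: CTDiff denominator is 0")
    }
    invisible(c(n0 = n0, n1 = n1))
}

.qiCompute <- function(pLow, group, metric) {
    .qiCheckInput(pLow, group, metric)
    switch(metric,
        pearson = abs(cor(pLow, group)),
        spearman = abs(cor(pLow, group, method = "spearman")),
        ctdiff = {
            num <- abs(median(pLow[group == 0]) - median(pLow[group == 1]))
            diffs <- abs(outer(pLow, pLow, "-"))
            den <- mean(diffs[upper.tri(diffs)])
            num / den
        })
}

#' Quality-imbalance index of a dataset
#'
#' The QI index quantifies how confounded sample quality is with the
#' case/control design.  Under the default `"pearson"` metric it is the
#' absolute Pearson correlation between the per-sample low-quality
#' probability `p_low` and the numeric group code (0 = control, 1 = disease)
#' — a point-biserial correlation, 0 when quality is independent of the
#' groups and 1 when it separates them perfectly.  `"spearman"` replaces the
#' correlation by its rank version; `"ctdiff"` is the central tendency
#' difference: the absolute difference of the two group medians of `p_low`
#' divided by the mean absolute difference over all unordered sample pairs in
#' the pooled dataset (non-negative, no upper bound).
#'
#' All three metrics are invariant to swapping which group is coded 1.
#' Degenerate inputs (constant `p_low`, or fewer than 2 samples per group for
#' the correlation metrics) raise an error rather than silently returning 0:
#' a broken dataset must not be reported as balanced.
#'
#' @param x A [QualityExperiment-class] or a sample-table `data.frame` with
#'   columns `group` and `p_low` (see [readSampleTable()]).
#' @param metric `"pearson"` (default), `"spearman"` or `"ctdiff"`.
#' @param cutoffs Class boundaries passed to [classifyQI()].
#' @return A [QIResult-class].
#' @examples
#' tab <- data.frame(sample_id = paste0("S", 1:4),
#'                   group = c("control", "control", "disease", "disease"),
#'                   p_low = c(0.1, 0.1, 0.9, 0.9))
#' qiValue(qiIndex(tab))  # 1: quality fully confounded with the groups
#' @export
setGeneric("qiIndex", function(x, metric = c("pearson", "spearman", "ctdiff"),
                               cutoffs = NULL) standardGeneric("qiIndex"))

.qiResult <- function(pLow, group, metric, cutoffs) {
    if (is.null(cutoffs)) cutoffs <- qiCutoffs(metric)
    value <- .qiCompute(pLow, group, metric)
    new("QIResult", metric = metric, value = value,
        qiClass = classifyQI(value, metric, cutoffs),
        nSamples = length(pLow))
}

.groupCode <- function(group) {
    if (is.numeric(group)) as.integer(group != 0)
    else as.integer(as.character(group) == "disease")
}

#' @rdname qiIndex
#' @export
setMethod("qiIndex", "data.frame", function(x, metric, cutoffs = NULL) {
    metric <- match.arg(metric, c("pearson", "spearman", "ctdiff"))
    stopifnot(all(c("group", "p_low") %in% colnames(x)))
    .qiResult(x$p_low, .groupCode(x$group), metric, cutoffs)
})

#' @rdname qiIndex
#' @export
setMethod("qiIndex", "QualityExperiment", function(x, metric, cutoffs = NULL) {
    metric <- match.arg(metric, c("pearson", "spearman", "ctdiff"))
    .qiResult(pLow(x), .groupCode(sampleGroup(x)), metric, cutoffs)
})

#' Detect quality-outlier samples by the 1.5 IQR rule
#'
#' Flags samples whose `p_low` lies beyond 1.5 times the interquartile range
#' above the third quartile or below the first quartile, quartiles computed
#' on the pooled dataset (both groups together) with linear-interpolation
#' quantiles (`type = 7`, the convention of the boxplot-style outlier
#' helpers).  Removing these samples is one of the two quality-imbalance
#' mitigation strategies (see [evaluateMitigation()]).
#'
#' @param x A [QualityExperiment-class], sample-table `data.frame`, or bare
#'   numeric vector of `p_low` values (named, or names default to position).
#' @param k IQR multiplier (default 1.5).
#' @param type Quantile type passed to [stats::quantile()] (default 7,
#'   linear interpolation).
#' @return Character vector of outlying sample ids (possibly empty).
#' @export
detectQualityOutliers <- function(x, k = 1.5, type = 7) {
    if (is(x, "QualityExperiment")) {
        p <- pLow(x); ids <- colnames(x)
    } else if (is.data.frame(x)) {
        p <- x$p_low; ids <- x$sample_id
    } else {
        p <- as.numeric(x)
        ids <- if (!is.null(names(x))) names(x) else as.character(seq_along(x))
    }
    if (length(p) < 4L)
        stop("outlier detection needs at least 4 samples")
    q <- quantile(p, c(0.25, 0.75), type = type, names = FALSE)
    iqr <- q[2] - q[1]
    ids[p > q[2] + k * iqr | p < q[1] - k * iqr]
}
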