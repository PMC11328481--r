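#' QualityExperiment: counts plus group labels and low-quality probabilities
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' gene-by-sample count matrix (assay `"counts"`) together with the two
#' per-sample variables every quality-imbalance computation consumes: the
#' binary `group` label (`"control"`/`"disease"`) and `p_low`, the probability
#' that the sample is of low quality as returned by an external quality
#' classifier.  An optional `pair_id` column links one control to one disease
#' sample in paired designs.  Simulated objects additionally carry the ground
#' truth (per-gene roles and effect sizes in `rowData`, the latent quality in
#' `colData$quality`, and the realized QI index in `metadata`).
#'
#' @seealso [QualityExperiment()] (constructor), [qiIndex()],
#'   [simulateQualityDataset()]
#' @export
setClass("QualityExperiment", contains = "SummarizedExperiment")

.validQualityExperiment <- function(object) {
    msg <- character()
    cd <- colData(object)
    if (!all(c("group", "p_low") %in% colnames(cd)))
        return("colData must contain 'group' and 'p_low'")
    grp <- cd$group
    if (!is.factor(grp) || !identical(levels(grp), c("control", "disease")))
        msg <- c(msg, "'group' must be a factor with levels control, disease")
    else if (any(table(grp) == 0L))
        msg <- c(msg, "both groups must be non-empty")
    pl <- cd$p_low
    if (!is.numeric(pl) || anyNA(pl) || any(pl < 0) || any(pl > 1))
        msg <- c(msg, "'p_low' must be numeric in [0, 1]")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be unique")
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- assay(object, "counts")
        if (any(k < 0) || any(k != floor(k)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if ("pair_id" %in% colnames(cd) && !all(is.na(cd$pair_id))) {
        ok <- .checkPairing(as.character(cd$pair_id), grp)
        if (!isTRUE(ok)) msg <- c(msg, ok)
    }
    if (length(msg)) msg else TRUE
}
setValidity("QualityExperiment", .validQualityExperiment)

# pair_id must be a bijection between the two groups
.checkPairing <- function(pair, grp) {
    if (anyNA(pair))
        return("pair_id must be set for all samples or none")
    tab <- table(pair, grp)
    if (any(tab != 1L) || ncol(tab) != 2L)
        return("pair_id must link exactly one control to one disease sample")
    TRUE
}

#' Construct a QualityExperiment
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns.  Column names are sample ids.
#' @param group Group label per sample: a factor/character with values
#'   `"control"`/`"disease"`, or a 0/1 vector (0 = control, 1 = disease).
#' @param pLow Numeric vector in `[0, 1]`, one low-quality probability per
#'   sample.
#' @param pairId Optional character vector of pair identifiers forming a
#'   bijection between control and disease samples.
#' @param rowData,metadata Passed to the underlying
#'   `SummarizedExperiment`.
#' @return A [QualityExperiment-class] object.
#' @examples
#' k <- matrix(rpois(40, 10), nrow = 10,
#'             dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
#' qe <- QualityExperiment(k, group = c(0, 0, 1, 1),
#'                         pLow = c(.1, .2, .7, .8))
#' qiIndex(qe)
#' @export
QualityExperiment <- function(counts, group, pLow, pairId = NULL,
                              rowData = NULL, metadata = list()) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("S", seq_len(ncol(counts)))
    if (is.numeric(group))
        group <- ifelse(group == 1, "disease", "control")
    group <- factor(as.character(group), levels = c("control", "disease"))
    cd <- DataFrame(group = group, p_low = as.numeric(pLow),
                    row.names = colnames(counts))
    if (!is.null(pairId)) cd$pair_id <- as.character(pairId)
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = cd, metadata = metadata)
    if (!is.null(rowData)) rowData(se) <- rowData
    new("QualityExperiment", se)
}

#' @describeIn QualityExperiment Per-sample low-quality probabilities.
#' @param x A `QualityExperiment`.
#' @export
pLow <- function(x) colData(x)$p_low

#' @describeIn QualityExperiment Group factor (`control`/`disease`).
#' @export
sampleGroup <- function(x) colData(x)$group

#' @describeIn QualityExperiment Pair ids, or `NULL` for unpaired designs.
#' @export
pairId <- function(x) {
    cd <- colData(x)
    if ("pair_id" %in% colnames(cd)) as.character(cd$pair_id) else NULL
}

#' @describeIn QualityExperiment Count matrix (assay `"counts"`); method for
#'   the `BiocGenerics::counts` generic.
#' @param object A `QualityExperiment` (for `counts`).
#' @param ... Ignored.
#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "QualityExperiment",
          function(object, ...) assay(object, "counts"))

#' @describeIn QualityExperiment Realized QI index recorded at simulation
#'   time, or `NA` for objects without ground truth.
#' @export
realizedQI <- function(x) {
    v <- metadata(x)$realized_qi
    if (is.null(v)) NA_real_ else v
}

#' @describeIn QualityExperiment Sample metadata as a plain data.frame with
#'   columns `sample_id`, `group`, `p_low` and (if present) `pair_id`.
#' @export
sampleTable <- function(x) {
    cd <- colData(x)
    df <- data.frame(sample_id = rownames(cd),
                     group = as.character(cd$group),
                     p_low = cd$p_low,
                     stringsAsFactors = FALSE)
    if ("pair_id" %in% colnames(cd)) df$pair_id <- as.character(cd$pair_id)
    rownames(df) <- NULL
    df
}

setMethod("show", "QualityExperiment", function(object) {
    callNextMethod()
    grp <- sampleGroup(object)
    cat(sprintf("groups: %d control, %d disease; p_low range [%.3f, %.3f]\n",
                sum(grp == "control"), sum(grp == "disease"),
                min(pLow(object)), max(pLow(object))))
    rq <- realizedQI(object)
    if (!is.na(rq)) cat(sprintf("realized QI index: %.3f\n", rq))
})
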