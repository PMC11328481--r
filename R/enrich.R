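#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then one gene per
#' field.  Duplicate genes within a set are counted once; a line with fewer
#' than 3 fields is a parse error reporting the line number.
#'
#' @param path Path to a GMT file.
#' @return Named list of unique gene-id character vectors.
#' @export
readGMT <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- vector("list", length(lines))
    nms <- character(length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
        nms[i] <- f[1]
        sets[[i]] <- unique(f[-(1:2)])
    }
    if (anyDuplicated(nms)) stop("duplicate set names in GMT")
    names(sets) <- nms
    sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = "na") {
    stopifnot(length(sets) > 0, !is.null(names(sets)))
    description <- rep_len(description, length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' One-sided hypergeometric (Fisher) test per gene set: the probability,
#' under random sampling of `|query|` genes from the universe, of an
#' overlap at least as large as observed.  Sets are intersected with the
#' universe first and only sets whose intersected size lies within
#' `[minSize, maxSize]` are tested.  Adjustment is Bonferroni by default
#' (`padj = min(1, m p)` with `m` the number of tested sets), matching the
#' convention of the marker-regulator tables; Benjamini-Hochberg is
#' available.
#'
#' @param query Character vector of genes of interest; genes outside the
#'   universe are dropped (with a warning).
#' @param geneSets Named list of gene-id vectors (e.g. from [readGMT()] or
#'   [simulateGeneSets()]).
#' @param universe Character vector of background genes (e.g. all tested
#'   genes of the originating analysis).
#' @param minSize,maxSize Set-size bounds after universe intersection
#'   (defaults 15 and 500).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return `data.frame`, one row per tested set, ordered by `p`: `set`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p`, `padj`.
#' @examples
#' uni <- paste0("G", 1:20)
#' sets <- list(S1 = paste0("G", 1:5))
#' ora(paste0("G", 1:5), sets, uni, minSize = 1)$p  # 1 / choose(20, 5)
#' @export
ora <- function(query, geneSets, universe, minSize = 15, maxSize = 500,
                adjust = c("bonferroni", "BH")) {
    adjust <- match.arg(adjust)
    universe <- unique(as.character(universe))
    if (length(universe) == 0) stop("empty universe")
    query <- unique(as.character(query))
    if (length(query) == 0) stop("empty query")
    if (!all(query %in% universe)) {
        warning("dropping query genes outside the universe")
        query <- intersect(query, universe)
        if (length(query) == 0) stop("no query genes in the universe")
    }
    N <- length(universe); n <- length(query)
    rows <- lapply(names(geneSets), function(nm) {
        s <- intersect(unique(geneSets[[nm]]), universe)
        K <- length(s)
        if (K < minSize || K > maxSize) return(NULL)
        ov <- length(intersect(s, query))
        p <- phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm, overlap = ov, set_size = K,
                   query_size = n, universe_size = N, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(set = character(), overlap = integer(),
                          set_size = integer(), query_size = integer(),
                          universe_size = integer(), p = numeric(),
                          padj = numeric()))
    out$padj <- if (adjust == "bonferroni") pmin(1, nrow(out) * out$p)
                else p.adjust(out$p, method = "BH")
    out[order(out$p, out$set), , drop = FALSE]
}

#' Pathways enriched in low-quality marker genes
#'
#' Convenience wrapper deriving the "low-quality pathway" set used by
#' mitigation evaluation: over-representation of the low-quality markers of
#' a catalog in a gene-set collection, keeping sets significant at
#' `alpha` after adjustment.
#'
#' @param catalog A [MarkerCatalog-class] (gene-level), or a character
#'   vector of low-quality marker gene ids.
#' @param geneSets,universe,minSize,maxSize,adjust As in [ora()].
#' @param alpha Adjusted-p cutoff for calling a pathway low-quality.
#' @return Character vector of significant set names.
#' @export
lowQualityPathways <- function(catalog, geneSets, universe, alpha = 0.05,
                               minSize = 15, maxSize = 500,
                               adjust = c("bonferroni", "BH")) {
    adjust <- match.arg(adjust)
    markers <- if (is(catalog, "MarkerCatalog"))
        markerFeatures(catalog, "low") else as.character(catalog)
    if (length(markers) == 0) return(character())
    res <- ora(markers, geneSets, universe, minSize = minSize,
               maxSize = maxSize, adjust = adjust)
    res$set[res$padj < alpha]
}
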