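suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
})

# minimal sample table for metric tests
makeSampleTab <- function(pLow, group) {
    data.frame(sample_id = sprintf("S%02d", seq_along(pLow)),
               group = group, p_low = pLow, stringsAsFactors = FALSE)
}

# random QI instance: n in [8, 96], balanced-ish groups, non-constant p_low
randomQIInstance <- function() {
    n <- sample(8:96, 1)
    n0 <- sample(2:(n - 2), 1)
    repeat {
        p <- round(runif(n), 4)
        if (length(unique(p)) >= 2) break
    }
    makeSampleTab(p, rep(c("control", "disease"), c(n0, n - n0)))
}

# independent Pearson oracle written from the definition
bruteForcePearson <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# point-biserial closed form: (M1 - M0) / sd_n * sqrt(n1 n0 / n^2)
pointBiserial <- function(p, g) {
    n <- length(p)
    m1 <- mean(p[g == 1]); m0 <- mean(p[g == 0])
    sdn <- sqrt(sum((p - mean(p))^2) / n)
    (m1 - m0) / sdn * sqrt(sum(g == 1) * sum(g == 0) / n^2)
}

# all-pairs CTDiff oracle by explicit enumeration
ctdiffOracle <- function(p, g) {
    num <- abs(median(p[g == 0]) - median(p[g == 1]))
    pairs <- combn(length(p), 2)
    num / mean(abs(p[pairs[1, ]] - p[pairs[2, ]]))
}

# textbook BH step-up oracle
bhStepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(1, adj)
    out
}

# exact hypergeometric upper-tail by enumerating overlap outcomes
hyperTailOracle <- function(overlap, setSize, universeSize, querySize) {
    ks <- max(0, querySize + setSize - universeSize):min(setSize, querySize)
    probs <- choose(setSize, ks) * choose(universeSize - setSize,
                                          querySize - ks) /
        choose(universeSize, querySize)
    sum(probs[ks >= overlap])
}
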