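#' Expected (population) QI index for a given quality separation
#'
#' Under the generator model the latent quality of each sample is Beta
#' distributed with common concentration `kappa` and group means
#' `center - delta/2` (control) and `center + delta/2` (disease).  The
#' population point-biserial correlation between quality and the group code
#' is `delta * sqrt(p0 p1) / sd_total`, where `p0, p1` are the group
#' proportions and `sd_total` the standard deviation of the two-component
#' Beta mixture.  This closed form is the calibration target of
#' [calibrateQualitySeparation()].
#'
#' @param delta Difference between the group mean qualities (in `[0, 1)`).
#' @param nControl,nDisease Group sizes.
#' @param center Midpoint of the two group means.
#' @param concentration Beta concentration `kappa` (`alpha + beta`); larger
#'   values give a tighter within-group quality spread,
#'   `var = mu (1 - mu) / (kappa + 1)`.
#' @return Expected QI index in `[0, 1)`.
#' @export
expectedQI <- function(delta, nControl, nDisease, center = 0.5,
                       concentration = 8) {
    mu0 <- center - delta / 2
    mu1 <- center + delta / 2
    p0 <- nControl / (nControl + nDisease)
    p1 <- 1 - p0
    w0 <- mu0 * (1 - mu0) / (concentration + 1)
    w1 <- mu1 * (1 - mu1) / (concentration + 1)
    vtot <- p0 * w0 + p1 * w1 + p0 * p1 * delta^2
    delta * sqrt(p0 * p1) / sqrt(vtot)
}

#' Calibrate the group quality separation for a target QI index
#'
#' Finds, by bisection, the difference `delta` between the group mean
#' qualities whose population QI index ([expectedQI()]) equals `qiTarget`.
#' The expected index is strictly increasing in `delta`, so bisection
#' converges; the search stops when the expected index is within `tol` of
#' the target.  If the target exceeds the maximum achievable index (group
#' means clipped to `[0.02, 0.98]`), an error reports the achievable bound.
#'
#' @inheritParams expectedQI
#' @param qiTarget Desired QI index in `[0, 1]`.
#' @param tol Calibration tolerance on the expected QI (default 0.02).
#' @return `delta`, the calibrated group mean difference.
#' @export
calibrateQualitySeparation <- function(qiTarget, nControl, nDisease,
                                       center = 0.5, concentration = 8,
                                       tol = 0.02) {
    stopifnot(qiTarget >= 0, qiTarget <= 1)
    if (qiTarget == 0) return(0)
    deltaMax <- 2 * min(center - 0.02, 1 - center - 0.02)
    if (deltaMax <= 0)
        stop("quality center too extreme to separate the groups")
    qiMax <- expectedQI(deltaMax, nControl, nDisease, center, concentration)
    if (qiTarget > qiMax + tol)
        stop(sprintf(paste0("qi_target %.3f unreachable for these group ",
                            "sizes; maximum achievable expected QI is %.3f"),
                     qiTarget, qiMax))
    lo <- 0; hi <- deltaMax
    for (i in 1:200) {
        mid <- (lo + hi) / 2
        f <- expectedQI(mid, nControl, nDisease, center, concentration)
        if (abs(f - qiTarget) <= tol) return(mid)
        if (f < qiTarget) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

.rbetaMean <- function(n, mu, kappa) rbeta(n, mu * kappa, (1 - mu) * kappa)

#' Simulate a case-control RNA-seq dataset with planted quality effects
#'
#' Generates a negative-binomial count matrix for two patient groups with a
#' latent per-sample quality `q` that doubles as the reported low-quality
#' probability (`p_low = q`: the classifier output is treated as the quality
#' measurement itself).  Counts for gene `j` in sample `i` have mean
#' `s_i * b_j * 2^(beta_dis_j g_i + beta_q_j q_i)` with per-gene dispersion:
#' log-normal baselines `b_j`, log-normal size factors `s_i` (geometric mean
#' 1), group code `g_i`, and log2-scale effects.  Planted low-quality marker
#' genes get `beta_q = +qualityEffect`, high-quality markers
#' `-qualityEffect`, disease genes `beta_dis = +-diseaseEffect` (random
#' sign); all other genes are null.
#'
#' The quality of each group is Beta distributed around
#' `center -/+ delta/2`, with `delta` calibrated by
#' [calibrateQualitySeparation()] so the population QI index matches
#' `qiTarget`.  At `qiTarget = 0` quality is independent of the groups; the
#' realized absolute sample correlation then sits at the null floor for the
#' sample size (about 0.19 at n = 20), not at exactly 0.
#'
#' For mitigation experiments, `nQualityOutliers` samples of `outlierGroup`
#' can be forced to an extreme quality `outlierPLow` (the last samples of
#' that group by index are replaced, so the outliers are arbitrary group
#' members rather than relabeled order statistics of the quality draw).
#'
#' @param nControl,nDisease Group sizes (each at least 2).
#' @param nGenes Total number of genes.
#' @param nLowMarkers,nHighMarkers,nDiseaseGenes Numbers of planted
#'   low-quality-marker, high-quality-marker and disease genes
#'   (their sum must not exceed `nGenes`).
#' @param qualityEffect Log2 effect magnitude of quality on marker genes
#'   (per unit of `q`).
#' @param diseaseEffect Log2 effect magnitude of disease on disease genes.
#' @param qiTarget Target QI index in `[0, 1]`.
#' @param qualityCenter,qualityConcentration Location and concentration of
#'   the Beta quality distribution (see [expectedQI()]).
#' @param dispersionShape `c(meanlog, sdlog)` of the log-normal per-gene
#'   dispersion distribution.
#' @param baselineShape `c(meanlog, sdlog)` of the log-normal per-gene
#'   baseline means.
#' @param libsizeSd Log-scale spread of the size factors.
#' @param paired If `TRUE`, requires equal group sizes, links sample `i` of
#'   each group into pair `P<i>` and adds a shared log-normal pair effect of
#'   spread `pairEffectSd` to both members.
#' @param pairEffectSd Log2-scale spread of the per-pair baseline effect.
#' @param nQualityOutliers,outlierPLow,outlierGroup Planted extreme-quality
#'   samples (see Details).
#' @param markerGenes Optional character vector of gene ids to use as
#'   markers (first the low, then the high markers); defaults to the first
#'   `nLowMarkers + nHighMarkers` gene ids, so collections built with
#'   [simulateQualityCollection()] share marker identities.
#' @param diseaseGenes Optional character vector of gene ids to plant as
#'   disease genes (must be disjoint from the markers); defaults to a
#'   seeded random draw from the remaining genes.
#' @param seed Integer RNG seed; identical configurations give identical
#'   datasets.
#' @return A [QualityExperiment-class] whose `rowData` records the ground
#'   truth (`role`, `beta_quality`, `beta_disease`), whose `colData` records
#'   the latent `quality` and `size_factor`, and whose `metadata` records
#'   `realized_qi`, the calibrated `delta` and the full configuration.
#' @examples
#' qe <- simulateQualityDataset(nGenes = 200, nLowMarkers = 20,
#'                              nHighMarkers = 20, nDiseaseGenes = 10,
#'                              qiTarget = 0.8, seed = 1)
#' realizedQI(qe)
#' @export
simulateQualityDataset <- function(nControl = 10, nDisease = 10,
                                   nGenes = 2000,
                                   nLowMarkers = 150, nHighMarkers = 150,
                                   nDiseaseGenes = 100,
                                   qualityEffect = 2, diseaseEffect = 2,
                                   qiTarget = 0.2,
                                   qualityCenter = 0.5,
                                   qualityConcentration = 8,
                                   dispersionShape = c(meanlog = log(0.05),
                                                       sdlog = 0.5),
                                   baselineShape = c(meanlog = log(150),
                                                     sdlog = 1.2),
                                   libsizeSd = 0.2,
                                   paired = FALSE, pairEffectSd = 0.5,
                                   nQualityOutliers = 0, outlierPLow = 0.95,
                                   outlierGroup = "disease",
                                   markerGenes = NULL, diseaseGenes = NULL,
                                   seed = 1) {
    stopifnot(nControl >= 2, nDisease >= 2, nGenes >= 1,
              nLowMarkers + nHighMarkers + nDiseaseGenes <= nGenes,
              qiTarget >= 0, qiTarget <= 1,
              qualityEffect >= 0, diseaseEffect >= 0,
              all(is.finite(c(dispersionShape, baselineShape, libsizeSd))))
    if (paired && nControl != nDisease)
        stop("paired designs need equal group sizes")
    nTot <- nControl + nDisease
    delta <- calibrateQualitySeparation(qiTarget, nControl, nDisease,
                                        qualityCenter, qualityConcentration)

    set.seed(seed)
    geneIds <- sprintf("G%05d", seq_len(nGenes))
    if (is.null(markerGenes)) {
        markerGenes <- geneIds[seq_len(nLowMarkers + nHighMarkers)]
    } else {
        stopifnot(length(markerGenes) == nLowMarkers + nHighMarkers,
                  all(markerGenes %in% geneIds))
    }
    lowIds <- head(markerGenes, nLowMarkers)
    highIds <- if (nHighMarkers > 0)
        markerGenes[(nLowMarkers + 1):(nLowMarkers + nHighMarkers)]
    else character()
    if (is.null(diseaseGenes)) {
        free <- setdiff(geneIds, markerGenes)
        diseaseGenes <- sort(sample(free, nDiseaseGenes))
    } else {
        stopifnot(length(diseaseGenes) == nDiseaseGenes,
                  !any(diseaseGenes %in% markerGenes))
    }

    role <- rep("null", nGenes); names(role) <- geneIds
    role[lowIds] <- "low_marker"
    role[highIds] <- "high_marker"
    role[diseaseGenes] <- "disease"
    betaQ <- numeric(nGenes); names(betaQ) <- geneIds
    betaQ[lowIds] <- qualityEffect
    betaQ[highIds] <- -qualityEffect
    betaD <- numeric(nGenes); names(betaD) <- geneIds
    betaD[diseaseGenes] <- diseaseEffect *
        sample(c(-1, 1), nDiseaseGenes, replace = TRUE)

    grp <- c(rep(0L, nControl), rep(1L, nDisease))
    q <- c(.rbetaMean(nControl, qualityCenter - delta / 2,
                      qualityConcentration),
           .rbetaMean(nDisease, qualityCenter + delta / 2,
                      qualityConcentration))
    if (nQualityOutliers > 0) {
        gsel <- which(grp == (if (outlierGroup == "disease") 1L else 0L))
        if (nQualityOutliers > length(gsel))
            stop("more planted outliers than samples in the target group")
        pick <- gsel[seq(length(gsel) - nQualityOutliers + 1,
                         length(gsel))]
        q[pick] <- outlierPLow
    }

    s <- exp(rnorm(nTot, 0, libsizeSd))
    s <- s / exp(mean(log(s)))
    b <- rlnorm(nGenes, baselineShape[1], baselineShape[2])
    alpha <- rlnorm(nGenes, dispersionShape[1], dispersionShape[2])

    logmu <- outer(betaD, grp) + outer(betaQ, q)   # log2 scale
    if (paired) {
        pairEff <- rnorm(nControl, 0, pairEffectSd)
        logmu <- logmu + matrix(rep(pairEff, 2), nrow = nGenes,
                                ncol = nTot, byrow = TRUE)
    }
    mu <- b * 2^logmu
    mu <- sweep(mu, 2, s, "*")
    k <- matrix(rnbinom(nGenes * nTot, mu = mu,
                        size = rep(1 / alpha, nTot)),
                nrow = nGenes,
                dimnames = list(geneIds,
                                sprintf("S%03d", seq_len(nTot))))

    pair <- if (paired) rep(sprintf("P%03d", seq_len(nControl)), 2) else NULL
    qe <- QualityExperiment(
        k, group = grp, pLow = q, pairId = pair,
        rowData = DataFrame(role = unname(role),
                            beta_quality = unname(betaQ),
                            beta_disease = unname(betaD),
                            baseline = b, dispersion = alpha,
                            row.names = geneIds),
        metadata = list(
            realized_qi = abs(cor(q, grp)),
            qi_target = qiTarget, delta = delta, seed = seed,
            config = list(nControl = nControl, nDisease = nDisease,
                          nGenes = nGenes, nLowMarkers = nLowMarkers,
                          nHighMarkers = nHighMarkers,
                          nDiseaseGenes = nDiseaseGenes,
                          qualityEffect = qualityEffect,
                          diseaseEffect = diseaseEffect,
                          qiTarget = qiTarget,
                          qualityCenter = qualityCenter,
                          qualityConcentration = qualityConcentration,
                          libsizeSd = libsizeSd, paired = paired,
                          nQualityOutliers = nQualityOutliers)))
    colData(qe)$quality <- q
    colData(qe)$size_factor <- s
    qe
}

#' Simulate a collection of datasets sharing quality-marker identities
#'
#' Emulates the marker-derivation setting: several independent low-imbalance
#' datasets in which the same genes respond to sample quality (the
#' biological quality response is shared across studies) while disease genes
#' differ from dataset to dataset.  Dataset `i` uses seed `seed + i`, so the
#' collection is reproducible without seed collisions.
#'
#' @param nDatasets Number of datasets (at least 2).
#' @param nLowMarkers,nHighMarkers Planted shared marker counts per
#'   dataset.
#' @param sharedMarkerGenes Gene ids planted as markers in every dataset
#'   (first the low, then the high markers); defaults to the first
#'   `nLowMarkers + nHighMarkers` gene ids.
#' @param seed Base seed.
#' @param ... Further arguments to [simulateQualityDataset()].
#' @inheritParams simulateQualityDataset
#' @return List of [QualityExperiment-class] objects.
#' @export
simulateQualityCollection <- function(nDatasets = 13,
                                      nLowMarkers = 200, nHighMarkers = 200,
                                      sharedMarkerGenes = NULL,
                                      qiTarget = 0.1, seed = 1, ...) {
    stopifnot(nDatasets >= 2)
    if (!is.null(sharedMarkerGenes) && length(sharedMarkerGenes) == 0 &&
        nLowMarkers > 0)
        stop("empty sharedMarkerGenes with nLowMarkers > 0")
    lapply(seq_len(nDatasets), function(i) {
        simulateQualityDataset(nLowMarkers = nLowMarkers,
                               nHighMarkers = nHighMarkers,
                               markerGenes = sharedMarkerGenes,
                               qiTarget = qiTarget,
                               seed = seed + i, ...)
    })
}

#' Simulate ChIP-seq-like peak sets with planted quality-marker bins
#'
#' Builds, for each sample, a set of peak intervals on a toy chromosome
#' (`chrS`, tiled by `nBins` bins of `binWidth` bp) with one potential peak
#' per bin.  A peak is present in a sample with probability `presenceProb`
#' (`markerPresenceProb` for marker bins, so markers are observed in enough
#' samples to be testable); its enrichment is log-normal around
#' `baseEnrichment` with a log2-linear quality effect in marker bins:
#' positive in low-quality-marker bins, negative in high-quality-marker
#' bins, centered on `qualityCenter` so marker enrichment is
#' quality-correlated but not globally shifted.  Peak intervals jitter
#' around their bin and may span bin boundaries.
#'
#' @param nControl,nDisease Group sizes.
#' @param nBins Number of 1-based bins tiling the toy chromosome.
#' @param binWidth Bin width in bp (default 500).
#' @param nLowMarkerBins,nHighMarkerBins Planted marker bins (first bins of
#'   the chromosome, low then high).
#' @param enrichmentEffect Log2 enrichment effect per unit of quality in
#'   marker bins.
#' @param baseEnrichment Median peak enrichment in unaffected bins.
#' @param enrichmentNoiseSd Log-scale enrichment noise.
#' @param presenceProb,markerPresenceProb Probability that a bin carries a
#'   peak in a given sample.
#' @param qiTarget,qualityCenter,qualityConcentration As in
#'   [simulateQualityDataset()].
#' @param seed RNG seed.
#' @return List with `peaks` (named [GenomicRanges::GRangesList], one
#'   element per sample, each with an `enrichment` metadata column),
#'   `samples` (sample-table `data.frame`), `truth` (per-bin role and
#'   effect, per-sample quality, realized QI) and `seqlengths` (toy genome).
#' @export
simulatePeakDataset <- function(nControl = 8, nDisease = 8,
                                nBins = 400, binWidth = 500,
                                nLowMarkerBins = 40, nHighMarkerBins = 40,
                                enrichmentEffect = 2, baseEnrichment = 5,
                                enrichmentNoiseSd = 0.25,
                                presenceProb = 0.6,
                                markerPresenceProb = 0.95,
                                qiTarget = 0.2, qualityCenter = 0.5,
                                qualityConcentration = 8, seed = 1) {
    stopifnot(nBins >= nLowMarkerBins + nHighMarkerBins, binWidth >= 50)
    delta <- calibrateQualitySeparation(qiTarget, nControl, nDisease,
                                        qualityCenter, qualityConcentration)
    set.seed(seed)
    nTot <- nControl + nDisease
    grp <- c(rep(0L, nControl), rep(1L, nDisease))
    q <- c(.rbetaMean(nControl, qualityCenter - delta / 2,
                      qualityConcentration),
           .rbetaMean(nDisease, qualityCenter + delta / 2,
                      qualityConcentration))
    sampleIds <- sprintf("S%03d", seq_len(nTot))
    chromLen <- nBins * binWidth

    role <- rep("null", nBins)
    if (nLowMarkerBins > 0) role[seq_len(nLowMarkerBins)] <- "low_marker"
    if (nHighMarkerBins > 0)
        role[nLowMarkerBins + seq_len(nHighMarkerBins)] <- "high_marker"
    betaBin <- ifelse(role == "low_marker", enrichmentEffect,
                      ifelse(role == "high_marker", -enrichmentEffect, 0))
    binStart0 <- (seq_len(nBins) - 1L) * binWidth   # 0-based

    peaks <- lapply(seq_len(nTot), function(i) {
        pPresent <- ifelse(role == "null", presenceProb, markerPresenceProb)
        present <- which(runif(nBins) < pPresent)
        wid <- round(runif(length(present), 200, 600))
        jit <- round(runif(length(present), -150, 150))
        st0 <- pmax(0L, pmin(chromLen - wid,
                             binStart0[present] + jit))
        enr <- baseEnrichment *
            2^(betaBin[present] * (q[i] - qualityCenter)) *
            exp(rnorm(length(present), 0, enrichmentNoiseSd))
        gr <- GRanges("chrS", IRanges(start = st0 + 1L, width = wid),
                      strand = "*",
                      seqinfo = Seqinfo("chrS", chromLen))
        gr$enrichment <- enr
        gr$name <- sprintf("%s_peak%04d", sampleIds[i], seq_along(gr))
        gr
    })
    names(peaks) <- sampleIds
    samples <- data.frame(sample_id = sampleIds,
                          group = ifelse(grp == 1, "disease", "control"),
                          p_low = q, stringsAsFactors = FALSE)
    list(peaks = GRangesList(peaks), samples = samples,
         truth = list(bin_role = role, beta_bin = betaBin, quality = q,
                      realized_qi = abs(cor(q, grp))),
         seqlengths = c(chrS = chromLen))
}

#' Simulate a gene-set collection aligned with planted gene roles
#'
#' Builds a synthetic GMT-style collection in which some sets are enriched
#' in the planted low-quality markers ("low-quality pathways"), some in the
#' planted disease genes, and the rest are random draws from all genes.
#' Used to exercise over-representation analysis and mitigation evaluation
#' against known ground truth.
#'
#' @param x A simulated [QualityExperiment-class] (its `rowData$role` drives
#'   the set composition).
#' @param nLowSets,nDiseaseSets,nNullSets Numbers of sets of each flavour.
#' @param setSize Genes per set.
#' @param signalFraction Fraction of each signal set drawn from its role
#'   genes (the rest are random background).
#' @param seed RNG seed.
#' @return Named list of gene-id character vectors with a `category`
#'   attribute (`"low_quality"`, `"disease"`, `"null"` per set).
#' @export
simulateGeneSets <- function(x, nLowSets = 5, nDiseaseSets = 5,
                             nNullSets = 10, setSize = 40,
                             signalFraction = 0.75, seed = 1) {
    stopifnot(is(x, "QualityExperiment"),
              "role" %in% colnames(rowData(x)))
    set.seed(seed)
    role <- rowData(x)$role
    genes <- rownames(x)
    lowGenes <- genes[role == "low_marker"]
    disGenes <- genes[role == "disease"]
    nSig <- round(setSize * signalFraction)
    mkSet <- function(pool) {
        sig <- sample(pool, min(nSig, length(pool)))
        bg <- sample(setdiff(genes, sig), setSize - length(sig))
        sort(unique(c(sig, bg)))
    }
    sets <- c(
        lapply(seq_len(nLowSets), function(i) mkSet(lowGenes)),
        lapply(seq_len(nDiseaseSets), function(i) mkSet(disGenes)),
        lapply(seq_len(nNullSets), function(i)
            sort(sample(genes, setSize))))
    names(sets) <- c(sprintf("LOWQ_SET_%02d", seq_len(nLowSets)),
                     sprintf("DISEASE_SET_%02d", seq_len(nDiseaseSets)),
                     sprintf("RANDOM_SET_%02d", seq_len(nNullSets)))
    attr(sets, "category") <- c(rep("low_quality", nLowSets),
                                rep("disease", nDiseaseSets),
                                rep("null", nNullSets))
    sets
}
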