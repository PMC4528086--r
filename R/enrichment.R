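## Feature-overlap statistics: % length overlap, fold changes vs the
## common peak set and vs the genome average, the Monte Carlo empirical
## p-value with length-matched shuffles drawn from the common peak set,
## domain occupancy, and peak-set methylation comparisons.

#' Percent length overlap of a query interval set with a feature set
#'
#' `100 * bp(query intersect feature) / bp(query)` after merging each
#' set.
#'
#' @param query,features `GRanges`.
#' @return Percentage in `[0, 100]`.
#' @export
percentLengthOverlap <- function(query, features) {
    .assertGRanges(query, "query"); .assertGRanges(features, "features")
    query <- GenomicRanges::reduce(query, ignore.strand = TRUE)
    if (length(query) == 0L) stop("percent overlap undefined for empty query")
    features <- GenomicRanges::reduce(features, ignore.strand = TRUE)
    inter <- GenomicRanges::intersect(query, features, ignore.strand = TRUE)
    100 * sum(BiocGenerics::width(inter)) / sum(BiocGenerics::width(query))
}

#' Fold change of feature overlap relative to the common peak set
#'
#' Ratio of the % length overlap of the unique set to that of the common
#' set; values above 1 mean the unique peaks are enriched over the
#' feature relative to common peaks (plotting baseline 1.0).
#'
#' @param uniqueSet,commonSet,feature `GRanges`.
#' @return List with `fold`, `uniquePct`, `commonPct`, `direction`
#'   (`"enriched"`/`"depleted"`); `fold` is `Inf` with a warning when the
#'   common set has zero overlap.
#' @export
foldChangeVsCommon <- function(uniqueSet, commonSet, feature) {
    pu <- percentLengthOverlap(uniqueSet, feature)
    pc <- percentLengthOverlap(commonSet, feature)
    fold <- if (pc == 0) {
        warning("common peak set has zero overlap with the feature; ",
                "fold change is infinite")
        Inf
    } else pu / pc
    list(fold = fold, uniquePct = pu, commonPct = pc,
         direction = if (fold >= 1) "enriched" else "depleted")
}

#' Draw one length-matched shuffle from the common peak set
#'
#' Chooses a common peak with probability proportional to its number of
#' valid start positions (`len - lengthBp + 1`, peaks shorter than the
#' query excluded) and a start uniformly within it, so every possible
#' placement is equally likely. When no common peak is long enough the
#' longest one is returned whole (with a message).
#'
#' @param lengthBp Length of the interval to draw.
#' @param commonSet `GRanges` of common peaks.
#' @return Width-`lengthBp` `GRanges` contained in a common peak. Uses
#'   the current RNG state; wrap in your own seed handling (or use
#'   [monteCarloEnrichment()], which seeds internally).
#' @export
shuffleFromCommon <- function(lengthBp, commonSet) {
    .assertGRanges(commonSet, "commonSet")
    if (length(commonSet) == 0L) stop("empty common peak set")
    sl <- GenomeInfoDb::seqlengths(commonSet)
    if (any(is.na(sl)))
        sl <- stats::setNames(
            vapply(split(BiocGenerics::end(commonSet),
                         as.character(GenomeInfoDb::seqnames(commonSet))),
                   max, numeric(1)),
            unique(as.character(GenomeInfoDb::seqnames(commonSet))))
    off <- .chromOffsets(sl)
    lin <- .linearize(commonSet, off)
    res <- .shuffleMany(lengthBp, lin$start, lin$end)
    if (res$fallbacks > 0)
        message("no common peak of length >= ", lengthBp,
                "; returning the longest common peak whole")
    .delinearize(res$start, res$end, off, sl)
}

## shared empirical-p machinery
.empiricalP <- function(observed, nulls, alternative) {
    n <- length(nulls)
    if (alternative == "auto")
        alternative <- if (observed >= stats::median(nulls)) "enriched"
                       else "depleted"
    k <- if (alternative == "enriched") sum(nulls >= observed)
         else sum(nulls <= observed)
    list(p = (1 + k) / (1 + n), direction = alternative)
}

#' Monte Carlo feature-enrichment test against the common peak set
#'
#' The observed statistic is the aggregate % length overlap of the
#' unique peak set with the feature (pooled bp by default). Each of
#' `nShuffles` null replicates replaces every unique peak with a
#' length-matched shuffle drawn from the common peak set and records the
#' same statistic. The empirical p is `(1 + k) / (nShuffles + 1)` where
#' `k` counts replicates at least as extreme as the observed value in
#' the tested direction; with `alternative = "auto"` the direction is
#' taken from the sign of observed minus the null median. Significance
#' combines `p < alpha` with a fold change vs the common set deviating
#' more than `minFold - 1` from 1 (the `p < 0.002` and `fold > 20%`
#' convention at the 500-shuffle default, where the smallest attainable
#' p is `1/501`).
#'
#' @param uniqueSet,commonSet,feature `GRanges` (non-empty).
#' @param featureName Label for the result.
#' @param nShuffles Number of null replicates (>= 1).
#' @param seed Integer seed (bit-for-bit reproducible).
#' @param alternative `"auto"`, `"enriched"` or `"depleted"`; `"auto"`
#'   picks the observed direction, a pre-specified direction gives a
#'   calibrated one-sided test.
#' @param statistic `"pooled"` (pooled bp percentage) or `"perPeak"`
#'   (mean of per-peak percentages).
#' @param alpha,minFold Significance rule parameters.
#' @return An [EnrichmentResult-class].
#' @export
monteCarloEnrichment <- function(uniqueSet, commonSet, feature,
                                 featureName = "feature", nShuffles = 500,
                                 seed = 1L,
                                 alternative = c("auto", "enriched", "depleted"),
                                 statistic = c("pooled", "perPeak"),
                                 alpha = 0.002, minFold = 1.2) {
    alternative <- match.arg(alternative)
    statistic <- match.arg(statistic)
    if (nShuffles < 1) stop("nShuffles must be >= 1")
    .assertGRanges(uniqueSet, "uniqueSet")
    if (length(uniqueSet) == 0L || length(commonSet) == 0L ||
        length(feature) == 0L)
        stop("unique, common and feature sets must be non-empty")
    allChr <- unique(c(as.character(GenomeInfoDb::seqnames(uniqueSet)),
                       as.character(GenomeInfoDb::seqnames(commonSet)),
                       as.character(GenomeInfoDb::seqnames(feature))))
    sl <- GenomeInfoDb::seqlengths(commonSet)
    sl <- sl[!is.na(sl)]
    missing <- setdiff(allChr, names(sl))
    if (length(missing)) {
        mx <- vapply(missing, function(ch) max(
            BiocGenerics::end(uniqueSet)[as.character(GenomeInfoDb::seqnames(uniqueSet)) == ch],
            BiocGenerics::end(commonSet)[as.character(GenomeInfoDb::seqnames(commonSet)) == ch],
            BiocGenerics::end(feature)[as.character(GenomeInfoDb::seqnames(feature)) == ch],
            0), numeric(1))
        sl <- c(sl, mx)
    }
    off <- .chromOffsets(sl)
    fRed <- GenomicRanges::reduce(feature, ignore.strand = TRUE)
    fLin <- .linearize(fRed, off)
    cLin <- .linearize(GenomicRanges::reduce(commonSet, ignore.strand = TRUE), off)
    uRed <- GenomicRanges::reduce(uniqueSet, ignore.strand = TRUE)
    uLin <- .linearize(uRed, off)
    covFun <- .coverageLookup(fLin$start, fLin$end)
    pctOf <- function(s, e) {
        ovBp <- covFun(e) - covFun(s)
        if (statistic == "pooled") 100 * sum(ovBp) / sum(e - s)
        else mean(100 * ovBp / (e - s))
    }
    observed <- pctOf(uLin$start, uLin$end)
    lens <- uLin$end - uLin$start
    m <- length(lens)
    nulls <- withSeed(substreamSeed(seed, "mcshuffle"), {
        allLens <- rep(lens, nShuffles)
        sh <- .shuffleMany(allLens, cLin$start, cLin$end)
        ovBp <- covFun(sh$end) - covFun(sh$start)
        if (statistic == "pooled") {
            grp <- rep(seq_len(nShuffles), each = m)
            100 * as.numeric(rowsum(ovBp, grp)) /
                as.numeric(rowsum(sh$end - sh$start, grp))
        } else {
            grp <- rep(seq_len(nShuffles), each = m)
            as.numeric(rowsum(100 * ovBp / (sh$end - sh$start), grp)) / m
        }
    })
    ep <- .empiricalP(observed, nulls, alternative)
    fc <- foldChangeVsCommon(uRed, commonSet, fRed)
    sig <- is.finite(fc$fold) && ep$p < alpha &&
        (fc$fold > minFold || fc$fold < 1 / minFold)
    methods::new("EnrichmentResult", feature = featureName,
                 observedPct = observed, nullPcts = nulls,
                 foldChangeVsCommon = fc$fold, empiricalP = ep$p,
                 direction = ep$direction, significant = sig,
                 nShuffles = as.integer(nShuffles))
}

#' Percent of peaks overlapping GC-skew blocks, per category
#'
#' Peak-count based: `100 * #(peaks with >= 1 bp skew overlap) / #peaks`
#' for each category set.
#'
#' @param peakSets Named list of `GRanges`.
#' @param skewBlocks `GRanges` of skew blocks.
#' @return Named numeric vector of percentages (`NA` for empty
#'   categories).
#' @export
overlapWithSkew <- function(peakSets, skewBlocks) {
    vapply(peakSets, function(p) {
        if (length(p) == 0L) return(NA_real_)
        100 * mean(IRanges::overlapsAny(p, skewBlocks, ignore.strand = TRUE))
    }, numeric(1))
}

#' Domain occupancy of peak sets
#'
#' Each peak is assigned to the segmentation domain containing its
#' midpoint (a midpoint at a domain boundary belongs to the right-hand
#' domain by the half-open rule); peaks whose midpoint falls in an
#' unsegmented gap are counted as unassigned. PMD hits are further split
#' by an optional set of sample-specific ("unique") PMD intervals.
#'
#' @param peakSets Named list of `GRanges`.
#' @param segmentation A [DomainSegmentation-class].
#' @param uniquePmds Optional `GRanges` marking sample-specific PMDs.
#' @return `data.frame` per category: `pctHMD`, `pctPMD`,
#'   `pctUnassigned`, and when `uniquePmds` is given `pctPmdUnique` /
#'   `pctPmdCommon` (fractions of all peaks).
#' @export
domainOccupancy <- function(peakSets, segmentation, uniquePmds = NULL) {
    d <- domains(segmentation)
    lab <- S4Vectors::mcols(d)$label
    rows <- lapply(names(peakSets), function(nm) {
        p <- peakSets[[nm]]
        if (length(p) == 0L)
            return(data.frame(category = nm, n = 0L, pctHMD = NA_real_,
                              pctPMD = NA_real_, pctUnassigned = NA_real_))
        mid0 <- (BiocGenerics::start(p) - 1 + BiocGenerics::end(p)) %/% 2
        midGr <- GRanges(GenomeInfoDb::seqnames(p),
                         IRanges::IRanges(mid0 + 1, width = 1))
        hit <- GenomicRanges::findOverlaps(midGr, d, select = "first")
        assigned <- !is.na(hit)
        isPmd <- assigned & lab[ifelse(is.na(hit), 1L, hit)] == "PMD"
        isHmd <- assigned & !isPmd
        out <- data.frame(category = nm, n = length(p),
                          pctHMD = 100 * mean(isHmd),
                          pctPMD = 100 * mean(isPmd),
                          pctUnassigned = 100 * mean(!assigned))
        if (!is.null(uniquePmds)) {
            inU <- isPmd & IRanges::overlapsAny(midGr, uniquePmds,
                                                ignore.strand = TRUE)
            out$pctPmdUnique <- 100 * mean(inU)
            out$pctPmdCommon <- 100 * mean(isPmd & !inU)
        }
        out
    })
    do.call(rbind, rows)
}

#' Fold change of feature coverage relative to the genome average
#'
#' `(fraction of query bp overlapping the mark) / (fraction of genome bp
#' overlapping the mark)`, with a Monte Carlo empirical p from
#' length-matched placement uniformly across the genome (same
#' empirical-p machinery as [monteCarloEnrichment()]).
#'
#' @param query `GRanges` (e.g. a PMD set).
#' @param mark `GRanges` of the chromatin mark (H3K9me3, Lamin-B1, ...).
#' @param seqlengths Named chromosome lengths.
#' @param nShuffles Number of random placements.
#' @param seed Integer seed.
#' @param alternative Direction handling as in [monteCarloEnrichment()].
#' @return List with `fold`, `queryPct`, `genomePct`, `empiricalP`,
#'   `direction`, `nullFolds`.
#' @export
foldChangeVsGenome <- function(query, mark, seqlengths, nShuffles = 500,
                               seed = 1L,
                               alternative = c("auto", "enriched", "depleted")) {
    alternative <- match.arg(alternative)
    if (sum(BiocGenerics::width(GenomicRanges::reduce(mark))) == 0)
        stop("mark covers 0 bp")
    off <- .chromOffsets(seqlengths)
    mLin <- .linearize(GenomicRanges::reduce(mark, ignore.strand = TRUE), off)
    qRed <- GenomicRanges::reduce(query, ignore.strand = TRUE)
    qLin <- .linearize(qRed, off)
    covFun <- .coverageLookup(mLin$start, mLin$end)
    genomeBp <- sum(as.numeric(seqlengths))
    genomePct <- 100 * sum(mLin$end - mLin$start) / genomeBp
    queryPct <- 100 * sum(covFun(qLin$end) - covFun(qLin$start)) /
        sum(qLin$end - qLin$start)
    fold <- queryPct / genomePct
    chromLin <- .linearize(GRanges(names(seqlengths),
                                   IRanges::IRanges(1, seqlengths)), off)
    lens <- qLin$end - qLin$start
    m <- length(lens)
    nulls <- withSeed(substreamSeed(seed, "genomeshuffle"), {
        allLens <- rep(lens, nShuffles)
        sh <- .shuffleMany(allLens, chromLin$start, chromLin$end)
        ovBp <- covFun(sh$end) - covFun(sh$start)
        grp <- rep(seq_len(nShuffles), each = m)
        100 * as.numeric(rowsum(ovBp, grp)) /
            as.numeric(rowsum(sh$end - sh$start, grp))
    })
    ep <- .empiricalP(queryPct, nulls, alternative)
    list(fold = fold, queryPct = queryPct, genomePct = genomePct,
         empiricalP = ep$p, direction = ep$direction,
         nullFolds = nulls / genomePct)
}

#' Percent methylation of peak sets per sample, with paired tests
#'
#' Computes weighted percent methylation of every peak in every sample's
#' methylome, then for each non-control sample runs the one-sided paired
#' Wilcoxon test (pairs = peaks) for the alternative that the sample is
#' less methylated than control over those peaks. Peaks with no CpG
#' coverage in either member of a pair are dropped (count reported).
#'
#' @param peakSets Named list of `GRanges` (categories).
#' @param samples Named list of filtered `MethylomeSample`s.
#' @param controlId Name of the control sample.
#' @return Nested list: category -> list with `meanPct` (per sample),
#'   `tests` (per AGS sample: `p`, `nPairs`, `dropped`).
#' @export
peakMethylationBySample <- function(peakSets, samples, controlId) {
    if (!controlId %in% names(samples)) stop("unknown control id")
    lapply(peakSets, function(peaks) {
        pct <- vapply(samples, function(s)
            regionMethylation(s, peaks, mode = "weighted")$pctMeth,
            numeric(length(peaks)))
        if (length(peaks) == 1L) pct <- matrix(pct, nrow = 1,
                                               dimnames = list(NULL, names(samples)))
        tests <- lapply(setdiff(names(samples), controlId), function(s) {
            ok <- stats::complete.cases(pct[, c(s, controlId), drop = FALSE])
            res <- list(p = NA_real_, nPairs = sum(ok),
                        dropped = sum(!ok))
            if (sum(ok) >= 2) {
                res$p <- tryCatch(
                    pairedWilcoxonLess(pct[ok, s], pct[ok, controlId]),
                    error = function(e) NA_real_)
            }
            res
        })
        names(tests) <- setdiff(names(samples), controlId)
        list(meanPct = colMeans(pct, na.rm = TRUE), tests = tests,
             peakPct = pct)
    })
}
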