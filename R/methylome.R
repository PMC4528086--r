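## Methylome module: per-cytosine call tables -> QC'd CpG-unit samples,
## coverage filtering, regional methylation, binned tracks, metaplots.

#' Read / write per-cytosine call tables
#'
#' Tab-separated table with columns `chrom`, `pos0` (0-based position of
#' the cytosine), `strand`, `context` (`CG`/`CHG`/`CHH`), `meth`,
#' `total`.
#'
#' @param path File path.
#' @return `readCpGCalls`: a `data.frame` of raw calls.
#' @export
readCpGCalls <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos0", "strand", "context", "meth", "total")
    if (!all(need %in% colnames(df)))
        stop("call table must have columns: ", paste(need, collapse = ", "))
    if (any(df$meth > df$total) || any(df$meth < 0))
        stop("invalid counts: need 0 <= meth <= total")
    df
}

#' @rdname readCpGCalls
#' @param calls Raw call `data.frame`.
#' @export
writeCpGCalls <- function(calls, path) {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Combine strand records of CpG dyads
#'
#' A forward-strand CG record at `pos0 = p` and the reverse-strand record
#' of the same dyad at `pos0 = p + 1` are merged into one CpG-unit record
#' at `p` with summed counts; unpaired records pass through unchanged.
#' Non-CG records are dropped (their count is reported in the `nonCG`
#' attribute). Counts are conserved: the summed `meth` and `total` of the
#' CG input equal those of the output.
#'
#' @param calls Raw call `data.frame` (see [readCpGCalls()]).
#' @return `data.frame` with columns `chrom`, `pos0` (forward-strand C of
#'   the dyad), `meth`, `total`, sorted by position.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos0 = c(10, 11), strand = c("+", "-"),
#'                     context = "CG", meth = c(3, 2), total = c(5, 5))
#' combineStrands(calls)  # one dyad record: 5/10 at pos0 = 10
#' @export
combineStrands <- function(calls) {
    nonCG <- sum(calls$context != "CG")
    cg <- calls[calls$context == "CG", , drop = FALSE]
    if (nrow(cg) == 0L) {
        out <- data.frame(chrom = character(0), pos0 = numeric(0),
                          meth = numeric(0), total = numeric(0))
        attr(out, "nonCG") <- nonCG
        return(out)
    }
    unitPos <- ifelse(cg$strand == "+", cg$pos0, cg$pos0 - 1)
    key <- paste(cg$chrom, unitPos)
    meth <- rowsum(cg$meth, key, reorder = FALSE)
    total <- rowsum(cg$total, key, reorder = FALSE)
    first <- !duplicated(key)
    out <- data.frame(chrom = cg$chrom[first], pos0 = unitPos[first],
                      meth = as.numeric(meth[, 1]),
                      total = as.numeric(total[, 1]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$pos0), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "nonCG") <- nonCG
    out
}

#' Build a MethylomeSample from a raw call table
#'
#' Computes the bisulfite conversion rate from CHG/CHH records, combines
#' CpG strands into dyad units, and wraps the result in a
#' [MethylomeSample-class] (unfiltered; apply [coverageFilter()] next).
#'
#' @param calls Raw call `data.frame`.
#' @param sampleId Sample identifier.
#' @param seqlengths Optional named chromosome lengths (needed later for
#'   binned tracks and segmentation windows).
#' @return A `MethylomeSample`.
#' @export
asMethylomeSample <- function(calls, sampleId, seqlengths = NULL) {
    hasNonCpG <- any(calls$context %in% c("CHG", "CHH") & calls$total > 0)
    convRate <- if (hasNonCpG) conversionRate(calls) else NA_real_
    units <- combineStrands(calls)
    gr <- GRanges(units$chrom, IRanges::IRanges(units$pos0 + 1, width = 1))
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    S4Vectors::mcols(gr)$meth <- units$meth
    S4Vectors::mcols(gr)$total <- units$total
    gr <- BiocGenerics::sort(gr)
    methods::new("MethylomeSample", sampleId = sampleId, records = gr,
                 conversionRate = convRate,
                 meanCoverage = if (length(gr)) mean(S4Vectors::mcols(gr)$total)
                                else NA_real_,
                 filterBounds = c(NA_real_, NA_real_), filterLog = list())
}

#' Coverage-filter CpG records
#'
#' Discards CpG units with coverage below `minCov` or above the
#' `upperPct` percentile of the sample's own coverage distribution
#' (linear-interpolation percentile). On a `MethylomeSample` the bounds
#' are computed once and recorded in `filterBounds`; re-applying the
#' filter with the same settings is a no-op, making the filter a fixed
#' property of the sample.
#'
#' @param x A `MethylomeSample` or CpG-unit `GRanges`/`data.frame` with a
#'   `total` column.
#' @param minCov Minimum coverage (>= 1).
#' @param upperPct Upper percentile cut (e.g. 99.9).
#' @return Filtered object of the same class; the drop report is stored
#'   in `filterLog` (sample) or the `"report"` attribute.
#' @export
setGeneric("coverageFilter",
           function(x, minCov = 4, upperPct = 99.9)
               standardGeneric("coverageFilter"))

.coverageFilterCore <- function(total, minCov, upperPct) {
    if (minCov < 1) stop("minCov must be >= 1")
    if (upperPct <= 0 || upperPct > 100) stop("upperPct must be in (0, 100]")
    hi <- stats::quantile(total, upperPct / 100, type = 7, names = FALSE)
    low <- total < minCov
    high <- !low & total > hi
    list(keep = !(low | high),
         report = list(droppedLow = sum(low), droppedHigh = sum(high),
                       upperValue = hi, minCov = minCov, upperPct = upperPct))
}

#' @rdname coverageFilter
#' @export
setMethod("coverageFilter", "GRanges", function(x, minCov = 4, upperPct = 99.9) {
    res <- .coverageFilterCore(S4Vectors::mcols(x)$total, minCov, upperPct)
    out <- x[res$keep]
    attr(out, "report") <- res$report
    out
})

#' @rdname coverageFilter
#' @export
setMethod("coverageFilter", "data.frame", function(x, minCov = 4, upperPct = 99.9) {
    res <- .coverageFilterCore(x$total, minCov, upperPct)
    out <- x[res$keep, , drop = FALSE]
    attr(out, "report") <- res$report
    out
})

#' @rdname coverageFilter
#' @export
setMethod("coverageFilter", "MethylomeSample", function(x, minCov = 4,
                                                        upperPct = 99.9) {
    if (!all(is.na(x@filterBounds))) {
        prev <- x@filterLog
        if (identical(prev$minCov, minCov) && identical(prev$upperPct, upperPct))
            return(x)                      # already filtered with these settings
        stop("sample already coverage-filtered with different settings")
    }
    res <- .coverageFilterCore(S4Vectors::mcols(x@records)$total, minCov, upperPct)
    x@records <- x@records[res$keep]
    x@filterBounds <- c(minCov, res$report$upperValue)
    x@filterLog <- res$report
    methods::validObject(x)
    x
})

#' Global percent methylation of a sample
#'
#' Coverage-weighted: `100 * sum(meth) / sum(total)` over all CpG units.
#'
#' @param sample A `MethylomeSample`.
#' @return Percentage in `[0, 100]`.
#' @export
globalMethylation <- function(sample) {
    mc <- S4Vectors::mcols(records(sample))
    if (sum(mc$total) == 0) stop("no covered CpGs")
    100 * sum(mc$meth) / sum(mc$total)
}

#' Percent methylation over genomic intervals
#'
#' Default `weighted` mode pools read counts, `100 * sum(meth) /
#' sum(total)` over CpG units in the interval; `sitemean` averages the
#' per-site percentages instead. Intervals without covered CpGs get `NA`
#' and `covered = FALSE`.
#'
#' @param sample A `MethylomeSample` (typically coverage-filtered).
#' @param intervals Query `GRanges`.
#' @param mode `"weighted"` or `"sitemean"`.
#' @return `data.frame` with one row per interval: `chrom`, `start`,
#'   `end`, `pctMeth`, `nSites`, `covered`.
#' @export
regionMethylation <- function(sample, intervals,
                              mode = c("weighted", "sitemean")) {
    mode <- match.arg(mode)
    .assertGRanges(intervals, "intervals")
    if (any(BiocGenerics::start(intervals) < 1) ||
        any(BiocGenerics::width(intervals) < 1))
        stop("malformed interval")
    rec <- records(sample)
    mc <- S4Vectors::mcols(rec)
    ov <- GenomicRanges::findOverlaps(rec, intervals, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    n <- length(intervals)
    pct <- rep(NA_real_, n)
    nSites <- integer(n)
    if (length(ov)) {
        f <- factor(s, levels = seq_len(n))
        methSum <- vapply(split(mc$meth[q], f), sum, numeric(1))
        totSum <- vapply(split(mc$total[q], f), sum, numeric(1))
        cnt <- as.integer(table(f))
        nSites <- cnt
        hasCov <- totSum > 0
        if (mode == "weighted") {
            pct[hasCov] <- 100 * methSum[hasCov] / totSum[hasCov]
        } else {
            sitePct <- 100 * mc$meth[q] / mc$total[q]
            pm <- vapply(split(sitePct, f), sum, numeric(1)) / cnt
            pct[hasCov] <- pm[hasCov]
        }
    }
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(intervals)),
               start = BiocGenerics::start(intervals),
               end = BiocGenerics::end(intervals),
               pctMeth = pct, nSites = nSites, covered = nSites > 0,
               stringsAsFactors = FALSE)
}

#' Fixed-bin genome-wide percent-methylation track
#'
#' Tiles each chromosome with `binSize` bins (the last partial bin is
#' kept) and reports the coverage-weighted percent methylation per bin,
#' suitable for bedGraph export with [writeBedGraph()].
#'
#' @param sample A `MethylomeSample` whose records carry seqlengths.
#' @param binSize Bin width in bp (>= 1).
#' @return `GRanges` of bins with metadata `pctMeth`, `meth`, `total`,
#'   `nSites` (bins without sites have `NA` percent).
#' @export
binnedTrack <- function(sample, binSize = 2e6) {
    if (binSize < 1) stop("binSize must be >= 1")
    rec <- records(sample)
    sl <- GenomeInfoDb::seqlengths(rec)
    if (any(is.na(sl))) stop("sample records need seqlengths for binning")
    bins <- GRanges(seqlengths = sl)
    for (chrom in names(sl)) {
        starts <- seq(1, sl[[chrom]], by = binSize)
        ends <- pmin(starts + binSize - 1, sl[[chrom]])
        bins <- c(bins, GRanges(chrom, IRanges::IRanges(starts, ends),
                                seqlengths = sl))
    }
    rm <- regionMethylation(sample, bins, mode = "weighted")
    mc <- S4Vectors::mcols(rec)
    ov <- GenomicRanges::findOverlaps(rec, bins, ignore.strand = TRUE)
    f <- factor(S4Vectors::subjectHits(ov), levels = seq_along(bins))
    S4Vectors::mcols(bins)$pctMeth <- rm$pctMeth
    S4Vectors::mcols(bins)$meth <- unname(
        vapply(split(mc$meth[S4Vectors::queryHits(ov)], f), sum, numeric(1)))
    S4Vectors::mcols(bins)$total <- unname(
        vapply(split(mc$total[S4Vectors::queryHits(ov)], f), sum, numeric(1)))
    S4Vectors::mcols(bins)$nSites <- rm$nSites
    bins
}

#' Methylation metaplot around oriented anchors
#'
#' Sites within `flankBp` of each anchor are assigned to `nBins` bins of
#' equal width in transcriptional orientation (offsets are mirrored for
#' minus-strand anchors); by default read counts are pooled across all
#' anchors per bin (`perGene = TRUE` averages per-anchor profiles with
#' equal weight instead).
#'
#' @param sample A `MethylomeSample`.
#' @param anchors Width-1 `GRanges` with strand (TSSs or TTSs).
#' @param flankBp Flank on each side of the anchor; must be divisible by
#'   `nBins`.
#' @param nBins Number of bins per side... total bins span
#'   `[-flankBp, +flankBp)` in steps of `2 * flankBp / nBins`.
#' @param perGene Average per-anchor profiles instead of pooling sites.
#' @return `data.frame` with `bin`, `offset` (bin left edge relative to
#'   the anchor), `meanMeth` (fraction in `[0, 1]`), `nSites`.
#' @export
metaplot <- function(sample, anchors, flankBp = 5000, nBins = 50,
                     perGene = FALSE) {
    .assertGRanges(anchors, "anchors")
    if (length(anchors) == 0L) stop("no anchors supplied")
    if (flankBp %% nBins != 0)
        stop("flankBp must be divisible by nBins")
    binW <- 2 * flankBp / nBins
    rec <- records(sample)
    mc <- S4Vectors::mcols(rec)
    win <- GenomicRanges::trim(suppressWarnings(
        GenomicRanges::resize(anchors, width = 2 * flankBp, fix = "center")))
    ov <- GenomicRanges::findOverlaps(rec, win, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); a <- S4Vectors::subjectHits(ov)
    off <- BiocGenerics::start(rec)[q] - BiocGenerics::start(anchors)[a]
    minus <- as.character(BiocGenerics::strand(anchors))[a] == "-"
    off[minus] <- -off[minus]
    keep <- off >= -flankBp & off < flankBp
    q <- q[keep]; a <- a[keep]; off <- off[keep]
    bin <- floor((off + flankBp) / binW)             # 0 .. nBins-1
    f <- factor(bin, levels = 0:(nBins - 1))
    if (!perGene) {
        methSum <- unname(vapply(split(mc$meth[q], f), sum, numeric(1)))
        totSum <- unname(vapply(split(mc$total[q], f), sum, numeric(1)))
        meanMeth <- ifelse(totSum > 0, methSum / totSum, NA_real_)
    } else {
        key <- interaction(f, a, drop = FALSE)
        ms <- rowsum(mc$meth[q], key)
        ts <- rowsum(mc$total[q], key)
        prof <- ms[, 1] / ts[, 1]
        binOf <- as.integer(sub("\\..*", "", rownames(ms)))
        meanMeth <- vapply(0:(nBins - 1), function(b) {
            v <- prof[binOf == b & is.finite(prof)]
            if (length(v)) mean(v) else NA_real_
        }, numeric(1))
    }
    data.frame(bin = 0:(nBins - 1),
               offset = seq(-flankBp, flankBp - binW, by = binW),
               meanMeth = meanMeth,
               nSites = as.integer(table(f)))
}

#' Write a bedGraph track (0-based half-open)
#'
#' @param track `GRanges` with a numeric metadata column (first one is
#'   used as the score).
#' @param path Output path.
#' @param column Metadata column to write.
#' @export
writeBedGraph <- function(track, path, column = "pctMeth") {
    val <- S4Vectors::mcols(track)[[column]]
    keep <- !is.na(val)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(track))[keep],
                     start = BiocGenerics::start(track)[keep] - 1L,
                     end = BiocGenerics::end(track)[keep],
                     value = val[keep])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' One-sided paired Wilcoxon signed-rank test (H1: a < b)
#'
#' Tests whether paired values in `a` are shifted below `b` (e.g. AGS
#' sample methylation below control). Zero differences are dropped by the
#' standard signed-rank convention. For up to `exactMax` non-zero pairs
#' the exact null distribution of the positive-rank sum is computed by
#' dynamic programming over the (average) ranks, which stays exact under
#' tied absolute differences; beyond that the normal approximation with
#' continuity and tie correction is used.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @param exactMax Largest n for which the exact distribution is used.
#' @return One-sided p-value for H1: `a < b`.
#' @examples
#' pairedWilcoxonLess(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))  # 1/32
#' @export
pairedWilcoxonLess <- function(a, b, exactMax = 25L) {
    if (length(a) != length(b)) stop("a and b must be paired (equal length)")
    d <- a - b
    d <- d[!is.na(d)]
    d <- d[d != 0]
    n <- length(d)
    if (n < 1L)
        stop("all pairs tied: signed-rank test undefined")
    if (n <= exactMax) {
        ## exact P(V <= v_obs) where V = sum of ranks of positive
        ## differences; doubled average ranks keep the DP integral
        r2 <- as.integer(round(2 * rank(abs(d))))
        vObs2 <- as.integer(round(2 * sum(rank(abs(d))[d > 0])))
        maxS <- sum(r2)
        cnt <- numeric(maxS + 1)                 # counts over subset sums
        cnt[1] <- 1
        for (x in r2)
            cnt <- cnt + c(rep(0, x), cnt[seq_len(maxS + 1 - x)])
        return(sum(cnt[seq_len(vObs2 + 1)]) / 2^n)
    }
    p <- suppressWarnings(stats::wilcox.test(
        a, b, paired = TRUE, alternative = "less",
        exact = FALSE, correct = TRUE)$p.value)
    unname(p)
}
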