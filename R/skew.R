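## Windowed GC-skew block caller. A deliberately simple sliding-window
## annotator for strand-asymmetric (G-C)/(G+C) blocks, standing in for
## full HMM-based skew callers: it captures the same low-stringency
## signal (sustained same-sign skew) with transparent parameters.

#' Call GC-skew blocks from a genome
#'
#' Computes the skew `(G - C) / (G + C)` of the forward strand in
#' sliding windows (`window` bp every `step` bp; windows with no G or C
#' are skipped). Runs of consecutive windows whose skew is at least
#' `minAbsSkew` with the same sign are merged into blocks; each window
#' in a run contributes its `step`-bp quantum (so a run of `k` windows
#' spans `k * step` bp from the first window's start), and blocks
#' shorter than `minBlock` are dropped. This quantum rule keeps isolated
#' noisy windows from spawning window-sized blocks, which matters at the
#' default thresholds where single-window excursions are common in
#' skew-free sequence.
#'
#' @param genome `DNAStringSet`.
#' @param window Window size in bp (>= 1).
#' @param step Step between window starts.
#' @param minAbsSkew Minimum absolute skew of a qualifying window.
#' @param minBlock Minimum block length in bp.
#' @return `GRanges` of skew blocks with metadata `skew` (mean window
#'   skew) and `sign` (`"+"`/`"-"` for G-rich / C-rich forward strand).
#' @export
gcSkewBlocks <- function(genome, window = 500, step = 100,
                         minAbsSkew = 0.1, minBlock = 300) {
    if (window < 1) stop("window must be >= 1")
    if (step < 1) stop("step must be >= 1")
    sl <- genomeSeqlengths(genome)
    out <- GRanges(seqlengths = sl)
    for (chrom in names(genome)) {
        rawSeq <- charToRaw(as.character(genome[[chrom]]))
        L <- length(rawSeq)
        if (L < window) next
        isG <- cumsum(rawSeq == as.raw(71L))
        isC <- cumsum(rawSeq == as.raw(67L))
        starts <- seq(1L, L - window + 1L, by = step)
        g <- isG[starts + window - 1L] - c(0, isG)[starts]
        cc <- isC[starts + window - 1L] - c(0, isC)[starts]
        denom <- g + cc
        skew <- ifelse(denom > 0, (g - cc) / denom, NA_real_)
        qual <- ifelse(is.na(skew), 0L, sign(skew) * (abs(skew) >= minAbsSkew))
        r <- rle(qual)
        endIdx <- cumsum(r$lengths)
        startIdx <- c(1L, utils::head(endIdx, -1L) + 1L)
        for (k in which(r$values != 0L)) {
            nWin <- r$lengths[k]
            s <- starts[startIdx[k]]
            e <- min(s + nWin * step - 1L, L)
            if (e - s + 1L < minBlock) next
            blk <- GRanges(chrom, IRanges::IRanges(s, e), seqlengths = sl)
            S4Vectors::mcols(blk)$skew <-
                mean(skew[startIdx[k]:endIdx[k]])
            S4Vectors::mcols(blk)$sign <- if (r$values[k] > 0) "+" else "-"
            out <- c(out, blk)
        }
    }
    out
}
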