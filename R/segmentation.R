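## Two-state (HMD/PMD) hidden Markov segmentation of a filtered
## methylome. Observations are fixed windows of weighted methylation;
## emissions are discrete pmfs over K methylation bins (plus a missing
## symbol) trained on stratified random 25-kb regions; transitions are
## fixed from an expected domain length; decoding is exact Viterbi.

#' Windowize a methylome into the HMM observation sequence
#'
#' Tiles each chromosome with non-overlapping `windowBp` windows and
#' computes the coverage-weighted methylation fraction per window;
#' windows with no covered CpG emit the missing symbol (`NA`). Counts are
#' conserved: summed window `meth`/`total` equal the record sums.
#'
#' @param sample A filtered `MethylomeSample` with seqlengths.
#' @param windowBp Window size (>= 100 bp; smaller windows are too
#'   sparse at the few-fold coverage this design targets).
#' @return `data.frame`: `chrom`, `start` (1-based), `end`, `value`
#'   (fraction or `NA`), `meth`, `total`, `nSites`.
#' @export
windowize <- function(sample, windowBp = 1000) {
    if (windowBp < 100) stop("windowBp must be >= 100")
    rec <- records(sample)
    sl <- GenomeInfoDb::seqlengths(rec)
    if (any(is.na(sl))) stop("sample records need seqlengths")
    mc <- S4Vectors::mcols(rec)
    pieces <- lapply(names(sl), function(chrom) {
        L <- sl[[chrom]]
        starts <- seq(1, L, by = windowBp)
        ends <- pmin(starts + windowBp - 1, L)
        idx <- which(as.character(GenomeInfoDb::seqnames(rec)) == chrom)
        win <- (BiocGenerics::start(rec)[idx] - 1) %/% windowBp + 1
        f <- factor(win, levels = seq_along(starts))
        meth <- unname(vapply(split(mc$meth[idx], f), sum, numeric(1)))
        total <- unname(vapply(split(mc$total[idx], f), sum, numeric(1)))
        data.frame(chrom = chrom, start = starts, end = ends,
                   value = ifelse(total > 0, meth / total, NA_real_),
                   meth = meth, total = total,
                   nSites = as.integer(table(f)), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
}

#' Draw stratified random training regions
#'
#' Samples random `regionBp` regions uniformly over the genome, computes
#' each region's weighted methylation, and pools regions whose
#' methylation falls inside the PMD stratum (default 25-55%) or the HMD
#' stratum (60-100%); regions in the 55-60% gap or below 25% are
#' discarded as unlabeled. Sampling continues until both pools hold at
#' least `minPool` regions (up to `maxDrawsFactor * nRegions` draws).
#'
#' @param sample Filtered `MethylomeSample` with seqlengths.
#' @param regionBp Training region size (bp).
#' @param nRegions Target pool size per stratum.
#' @param strata Named list `PMD`/`HMD` of `c(lo, hi)` methylation
#'   fraction bounds.
#' @param minPool Minimum acceptable pool size.
#' @param maxDrawsFactor Draw budget multiplier.
#' @param seed Integer seed.
#' @return List with `PMD` and `HMD`: each a `GRanges` of training
#'   regions with a `meth` metadata column.
#' @export
sampleTrainingWindows <- function(sample, regionBp = 25000, nRegions = 500,
                                  strata = list(PMD = c(0.25, 0.55),
                                                HMD = c(0.60, 1.00)),
                                  minPool = 200, maxDrawsFactor = 50,
                                  seed = 1L) {
    rec <- records(sample)
    sl <- GenomeInfoDb::seqlengths(rec)
    if (any(is.na(sl))) stop("sample records need seqlengths")
    if (any(sl < regionBp)) sl <- sl[sl >= regionBp]
    if (length(sl) == 0L) stop("genome smaller than one training region")
    mc <- S4Vectors::mcols(rec)
    ## per-chromosome cumulative counts for O(log n) region sums
    chrIdx <- split(seq_along(rec), as.character(GenomeInfoDb::seqnames(rec)))
    lookup <- lapply(chrIdx, function(idx) {
        pos <- BiocGenerics::start(rec)[idx]
        list(pos = pos, cumMeth = cumsum(mc$meth[idx]),
             cumTot = cumsum(mc$total[idx]))
    })
    regionMeth <- function(chrom, start) {
        lk <- lookup[[chrom]]
        if (is.null(lk)) return(NA_real_)
        i0 <- findInterval(start - 1, lk$pos)
        i1 <- findInterval(start + regionBp - 1, lk$pos)
        tot <- lk$cumTot[pmax(i1, 1)] * (i1 > 0) - ifelse(i0 > 0, lk$cumTot[i0], 0)
        met <- lk$cumMeth[pmax(i1, 1)] * (i1 > 0) - ifelse(i0 > 0, lk$cumMeth[i0], 0)
        ifelse(tot > 0, met / tot, NA_real_)
    }
    withSeed(substreamSeed(seed, "training"), {
        pools <- list(PMD = list(), HMD = list())
        draws <- 0L
        maxDraws <- maxDrawsFactor * nRegions
        batch <- max(200L, nRegions)
        while (draws < maxDraws &&
               (length(pools$PMD) < nRegions || length(pools$HMD) < nRegions)) {
            nb <- min(batch, maxDraws - draws)
            draws <- draws + nb
            chrom <- sample(names(sl), nb, replace = TRUE,
                            prob = as.numeric(sl - regionBp + 1))
            start <- floor(stats::runif(nb) * (sl[chrom] - regionBp + 1)) + 1
            for (i in seq_len(nb)) {
                m <- regionMeth(chrom[i], start[i])
                if (is.na(m)) next
                for (st in names(strata)) {
                    b <- strata[[st]]
                    if (m >= b[1] && m <= b[2] && length(pools[[st]]) < nRegions) {
                        pools[[st]][[length(pools[[st]]) + 1L]] <-
                            list(chrom = unname(chrom[i]),
                                 start = unname(start[i]), meth = unname(m))
                        break
                    }
                }
            }
        }
        for (st in names(strata)) {
            if (length(pools[[st]]) < minPool)
                stop("training pool '", st, "' could not be filled (",
                     length(pools[[st]]), " < ", minPool, " regions); the ",
                     "methylome lacks regions in the ",
                     paste(strata[[st]], collapse = "-"), " stratum")
        }
        lapply(pools, function(pl) {
            chrom <- vapply(pl, `[[`, character(1), "chrom")
            start <- vapply(pl, `[[`, numeric(1), "start")
            gr <- GRanges(chrom, IRanges::IRanges(start, width = regionBp),
                          seqlengths = GenomeInfoDb::seqlengths(rec))
            S4Vectors::mcols(gr)$meth <- vapply(pl, `[[`, numeric(1), "meth")
            gr
        })
    })
}

#' Fit discrete emission models from training pools
#'
#' Window-level methylation values inside each pool's regions are
#' discretized into `K` equal bins over `[0, 1]`; the smoothed empirical
#' pmf (add-`pseudocount`) per state is the emission model. The missing
#' symbol (uncovered window) is appended with equal probability in both
#' states, so missing windows carry no state information.
#'
#' @param windows Output of [windowize()].
#' @param pools Output of [sampleTrainingWindows()].
#' @param K Number of methylation bins (>= 2).
#' @param pseudocount Smoothing pseudocount.
#' @param missingProb Shared probability mass of the missing symbol.
#' @return Named list `HMD`/`PMD` of emission pmfs (length `K + 1`).
#' @export
fitEmissions <- function(windows, pools, K = 20, pseudocount = 1,
                         missingProb = 0.05) {
    if (K < 2) stop("K must be >= 2")
    if (any(lengths(pools) == 0L)) stop("both training pools must be non-empty")
    winGr <- GRanges(windows$chrom, IRanges::IRanges(windows$start, windows$end))
    emis <- lapply(pools[c("HMD", "PMD")], function(pool) {
        ov <- IRanges::overlapsAny(winGr, pool, ignore.strand = TRUE)
        v <- windows$value[ov]
        v <- v[!is.na(v)]
        bins <- pmin(floor(v * K), K - 1) + 1
        cnt <- tabulate(bins, nbins = K)
        pmf <- (cnt + pseudocount) / (sum(cnt) + K * pseudocount)
        c(pmf * (1 - missingProb), missingProb)
    })
    names(emis) <- c("HMD", "PMD")
    emis
}

#' Assemble the two-state domain HMM
#'
#' Transitions are fixed (not re-estimated): the self-transition
#' probability is `1 - windowBp / expectedDomainBp`, encoding an
#' expected domain length rather than Baum-Welch fitting.
#'
#' @param emissions From [fitEmissions()].
#' @param windowBp Observation window size.
#' @param expectedDomainBp Expected domain length (default 100 kb).
#' @param initial Initial state distribution (HMD, PMD).
#' @return A [DomainHMM-class].
#' @export
buildDomainHMM <- function(emissions, windowBp = 1000,
                           expectedDomainBp = 1e5,
                           initial = c(HMD = 0.5, PMD = 0.5)) {
    pSelf <- 1 - windowBp / expectedDomainBp
    tr <- matrix(c(pSelf, 1 - pSelf, 1 - pSelf, pSelf), 2, 2, byrow = TRUE,
                 dimnames = list(c("HMD", "PMD"), c("HMD", "PMD")))
    methods::new("DomainHMM", emissions = emissions, transitions = tr,
                 initial = initial, windowBp = windowBp,
                 K = length(emissions$HMD) - 1L)
}

## exact Viterbi over one chromosome's symbol sequence (1..K, K+1=missing)
## Ties break toward HMD (state 1) via which.max's first-max rule.
.viterbi <- function(symbols, logE, logT, logI) {
    n <- length(symbols)
    delta <- matrix(-Inf, 2, n)
    psi <- matrix(0L, 2, n)
    delta[, 1] <- logI + logE[, symbols[1]]
    for (t in 2:n) {
        for (s in 1:2) {
            cand <- delta[, t - 1] + logT[, s]
            best <- which.max(cand)
            psi[s, t] <- best
            delta[s, t] <- cand[best] + logE[s, symbols[t]]
        }
    }
    path <- integer(n)
    path[n] <- which.max(delta[, n])
    if (n > 1) for (t in (n - 1):1) path[t] <- psi[path[t + 1], t + 1]
    path
}

#' Viterbi-decode a windowized methylome into domains
#'
#' Computes the most probable HMD/PMD state path per chromosome in log
#' space (ties toward HMD), merges runs of equal state into intervals,
#' and reports each interval's weighted methylation over covered windows
#' (missing windows inherit the decoded state but do not contribute to
#' the mean).
#'
#' @param windows Output of [windowize()].
#' @param hmm A [DomainHMM-class].
#' @return A [DomainSegmentation-class].
#' @export
viterbiSegment <- function(windows, hmm) {
    v <- windows$value
    if (any(!is.na(v) & (v < 0 | v > 1)))
        stop("observations must lie in [0, 1]")
    K <- hmm@K
    logE <- rbind(log(hmm@emissions$HMD), log(hmm@emissions$PMD))
    logT <- log(hmm@transitions)
    logI <- log(hmm@initial)
    symbols <- ifelse(is.na(v), K + 1L, pmin(floor(v * K), K - 1) + 1L)
    states <- c("HMD", "PMD")
    segs <- list()
    for (chrom in unique(windows$chrom)) {
        idx <- which(windows$chrom == chrom)
        path <- .viterbi(symbols[idx], logE, logT, logI)
        r <- rle(path)
        endIdx <- cumsum(r$lengths)
        startIdx <- c(1L, utils::head(endIdx, -1L) + 1L)
        for (k in seq_along(r$values)) {
            block <- idx[startIdx[k]:endIdx[k]]
            segs[[length(segs) + 1L]] <- data.frame(
                chrom = chrom,
                start = windows$start[block[1]],
                end = windows$end[block[length(block)]],
                label = states[r$values[k]],
                meth = sum(windows$meth[block]),
                total = sum(windows$total[block]),
                nWindows = length(block), stringsAsFactors = FALSE)
        }
    }
    df <- do.call(rbind, segs)
    gr <- GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr)$label <- df$label
    S4Vectors::mcols(gr)$meanMeth <- ifelse(df$total > 0,
                                            df$meth / df$total, NA_real_)
    S4Vectors::mcols(gr)$nWindows <- df$nWindows
    S4Vectors::mcols(gr)$meth <- df$meth
    S4Vectors::mcols(gr)$total <- df$total
    methods::new("DomainSegmentation", domains = gr,
                 windowBp = hmm@windowBp)
}

#' Post-process a decoded segmentation
#'
#' Domains shorter than `minDomainBp` are absorbed into the flanking
#' domain whose mean methylation is closer; adjacent same-label domains
#' are merged (counts pooled). Output intervals alternate labels and
#' conserve total covered bp.
#'
#' @param seg A [DomainSegmentation-class].
#' @param minDomainBp Minimum domain length to keep.
#' @return A post-processed `DomainSegmentation`.
#' @export
postprocessSegmentation <- function(seg, minDomainBp = 10000) {
    d <- domains(seg)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(d)),
                     start = BiocGenerics::start(d),
                     end = BiocGenerics::end(d),
                     label = S4Vectors::mcols(d)$label,
                     meth = S4Vectors::mcols(d)$meth,
                     total = S4Vectors::mcols(d)$total,
                     nWindows = S4Vectors::mcols(d)$nWindows,
                     stringsAsFactors = FALSE)
    mergeSame <- function(x) {
        repeat {
            if (nrow(x) < 2L) return(x)
            same <- which(x$label[-1] == x$label[-nrow(x)] &
                          x$chrom[-1] == x$chrom[-nrow(x)])
            if (length(same) == 0L) return(x)
            i <- same[1]
            x$end[i] <- x$end[i + 1]
            x$meth[i] <- x$meth[i] + x$meth[i + 1]
            x$total[i] <- x$total[i] + x$total[i + 1]
            x$nWindows[i] <- x$nWindows[i] + x$nWindows[i + 1]
            x <- x[-(i + 1), , drop = FALSE]
        }
    }
    out <- list()
    for (chrom in unique(df$chrom)) {
        x <- df[df$chrom == chrom, , drop = FALSE]
        x <- x[order(x$start), , drop = FALSE]
        x <- mergeSame(x)
        repeat {
            len <- x$end - x$start + 1
            short <- which(len < minDomainBp)
            if (length(short) == 0L || nrow(x) == 1L) break
            i <- short[which.min(len[short])]
            mm <- function(j) if (x$total[j] > 0) x$meth[j] / x$total[j] else NA
            left <- if (i > 1) i - 1 else NA
            right <- if (i < nrow(x)) i + 1 else NA
            target <- if (is.na(left)) right
                      else if (is.na(right)) left
                      else {
                          di <- mm(i)
                          dl <- abs(mm(left) - di); dr <- abs(mm(right) - di)
                          if (is.na(dl)) right
                          else if (is.na(dr)) left
                          else if (dl <= dr) left else right
                      }
            x$label[i] <- x$label[target]
            x <- mergeSame(x)
        }
        out[[chrom]] <- x
    }
    df <- do.call(rbind, out)
    gr <- GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr)$label <- df$label
    S4Vectors::mcols(gr)$meanMeth <- ifelse(df$total > 0,
                                            df$meth / df$total, NA_real_)
    S4Vectors::mcols(gr)$nWindows <- df$nWindows
    S4Vectors::mcols(gr)$meth <- df$meth
    S4Vectors::mcols(gr)$total <- df$total
    methods::new("DomainSegmentation", domains = gr, windowBp = seg@windowBp)
}

#' Train and decode a methylome segmentation end to end
#'
#' Convenience wrapper: windowize, draw stratified training pools, fit
#' emissions, decode and post-process.
#'
#' @inheritParams sampleTrainingWindows
#' @inheritParams windowize
#' @inheritParams buildDomainHMM
#' @inheritParams fitEmissions
#' @inheritParams postprocessSegmentation
#' @return A [DomainSegmentation-class].
#' @export
segmentMethylome <- function(sample, windowBp = 1000, regionBp = 25000,
                             nRegions = 500,
                             strata = list(PMD = c(0.25, 0.55),
                                           HMD = c(0.60, 1.00)),
                             minPool = 200, K = 20, pseudocount = 1,
                             expectedDomainBp = 1e5, minDomainBp = 10000,
                             seed = 1L) {
    win <- windowize(sample, windowBp)
    pools <- sampleTrainingWindows(sample, regionBp = regionBp,
                                   nRegions = nRegions, strata = strata,
                                   minPool = minPool, seed = seed)
    emis <- fitEmissions(win, pools, K = K, pseudocount = pseudocount)
    hmm <- buildDomainHMM(emis, windowBp = windowBp,
                          expectedDomainBp = expectedDomainBp)
    postprocessSegmentation(viterbiSegment(win, hmm),
                            minDomainBp = minDomainBp)
}

#' Compare PMD (or HMD) sets across segmentations
#'
#' bp-level intersection/union and Jaccard for 2-3 segmentations on the
#' same genome, plus Venn region sizes.
#'
#' @param ... Two or three `DomainSegmentation` objects (or plain
#'   `GRanges` domain sets), optionally named.
#' @param label Which domain label to compare (default `"PMD"`).
#' @return List with `jaccard` (matrix), `venn` (`data.frame` of
#'   exclusive region bp) and `bp` (per-set total bp).
#' @export
comparePmds <- function(..., label = "PMD") {
    args <- list(...)
    if (length(args) < 2L || length(args) > 3L)
        stop("supply two or three segmentations")
    sets <- lapply(args, function(a) {
        gr <- if (methods::is(a, "DomainSegmentation")) {
            d <- domains(a)
            d[S4Vectors::mcols(d)$label == label]
        } else a
        GenomicRanges::reduce(gr, ignore.strand = TRUE)
    })
    nms <- names(args)
    if (is.null(nms) || any(nms == ""))
        nms <- paste0("set", seq_along(sets))
    names(sets) <- nms
    sl <- lapply(sets, GenomeInfoDb::seqlengths)
    for (i in seq_along(sl)[-1]) {
        common <- intersect(names(sl[[1]]), names(sl[[i]]))
        if (length(common) &&
            !isTRUE(all.equal(sl[[1]][common], sl[[i]][common])))
            stop("segmentations are on mismatched genomes")
    }
    n <- length(sets)
    jac <- matrix(1, n, n, dimnames = list(nms, nms))
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
        inter <- sum(BiocGenerics::width(
            GenomicRanges::intersect(sets[[i]], sets[[j]], ignore.strand = TRUE)))
        uni <- sum(BiocGenerics::width(
            GenomicRanges::union(sets[[i]], sets[[j]], ignore.strand = TRUE)))
        jac[i, j] <- jac[j, i] <- if (uni > 0) inter / uni else NA_real_
    }
    ## Venn regions by membership pattern
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
    colnames(combos) <- nms
    vennBp <- apply(combos, 1, function(memb) {
        cur <- NULL
        for (k in seq_len(n)) {
            s <- sets[[k]]
            cur <- if (memb[k]) {
                if (is.null(cur)) s
                else GenomicRanges::intersect(cur, s, ignore.strand = TRUE)
            } else cur
        }
        for (k in seq_len(n)) if (!memb[k] && !is.null(cur))
            cur <- GenomicRanges::setdiff(cur, sets[[k]], ignore.strand = TRUE)
        if (is.null(cur)) 0 else sum(BiocGenerics::width(cur))
    })
    venn <- cbind(as.data.frame(combos), bp = as.numeric(vennBp))
    list(jaccard = jac, venn = venn,
         bp = vapply(sets, function(s) sum(BiocGenerics::width(s)), numeric(1)))
}

#' Write a domain segmentation as BED6
#'
#' Name = label, score = mean methylation x 10 (0-1000 scale).
#'
#' @param seg A `DomainSegmentation`.
#' @param path Output path.
#' @export
writeDomainBed <- function(seg, path) {
    d <- domains(seg)
    mm <- S4Vectors::mcols(d)$meanMeth
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(d)),
                     start = BiocGenerics::start(d) - 1L,
                     end = BiocGenerics::end(d),
                     name = S4Vectors::mcols(d)$label,
                     score = round(ifelse(is.na(mm), 0, mm * 1000)),
                     strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
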