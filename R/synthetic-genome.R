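## Synthetic genome and annotation generators. These provide ground-truth
## inputs for every downstream stage: an i.i.d.-base genome with optional
## GC-skew blocks, a gene/repeat annotation partitioning each chromosome,
## and block-structured methylation domain plans.

#' Generate a random genome with controlled GC content and GC-skew blocks
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gcFraction` and A/T sharing
#' the remainder equally. Inside a skew block the G/C split is tilted so
#' that `P(G) - P(C) = skew * gcFraction` on the forward strand, which
#' plants detectable GC-skew signal for the skew-block caller.
#'
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#' @param gcFraction Genome GC fraction in `[0, 1]`.
#' @param skewBlocks Optional `GRanges` with a numeric metadata column
#'   `skew` in `[-1, 1]`; blocks must lie within chromosome bounds and
#'   must not overlap.
#' @param seed Integer seed; identical seed and arguments give a
#'   byte-identical genome.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome;
#'   `metadata()` records the seed and any skew blocks.
#' @examples
#' g <- makeGenome(c(chr1 = 10000), gcFraction = 0.42, seed = 7)
#' @export
makeGenome <- function(chromLengths, gcFraction = 0.42, skewBlocks = NULL,
                       seed = 1L) {
    stopifnot(is.numeric(chromLengths), length(chromLengths) >= 1L,
              !is.null(names(chromLengths)), all(chromLengths >= 1))
    if (gcFraction < 0 || gcFraction > 1) stop("gcFraction must be in [0, 1]")
    if (!is.null(skewBlocks)) {
        .assertGRanges(skewBlocks, "skewBlocks")
        sk <- S4Vectors::mcols(skewBlocks)$skew
        if (is.null(sk) || any(abs(sk) > 1)) stop("skew values must be in [-1, 1]")
        if (any(!as.character(GenomeInfoDb::seqnames(skewBlocks)) %in%
                names(chromLengths)))
            stop("skew block on unknown chromosome")
        if (any(BiocGenerics::end(skewBlocks) >
                chromLengths[as.character(GenomeInfoDb::seqnames(skewBlocks))]))
            stop("skew block outside chromosome bounds")
        red <- GenomicRanges::reduce(skewBlocks, ignore.strand = TRUE)
        if (sum(BiocGenerics::width(red)) < sum(BiocGenerics::width(skewBlocks)))
            stop("skew blocks must not overlap")
    }
    baseProbs <- function(gc, skew = 0) {
        c(A = (1 - gc) / 2, C = gc * (1 - skew) / 2,
          G = gc * (1 + skew) / 2, T = (1 - gc) / 2)
    }
    bases <- as.raw(c(65L, 67L, 71L, 84L))          # A C G T
    seqs <- withSeed(substreamSeed(seed, "genome"), {
        lapply(names(chromLengths), function(chrom) {
            L <- as.integer(chromLengths[[chrom]])
            idx <- sample.int(4L, L, replace = TRUE, prob = baseProbs(gcFraction))
            if (!is.null(skewBlocks)) {
                blk <- skewBlocks[as.character(GenomeInfoDb::seqnames(skewBlocks)) == chrom]
                for (i in seq_along(blk)) {
                    s <- BiocGenerics::start(blk)[i]; e <- BiocGenerics::end(blk)[i]
                    idx[s:e] <- sample.int(4L, e - s + 1L, replace = TRUE,
                        prob = baseProbs(gcFraction, S4Vectors::mcols(blk)$skew[i]))
                }
            }
            rawToChar(bases[idx])
        })
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(chromLengths)
    S4Vectors::metadata(genome) <- list(seed = seed, gcFraction = gcFraction,
                                        skewBlocks = skewBlocks)
    genome
}

## seqlengths helper for a DNAStringSet genome
genomeSeqlengths <- function(genome) {
    sl <- Biostrings::width(genome)
    names(sl) <- names(genome)
    sl
}

#' Generate a gene/repeat annotation for a synthetic genome
#'
#' Places `nGenes` non-overlapping genes (log-normal lengths, random
#' strand) across chromosomes proportionally to their length; the gene
#' body runs from TSS to TTS and the intergenic set is the exact
#' complement, so gene bodies plus intergenic partition each chromosome.
#' Repeat elements of each class are placed uniformly within the
#' intergenic compartment (non-overlapping within a class) until the
#' requested fraction of intergenic bp is covered.
#'
#' @param genome A `DNAStringSet` from [makeGenome()].
#' @param nGenes Total number of genes to place.
#' @param repeatDensity Named numeric vector: repeat class -> target
#'   fraction of intergenic bp (classes typically `LINE`, `LTR`, `SINE`,
#'   `satellite`).
#' @param seed Integer seed.
#' @param geneMeanLog,geneSdLog Log-normal parameters for gene lengths.
#' @return Named list of `GRanges`: `genes`, `tss`, `tts` (width-1,
#'   stranded), `intergenic`, and one entry per repeat class.
#' @export
makeAnnotation <- function(genome, nGenes,
                           repeatDensity = c(LINE = 0.15, LTR = 0.08,
                                             SINE = 0.10, satellite = 0.02),
                           seed = 1L, geneMeanLog = log(2e4), geneSdLog = 0.6) {
    sl <- genomeSeqlengths(genome)
    stopifnot(nGenes >= 0, all(repeatDensity >= 0), all(repeatDensity < 1))
    repLenRange <- list(LINE = c(1000, 6000), LTR = c(300, 1000),
                        SINE = c(100, 400), satellite = c(500, 2000))
    withSeed(substreamSeed(seed, "annotation"), {
        nPer <- if (nGenes == 0) integer(length(sl)) else {
            frac <- sl / sum(sl)
            n0 <- floor(nGenes * frac)
            rem <- nGenes - sum(n0)
            if (rem > 0) {
                o <- order(nGenes * frac - n0, decreasing = TRUE)
                n0[o[seq_len(rem)]] <- n0[o[seq_len(rem)]] + 1
            }
            as.integer(n0)
        }
        genes <- GRanges(seqlengths = sl)
        for (ci in seq_along(sl)) {
            n <- nPer[ci]
            if (n == 0L) next
            L <- sl[ci]
            lens <- pmax(2000, round(stats::rlnorm(n, geneMeanLog, geneSdLog)))
            if (sum(lens) + n > L)
                stop("nGenes infeasible for genome size on ", names(sl)[ci])
            free <- L - sum(lens)
            gaps <- diff(c(0, sort(stats::runif(n, 0, free)), free))
            starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, lens[-n])) + 1
            gr <- GRanges(names(sl)[ci],
                          IRanges::IRanges(start = round(starts), width = lens),
                          strand = sample(c("+", "-"), n, replace = TRUE),
                          seqlengths = sl)
            genes <- c(genes, gr)
        }
        genes <- BiocGenerics::sort(genes, ignore.strand = TRUE)
        if (length(genes))
            S4Vectors::mcols(genes)$gene_id <- sprintf("gene%04d", seq_along(genes))
        plus <- as.character(BiocGenerics::strand(genes)) == "+"
        tssPos <- ifelse(plus, BiocGenerics::start(genes), BiocGenerics::end(genes))
        ttsPos <- ifelse(plus, BiocGenerics::end(genes), BiocGenerics::start(genes))
        tss <- GRanges(GenomeInfoDb::seqnames(genes),
                       IRanges::IRanges(tssPos, width = 1),
                       strand = BiocGenerics::strand(genes), seqlengths = sl)
        tts <- GRanges(GenomeInfoDb::seqnames(genes),
                       IRanges::IRanges(ttsPos, width = 1),
                       strand = BiocGenerics::strand(genes), seqlengths = sl)
        whole <- GRanges(names(sl), IRanges::IRanges(1, sl), seqlengths = sl)
        intergenic <- GenomicRanges::setdiff(whole, genes, ignore.strand = TRUE)
        out <- list(genes = genes, tss = tss, tts = tts, intergenic = intergenic)
        igW <- sum(BiocGenerics::width(intergenic))
        for (cls in names(repeatDensity)) {
            target <- repeatDensity[[cls]] * igW
            rng <- repLenRange[[cls]]
            if (is.null(rng)) rng <- c(300, 2000)
            placed <- GRanges(seqlengths = sl)
            attempts <- 0L
            while (sum(BiocGenerics::width(placed)) < target && attempts < 200L) {
                attempts <- attempts + 1L
                need <- target - sum(BiocGenerics::width(placed))
                nDraw <- max(10L, ceiling(need / mean(rng)) * 2L)
                host <- sample(seq_along(intergenic), nDraw, replace = TRUE,
                               prob = BiocGenerics::width(intergenic))
                eLen <- round(stats::runif(nDraw, rng[1], rng[2]))
                hw <- BiocGenerics::width(intergenic)[host]
                ok <- eLen <= hw
                if (!any(ok)) break
                host <- host[ok]; eLen <- eLen[ok]
                off <- floor(stats::runif(length(host)) *
                             (BiocGenerics::width(intergenic)[host] - eLen + 1))
                cand <- GRanges(GenomeInfoDb::seqnames(intergenic)[host],
                    IRanges::IRanges(BiocGenerics::start(intergenic)[host] + off,
                                     width = eLen), seqlengths = sl)
                cand <- cand[!IRanges::overlapsAny(cand, placed)]
                cand <- cand[!duplicated(cand)]
                if (length(cand) > 1L) {
                    selfOv <- GenomicRanges::findOverlaps(cand, drop.self = TRUE,
                                                          drop.redundant = TRUE)
                    if (length(selfOv))
                        cand <- cand[-unique(S4Vectors::subjectHits(selfOv))]
                }
                if (length(cand)) {
                    cw <- cumsum(BiocGenerics::width(cand))
                    stopAt <- which(cw >= need)[1]
                    if (!is.na(stopAt)) cand <- cand[seq_len(stopAt)]
                    placed <- c(placed, cand)
                }
                if (sum(BiocGenerics::width(placed)) >= target) break
            }
            out[[cls]] <- BiocGenerics::sort(placed, ignore.strand = TRUE)
        }
        out
    })
}

#' Plan alternating HMD/PMD methylation domains over a genome
#'
#' Draws domain lengths from an exponential distribution (clipped to
#' `[minDomainBp, maxDomainBp]`), tiles each chromosome, labels each
#' segment PMD with probability `pmdFraction`, and assigns a per-domain
#' mean methylation level: the stratum midpoint (`pmdMeanLevel` /
#' `hmdMeanLevel`) plus truncated Gaussian jitter kept inside the
#' conventional strata (PMD 0.25-0.55, HMD 0.60-1.00).
#'
#' @param seqlengths Named chromosome lengths.
#' @param pmdFraction Expected fraction of segments labeled PMD.
#' @param pmdMeanLevel,hmdMeanLevel Central methylation levels.
#' @param meanDomainBp Mean planned domain length.
#' @param minDomainBp,maxDomainBp Length clip bounds.
#' @param levelJitterSd SD of the per-domain level jitter (0 disables).
#' @param seed Integer seed.
#' @return `GRanges` with metadata columns `label` and `meanLevel`,
#'   tiling every chromosome.
#' @export
planDomains <- function(seqlengths, pmdFraction = 0.3, pmdMeanLevel = 0.40,
                        hmdMeanLevel = 0.85, meanDomainBp = 3e5,
                        minDomainBp = 5e4, maxDomainBp = 1.5e6,
                        levelJitterSd = 0.04, seed = 1L) {
    stopifnot(pmdFraction >= 0, pmdFraction <= 1)
    strata <- list(PMD = c(0.25, 0.55), HMD = c(0.60, 1.00))
    withSeed(substreamSeed(seed, "domainplan"), {
        res <- GRanges(seqlengths = seqlengths)
        for (chrom in names(seqlengths)) {
            L <- seqlengths[[chrom]]
            lens <- numeric(0)
            while (sum(lens) < L)
                lens <- c(lens, pmin(pmax(round(stats::rexp(16, 1 / meanDomainBp)),
                                          minDomainBp), maxDomainBp))
            cut <- which(cumsum(lens) >= L)[1]
            lens <- lens[seq_len(cut)]
            ends <- pmin(cumsum(lens), L)
            starts <- c(1, utils::head(ends, -1) + 1)
            keep <- starts <= L
            starts <- starts[keep]; ends <- ends[keep]
            n <- length(starts)
            lab <- ifelse(stats::runif(n) < pmdFraction, "PMD", "HMD")
            center <- ifelse(lab == "PMD", pmdMeanLevel, hmdMeanLevel)
            lv <- center + stats::rnorm(n, 0, levelJitterSd)
            for (i in seq_len(n)) {
                b <- strata[[lab[i]]]
                lv[i] <- min(max(lv[i], b[1]), b[2])
            }
            gr <- GRanges(chrom, IRanges::IRanges(starts, ends),
                          seqlengths = seqlengths)
            S4Vectors::mcols(gr)$label <- lab
            S4Vectors::mcols(gr)$meanLevel <- lv
            res <- c(res, gr)
        }
        res
    })
}

#' Convert a fraction of planned HMDs into extra (sample-specific) PMDs
#'
#' Models the AGS-like situation where a sample gains PMDs on top of the
#' domains shared with control: a random subset of HMD segments is
#' relabeled PMD at `pmdMeanLevel`.
#'
#' @param plan Domain plan from [planDomains()].
#' @param fraction Fraction of HMD segments to convert.
#' @param pmdMeanLevel Methylation level of the new PMDs.
#' @param seed Integer seed.
#' @return List with `plan` (modified `GRanges`) and `extraPmds` (the
#'   converted intervals).
#' @export
addExtraPmds <- function(plan, fraction = 0.15, pmdMeanLevel = 0.40, seed = 1L) {
    .assertGRanges(plan, "plan")
    hmdIdx <- which(S4Vectors::mcols(plan)$label == "HMD")
    withSeed(substreamSeed(seed, "extrapmd"), {
        nConv <- round(fraction * length(hmdIdx))
        conv <- sort(sample(hmdIdx, nConv))
        S4Vectors::mcols(plan)$label[conv] <- "PMD"
        S4Vectors::mcols(plan)$meanLevel[conv] <-
            pmin(pmax(pmdMeanLevel + stats::rnorm(nConv, 0, 0.03), 0.25), 0.55)
        list(plan = plan, extraPmds = plan[conv])
    })
}
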