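## Bisulfite methylome simulator: emits Bismark-style per-cytosine call
## records for every cytosine in the genome, with block-structured CpG
## methylation defined by a domain plan and binomial read sampling at
## realistic low coverage.

## classify every cytosine position in a chromosome (raw byte vector)
## returns list of data.frames by context/strand pieces
.cytosinePositions <- function(rawSeq) {
    C <- as.raw(67L); G <- as.raw(71L)
    L <- length(rawSeq)
    Cpos <- which(rawSeq == C)
    Gpos <- which(rawSeq == G)
    ## forward strand contexts
    isCG <- Cpos < L & rawSeq[pmin(Cpos + 1L, L)] == G
    cgPlus <- Cpos[isCG]
    nonCgPlus <- Cpos[!isCG]
    plusCHG <- nonCgPlus[nonCgPlus < L - 1L &
                         rawSeq[pmin(nonCgPlus + 2L, L)] == G]
    plusCHH <- setdiff(nonCgPlus, plusCHG)
    ## reverse strand: a C on the minus strand sits at a G on the plus
    ## strand; its downstream bases are the complements of the preceding
    ## plus-strand bases.
    minusCG <- Gpos[Gpos > 1L & rawSeq[pmax(Gpos - 1L, 1L)] == C]
    nonCgMinus <- setdiff(Gpos, minusCG)
    minusCHG <- nonCgMinus[nonCgMinus > 2L &
                           rawSeq[pmax(nonCgMinus - 2L, 1L)] == C]
    minusCHH <- setdiff(nonCgMinus, minusCHG)
    list(cgPlus = cgPlus, plusCHG = plusCHG, plusCHH = plusCHH,
         minusCHG = minusCHG, minusCHH = minusCHH)
}

#' Simulate a whole-genome bisulfite methylome with known ground truth
#'
#' Every CpG dyad receives a latent methylation probability drawn from a
#' Beta distribution centered on the mean level of the planned domain
#' containing it (concentration `dispersion`; `Inf` collapses to the
#' domain mean). Read coverage per dyad is Poisson(`meanCoverage`)
#' truncated at zero, split binomially between the two strand records.
#' Methylated counts are Binomial(coverage, p) where the observed
#' per-read methylation probability includes bisulfite conversion
#' failures: an unmethylated cytosine is read as C with probability
#' `conversionFailureRate`. Non-CpG cytosines (CHG/CHH) are emitted
#' unmethylated except for conversion failures, at per-strand coverage
#' Poisson(`meanCoverage / 2`).
#'
#' @param genome `DNAStringSet` from [makeGenome()].
#' @param plan Domain plan `GRanges` with `meanLevel` (and `label`)
#'   metadata; CpGs outside any planned interval use `backgroundLevel`.
#' @param meanCoverage Mean reads per CpG dyad (> 0).
#' @param conversionFailureRate Probability an unmethylated C escapes
#'   conversion, in `[0, 1)`.
#' @param dispersion Beta concentration of per-site levels around the
#'   domain mean (default 30; `Inf` = no site-level variation).
#' @param backgroundLevel Methylation level outside planned domains.
#' @param emitNonCpG Emit CHG/CHH records (needed for conversion-rate
#'   estimation; can be disabled when only CpG methylation matters).
#' @param nonCpGFraction Fraction of non-CpG cytosines to emit
#'   (subsampling keeps large simulations light; the survivors are an
#'   unbiased sample).
#' @param seed Integer seed.
#' @return List with `calls` (raw per-cytosine `data.frame`: `chrom`,
#'   `pos0`, `strand`, `context`, `meth`, `total`) and `truth` (list with
#'   `siteLevels` per-dyad latent probabilities and the `plan`).
#' @export
simulateMethylome <- function(genome, plan, meanCoverage = 5,
                              conversionFailureRate = 0.005,
                              dispersion = 30, backgroundLevel = 0.85,
                              emitNonCpG = TRUE, nonCpGFraction = 1,
                              seed = 1L) {
    stopifnot(meanCoverage > 0)
    if (conversionFailureRate < 0 || conversionFailureRate >= 1)
        stop("conversionFailureRate must be in [0, 1)")
    .assertGRanges(plan, "plan")
    sl <- genomeSeqlengths(genome)
    planChr <- as.character(GenomeInfoDb::seqnames(plan))
    if (any(!planChr %in% names(sl)) ||
        any(BiocGenerics::end(plan) > sl[planChr]))
        stop("plan interval outside genome")
    cf <- conversionFailureRate
    withSeed(substreamSeed(seed, "methylome"), {
        callPieces <- list()
        truthPieces <- list()
        for (chrom in names(genome)) {
            rawSeq <- charToRaw(as.character(genome[[chrom]]))
            pos <- .cytosinePositions(rawSeq)
            p <- pos$cgPlus
            n <- length(p)
            if (n > 0L) {
                lev <- rep(backgroundLevel, n)
                lab <- rep("background", n)
                chrPlan <- plan[as.character(GenomeInfoDb::seqnames(plan)) == chrom]
                if (length(chrPlan)) {
                    ov <- GenomicRanges::findOverlaps(
                        GRanges(chrom, IRanges::IRanges(p, width = 1)), chrPlan,
                        select = "first")
                    hit <- !is.na(ov)
                    lev[hit] <- S4Vectors::mcols(chrPlan)$meanLevel[ov[hit]]
                    if (!is.null(S4Vectors::mcols(chrPlan)$label))
                        lab[hit] <- S4Vectors::mcols(chrPlan)$label[ov[hit]]
                }
                if (is.finite(dispersion)) {
                    pSite <- stats::rbeta(n, lev * dispersion,
                                          (1 - lev) * dispersion)
                    deg <- lev <= 0 | lev >= 1
                    pSite[deg] <- lev[deg]
                } else pSite <- lev
                tot <- stats::rpois(n, meanCoverage)
                plusCov <- stats::rbinom(n, tot, 0.5)
                minusCov <- tot - plusCov
                pObs <- pSite + (1 - pSite) * cf
                methPlus <- stats::rbinom(n, plusCov, pObs)
                methMinus <- stats::rbinom(n, minusCov, pObs)
                kp <- plusCov > 0L; km <- minusCov > 0L
                callPieces[[length(callPieces) + 1L]] <- data.frame(
                    chrom = chrom, pos0 = p[kp] - 1L, strand = "+",
                    context = "CG", meth = methPlus[kp], total = plusCov[kp],
                    stringsAsFactors = FALSE)
                callPieces[[length(callPieces) + 1L]] <- data.frame(
                    chrom = chrom, pos0 = p[km], strand = "-",
                    context = "CG", meth = methMinus[km], total = minusCov[km],
                    stringsAsFactors = FALSE)
                truthPieces[[length(truthPieces) + 1L]] <- data.frame(
                    chrom = chrom, pos0 = p - 1L, level = pSite,
                    domainLevel = lev, label = lab, stringsAsFactors = FALSE)
            }
            if (emitNonCpG) {
                emitCtx <- function(positions, strand, context) {
                    if (length(positions) == 0L) return(NULL)
                    if (nonCpGFraction < 1) {
                        keep <- stats::runif(length(positions)) < nonCpGFraction
                        positions <- positions[keep]
                        if (length(positions) == 0L) return(NULL)
                    }
                    cov <- stats::rpois(length(positions), meanCoverage / 2)
                    meth <- stats::rbinom(length(positions), cov, cf)
                    k <- cov > 0L
                    if (!any(k)) return(NULL)
                    data.frame(chrom = chrom, pos0 = positions[k] - 1L,
                               strand = strand, context = context,
                               meth = meth[k], total = cov[k],
                               stringsAsFactors = FALSE)
                }
                callPieces <- c(callPieces, Filter(Negate(is.null), list(
                    emitCtx(pos$plusCHG, "+", "CHG"),
                    emitCtx(pos$plusCHH, "+", "CHH"),
                    emitCtx(pos$minusCHG, "-", "CHG"),
                    emitCtx(pos$minusCHH, "-", "CHH"))))
            }
        }
        calls <- do.call(rbind, callPieces)
        calls <- calls[order(match(calls$chrom, names(genome)), calls$pos0,
                             calls$strand), , drop = FALSE]
        rownames(calls) <- NULL
        truth <- do.call(rbind, truthPieces)
        rownames(truth) <- NULL
        list(calls = calls, truth = list(siteLevels = truth, plan = plan))
    })
}
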