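test_that("windowize conserves counts and emits missing symbols in gaps", {
    sl <- c(chr1 = 10000)
    pos <- c(seq(100, 2900, by = 100), seq(7100, 9900, by = 100))
    n <- length(pos)
    set.seed(2)
    tot <- rpois(n, 6) + 1
    smp <- sampleFromSites(pos, rbinom(n, tot, 0.8), tot, sl = sl)
    win <- windowize(smp, windowBp = 1000)
    expect_equal(nrow(win), 10L)
    expect_equal(sum(win$meth), sum(S4Vectors::mcols(records(smp))$meth))
    expect_equal(sum(win$total), sum(S4Vectors::mcols(records(smp))$total))
    ## the 3-7 kb gap gives missing windows
    expect_equal(sum(is.na(win$value)), 4L)
    expect_error(windowize(smp, windowBp = 50), "windowBp")
    ## constant methylome -> constant values
    smpC <- sampleFromSites(seq(50, 9950, by = 50),
                            meth = rep(4, 199), total = rep(5, 199), sl = sl)
    winC <- windowize(smpC, 1000)
    expect_true(all(abs(winC$value - 0.8) < 1e-12))
})

test_that("stratified training pools fill from a bimodal methylome", {
    sl <- c(chr1 = 1e6)
    g <- makeGenome(sl, gcFraction = 0.45, seed = 31)
    plan <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 500001), c(500000, 1e6)), seqlengths = sl)
    S4Vectors::mcols(plan)$label <- c("HMD", "PMD")
    S4Vectors::mcols(plan)$meanLevel <- c(0.85, 0.40)
    sim <- simulateMethylome(g, plan, meanCoverage = 10, emitNonCpG = FALSE,
                             seed = 32)
    smp <- coverageFilter(asMethylomeSample(sim$calls, "S", seqlengths = sl))
    pools <- sampleTrainingWindows(smp, nRegions = 100, minPool = 30, seed = 33)
    expect_gte(length(pools$PMD), 30)
    expect_gte(length(pools$HMD), 30)
    expect_true(all(S4Vectors::mcols(pools$PMD)$meth >= 0.25 &
                    S4Vectors::mcols(pools$PMD)$meth <= 0.55))
    expect_true(all(S4Vectors::mcols(pools$HMD)$meth >= 0.60))
    ## determinism
    pools2 <- sampleTrainingWindows(smp, nRegions = 100, minPool = 30, seed = 33)
    expect_identical(as.data.frame(pools$PMD), as.data.frame(pools2$PMD))
    ## uniform methylome: PMD stratum cannot be filled
    S4Vectors::mcols(plan)$meanLevel <- c(0.9, 0.9)
    simU <- simulateMethylome(g, plan, meanCoverage = 10, emitNonCpG = FALSE,
                              seed = 34)
    smpU <- coverageFilter(asMethylomeSample(simU$calls, "U", seqlengths = sl))
    expect_error(sampleTrainingWindows(smpU, nRegions = 50, minPool = 10,
                                       seed = 35), "PMD")
})

test_that("emission fitting produces normalized pmfs centered on pool levels", {
    sl <- c(chr1 = 1e6)
    g <- makeGenome(sl, gcFraction = 0.45, seed = 41)
    plan <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 500001), c(500000, 1e6)), seqlengths = sl)
    S4Vectors::mcols(plan)$label <- c("HMD", "PMD")
    S4Vectors::mcols(plan)$meanLevel <- c(0.85, 0.40)
    sim <- simulateMethylome(g, plan, meanCoverage = 10, emitNonCpG = FALSE,
                             seed = 42)
    smp <- coverageFilter(asMethylomeSample(sim$calls, "S", seqlengths = sl))
    win <- windowize(smp, 1000)
    pools <- sampleTrainingWindows(smp, nRegions = 150, minPool = 40, seed = 43)
    emis <- fitEmissions(win, pools, K = 20)
    for (st in c("HMD", "PMD")) {
        expect_equal(sum(emis[[st]]), 1, tolerance = 1e-12)
        expect_true(all(emis[[st]] > 0))
    }
    ## moment check: pmf means (bin centers, excluding the missing symbol)
    centers <- (seq_len(20) - 0.5) / 20
    for (st in c("HMD", "PMD")) {
        pmf <- emis[[st]][1:20] / sum(emis[[st]][1:20])
        m <- sum(pmf * centers)
        expected <- mean(S4Vectors::mcols(pools[[st]])$meth)
        expect_lt(abs(m - expected), 0.03)
    }
    expect_error(fitEmissions(win, pools, K = 1), "K")
})

test_that("Viterbi decoding equals exhaustive path enumeration", {
    set.seed(77)
    K <- 6
    for (rep in 1:20) {
        n <- sample(8:12, 1)
        eH <- runif(K + 1) + 0.05; eH <- eH / sum(eH)
        eP <- runif(K + 1) + 0.05; eP <- eP / sum(eP)
        pSelf <- runif(1, 0.5, 0.99)
        tr <- matrix(c(pSelf, 1 - pSelf, 1 - pSelf, pSelf), 2, byrow = TRUE)
        init <- c(0.5, 0.5)
        symbols <- sample.int(K + 1, n, replace = TRUE)
        logE <- rbind(log(eH), log(eP))
        got <- agsmeth:::.viterbi(symbols, logE, log(tr), log(init))
        want <- viterbiEnumOracle(symbols, logE, log(tr), log(init))
        expect_identical(got, want, info = paste("rep", rep))
    }
})

test_that("saturated observation sequences decode to a single domain", {
    sl <- c(chr1 = 50000)
    mkSample <- function(level) {
        pos <- seq(20, 49980, by = 40)
        tot <- rep(10L, length(pos))
        sampleFromSites(pos, round(tot * level), tot, sl = sl)
    }
    win <- windowize(mkSample(0.9), 1000)
    emis <- list(HMD = c(rep(0.001, 20), 0.05), PMD = c(rep(0.001, 20), 0.05))
    emis$HMD[19] <- 1 - sum(emis$HMD[-19])   # mass near 0.9
    emis$PMD[9] <- 1 - sum(emis$PMD[-9])     # mass near 0.4
    hmm <- buildDomainHMM(emis, windowBp = 1000)
    seg <- viterbiSegment(win, hmm)
    d <- domains(seg)
    expect_equal(length(d), 1L)
    expect_equal(S4Vectors::mcols(d)$label, "HMD")
    expect_equal(BiocGenerics::width(d), 50000)
    segLow <- viterbiSegment(windowize(mkSample(0.4), 1000), hmm)
    expect_equal(S4Vectors::mcols(domains(segLow))$label, "PMD")
})

test_that("post-processing absorbs short domains and conserves bp", {
    mkSeg <- function(df) {
        gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
        S4Vectors::mcols(gr)$label <- df$label
        S4Vectors::mcols(gr)$meanMeth <- df$meth / pmax(df$total, 1)
        S4Vectors::mcols(gr)$nWindows <- df$nw
        S4Vectors::mcols(gr)$meth <- df$meth
        S4Vectors::mcols(gr)$total <- df$total
        methods::new("DomainSegmentation", domains = gr, windowBp = 1000)
    }
    ## 5-kb PMD inside an HMD is absorbed
    df <- data.frame(chrom = "chr1",
                     start = c(1, 40001, 45001), end = c(40000, 45000, 100000),
                     label = c("HMD", "PMD", "HMD"),
                     meth = c(800, 20, 900), total = c(1000, 50, 1100),
                     nw = c(40, 5, 55))
    out <- postprocessSegmentation(mkSeg(df), minDomainBp = 10000)
    d <- domains(out)
    expect_equal(length(d), 1L)
    expect_equal(S4Vectors::mcols(d)$label, "HMD")
    expect_equal(sum(BiocGenerics::width(d)), 100000)
    ## no short domains: fixpoint
    df2 <- data.frame(chrom = "chr1",
                      start = c(1, 50001), end = c(50000, 100000),
                      label = c("HMD", "PMD"),
                      meth = c(900, 300), total = c(1000, 800), nw = c(50, 50))
    out2 <- postprocessSegmentation(mkSeg(df2), minDomainBp = 10000)
    expect_equal(as.data.frame(domains(out2))[, 1:3],
                 as.data.frame(domains(mkSeg(df2)))[, 1:3])
    ## alternation: no two adjacent domains share a label
    lab <- S4Vectors::mcols(domains(out2))$label
    expect_true(all(lab[-1] != lab[-length(lab)]))
})

test_that("PMD comparison matches per-bp set arithmetic on a toy genome", {
    L <- 100000
    set.seed(88)
    mkSet <- function() {
        s <- sort(sample(1:(L - 5000), 8))
        GenomicRanges::reduce(GenomicRanges::GRanges("chr1",
            IRanges::IRanges(s, width = sample(2000:8000, 8, replace = TRUE))))
    }
    a <- mkSet(); b <- mkSet()
    cmp <- comparePmds(A = a, B = b)
    bm <- bitmapOverlapBp(a, b, L + 10000)
    expect_equal(cmp$jaccard["A", "B"], bm["overlap"] / bm["union"],
                 ignore_attr = TRUE)
    ## identity and disjoint cases
    expect_equal(comparePmds(A = a, B = a)$jaccard["A", "B"], 1,
                 ignore_attr = TRUE)
    left <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
    right <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000))
    cmpD <- comparePmds(L = left, R = right)
    expect_equal(cmpD$jaccard["L", "R"], 0, ignore_attr = TRUE)
    ## three-way Venn bp sums to union bp
    c3 <- mkSet()
    cmp3 <- comparePmds(A = a, B = b, C = c3)
    uni <- sum(BiocGenerics::width(GenomicRanges::reduce(c(a, b, c3))))
    expect_equal(sum(cmp3$venn$bp), uni)
})

test_that("label-swap symmetry: inverting methylation swaps HMD and PMD calls", {
    sl <- c(chr1 = 4e5)
    g <- makeGenome(sl, gcFraction = 0.45, seed = 91)
    plan <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 150001, 250001), c(150000, 250000, 4e5)),
        seqlengths = sl)
    S4Vectors::mcols(plan)$label <- c("HMD", "PMD", "HMD")
    S4Vectors::mcols(plan)$meanLevel <- c(0.85, 0.40, 0.85)
    sim <- simulateMethylome(g, plan, meanCoverage = 10, emitNonCpG = FALSE,
                             conversionFailureRate = 0, seed = 92)
    smp <- coverageFilter(asMethylomeSample(sim$calls, "S", seqlengths = sl))
    ## inverted sample: meth -> total - meth
    inv <- sim$calls
    inv$meth <- inv$total - inv$meth
    smpInv <- coverageFilter(asMethylomeSample(inv, "I", seqlengths = sl))
    strata <- list(PMD = c(0.25, 0.55), HMD = c(0.60, 1.00))
    strataInv <- list(PMD = c(0.45, 0.75), HMD = c(0.00, 0.40))
    seg <- segmentMethylome(smp, nRegions = 100, minPool = 20,
                            strata = strata, seed = 93)
    segInv <- segmentMethylome(smpInv, nRegions = 100, minPool = 20,
                               strata = strataInv, seed = 93)
    dA <- domains(seg); dB <- domains(segInv)
    pmdA <- GenomicRanges::reduce(dA[S4Vectors::mcols(dA)$label == "PMD"])
    pmdB <- GenomicRanges::reduce(dB[S4Vectors::mcols(dB)$label == "PMD"])
    inter <- sum(BiocGenerics::width(GenomicRanges::intersect(pmdA, pmdB)))
    uni <- sum(BiocGenerics::width(GenomicRanges::union(pmdA, pmdB)))
    expect_gt(inter / uni, 0.95)
})
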