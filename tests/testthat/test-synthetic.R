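test_that("genome generator respects composition, determinism and degeneracy", {
    ## degenerate composition: no GC at all
    g0 <- makeGenome(c(chr1 = 2000), gcFraction = 0, seed = 3)
    expect_true(all(strsplit(as.character(g0[[1]]), "")[[1]] %in% c("A", "T")))
    ## determinism: identical seed -> byte-identical sequence
    g1 <- makeGenome(c(chr1 = 50000, chr2 = 20000), gcFraction = 0.5, seed = 7)
    g2 <- makeGenome(c(chr1 = 50000, chr2 = 20000), gcFraction = 0.5, seed = 7)
    expect_identical(as.character(g1), as.character(g2))
    g3 <- makeGenome(c(chr1 = 50000, chr2 = 20000), gcFraction = 0.5, seed = 8)
    expect_false(identical(as.character(g1), as.character(g3)))
    ## binomial oracle: observed GC within 3 SDs of target at 1 Mb
    L <- 1e6; gc <- 0.42
    g <- makeGenome(c(chr1 = L), gcFraction = gc, seed = 11)
    obs <- sum(Biostrings::letterFrequency(g[[1]], c("G", "C")))
    expect_lt(abs(obs - gc * L), 3 * sqrt(L * gc * (1 - gc)))
})

test_that("skew blocks tilt the G/C split and reject bad input", {
    blk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 60000))
    S4Vectors::mcols(blk)$skew <- 0.4
    g <- makeGenome(c(chr1 = 1e5), gcFraction = 0.5, skewBlocks = blk, seed = 5)
    sub <- Biostrings::subseq(g[[1]], 10001, 60000)
    nG <- Biostrings::letterFrequency(sub, "G")
    nC <- Biostrings::letterFrequency(sub, "C")
    ## P(G) - P(C) = skew * gc = 0.2; binomial tolerance
    expect_lt(abs((nG - nC) / 50000 - 0.2), 3 * sqrt(0.5 / 50000) * 2)
    ## overlapping blocks rejected
    blk2 <- c(blk, blk)
    expect_error(makeGenome(c(chr1 = 1e5), 0.5, blk2, seed = 1), "overlap")
    ## out-of-bounds rejected
    blk3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90000, 120000))
    S4Vectors::mcols(blk3)$skew <- 0.2
    expect_error(makeGenome(c(chr1 = 1e5), 0.5, blk3, seed = 1), "bounds")
})

test_that("annotation partitions each chromosome into genes and intergenic", {
    g <- tinyGenome(2e5, seed = 2)
    anno <- makeAnnotation(g, nGenes = 6, repeatDensity = c(LINE = 0.2), seed = 4)
    covered <- GenomicRanges::reduce(c(
        GenomicRanges::granges(anno$genes), anno$intergenic),
        ignore.strand = TRUE)
    expect_equal(sum(BiocGenerics::width(covered)), 2e5)
    expect_equal(sum(BiocGenerics::width(GenomicRanges::intersect(
        GenomicRanges::granges(anno$genes), anno$intergenic,
        ignore.strand = TRUE))), 0)
    ## n_genes = 0 -> intergenic is the whole genome
    anno0 <- makeAnnotation(g, nGenes = 0, repeatDensity = c(LINE = 0), seed = 4)
    expect_equal(sum(BiocGenerics::width(anno0$intergenic)), 2e5)
    ## repeats live inside intergenic and approach the requested density
    ig <- sum(BiocGenerics::width(anno$intergenic))
    lineBp <- sum(BiocGenerics::width(anno$LINE))
    expect_true(all(IRanges::overlapsAny(anno$LINE, anno$intergenic,
                                         type = "within")))
    expect_gt(lineBp / ig, 0.1)   # target 0.2, placement is stochastic
    expect_lt(lineBp / ig, 0.35)
})

test_that("methylome simulator produces saturated and planted-level output", {
    sl <- c(chr1 = 50000)
    g <- makeGenome(sl, gcFraction = 0.5, seed = 9)
    ## saturated case: mean level 1, no site variation, no conversion failure
    plan <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50000),
                                   seqlengths = sl)
    S4Vectors::mcols(plan)$label <- "HMD"
    S4Vectors::mcols(plan)$meanLevel <- 1.0
    sim <- simulateMethylome(g, plan, meanCoverage = 6,
                             conversionFailureRate = 0, dispersion = Inf,
                             emitNonCpG = FALSE, seed = 1)
    expect_true(all(sim$calls$meth == sim$calls$total))
    expect_true(all(sim$calls$context == "CG"))
    ## planted PMD level recovered within 3 binomial SDs
    S4Vectors::mcols(plan)$meanLevel <- 0.40
    S4Vectors::mcols(plan)$label <- "PMD"
    sim2 <- simulateMethylome(g, plan, meanCoverage = 10, dispersion = 30,
                              conversionFailureRate = 0, emitNonCpG = FALSE,
                              seed = 2)
    p <- sum(sim2$calls$meth) / sum(sim2$calls$total)
    n <- sum(sim2$calls$total)
    ## allow for Beta dispersion on top of binomial sampling
    sdTot <- sqrt(0.4 * 0.6 / n) + sqrt(0.4 * 0.6 / 31 / length(unique(sim2$calls$pos0)))
    expect_lt(abs(p - 0.40), 3 * sdTot + 0.01)
    ## plan outside genome rejected
    bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 60000))
    S4Vectors::mcols(bad)$meanLevel <- 0.5
    expect_error(simulateMethylome(g, bad, seed = 1), "outside")
})

test_that("conversion failures surface in non-CpG contexts at the planted rate", {
    sl <- c(chr1 = 2e5)
    g <- makeGenome(sl, gcFraction = 0.5, seed = 13)
    plan <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e5),
                                   seqlengths = sl)
    S4Vectors::mcols(plan)$meanLevel <- 0.8
    sim <- simulateMethylome(g, plan, meanCoverage = 6,
                             conversionFailureRate = 0.005, seed = 3)
    nonCpG <- sim$calls[sim$calls$context != "CG", ]
    expect_gt(nrow(nonCpG), 1e4)
    rate <- conversionRate(sim$calls)
    expect_lt(abs(rate - 0.995), 0.002)
})

test_that("DRIP simulator honors degenerate plans and replicate structure", {
    g <- tinyGenome(1e5, seed = 21)
    frags <- digestGenome(g)
    ## null plan: nothing anywhere
    d0 <- simulateDripSamples(frags, sampleIds = "AGS2", pCommon = 0,
                              pControlUnique = 0, pUnique = 0, seed = 1)
    expect_true(all(vapply(d0$replicates,
                           function(r) length(r$rep1) + length(r$rep2),
                           numeric(1)) == 0))
    ## no dropout -> replicates identical
    d1 <- simulateDripSamples(frags, sampleIds = c("AGS2", "AGS4"),
                              dropout = 0, seed = 2)
    for (s in names(d1$replicates))
        expect_identical(d1$replicates[[s]]$rep1, d1$replicates[[s]]$rep2)
    ## empty fragment set rejected
    expect_error(simulateDripSamples(GenomicRanges::GRanges(), seed = 1),
                 "empty")
    ## planted common fraction recovered within 3 binomial SDs
    sl <- c(chr1 = 2e6)
    g2 <- makeGenome(sl, gcFraction = 0.45, seed = 22)
    frags2 <- digestGenome(g2)
    d2 <- simulateDripSamples(frags2, sampleIds = "AGS2", pCommon = 0.3,
                              pControlUnique = 0, pUnique = 0, dropout = 0,
                              seed = 3)
    nf <- length(frags2)
    obs <- sum(d2$truth$label == "common") / nf
    expect_lt(abs(obs - 0.3), 3 * sqrt(0.3 * 0.7 / nf))
    ## common fragments are positive in control and at least one AGS sample
    commons <- d2$truth$id[d2$truth$label == "common"]
    expect_true(all(commons %in% d2$replicates$CTRL$rep1))
    expect_true(all(commons %in% d2$replicates$AGS2$rep1))
})

test_that("clone simulator covers saturated, converted and intermediate cases", {
    ref <- "ATTACGATTTACGTTTAACGTTA"
    ## fully methylated: every CpG stays C
    cs1 <- simulateCloneSet(ref, 1, nClones = 4, seed = 1)
    for (s in as.character(cs1$clones))
        expect_identical(substring(s, cs1$cpgPositions, cs1$cpgPositions),
                         rep("C", length(cs1$cpgPositions)))
    ## unmethylated, perfect conversion: every cytosine reads T
    cs0 <- simulateCloneSet(ref, 0, nClones = 4, conversionFailureRate = 0,
                            seed = 2)
    for (s in as.character(cs0$clones))
        expect_false(grepl("C", s))
    ## binomial oracle at one site
    refOne <- "ATTTTTACGATTTTTT"
    csb <- simulateCloneSet(refOne, 0.75, nClones = 400, seed = 3)
    frac <- mean(csb$truth[, 1])
    expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 400))
    ## invalid probability rejected
    expect_error(simulateCloneSet(ref, 1.5, seed = 1), "\\[0, 1\\]")
    expect_error(simulateCloneSet("ATTA", 0.5, seed = 1), "no CpG")
})

test_that("generators are deterministic under a fixed master seed", {
    sl <- c(chr1 = 3e4)
    g <- makeGenome(sl, seed = 5)
    p <- planDomains(sl, seed = 5)
    a <- simulateMethylome(g, p, seed = 9, nonCpGFraction = 0.3)
    b <- simulateMethylome(g, p, seed = 9, nonCpGFraction = 0.3)
    expect_identical(a$calls, b$calls)
    expect_identical(a$truth$siteLevels, b$truth$siteLevels)
    f <- digestGenome(g)
    d1 <- simulateDripSamples(f, seed = 4)
    d2 <- simulateDripSamples(f, seed = 4)
    expect_identical(d1$truth, d2$truth)
    expect_identical(d1$replicates, d2$replicates)
})
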