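test_that("percent length overlap matches a per-bp bitmap oracle", {
    q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 500), c(199, 799)))
    f <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 1000))
    expect_equal(percentLengthOverlap(q, f), 100)
    fDisj <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 3000))
    expect_equal(percentLengthOverlap(q, fDisj), 0)
    expect_error(percentLengthOverlap(q[0], f), "empty query")
    set.seed(17)
    L <- 100000
    rnd <- function(n) GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sample(1:(L - 3000), n),
                         width = sample(100:3000, n, replace = TRUE)))
    for (i in 1:5) {
        qq <- rnd(15); ff <- rnd(10)
        bm <- bitmapOverlapBp(qq, ff, L + 3000)
        expect_equal(percentLengthOverlap(qq, ff),
                     100 * bm[["overlap"]] / bm[["query"]])
    }
})

test_that("percent overlap over a feature partition sums to 100%", {
    set.seed(18)
    L <- 50000
    q <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sample(1:(L - 2000), 10), width = 500))
    cuts <- c(1, sort(sample(2:L, 5)), L + 1)
    parts <- lapply(seq_len(length(cuts) - 1), function(i)
        GenomicRanges::GRanges("chr1",
            IRanges::IRanges(cuts[i], cuts[i + 1] - 1)))
    total <- sum(vapply(parts, function(p) percentLengthOverlap(q, p),
                        numeric(1)))
    expect_equal(total, 100, tolerance = 1e-12)
})

test_that("fold change vs common has identity and arithmetic behavior", {
    common <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
    feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
    expect_equal(foldChangeVsCommon(common, common, feat)$fold, 1)
    uniq <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200))
    fc <- foldChangeVsCommon(uniq, common, feat)   # 50% vs 10%
    expect_equal(fc$fold, 5)
    expect_equal(fc$direction, "enriched")
    farFeat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100))
    expect_warning(fcInf <- foldChangeVsCommon(uniq, common, farFeat),
                   "infinite")
    expect_true(is.infinite(fcInf$fold))
})

test_that("shuffles are contained in common peaks with uniform placement", {
    sl <- c(chr1 = 1e5)
    common <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1000, 30000, 60000), width = c(2000, 500, 4000)),
        seqlengths = sl)
    set.seed(23)
    for (i in 1:50) {
        sh <- shuffleFromCommon(400, common)
        expect_equal(BiocGenerics::width(sh), 400)
        expect_true(any(BiocGenerics::start(sh) >= BiocGenerics::start(common) &
                        BiocGenerics::end(sh) <= BiocGenerics::end(common)))
    }
    ## query equal to the common peak length: whole peaks, uniformly
    eq <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(100, 5000), width = 800), seqlengths = sl)
    set.seed(24)
    draws <- vapply(1:200, function(i)
        BiocGenerics::start(shuffleFromCommon(800, eq)), numeric(1))
    expect_true(all(draws %in% c(100, 5000)))
    expect_gt(mean(draws == 100), 0.35)  # ~0.5 each
    ## no long-enough peak: longest returned whole, with a message
    expect_message(whole <- shuffleFromCommon(5000, common), "longest")
    expect_equal(BiocGenerics::width(whole), 4000)
    expect_error(shuffleFromCommon(10, common[0]), "empty")
    ## start-position uniformity within donors (chi-square-style bound)
    one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1099),
                                  seqlengths = sl)
    set.seed(25)
    starts <- vapply(1:4000, function(i)
        BiocGenerics::start(shuffleFromCommon(50, one)), numeric(1))
    tb <- table(factor(starts, levels = 1000:1050))
    expected <- 4000 / 51
    ## each valid start within 4 SDs of uniform expectation
    expect_true(all(abs(tb - expected) < 4 * sqrt(expected)))
})

test_that("Monte Carlo enrichment is reproducible with a valid p floor", {
    sl <- c(chr1 = 2e5)
    set.seed(31)
    common <- GenomicRanges::reduce(GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sample(1:180000, 80), width = 1500), seqlengths = sl))
    feat <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, 199000, 20000), width = 8000), seqlengths = sl)
    uniq <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sample(1:198000, 25), width = 800), seqlengths = sl)
    r1 <- monteCarloEnrichment(uniq, common, feat, nShuffles = 200, seed = 5)
    r2 <- monteCarloEnrichment(uniq, common, feat, nShuffles = 200, seed = 5)
    expect_identical(r1@nullPcts, r2@nullPcts)
    expect_identical(r1@empiricalP, r2@empiricalP)
    expect_gte(r1@empiricalP, 1 / 201)
    expect_error(monteCarloEnrichment(uniq, common, feat, nShuffles = 0),
                 "nShuffles")
    ## strong planted bias: minimum p, enriched
    inFeat <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(2000, 190000, 20000), width = 500),
        seqlengths = sl)
    rStrong <- monteCarloEnrichment(inFeat, common, feat, nShuffles = 500,
                                    seed = 6)
    expect_equal(rStrong@empiricalP, 1 / 501)
    expect_equal(rStrong@direction, "enriched")
})

test_that("GC-skew caller saturates on poly-G and recovers planted blocks", {
    polyG <- Biostrings::DNAStringSet(c(chr1 = paste(rep("G", 2000),
                                                     collapse = "")))
    blocks <- gcSkewBlocks(polyG)
    expect_equal(length(blocks), 1L)
    expect_equal(S4Vectors::mcols(blocks)$skew, 1.0)
    expect_equal(S4Vectors::mcols(blocks)$sign, "+")
    ## planted skew block mostly recovered
    blk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(40001, 48000))
    S4Vectors::mcols(blk)$skew <- 0.3
    g <- makeGenome(c(chr1 = 1e5), gcFraction = 0.42, skewBlocks = blk,
                    seed = 44)
    called <- gcSkewBlocks(g)
    rec <- sum(BiocGenerics::width(GenomicRanges::intersect(
        called[S4Vectors::mcols(called)$sign == "+"], blk,
        ignore.strand = TRUE)))
    expect_gt(rec / 8000, 0.8)
    expect_error(gcSkewBlocks(g, window = 0), "window")
    ## skew-free sequence: the run requirement suppresses single-window
    ## noise (~15% of windows exceed the threshold by chance alone)
    gNull <- makeGenome(c(chr1 = 1e6), gcFraction = 0.42, seed = 45)
    nullBlocks <- gcSkewBlocks(gNull)
    expect_lt(sum(BiocGenerics::width(nullBlocks)) / 1e6, 0.10)
})

test_that("skew overlap percentages are peak-count based", {
    blocks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
    inside <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1100, 1500), width = 100))
    outside <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(5000, 9000), width = 100))
    res <- overlapWithSkew(list(all_in = inside, all_out = outside,
                                none = inside[0]), blocks)
    expect_equal(unname(res["all_in"]), 100)
    expect_equal(unname(res["all_out"]), 0)
    expect_true(is.na(res["none"]))
})

test_that("domain occupancy uses the midpoint half-open convention", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 10001), c(10000, 20000)))
    S4Vectors::mcols(gr)$label <- c("HMD", "PMD")
    S4Vectors::mcols(gr)$meanMeth <- c(0.8, 0.4)
    S4Vectors::mcols(gr)$nWindows <- c(10, 10)
    S4Vectors::mcols(gr)$meth <- c(1, 1)
    S4Vectors::mcols(gr)$total <- c(1, 1)
    seg <- methods::new("DomainSegmentation", domains = gr, windowBp = 1000)
    ## peak with 0-based midpoint exactly at the boundary (10000) ->
    ## 1-based 10001 -> right-hand (PMD) domain
    boundary <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9901, 10101))
    occ <- domainOccupancy(list(x = boundary), seg)
    expect_equal(occ$pctPMD, 100)
    inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 3000))
    expect_equal(domainOccupancy(list(x = inside), seg)$pctHMD, 100)
    ## gap midpoints are reported unassigned
    gap <- GenomicRanges::GRanges("chr1", IRanges::IRanges(25000, 26000))
    expect_equal(domainOccupancy(list(x = gap), seg)$pctUnassigned, 100)
    ## brute-force midpoint lookup on random peaks
    set.seed(71)
    pk <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sample(1:24000, 50), width = 150))
    occR <- domainOccupancy(list(x = pk), seg)
    mids <- (BiocGenerics::start(pk) - 1 + BiocGenerics::end(pk)) %/% 2 + 1
    wantPmd <- mean(mids >= 10001 & mids <= 20000) * 100
    expect_equal(occR$pctPMD, wantPmd)
})

test_that("fold change vs genome behaves at identity and known ratios", {
    sl <- c(chr1 = 1e5)
    mark <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000),
                                   seqlengths = sl)
    whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5),
                                    seqlengths = sl)
    res <- foldChangeVsGenome(whole, mark, sl, nShuffles = 50, seed = 3)
    expect_equal(res$fold, 1)
    ## query 30% in a 10% mark -> fold 3
    q <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 20000, 30000), width = c(3000, 3500, 3500)),
        seqlengths = sl)
    res2 <- foldChangeVsGenome(q, mark, sl, nShuffles = 50, seed = 3)
    expect_equal(res2$fold, (3000 / 10000) / 0.1)
    expect_error(foldChangeVsGenome(q, mark[0], sl), "0 bp")
    ## null placement: fold close to 1 across replicates
    set.seed(9)
    nullQ <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sample(1:90000, 40), width = 1000), seqlengths = sl)
    res3 <- foldChangeVsGenome(nullQ, mark, sl, nShuffles = 200, seed = 4)
    expect_gt(res3$empiricalP, 0.01)
})

test_that("peak methylation comparison flags planted hypomethylation", {
    sl <- c(chr1 = 2e5)
    set.seed(81)
    peakStarts <- seq(1000, 190000, by = 4000)
    peaks <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(peakStarts, width = 2000), seqlengths = sl)
    pos <- sort(sample(seq(2, 2e5 - 2, 2), 4000))
    tot <- rpois(length(pos), 10) + 2
    mkSample <- function(id, level) {
        sampleFromSites(pos, rbinom(length(pos), tot, level), tot,
                        sl = sl, id = id)
    }
    ctrl <- mkSample("CTRL", 0.8)
    low <- mkSample("AGS4", 0.6)
    res <- peakMethylationBySample(list(peaks = peaks),
                                   list(CTRL = ctrl, AGS4 = low), "CTRL")
    expect_lt(res$peaks$tests$AGS4$p, 1e-6)
    ## identical methylomes: no evidence of hypomethylation
    same <- peakMethylationBySample(list(peaks = peaks),
                                    list(CTRL = ctrl, AGS4 = ctrl), "CTRL")
    expect_true(is.na(same$peaks$tests$AGS4$p) ||
                same$peaks$tests$AGS4$p >= 0.5)
})
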