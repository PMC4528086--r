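## Independent oracles used across the suite. Each is deliberately
## brute-force and shares no code with the implementation it checks.

## exact one-sided paired Wilcoxon p (H1: a < b) by enumerating all 2^n
## sign assignments of the absolute-difference ranks
wilcoxonEnumOracle <- function(a, b) {
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    stopifnot(n >= 1, n <= 16)
    r <- rank(abs(d))
    vObs <- sum(r[d > 0])                  # positive-rank statistic
    total <- 0L
    for (mask in 0:(2^n - 1)) {
        signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
        v <- sum(r[signs])
        if (v <= vObs) total <- total + 1L
    }
    total / 2^n
}

## brute-force Viterbi by enumerating all 2^n state paths
viterbiEnumOracle <- function(symbols, logE, logT, logI) {
    n <- length(symbols)
    best <- -Inf; bestPath <- NULL
    for (mask in 0:(2^n - 1)) {
        path <- bitwAnd(mask, 2^(0:(n - 1))) > 0
        st <- ifelse(path, 2L, 1L)
        lp <- logI[st[1]] + logE[st[1], symbols[1]]
        if (n > 1) for (t in 2:n)
            lp <- lp + logT[st[t - 1], st[t]] + logE[st[t], symbols[t]]
        ## strict > keeps the first (lexicographically smallest = most
        ## HMD-leaning) maximizing path, matching the tie rule
        if (lp > best + 1e-12) { best <- lp; bestPath <- st }
    }
    bestPath
}

## per-bp bitmap overlap oracle on a small single-chromosome genome
bitmapOverlapBp <- function(query, feature, L) {
    qv <- logical(L); fv <- logical(L)
    for (i in seq_along(query))
        qv[BiocGenerics::start(query)[i]:BiocGenerics::end(query)[i]] <- TRUE
    for (i in seq_along(feature))
        fv[BiocGenerics::start(feature)[i]:BiocGenerics::end(feature)[i]] <- TRUE
    c(overlap = sum(qv & fv), query = sum(qv), union = sum(qv | fv))
}

## naive string-scan digest oracle: cut positions for one enzyme
naiveCutPositions <- function(seqChar, site, offset) {
    L <- nchar(seqChar)
    w <- nchar(site)
    cuts <- integer(0)
    if (L >= w) for (p in 1:(L - w + 1))
        if (substr(seqChar, p, p + w - 1) == site)
            cuts <- c(cuts, p - 1L + offset)
    cuts
}

## small random genome helper
tinyGenome <- function(L = 5000, seed = 1, gc = 0.45, name = "chr1") {
    makeGenome(stats::setNames(L, name), gcFraction = gc, seed = seed)
}

## build a MethylomeSample directly from per-dyad counts
sampleFromSites <- function(pos, meth, total, chrom = "chr1", sl = NULL,
                            id = "S") {
    calls <- data.frame(chrom = chrom, pos0 = pos, strand = "+",
                        context = "CG", meth = meth, total = total)
    asMethylomeSample(calls, id, seqlengths = sl)
}
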