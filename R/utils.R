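## Internal plumbing shared across modules: reproducible named RNG
## substreams and fast linearized interval arithmetic.

#' Derive a substream seed from a master seed and a stream name
#'
#' All randomness in the package flows from a single master seed; each
#' stage (genome, methylome, peaks, clones, ...) draws from a substream
#' derived by hashing a stable stream name, so stages can be re-run
#' individually with identical results.
#'
#' @param master Integer master seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substreamSeed <- function(master, stream) {
    stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
    h <- 0
    for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
    as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 + h) %% 2147483647)
}

## Evaluate `expr` under `set.seed(seed)` without disturbing the caller's
## RNG state.
withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed %% 2147483647))
    expr
}

## ---- linearized interval arithmetic -------------------------------------
## Several Monte Carlo loops need hundreds of thousands of interval-overlap
## queries; doing these through GRanges would dominate runtime, so intervals
## are mapped onto one linear axis (chromosomes laid end to end) and overlap
## is computed with cumulative-coverage lookups.

## Offsets that lay chromosomes end to end. `seqlengths` named numeric.
.chromOffsets <- function(seqlengths) {
    off <- cumsum(c(0, as.numeric(seqlengths)))[seq_along(seqlengths)]
    names(off) <- names(seqlengths)
    off
}

## GRanges -> 0-based half-open linearized intervals (list with start, end).
.linearize <- function(gr, offsets) {
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    bad <- !(chr %in% names(offsets))
    if (any(bad)) stop("intervals on unknown chromosome: ",
                       paste(unique(chr[bad]), collapse = ", "))
    o <- offsets[chr]
    list(start = o + BiocGenerics::start(gr) - 1,
         end   = o + BiocGenerics::end(gr))
}

## Linearized 0-based half-open intervals -> GRanges.
.delinearize <- function(start, end, offsets, seqlengths) {
    bounds <- c(as.numeric(offsets), sum(as.numeric(seqlengths)))
    idx <- findInterval(start, as.numeric(offsets))
    chr <- names(offsets)[idx]
    GenomicRanges::GRanges(chr,
        IRanges::IRanges(start = start - offsets[idx] + 1,
                         end = end - offsets[idx]),
        seqlengths = seqlengths)
}

## Merge (reduce) sorted-or-not 0-based half-open intervals.
.reduceIntervals <- function(s, e) {
    if (length(s) == 0L) return(list(start = numeric(0), end = numeric(0)))
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    keep_s <- numeric(length(s)); keep_e <- numeric(length(s))
    k <- 1L; cs <- s[1]; ce <- e[1]
    if (length(s) > 1L) for (i in 2L:length(s)) {
        if (s[i] <= ce) ce <- max(ce, e[i])
        else { keep_s[k] <- cs; keep_e[k] <- ce; k <- k + 1L; cs <- s[i]; ce <- e[i] }
    }
    keep_s[k] <- cs; keep_e[k] <- ce
    list(start = keep_s[seq_len(k)], end = keep_e[seq_len(k)])
}

## Cumulative-coverage closure over a reduced feature set. Returns a
## function C(x) = feature bp in (-Inf, x); overlap of [s,e) is C(e)-C(s).
.coverageLookup <- function(fs, fe) {
    if (length(fs) == 0L) return(function(x) rep(0, length(x)))
    w <- fe - fs
    cumBefore <- cumsum(c(0, w))
    function(x) {
        i <- findInterval(x, fs)
        out <- numeric(length(x))
        pos <- i >= 1L
        out[pos] <- cumBefore[i[pos]] +
            pmin(pmax(x[pos] - fs[i[pos]], 0), w[i[pos]])
        out
    }
}

## Overlap bp of each query [qs,qe) with a reduced feature set.
.coveredBp <- function(qs, qe, fs, fe) {
    cov <- .coverageLookup(fs, fe)
    cov(qe) - cov(qs)
}

## Weighted draw of length-matched subintervals from a donor interval set
## (0-based half-open, linearized). Each query length L picks a donor with
## probability proportional to its number of valid start positions
## (len - L + 1, donors shorter than L excluded), then a start uniformly.
## Queries longer than every donor fall back to the longest donor returned
## whole; the number of fallbacks is reported.
.shuffleMany <- function(L, ds, de) {
    if (length(ds) == 0L) stop("donor interval set is empty")
    lens <- de - ds
    ord <- order(lens, decreasing = TRUE)
    sl <- lens[ord]
    S <- cumsum(sl)
    n <- length(sl)
    asc <- rev(sl)                                  # ascending lengths
    k <- n - findInterval(L - 0.5, asc)             # donors with len >= L
    fallback <- k == 0L
    m <- length(L)
    outS <- numeric(m); outE <- numeric(m)
    if (any(fallback)) {
        j <- ord[1L]
        outS[fallback] <- ds[j]
        outE[fallback] <- de[j]
    }
    ok <- !fallback
    if (any(ok)) {
        Lk <- L[ok]; kk <- k[ok]
        Tk <- S[kk] - kk * (Lk - 1)                 # total valid starts
        u <- stats::runif(sum(ok)) * Tk
        lo <- rep(1L, length(u)); hi <- kk
        while (any(lo < hi)) {
            mid <- (lo + hi) %/% 2L
            val <- S[mid] - mid * (Lk - 1)
            take <- val >= u
            hi[take] <- mid[take]
            lo[!take] <- mid[!take] + 1L
        }
        j <- lo
        prev <- numeric(length(j))
        gt1 <- j > 1L
        prev[gt1] <- S[j[gt1] - 1L] - (j[gt1] - 1L) * (Lk[gt1] - 1)
        rem <- u - prev                             # in (0, valid starts of j]
        startOff <- pmin(ceiling(rem) - 1, sl[j] - Lk)
        startOff <- pmax(startOff, 0)
        di <- ord[j]
        outS[ok] <- ds[di] + startOff
        outE[ok] <- outS[ok] + Lk
    }
    list(start = outS, end = outE, fallbacks = sum(fallback))
}

## simple structural hash for provenance records
.configHash <- function(x) {
    txt <- paste(deparse(x), collapse = "")
    h <- 0
    for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
    sprintf("%08x", h)
}

.assertGRanges <- function(x, what = "argument") {
    if (!methods::is(x, "GRanges")) stop(what, " must be a GRanges object")
    invisible(x)
}
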