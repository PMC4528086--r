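## Bisulfite amplicon clone analysis: per-clone CpG calling against a
## reference amplicon, the clones x sites lollipop matrix, per-site
## percent methylation, and the KO-vs-scramble paired comparison.

#' Locate CpG sites in a reference sequence
#'
#' @param referenceSeq Character or `DNAString` over A/C/G/T.
#' @return Integer vector of 1-based positions `p` with
#'   `reference[p..p+1] == "CG"` (position of the C).
#' @examples
#' locateCpGs("ACGT")   # 2
#' locateCpGs("CGCG")   # 1 3
#' @export
locateCpGs <- function(referenceSeq) {
    ref <- toupper(as.character(referenceSeq))
    if (grepl("[^ACGT]", ref)) stop("reference must be over A/C/G/T")
    as.integer(Biostrings::start(
        Biostrings::matchPattern("CG", Biostrings::DNAString(ref))))
}

## bisulfite-aware substitution matrix: clone T aligned to reference C
## scores as a match (expected conversion), everything else standard.
.bisulfiteSubMat <- function(match = 2, mismatch = -2) {
    bases <- c("A", "C", "G", "T")
    m <- matrix(mismatch, 4, 4, dimnames = list(bases, bases))
    diag(m) <- match
    m["T", "C"] <- match            # pattern (clone) T vs subject (ref) C
    m
}

#' Call per-site methylation of one clone against the reference
#'
#' Globally aligns the clone to the reference amplicon (free end gaps,
#' affine gap penalties, conversion-aware scoring where clone T matches
#' reference C). At each reference CpG the aligned clone base gives the
#' call: C = methylated, T = unmethylated, gap or any other base =
#' missing. The clone conversion rate is estimated from non-CpG
#' reference cytosines as converted T over (T + unconverted C). Clones
#' covering less than `minAlignedFraction` of the reference, or whose
#' identity at non-cytosine reference positions falls below
#' `minIdentity`, are rejected (`NULL` with a message).
#'
#' @param reference Reference amplicon (character or `DNAString`).
#' @param cloneSeq Clone sequence.
#' @param minAlignedFraction Minimum fraction of reference positions the
#'   alignment must cover.
#' @param minIdentity Identity floor computed outside reference C
#'   positions.
#' @return List with `calls` (character `"M"`/`"U"`/`"."` per reference
#'   CpG), `conversionRate`, `cpgPositions`; or `NULL` if rejected.
#' @export
callClone <- function(reference, cloneSeq, minAlignedFraction = 0.9,
                      minIdentity = 0.8) {
    ref <- toupper(as.character(reference))
    clone <- toupper(as.character(cloneSeq))
    cpg <- locateCpGs(ref)
    aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(clone),
        subject = Biostrings::DNAString(ref),
        type = "overlap", substitutionMatrix = .bisulfiteSubMat(),
        gapOpening = 6, gapExtension = 1)
    alnP <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    alnS <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    refBase <- rep(NA_character_, nchar(ref))       # clone base per ref pos
    pos <- Biostrings::start(Biostrings::subject(aln)) - 1L
    for (i in seq_along(alnS)) {
        if (alnS[i] != "-") {
            pos <- pos + 1L
            refBase[pos] <- alnP[i]                  # "-" when clone gapped
        }
    }
    covered <- !is.na(refBase) & refBase != "-"
    if (mean(!is.na(refBase)) < minAlignedFraction) {
        message("clone rejected: alignment covers ",
                sprintf("%.0f%%", 100 * mean(!is.na(refBase))),
                " of the reference")
        return(NULL)
    }
    refChars <- strsplit(ref, "")[[1]]
    nonC <- which(refChars != "C")
    idBase <- nonC[covered[nonC]]
    if (length(idBase) &&
        mean(refBase[idBase] == refChars[idBase]) < minIdentity) {
        message("clone rejected: identity ",
                sprintf("%.0f%%", 100 * mean(refBase[idBase] == refChars[idBase])),
                " outside cytosine positions")
        return(NULL)
    }
    calls <- vapply(cpg, function(p) {
        b <- refBase[p]
        if (is.na(b) || b == "-") "."
        else if (b == "C") "M"
        else if (b == "T") "U"
        else "."
    }, character(1))
    nonCpgC <- setdiff(which(refChars == "C"), cpg)
    bb <- refBase[nonCpgC]
    nT <- sum(bb == "T", na.rm = TRUE)
    nC <- sum(bb == "C", na.rm = TRUE)
    convRate <- if (nT + nC > 0) nT / (nT + nC) else NA_real_
    list(calls = calls, conversionRate = convRate, cpgPositions = cpg)
}

#' Build a CloneMatrix from a reference and a clone set
#'
#' Calls every clone with [callClone()]; clones failing alignment QC or
#' whose non-CpG conversion rate falls below `minConversion` (standard
#' bisulfite QC) are excluded and listed in the `excluded` slot.
#'
#' @param reference Reference amplicon sequence.
#' @param clones Named `DNAStringSet` (or character vector) of clone
#'   sequences.
#' @param ampliconId Identifier for the amplicon.
#' @param minConversion Minimum acceptable per-clone non-CpG conversion
#'   rate (`NA` rates are kept — nothing to judge them by).
#' @param ... Passed to [callClone()].
#' @return A [CloneMatrix-class].
#' @export
buildCloneMatrix <- function(reference, clones, ampliconId = "amplicon",
                             minConversion = 0.95, ...) {
    seqs <- as.character(clones)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("clone%02d", seq_along(seqs))
    cpg <- locateCpGs(reference)
    calls <- matrix(".", 0, length(cpg))
    conv <- numeric(0)
    excluded <- character(0)
    for (nm in names(seqs)) {
        res <- callClone(reference, seqs[[nm]], ...)
        if (is.null(res)) { excluded <- c(excluded, nm); next }
        if (!is.na(res$conversionRate) && res$conversionRate < minConversion) {
            message("clone ", nm, " excluded: conversion rate ",
                    sprintf("%.3f", res$conversionRate), " < ", minConversion)
            excluded <- c(excluded, nm)
            next
        }
        calls <- rbind(calls, res$calls)
        rownames(calls)[nrow(calls)] <- nm
        conv <- c(conv, res$conversionRate)
    }
    names(conv) <- rownames(calls)
    methods::new("CloneMatrix", ampliconId = ampliconId,
                 cpgPositions = cpg, calls = calls,
                 cloneConversion = conv, excluded = excluded)
}

#' Per-site percent methylation of a clone matrix
#'
#' `100 * methylated / (methylated + unmethylated)` per CpG site;
#' missing calls are excluded from the denominator and all-missing
#' sites are flagged.
#'
#' @param mat A [CloneMatrix-class].
#' @return `data.frame`: `position`, `pctMeth`, `nMeth`, `nUnmeth`,
#'   `nMissing`, `covered`.
#' @export
sitePercentMethylation <- function(mat) {
    calls <- cloneCalls(mat)
    nM <- colSums(calls == "M")
    nU <- colSums(calls == "U")
    nMiss <- colSums(calls == ".")
    pct <- ifelse(nM + nU > 0, 100 * nM / (nM + nU), NA_real_)
    data.frame(position = cpgPositions(mat), pctMeth = pct,
               nMeth = nM, nUnmeth = nU, nMissing = nMiss,
               covered = nM + nU > 0)
}

#' Compare methylation between two conditions of the same amplicon
#'
#' Pairs per-site percent methylation by CpG position across the two
#' clone matrices and runs the one-sided paired Wilcoxon test for the
#' alternative that the first condition (e.g. a knockout) is less
#' methylated than the second (e.g. scramble control). Sites missing in
#' either condition are dropped and counted.
#'
#' @param matA,matB `CloneMatrix` objects for the same amplicon (A is
#'   the condition hypothesized to be hypomethylated).
#' @return List with `p`, `nSites`, `dropped`, `meanA`, `meanB`.
#' @export
compareConditions <- function(matA, matB) {
    pa <- sitePercentMethylation(matA)
    pb <- sitePercentMethylation(matB)
    shared <- intersect(pa$position[pa$covered], pb$position[pb$covered])
    dropped <- length(union(pa$position, pb$position)) - length(shared)
    if (length(shared) < 2L)
        stop("fewer than 2 CpG sites shared between conditions")
    va <- pa$pctMeth[match(shared, pa$position)]
    vb <- pb$pctMeth[match(shared, pb$position)]
    list(p = pairedWilcoxonLess(va, vb), nSites = length(shared),
         dropped = dropped, meanA = mean(va), meanB = mean(vb))
}

#' Write a lollipop matrix TSV
#'
#' Rows = clones, columns = reference CpG positions, values `M`/`U`/`.`.
#'
#' @param mat A [CloneMatrix-class].
#' @param path Output path.
#' @export
writeCloneMatrix <- function(mat, path) {
    df <- as.data.frame(cloneCalls(mat))
    colnames(df) <- cpgPositions(mat)
    df <- cbind(clone = rownames(cloneCalls(mat)), df)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a lollipop matrix TSV back into a CloneMatrix
#'
#' @param path TSV path written by [writeCloneMatrix()].
#' @param ampliconId Amplicon identifier.
#' @return A [CloneMatrix-class] (conversion rates are not stored in the
#'   TSV and come back as `NA`).
#' @export
readCloneMatrix <- function(path, ampliconId = "amplicon") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    calls <- as.matrix(df[, -1, drop = FALSE])
    dimnames(calls) <- list(df[[1]], NULL)
    methods::new("CloneMatrix", ampliconId = ampliconId,
                 cpgPositions = as.integer(colnames(df)[-1]),
                 calls = calls,
                 cloneConversion = rep(NA_real_, nrow(calls)),
                 excluded = character(0))
}
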