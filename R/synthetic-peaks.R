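## Multi-sample DRIP peak simulator on a restriction-fragment universe.
## Each fragment is assigned a ground-truth category (common, control-
## unique, unique to one AGS subtype, or absent) and per-replicate peak
## sets are emitted with independent replicate dropout.

#' Simulate multi-sample DRIP peak sets on a fragment universe
#'
#' Fragment categories are drawn independently per fragment:
#' `common` (probability `pCommon`) fragments are peak-positive in the
#' control and in each AGS sample with probability `pCommonPerAgs`
#' (at least one AGS sample enforced); `control_unique` fragments are
#' positive only in control; for each AGS subtype, fragments are unique
#' to it with base probability `pUnique`, multiplied by a feature bias
#' weight when the fragment midpoint falls in a biased feature — this is
#' how feature enrichment (e.g. an intergenic bias of AGS-unique R-loop
#' peaks) is planted. Two replicates per sample are emitted, each losing
#' a positive fragment independently with probability `dropout`.
#'
#' @param fragments Restriction-fragment `GRanges` (see
#'   [digestGenome()]), with or without an `id` column.
#' @param sampleIds AGS subtype sample ids.
#' @param controlId Control sample id.
#' @param pCommon,pControlUnique,pUnique Category base probabilities.
#' @param featureBias Named numeric placement weights (> 0) for unique
#'   peaks, e.g. `c(intergenic = 3)`.
#' @param biasFeatures Named list of `GRanges` matching `featureBias`.
#' @param pCommonPerAgs Probability a common fragment is positive in any
#'   given AGS sample.
#' @param dropout Per-replicate probability of losing a positive
#'   fragment.
#' @param seed Integer seed.
#' @return List with `replicates` (nested list sample -> `rep1`/`rep2`
#'   character vectors of positive fragment ids), `peaks` (same structure
#'   but `GRanges`), `truth` (`data.frame` fragment id -> label) and
#'   `fragments`.
#' @export
simulateDripSamples <- function(fragments,
                                sampleIds = c("AGS1", "AGS2", "AGS4", "AGS5"),
                                controlId = "CTRL",
                                pCommon = 0.25, pControlUnique = 0.03,
                                pUnique = 0.05, featureBias = NULL,
                                biasFeatures = NULL, pCommonPerAgs = 0.7,
                                dropout = 0.05, seed = 1L) {
    .assertGRanges(fragments, "fragments")
    if (length(fragments) == 0L) stop("empty fragment set")
    stopifnot(pCommon >= 0, pControlUnique >= 0, pUnique >= 0,
              dropout >= 0, dropout <= 1, pCommonPerAgs > 0, pCommonPerAgs <= 1)
    if (!is.null(featureBias)) {
        stopifnot(all(featureBias > 0),
                  all(names(featureBias) %in% names(biasFeatures)))
    }
    ids <- S4Vectors::mcols(fragments)$id
    if (is.null(ids)) {
        ids <- sprintf("frag%06d", seq_along(fragments))
        S4Vectors::mcols(fragments)$id <- ids
    }
    nf <- length(fragments)
    ## per-fragment unique-placement weight from feature bias (midpoint rule)
    w <- rep(1, nf)
    if (!is.null(featureBias)) {
        mid <- BiocGenerics::start(fragments) +
            floor((BiocGenerics::width(fragments) - 1) / 2)
        midGr <- GRanges(GenomeInfoDb::seqnames(fragments),
                         IRanges::IRanges(mid, width = 1))
        for (nm in names(featureBias)) {
            hit <- IRanges::overlapsAny(midGr, biasFeatures[[nm]],
                                        ignore.strand = TRUE)
            w[hit] <- pmax(w[hit], featureBias[[nm]])
        }
    }
    nA <- length(sampleIds)
    withSeed(substreamSeed(seed, "drippeaks"), {
        pU <- outer(w, rep(pUnique, nA))             # nf x nA unique probs
        pTot <- pCommon + pControlUnique + rowSums(pU)
        if (any(pTot > 1))
            stop("category probabilities exceed 1 for some fragments; ",
                 "reduce base probabilities or bias weights")
        u <- stats::runif(nf)
        cumU <- if (nA == 1L) pU else t(apply(pU, 1, cumsum))
        cum <- cbind(pCommon, pCommon + pControlUnique,
                     pCommon + pControlUnique + cumU)
        label <- rep("absent", nf)
        label[u < cum[, 1]] <- "common"
        label[u >= cum[, 1] & u < cum[, 2]] <- "control_unique"
        for (j in seq_len(nA)) {
            lo <- cum[, 1 + j]; hi <- cum[, 2 + j]
            label[u >= lo & u < hi] <- paste0("ags_unique:", sampleIds[j])
        }
        allSamples <- c(controlId, sampleIds)
        pres <- matrix(FALSE, nf, length(allSamples),
                       dimnames = list(ids, allSamples))
        isCommon <- label == "common"
        pres[isCommon, controlId] <- TRUE
        if (any(isCommon)) {
            agsHit <- matrix(stats::runif(sum(isCommon) * nA) < pCommonPerAgs,
                             ncol = nA)
            none <- rowSums(agsHit) == 0L
            if (any(none))
                agsHit[cbind(which(none),
                             sample.int(nA, sum(none), replace = TRUE))] <- TRUE
            pres[isCommon, sampleIds] <- agsHit
        }
        pres[label == "control_unique", controlId] <- TRUE
        for (j in seq_len(nA)) {
            uq <- label == paste0("ags_unique:", sampleIds[j])
            pres[uq, sampleIds[j]] <- TRUE
        }
        replicates <- list()
        peaks <- list()
        for (s in allSamples) {
            posIdx <- which(pres[, s])
            r1 <- posIdx[stats::runif(length(posIdx)) >= dropout]
            r2 <- posIdx[stats::runif(length(posIdx)) >= dropout]
            replicates[[s]] <- list(rep1 = ids[r1], rep2 = ids[r2])
            peaks[[s]] <- list(rep1 = fragments[r1], rep2 = fragments[r2])
        }
        list(replicates = replicates, peaks = peaks,
             truth = data.frame(id = ids, label = label,
                                stringsAsFactors = FALSE),
             presence = pres, fragments = fragments)
    })
}

#' Simulate a bisulfite-converted clone set from a reference amplicon
#'
#' Each clone is the bisulfite image of the reference: a CpG cytosine is
#' read as C (methylated) with its per-site methylation probability and
#' as T otherwise; every non-CpG cytosine converts to T except with
#' probability `conversionFailureRate`. Only the forward strand is
#' modeled (amplicons are strand-specific PCR products).
#'
#' @param referenceAmplicon Reference sequence (character or
#'   `DNAString`), containing at least one CpG.
#' @param perSiteMethProb Scalar or per-CpG-site vector of methylation
#'   probabilities in `[0, 1]`.
#' @param nClones Number of clones to draw.
#' @param conversionFailureRate Probability a non-CpG (or unmethylated
#'   CpG) cytosine escapes conversion.
#' @param seed Integer seed.
#' @return List with `clones` (`DNAStringSet`), `truth` (logical matrix
#'   clones x CpG sites of planted methylation states) and
#'   `cpgPositions`.
#' @export
simulateCloneSet <- function(referenceAmplicon, perSiteMethProb = 0.8,
                             nClones = 16L, conversionFailureRate = 0,
                             seed = 1L) {
    ref <- toupper(as.character(referenceAmplicon))
    if (any(perSiteMethProb < 0 | perSiteMethProb > 1))
        stop("methylation probabilities must be in [0, 1]")
    if (conversionFailureRate < 0 || conversionFailureRate > 1)
        stop("conversionFailureRate must be in [0, 1]")
    cpg <- locateCpGs(ref)
    if (length(cpg) == 0L) stop("reference contains no CpG")
    probs <- if (length(perSiteMethProb) == 1L)
        rep(perSiteMethProb, length(cpg)) else perSiteMethProb
    if (length(probs) != length(cpg))
        stop("perSiteMethProb must be scalar or one value per CpG site")
    rawRef <- charToRaw(ref)
    Cpos <- which(rawRef == as.raw(67L))
    nonCpgC <- setdiff(Cpos, cpg)
    withSeed(substreamSeed(seed, "clones"), {
        truth <- matrix(FALSE, nClones, length(cpg),
                        dimnames = list(sprintf("clone%02d", seq_len(nClones)),
                                        NULL))
        seqs <- character(nClones)
        for (i in seq_len(nClones)) {
            b <- rawRef
            state <- stats::runif(length(cpg)) < probs
            truth[i, ] <- state
            unmeth <- cpg[!state]
            stay <- stats::runif(length(unmeth)) < conversionFailureRate
            b[unmeth[!stay]] <- as.raw(84L)          # T
            conv <- stats::runif(length(nonCpgC)) >= conversionFailureRate
            b[nonCpgC[conv]] <- as.raw(84L)
            seqs[i] <- rawToChar(b)
        }
        clones <- Biostrings::DNAStringSet(seqs)
        names(clones) <- rownames(truth)
        list(clones = clones, truth = truth, cpgPositions = cpg)
    })
}
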