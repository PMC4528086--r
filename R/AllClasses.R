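#' @import methods
#' @importFrom GenomicRanges GRanges
NULL

#' MethylomeSample: a QC'd, strand-combined CpG methylome
#'
#' Holds CpG-unit methylation records for one sample after strand
#' combining: one record per CpG dyad, anchored at the forward-strand
#' cytosine, with summed methylated and total read counts. Conversion
#' rate (from non-CpG cytosines) and mean CpG coverage are recorded at
#' construction; coverage-filter bounds are recorded when
#' [coverageFilter()] is applied so that the filter is a fixed property
#' of the sample rather than something recomputed on its own output.
#'
#' @slot sampleId Sample identifier.
#' @slot records `GRanges` (width-1, unstranded, sorted) with metadata
#'   columns `meth` and `total`.
#' @slot conversionRate Bisulfite conversion rate estimated from CHG/CHH
#'   records of the raw call table (`NA` if none were present).
#' @slot meanCoverage Mean reads per covered CpG at construction time.
#' @slot filterBounds Numeric `c(minCov, upperValue)`; `NA` until
#'   [coverageFilter()] is applied.
#' @slot filterLog List with counts of records dropped by each rule.
#' @export
setClass("MethylomeSample",
    slots = c(sampleId = "character", records = "GRanges",
              conversionRate = "numeric", meanCoverage = "numeric",
              filterBounds = "numeric", filterLog = "list"),
    prototype = list(conversionRate = NA_real_, meanCoverage = NA_real_,
                     filterBounds = c(NA_real_, NA_real_), filterLog = list()))

setValidity("MethylomeSample", function(object) {
    rec <- object@records
    msg <- character(0)
    if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
    mc <- S4Vectors::mcols(rec)
    if (!all(c("meth", "total") %in% colnames(mc)))
        msg <- c(msg, "records must carry 'meth' and 'total' metadata columns")
    else {
        if (any(mc$meth < 0) || any(mc$meth > mc$total))
            msg <- c(msg, "0 <= meth <= total violated")
        if (S4Vectors::isSorted(rec) == FALSE)
            msg <- c(msg, "records must be sorted by (chrom, pos)")
    }
    if (!is.na(object@conversionRate) &&
        (object@conversionRate < 0 || object@conversionRate > 1))
        msg <- c(msg, "conversionRate must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' DomainSegmentation: HMD/PMD tiling of a covered genome
#'
#' Ordered, non-overlapping labeled intervals produced by Viterbi
#' decoding of the two-state methylation HMM (after post-processing,
#' adjacent intervals always carry different labels).
#'
#' @slot domains `GRanges` with metadata columns `label` (`"HMD"` or
#'   `"PMD"`), `meanMeth` (weighted methylation fraction over covered
#'   windows), `nWindows`, and internal count columns `meth`/`total`.
#' @slot windowBp Observation window size used for decoding.
#' @export
setClass("DomainSegmentation",
    slots = c(domains = "GRanges", windowBp = "numeric"))

setValidity("DomainSegmentation", function(object) {
    d <- object@domains
    msg <- character(0)
    mc <- S4Vectors::mcols(d)
    if (!all(c("label", "meanMeth") %in% colnames(mc)))
        msg <- c(msg, "domains need 'label' and 'meanMeth' columns")
    else if (!all(mc$label %in% c("HMD", "PMD")))
        msg <- c(msg, "labels must be HMD or PMD")
    if (length(d) > 1L) {
        byChrom <- split(d, GenomeInfoDb::seqnames(d))
        for (g in byChrom) {
            if (length(g) < 2L) next
            if (any(BiocGenerics::start(g)[-1L] <= BiocGenerics::end(g)[-length(g)]))
                msg <- c(msg, "domains overlap within a chromosome")
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

#' DomainHMM: two-state discrete-emission HMM over windowed methylation
#'
#' @slot emissions List with elements `HMD` and `PMD`, each a probability
#'   vector over `K` methylation bins plus one trailing missing symbol.
#' @slot transitions 2x2 row-stochastic matrix (rows/cols HMD, PMD).
#' @slot initial Initial state distribution.
#' @slot windowBp Observation granularity in bp.
#' @slot K Number of methylation bins.
#' @export
setClass("DomainHMM",
    slots = c(emissions = "list", transitions = "matrix",
              initial = "numeric", windowBp = "numeric", K = "integer"))

setValidity("DomainHMM", function(object) {
    msg <- character(0)
    if (!all(c("HMD", "PMD") %in% names(object@emissions)))
        msg <- c(msg, "emissions must be named HMD and PMD")
    for (nm in c("HMD", "PMD")) {
        p <- object@emissions[[nm]]
        if (abs(sum(p) - 1) > 1e-8) msg <- c(msg, paste0(nm, " pmf must sum to 1"))
        if (any(p <= 0)) msg <- c(msg, paste0(nm, " pmf must be positive after smoothing"))
    }
    tr <- object@transitions
    if (!all(dim(tr) == c(2L, 2L))) msg <- c(msg, "transitions must be 2x2")
    else {
        if (any(abs(rowSums(tr) - 1) > 1e-8)) msg <- c(msg, "transition rows must sum to 1")
        if (any(diag(tr) < 0.5)) msg <- c(msg, "self-transitions must be >= 0.5")
    }
    if (length(msg)) msg else TRUE
})

#' FragmentPresenceMatrix: restriction fragments x samples peak occupancy
#'
#' @slot fragments `GRanges` of restriction fragments with a metadata
#'   column `id`; fragments tile each chromosome exactly.
#' @slot presence Logical matrix, rows = fragment ids, cols = sample ids.
#' @slot roles Named character vector mapping sample id to `"control"` or
#'   `"ags"`.
#' @export
setClass("FragmentPresenceMatrix",
    slots = c(fragments = "GRanges", presence = "matrix", roles = "character"))

setValidity("FragmentPresenceMatrix", function(object) {
    msg <- character(0)
    if (!is.logical(object@presence)) msg <- c(msg, "presence must be logical")
    ids <- S4Vectors::mcols(object@fragments)$id
    if (is.null(ids)) msg <- c(msg, "fragments need an 'id' column")
    else if (!all(rownames(object@presence) %in% ids))
        msg <- c(msg, "every presence row must map to a fragment id")
    if (!all(object@roles %in% c("control", "ags")))
        msg <- c(msg, "roles must be 'control' or 'ags'")
    if (!all(colnames(object@presence) %in% names(object@roles)))
        msg <- c(msg, "every sample column needs a role")
    if (length(msg)) msg else TRUE
})

#' PeakClassification: common / unique labeling of the fragment universe
#'
#' Fragment categories follow the DRIP stack-plot rules: `common` =
#' peak-positive in control and at least one AGS sample; `control_unique`
#' = positive in control only; `ags_specific` = positive in at least one
#' AGS sample but not in control (per-subtype membership kept in
#' `agsUnique`); `absent` otherwise.
#'
#' @slot category Factor per fragment (named by fragment id).
#' @slot agsUnique Named list: subtype -> fragment ids unique to it
#'   (absent from control; a fragment may appear under several subtypes).
#' @slot fragments `GRanges` fragment universe.
#' @slot summary `data.frame` with per-category fragment counts and bp.
#' @slot controlId Control sample id.
#' @export
setClass("PeakClassification",
    slots = c(category = "factor", agsUnique = "list", fragments = "GRanges",
              summary = "data.frame", controlId = "character"))

#' EnrichmentResult: Monte Carlo feature-overlap test result
#'
#' @slot feature Feature name.
#' @slot observedPct Observed % length overlap of the query set.
#' @slot nullPcts Null distribution of the statistic over the shuffles.
#' @slot foldChangeVsCommon Fold change of % overlap relative to the
#'   common peak set (baseline 1).
#' @slot empiricalP Empirical p, `(1 + k) / (1 + n)`.
#' @slot direction `"enriched"` or `"depleted"`.
#' @slot significant Logical under the `p < alpha` and `|fold - 1| >`
#'   `minFold - 1` rule.
#' @slot nShuffles Number of shuffle replicates.
#' @export
setClass("EnrichmentResult",
    slots = c(feature = "character", observedPct = "numeric",
              nullPcts = "numeric", foldChangeVsCommon = "numeric",
              empiricalP = "numeric", direction = "character",
              significant = "logical", nShuffles = "integer"))

setValidity("EnrichmentResult", function(object) {
    msg <- character(0)
    n <- object@nShuffles
    if (length(object@nullPcts) != n) msg <- c(msg, "nullPcts length must equal nShuffles")
    if (!is.na(object@empiricalP) &&
        (object@empiricalP < 1 / (n + 1) - 1e-12 || object@empiricalP > 1))
        msg <- c(msg, "empiricalP must lie in [1/(n+1), 1]")
    if (!object@direction %in% c("enriched", "depleted"))
        msg <- c(msg, "direction must be enriched or depleted")
    if (length(msg)) msg else TRUE
})

#' CloneMatrix: bisulfite amplicon clones x CpG sites
#'
#' @slot ampliconId Amplicon identifier.
#' @slot cpgPositions 1-based positions of reference CpGs (position of
#'   the C).
#' @slot calls Character matrix clones x sites with values `"M"`
#'   (methylated), `"U"` (unmethylated) or `"."` (missing).
#' @slot cloneConversion Per-clone non-CpG conversion rate.
#' @slot excluded Character vector of clone names failing conversion QC.
#' @export
setClass("CloneMatrix",
    slots = c(ampliconId = "character", cpgPositions = "integer",
              calls = "matrix", cloneConversion = "numeric",
              excluded = "character"))

setValidity("CloneMatrix", function(object) {
    msg <- character(0)
    if (ncol(object@calls) != length(object@cpgPositions))
        msg <- c(msg, "one call column per reference CpG required")
    if (!all(object@calls %in% c("M", "U", ".")))
        msg <- c(msg, "calls must be 'M', 'U' or '.'")
    cc <- object@cloneConversion[!is.na(object@cloneConversion)]
    if (any(cc < 0 | cc > 1)) msg <- c(msg, "conversion rates must be in [0,1]")
    if (length(msg)) msg else TRUE
})
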