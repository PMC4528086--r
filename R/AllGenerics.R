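## Generics, accessors and show methods for the package's S4 classes.

#' @rdname MethylomeSample-class
#' @param object,x A `MethylomeSample`.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname MethylomeSample-class
#' @export
setMethod("sampleId", "MethylomeSample", function(x) x@sampleId)

#' @rdname MethylomeSample-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname MethylomeSample-class
#' @export
setMethod("records", "MethylomeSample", function(x) x@records)

#' Bisulfite conversion rate
#'
#' For a raw per-cytosine call table (`data.frame`), computes the C-to-T
#' conversion rate as the ratio of converted cytosines over total
#' coverage in CHG and CHH contexts, `sum(total - meth) / sum(total)`.
#' For a `MethylomeSample`, returns the rate recorded at construction.
#'
#' @param x Raw call `data.frame` (columns `context`, `meth`, `total`) or
#'   a `MethylomeSample`.
#' @return Fraction in `[0, 1]`.
#' @export
setGeneric("conversionRate", function(x) standardGeneric("conversionRate"))

#' @rdname conversionRate
#' @export
setMethod("conversionRate", "data.frame", function(x) {
    sub <- x[x$context %in% c("CHG", "CHH"), , drop = FALSE]
    tot <- sum(sub$total)
    if (tot == 0) stop("conversion rate undefined: no CHG/CHH coverage")
    sum(sub$total - sub$meth) / tot
})

#' @rdname conversionRate
#' @export
setMethod("conversionRate", "MethylomeSample", function(x) x@conversionRate)

#' Mean reads per covered CpG
#'
#' @param x CpG-unit records (`data.frame` with a `total` column, a
#'   `GRanges` with a `total` metadata column, or a `MethylomeSample`).
#' @return Arithmetic mean of per-CpG total counts.
#' @export
setGeneric("cpgCoverage", function(x) standardGeneric("cpgCoverage"))

#' @rdname cpgCoverage
#' @export
setMethod("cpgCoverage", "data.frame", function(x) {
    if (nrow(x) == 0L) stop("coverage undefined on an empty record set")
    mean(x$total)
})

#' @rdname cpgCoverage
#' @export
setMethod("cpgCoverage", "GRanges", function(x) {
    if (length(x) == 0L) stop("coverage undefined on an empty record set")
    mean(S4Vectors::mcols(x)$total)
})

#' @rdname cpgCoverage
#' @export
setMethod("cpgCoverage", "MethylomeSample", function(x) cpgCoverage(x@records))

#' @rdname DomainSegmentation-class
#' @param x A `DomainSegmentation`.
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname DomainSegmentation-class
#' @export
setMethod("domains", "DomainSegmentation", function(x) x@domains)

#' @rdname FragmentPresenceMatrix-class
#' @param x A `FragmentPresenceMatrix`.
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname FragmentPresenceMatrix-class
#' @export
setMethod("presence", "FragmentPresenceMatrix", function(x) x@presence)

#' @rdname FragmentPresenceMatrix-class
#' @export
setGeneric("fragmentRanges", function(x) standardGeneric("fragmentRanges"))

#' @rdname FragmentPresenceMatrix-class
#' @export
setMethod("fragmentRanges", "FragmentPresenceMatrix", function(x) x@fragments)

#' @rdname CloneMatrix-class
#' @param x A `CloneMatrix`.
#' @export
setGeneric("cloneCalls", function(x) standardGeneric("cloneCalls"))

#' @rdname CloneMatrix-class
#' @export
setMethod("cloneCalls", "CloneMatrix", function(x) x@calls)

#' @rdname CloneMatrix-class
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))

#' @rdname CloneMatrix-class
#' @export
setMethod("cpgPositions", "CloneMatrix", function(x) x@cpgPositions)

#' @rdname EnrichmentResult-class
#' @param x An `EnrichmentResult`.
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname EnrichmentResult-class
#' @export
setMethod("empiricalP", "EnrichmentResult", function(x) x@empiricalP)

## ---- show methods -------------------------------------------------------

setMethod("show", "MethylomeSample", function(object) {
    filt <- if (all(is.na(object@filterBounds))) "unfiltered"
            else sprintf("filtered [%g, %.1f]", object@filterBounds[1],
                         object@filterBounds[2])
    cat("MethylomeSample '", object@sampleId, "': ",
        length(object@records), " CpG units (", filt, ")\n", sep = "")
    cat("  conversion rate: ",
        ifelse(is.na(object@conversionRate), "NA",
               sprintf("%.4f", object@conversionRate)),
        ", mean CpG coverage: ",
        sprintf("%.2f", object@meanCoverage), "\n", sep = "")
})

setMethod("show", "DomainSegmentation", function(object) {
    d <- object@domains
    lab <- S4Vectors::mcols(d)$label
    cat("DomainSegmentation: ", length(d), " domains (",
        sum(lab == "HMD"), " HMD / ", sum(lab == "PMD"), " PMD), window ",
        object@windowBp, " bp\n", sep = "")
    cat("  PMD bp: ", sum(BiocGenerics::width(d[lab == "PMD"])),
        "; HMD bp: ", sum(BiocGenerics::width(d[lab == "HMD"])), "\n", sep = "")
})

setMethod("show", "DomainHMM", function(object) {
    cat("DomainHMM: 2 states, K =", object@K, "bins, window",
        object@windowBp, "bp\n")
    cat("  self-transitions:", paste(sprintf("%.4f", diag(object@transitions)),
                                     collapse = ", "), "\n")
})

setMethod("show", "FragmentPresenceMatrix", function(object) {
    cat("FragmentPresenceMatrix:", nrow(object@presence), "fragments x",
        ncol(object@presence), "samples\n")
    cat("  roles:", paste(sprintf("%s=%s", names(object@roles), object@roles),
                          collapse = ", "), "\n")
})

setMethod("show", "PeakClassification", function(object) {
    cat("PeakClassification (control:", object@controlId, ")\n")
    print(object@summary, row.names = FALSE)
})

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult '", object@feature, "': observed ",
        sprintf("%.3f%%", object@observedPct), ", fold vs common ",
        sprintf("%.3f", object@foldChangeVsCommon), "\n", sep = "")
    cat("  ", object@direction, ", empirical p = ",
        format(object@empiricalP, digits = 4), " (", object@nShuffles,
        " shuffles); significant: ", object@significant, "\n", sep = "")
})

setMethod("show", "CloneMatrix", function(object) {
    cat("CloneMatrix '", object@ampliconId, "': ", nrow(object@calls),
        " clones x ", ncol(object@calls), " CpG sites\n", sep = "")
    if (length(object@excluded))
        cat("  excluded clones (conversion QC):",
            paste(object@excluded, collapse = ", "), "\n")
})
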