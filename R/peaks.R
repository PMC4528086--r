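## DRIP peak universe on restriction fragments: in-silico digestion,
## assignment of called peaks onto fragments, replicate merging and the
## common / control-unique / AGS-unique classification.

#' Default DRIP restriction enzyme cocktail
#'
#' HindIII, EcoRI, BsrGI, XbaI and SspI — the five-enzyme cocktail of
#' the standard DRIP digestion protocol. All recognition sites are
#' palindromic; cut offsets are 0-based within the site.
#'
#' @return `data.frame` with columns `name`, `site`, `cutOffset`.
#' @export
defaultEnzymes <- function() {
    data.frame(name = c("HindIII", "EcoRI", "BsrGI", "XbaI", "SspI"),
               site = c("AAGCTT", "GAATTC", "TGTACA", "TCTAGA", "AATATT"),
               cutOffset = c(1L, 1L, 1L, 1L, 3L),
               stringsAsFactors = FALSE)
}

#' In-silico restriction digest of a genome
#'
#' Scans each chromosome for every enzyme's recognition site (both
#' strands; palindromic sites are counted once) and cuts at the given
#' offset within the site. Fragments are the intervals between
#' consecutive cuts and the chromosome ends, so they tile each
#' chromosome exactly.
#'
#' @param genome `DNAStringSet` (or a FASTA path readable by
#'   [Biostrings::readDNAStringSet()]).
#' @param enzymes `data.frame` as returned by [defaultEnzymes()];
#'   recognition sequences must be plain A/C/G/T of length >= 4.
#' @return `GRanges` of fragments with metadata column `id`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAGAATTCAA"))
#' digestGenome(g, data.frame(name = "EcoRI", site = "GAATTC", cutOffset = 1))
#' @export
digestGenome <- function(genome, enzymes = defaultEnzymes()) {
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    stopifnot(all(c("name", "site", "cutOffset") %in% colnames(enzymes)))
    if (any(nchar(enzymes$site) < 4))
        stop("recognition sequences must be at least 4 bp")
    if (any(grepl("[^ACGT]", enzymes$site)))
        stop("ambiguous IUPAC codes in recognition sequences are not supported")
    sl <- genomeSeqlengths(genome)
    frags <- GRanges(seqlengths = sl)
    for (chrom in names(genome)) {
        seq <- genome[[chrom]]
        cuts <- integer(0)
        for (i in seq_len(nrow(enzymes))) {
            site <- enzymes$site[i]
            off <- enzymes$cutOffset[i]
            hits <- Biostrings::start(Biostrings::matchPattern(site, seq))
            cuts <- c(cuts, hits - 1L + off)         # 0-based cut coordinate
            rc <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(site)))
            if (rc != site) {                        # non-palindromic: minus strand
                hits2 <- Biostrings::start(Biostrings::matchPattern(rc, seq))
                cuts <- c(cuts, hits2 - 1L + (nchar(site) - off))
            }
        }
        L <- sl[[chrom]]
        cuts <- sort(unique(cuts))
        cuts <- cuts[cuts > 0 & cuts < L]
        bounds <- c(0L, cuts, L)
        gr <- GRanges(chrom,
                      IRanges::IRanges(start = utils::head(bounds, -1) + 1,
                                       end = bounds[-1]),
                      seqlengths = sl)
        frags <- c(frags, gr)
    }
    S4Vectors::mcols(frags)$id <- sprintf("frag%06d", seq_along(frags))
    S4Vectors::metadata(frags)$enzymes <- enzymes
    frags
}

#' Assign called peaks onto restriction fragments
#'
#' A fragment is peak-positive when, for some peak, the overlap covers at
#' least `minOverlapFraction` of the shorter of the two intervals (so
#' short fragments inside broad peaks are captured). Peaks are merged
#' within the sample before assignment.
#'
#' @param peaks Peak `GRanges` (narrowPeak/BED; only coordinates used).
#' @param fragments Fragment `GRanges` from [digestGenome()].
#' @param minOverlapFraction Reciprocal-to-shorter overlap threshold in
#'   `(0, 1]`; use `.Machine$double.eps`-like small values for a 1-bp
#'   rule, or set `minOverlapBp = 1` behavior via `minOverlapFraction = 0`.
#' @return Character vector of positive fragment ids.
#' @export
assignPeaksToFragments <- function(peaks, fragments,
                                   minOverlapFraction = 0.25) {
    .assertGRanges(peaks, "peaks")
    .assertGRanges(fragments, "fragments")
    sl <- GenomeInfoDb::seqlengths(fragments)
    chr <- as.character(GenomeInfoDb::seqnames(peaks))
    if (any(!chr %in% names(sl)) ||
        any(BiocGenerics::end(peaks) > sl[chr]) ||
        any(BiocGenerics::start(peaks) < 1))
        stop("peaks extend off the genome")
    peaks <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(fragments, peaks, ignore.strand = TRUE)
    if (length(ov) == 0L) return(character(0))
    f <- S4Vectors::queryHits(ov); p <- S4Vectors::subjectHits(ov)
    ovBp <- pmin(BiocGenerics::end(fragments)[f], BiocGenerics::end(peaks)[p]) -
            pmax(BiocGenerics::start(fragments)[f], BiocGenerics::start(peaks)[p]) + 1
    shorter <- pmin(BiocGenerics::width(fragments)[f],
                    BiocGenerics::width(peaks)[p])
    pos <- if (minOverlapFraction <= 0) ovBp >= 1
           else ovBp / shorter >= minOverlapFraction
    unique(S4Vectors::mcols(fragments)$id[f[pos]])
}

#' Merge two replicate fragment sets into one sample
#'
#' Set union: a fragment positive in either replicate is positive in the
#' merged sample.
#'
#' @param rep1,rep2 Character vectors of fragment ids.
#' @param fragments Fragment universe `GRanges` (for validation).
#' @return Character vector of merged positive fragment ids.
#' @export
mergeReplicates <- function(rep1, rep2, fragments = NULL) {
    if (!is.null(fragments)) {
        ids <- S4Vectors::mcols(fragments)$id
        if (any(!c(rep1, rep2) %in% ids))
            stop("replicate fragment ids not in the fragment universe")
    }
    sort(union(rep1, rep2))
}

#' Build a fragment presence matrix from per-sample fragment sets
#'
#' @param sampleSets Named list: sample id -> character vector of
#'   positive fragment ids (already replicate-merged).
#' @param fragments Fragment universe `GRanges`.
#' @param controlId Which sample is the control.
#' @return A [FragmentPresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(sampleSets, fragments, controlId) {
    ids <- S4Vectors::mcols(fragments)$id
    if (!controlId %in% names(sampleSets)) stop("unknown control id")
    pres <- vapply(sampleSets, function(s) ids %in% s,
                   logical(length(ids)))
    rownames(pres) <- ids
    roles <- stats::setNames(
        ifelse(names(sampleSets) == controlId, "control", "ags"),
        names(sampleSets))
    methods::new("FragmentPresenceMatrix", fragments = fragments,
                 presence = pres, roles = roles)
}

#' Classify fragments into common / unique peak categories
#'
#' `common`: positive in control AND at least one AGS sample;
#' `control_unique`: positive in control only; per-subtype
#' `ags_unique:<id>`: positive in that subtype and negative in control
#' (a fragment may be unique to several subtypes; the combined
#' AGS-specific union counts it once); `absent`: otherwise. The summary
#' reports fragment counts and total bp per category (per subtype and
#' for the combined AGS-specific union).
#'
#' @param pm A [FragmentPresenceMatrix-class].
#' @param controlId Control sample id.
#' @return A [PeakClassification-class].
#' @export
classifyFragments <- function(pm, controlId) {
    pres <- presence(pm)
    if (!controlId %in% colnames(pres)) stop("unknown control id: ", controlId)
    agsIds <- setdiff(colnames(pres), controlId)
    if (length(agsIds) == 0L) stop("need at least one AGS sample")
    ctrl <- pres[, controlId]
    anyAgs <- rowSums(pres[, agsIds, drop = FALSE]) > 0
    cat <- rep("absent", nrow(pres))
    cat[ctrl & anyAgs] <- "common"
    cat[ctrl & !anyAgs] <- "control_unique"
    cat[!ctrl & anyAgs] <- "ags_specific"
    cat <- factor(cat, levels = c("common", "control_unique",
                                  "ags_specific", "absent"))
    names(cat) <- rownames(pres)
    agsUnique <- lapply(agsIds, function(s)
        rownames(pres)[pres[, s] & !ctrl])
    names(agsUnique) <- agsIds
    frag <- fragmentRanges(pm)
    w <- stats::setNames(BiocGenerics::width(frag),
                         S4Vectors::mcols(frag)$id)
    catBp <- vapply(levels(cat), function(lv)
        sum(w[names(cat)[cat == lv]]), numeric(1))
    summ <- data.frame(
        category = c(levels(cat), paste0("ags_unique:", agsIds)),
        count = c(as.integer(table(cat)), lengths(agsUnique)),
        bp = c(catBp, vapply(agsUnique, function(idv) sum(w[idv]), numeric(1))),
        stringsAsFactors = FALSE)
    methods::new("PeakClassification", category = cat, agsUnique = agsUnique,
                 fragments = frag, summary = summ, controlId = controlId)
}

#' Extract the interval set of a classification category
#'
#' @param cls A [PeakClassification-class].
#' @param category `"common"`, `"control_unique"`, `"ags_specific"`,
#'   `"absent"`, or `"ags_unique:<subtype>"`.
#' @return `GRanges` of the category's fragments.
#' @export
categoryRanges <- function(cls, category) {
    frag <- cls@fragments
    ids <- S4Vectors::mcols(frag)$id
    sel <- if (startsWith(category, "ags_unique:")) {
        s <- sub("^ags_unique:", "", category)
        if (!s %in% names(cls@agsUnique)) stop("unknown subtype: ", s)
        ids %in% cls@agsUnique[[s]]
    } else {
        if (!category %in% levels(cls@category))
            stop("unknown category: ", category)
        ids %in% names(cls@category)[cls@category == category]
    }
    frag[sel]
}

#' Write fragment / classification BED files
#'
#' @param gr `GRanges` with an `id` (and optionally category) column.
#' @param path Output path.
#' @param names Values for the BED name field.
#' @export
writeBed6 <- function(gr, path, names = NULL) {
    if (is.null(names)) {
        names <- S4Vectors::mcols(gr)$id
        if (is.null(names)) names <- "."
    }
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     name = names, score = 0,
                     strand = ifelse(as.character(BiocGenerics::strand(gr)) == "*",
                                     ".", as.character(BiocGenerics::strand(gr))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a BED/narrowPeak interval file as GRanges
#'
#' Only chrom/start/end are used; coordinates are converted from 0-based
#' half-open to the 1-based closed convention used internally.
#'
#' @param path BED file path.
#' @param seqlengths Optional named chromosome lengths.
#' @return `GRanges`.
#' @export
readBed <- function(path, seqlengths = NULL) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    gr <- GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1, df[[3]]))
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- df[[4]]
    gr
}
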