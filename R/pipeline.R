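## End-to-end orchestration of the synthetic study: simulate a genome,
## annotation and domain structure; per-sample methylomes and DRIP peak
## sets; then run QC, segmentation, peak classification, enrichment and
## the clone comparison, collecting one machine-readable summary.

#' Default pipeline configuration
#'
#' Every stage parameter is surfaced here; thresholds default to the
#' conventional values of this analysis family (4x / 99.9th-percentile
#' coverage filter, 25-kb training regions with 25-55% / 60-100%
#' strata, 500 shuffles, p < 0.002 with fold change > 20%, 16 clones).
#' The AGS-like design plants extra PMDs in the AGS sample and places
#' its unique DRIP peaks preferentially inside them.
#'
#' @param seed Master seed; all stage substreams derive from it.
#' @return Nested configuration list accepted by [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 1L) {
    list(
        seed = as.integer(seed),
        genome = list(chromLengths = c(chr1 = 3e6, chr2 = 2e6),
                      gcFraction = 0.42,
                      skew = list(n = 20, lengthBp = 4000, value = 0.3)),
        annotation = list(nGenes = 150,
                          repeatDensity = c(LINE = 0.15, LTR = 0.08,
                                            SINE = 0.10, satellite = 0.02)),
        domains = list(pmdFraction = 0.25, pmdMeanLevel = 0.40,
                       hmdMeanLevel = 0.85, meanDomainBp = 3e5,
                       agsExtraPmdFraction = 0.25),
        samples = list(control = "CTRL", ags = c("AGS4")),
        methylome = list(meanCoverage = 5, conversionFailureRate = 0.005,
                         dispersion = 30, nonCpGFraction = 0.05),
        filter = list(minCov = 4, upperPct = 99.9),
        segmentation = list(windowBp = 1000, regionBp = 25000,
                            nRegions = 400, minPool = 200,
                            strata = list(PMD = c(0.25, 0.55),
                                          HMD = c(0.60, 1.00)),
                            K = 20, pseudocount = 1,
                            expectedDomainBp = 1e5, minDomainBp = 10000),
        peaks = list(pCommon = 0.20, pControlUnique = 0.02, pUnique = 0.06,
                     uniquePmdBias = 4, dropout = 0.05,
                     minOverlapFraction = 0.25),
        enrichment = list(nShuffles = 500, alpha = 0.002, minFold = 1.2),
        clones = list(nClones = 16, nSites = 20, ampliconBp = 420,
                      koProb = 0.5, scrambleProb = 0.8,
                      conversionFailureRate = 0.005))
}

## deterministic amplicon with ~nSites CpGs: CG planted on a regular
## grid in an AT-rich carrier so bisulfite conversion is informative
.makeAmplicon <- function(nSites, lengthBp, seed) {
    withSeed(substreamSeed(seed, "amplicon"), {
        spacing <- lengthBp %/% (nSites + 1)
        bases <- sample(c("A", "C", "G", "T"), lengthBp, replace = TRUE,
                        prob = c(0.35, 0.15, 0.15, 0.35))
        s <- paste(bases, collapse = "")
        s <- gsub("CG", "CA", s)                     # clear accidental CpGs
        v <- strsplit(s, "")[[1]]
        for (k in seq_len(nSites)) {
            p <- k * spacing
            v[p] <- "C"; v[p + 1] <- "G"
            if (p + 2 <= lengthBp && v[p + 2] == "G") v[p + 2] <- "A"
            if (p > 1 && v[p - 1] == "C") v[p - 1] <- "A"
        }
        paste(v, collapse = "")
    })
}

#' Run the full synthetic AGS-style study
#'
#' Executes all stages in dependency order: genome + annotation +
#' domain plans, per-sample methylome and DRIP simulation, methylome QC
#' and filtering, HMM segmentation, fragment classification, GC-skew
#' and feature enrichment, peak methylation comparison, and the
#' bisulfite clone comparison. Identical configuration and seed give
#' identical summaries.
#'
#' @param config Configuration list (see [defaultPipelineConfig()]) or a
#'   path to a YAML file with the same structure.
#' @param outdir Optional output directory; when given, BED/TSV/JSON
#'   artifacts are written there.
#' @param verbose Print stage progress.
#' @return List with the stage objects and a `summary` list; the summary
#'   records the config hash and master seed for provenance.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir = NULL,
                        verbose = TRUE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- config
    if (is.null(cfg$genome$chromLengths) ||
        length(cfg$genome$chromLengths) == 0L ||
        any(cfg$genome$chromLengths <= 0))
        stop("invalid config: genome$chromLengths must be positive")
    seed <- cfg$seed
    say <- function(...) if (verbose) message("[agsmeth] ", ...)
    if (!is.null(outdir) && !dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)

    ## ---- stage: genome + annotation ------------------------------------
    say("simulating genome and annotation")
    sl <- unlist(cfg$genome$chromLengths)
    skewBlocks <- NULL
    if (!is.null(cfg$genome$skew) && cfg$genome$skew$n > 0) {
        skewBlocks <- withSeed(substreamSeed(seed, "skewplan"), {
            n <- cfg$genome$skew$n
            lb <- cfg$genome$skew$lengthBp
            chrom <- sample(names(sl), n, replace = TRUE, prob = sl)
            start <- floor(stats::runif(n) * (sl[chrom] - lb)) + 1
            gr <- GenomicRanges::reduce(GRanges(chrom,
                IRanges::IRanges(start, width = lb), seqlengths = sl))
            S4Vectors::mcols(gr)$skew <- cfg$genome$skew$value
            gr
        })
    }
    genome <- makeGenome(sl, cfg$genome$gcFraction, skewBlocks, seed = seed)
    anno <- makeAnnotation(genome, cfg$annotation$nGenes,
                           unlist(cfg$annotation$repeatDensity), seed = seed)

    ## ---- stage: domain plans -------------------------------------------
    controlId <- cfg$samples$control
    agsIds <- cfg$samples$ags
    basePlan <- planDomains(sl, pmdFraction = cfg$domains$pmdFraction,
                            pmdMeanLevel = cfg$domains$pmdMeanLevel,
                            hmdMeanLevel = cfg$domains$hmdMeanLevel,
                            meanDomainBp = cfg$domains$meanDomainBp,
                            seed = seed)
    plans <- stats::setNames(list(basePlan), controlId)
    extraPmds <- list()
    for (i in seq_along(agsIds)) {
        ex <- addExtraPmds(basePlan, cfg$domains$agsExtraPmdFraction,
                           cfg$domains$pmdMeanLevel,
                           seed = substreamSeed(seed, agsIds[i]))
        plans[[agsIds[i]]] <- ex$plan
        extraPmds[[agsIds[i]]] <- ex$extraPmds
    }

    ## ---- stage: methylomes ---------------------------------------------
    say("simulating and QC-ing methylomes")
    samples <- list()
    methTruth <- list()
    for (sid in names(plans)) {
        sim <- simulateMethylome(genome, plans[[sid]],
            meanCoverage = cfg$methylome$meanCoverage,
            conversionFailureRate = cfg$methylome$conversionFailureRate,
            dispersion = cfg$methylome$dispersion,
            nonCpGFraction = cfg$methylome$nonCpGFraction,
            seed = substreamSeed(seed, paste0("meth_", sid)))
        smp <- asMethylomeSample(sim$calls, sid, seqlengths = sl)
        smp <- coverageFilter(smp, cfg$filter$minCov, cfg$filter$upperPct)
        samples[[sid]] <- smp
        methTruth[[sid]] <- sim$truth
    }

    ## ---- stage: segmentation -------------------------------------------
    say("segmenting methylomes into HMDs/PMDs")
    segs <- lapply(names(samples), function(sid)
        segmentMethylome(samples[[sid]],
            windowBp = cfg$segmentation$windowBp,
            regionBp = cfg$segmentation$regionBp,
            nRegions = cfg$segmentation$nRegions,
            strata = cfg$segmentation$strata,
            minPool = cfg$segmentation$minPool,
            K = cfg$segmentation$K,
            pseudocount = cfg$segmentation$pseudocount,
            expectedDomainBp = cfg$segmentation$expectedDomainBp,
            minDomainBp = cfg$segmentation$minDomainBp,
            seed = substreamSeed(seed, paste0("seg_", sid))))
    names(segs) <- names(samples)

    ## ---- stage: peaks ---------------------------------------------------
    say("digesting genome and simulating DRIP peak sets")
    frags <- digestGenome(genome)
    biasFeatures <- list(intergenic = anno$intergenic)
    featureBias <- NULL
    if (length(extraPmds)) {
        biasFeatures$agsPmd <- GenomicRanges::reduce(
            do.call(c, unname(extraPmds)), ignore.strand = TRUE)
        featureBias <- c(agsPmd = cfg$peaks$uniquePmdBias)
    }
    drip <- simulateDripSamples(frags, sampleIds = agsIds,
        controlId = controlId, pCommon = cfg$peaks$pCommon,
        pControlUnique = cfg$peaks$pControlUnique,
        pUnique = cfg$peaks$pUnique, featureBias = featureBias,
        biasFeatures = biasFeatures, dropout = cfg$peaks$dropout,
        seed = substreamSeed(seed, "drip"))
    sampleSets <- lapply(drip$replicates, function(r)
        mergeReplicates(r$rep1, r$rep2, frags))
    pmx <- buildPresenceMatrix(sampleSets, frags, controlId)
    cls <- classifyFragments(pmx, controlId)

    ## ---- stage: enrichment ----------------------------------------------
    say("running skew, enrichment and occupancy analyses")
    skew <- gcSkewBlocks(genome)
    commonPeaks <- categoryRanges(cls, "common")
    peakSets <- list(common = commonPeaks)
    for (sid in agsIds)
        peakSets[[paste0("unique_", sid)]] <-
            categoryRanges(cls, paste0("ags_unique:", sid))
    skewPct <- overlapWithSkew(peakSets, skew)
    featureSets <- list(gene_body = anno$genes, intergenic = anno$intergenic,
                        LINE = anno$LINE, LTR = anno$LTR, SINE = anno$SINE)
    featureSets <- Filter(function(f) !is.null(f) && length(f) > 0, featureSets)
    enr <- list()
    firstAgs <- agsIds[1]
    uniqSet <- peakSets[[paste0("unique_", firstAgs)]]
    if (length(uniqSet) && length(commonPeaks)) {
        for (fn in names(featureSets))
            enr[[fn]] <- monteCarloEnrichment(uniqSet, commonPeaks,
                featureSets[[fn]], featureName = fn,
                nShuffles = cfg$enrichment$nShuffles,
                seed = substreamSeed(seed, paste0("enr_", fn)),
                alpha = cfg$enrichment$alpha,
                minFold = cfg$enrichment$minFold)
    }
    occ <- lapply(agsIds, function(sid)
        domainOccupancy(peakSets, segs[[sid]],
                        uniquePmds = extraPmds[[sid]]))
    names(occ) <- agsIds
    pkMeth <- peakMethylationBySample(peakSets, samples, controlId)

    ## ---- stage: clones ---------------------------------------------------
    say("simulating and analyzing bisulfite clones")
    amp <- .makeAmplicon(cfg$clones$nSites, cfg$clones$ampliconBp, seed)
    koSim <- simulateCloneSet(amp, cfg$clones$koProb, cfg$clones$nClones,
                              cfg$clones$conversionFailureRate,
                              seed = substreamSeed(seed, "clone_ko"))
    scSim <- simulateCloneSet(amp, cfg$clones$scrambleProb, cfg$clones$nClones,
                              cfg$clones$conversionFailureRate,
                              seed = substreamSeed(seed, "clone_scramble"))
    koMat <- suppressMessages(buildCloneMatrix(amp, koSim$clones, "LINE1_KO"))
    scMat <- suppressMessages(buildCloneMatrix(amp, scSim$clones,
                                               "LINE1_scramble"))
    cloneCmp <- compareConditions(koMat, scMat)

    ## ---- summary ----------------------------------------------------------
    segJaccard <- lapply(names(segs), function(sid) {
        truePmd <- plans[[sid]][S4Vectors::mcols(plans[[sid]])$label == "PMD"]
        called <- domains(segs[[sid]])
        called <- called[S4Vectors::mcols(called)$label == "PMD"]
        inter <- sum(BiocGenerics::width(GenomicRanges::intersect(
            GenomicRanges::reduce(called), GenomicRanges::reduce(truePmd),
            ignore.strand = TRUE)))
        uni <- sum(BiocGenerics::width(GenomicRanges::union(
            GenomicRanges::reduce(called), GenomicRanges::reduce(truePmd),
            ignore.strand = TRUE)))
        if (uni > 0) inter / uni else NA_real_
    })
    names(segJaccard) <- names(segs)
    pmdBp <- vapply(segs, function(s) {
        d <- domains(s)
        sum(BiocGenerics::width(d[S4Vectors::mcols(d)$label == "PMD"]))
    }, numeric(1))
    summary <- list(
        configHash = .configHash(cfg), seed = seed,
        samples = lapply(samples, function(s) list(
            conversionRate = conversionRate(s),
            meanCpGCoverage = cpgCoverage(s),
            globalMethylationPct = globalMethylation(s))),
        pmdBp = as.list(pmdBp),
        pmdJaccardVsTruth = segJaccard,
        peakSummary = cls@summary,
        skewOverlapPct = as.list(skewPct),
        enrichment = lapply(enr, function(e) list(
            observedPct = e@observedPct, fold = e@foldChangeVsCommon,
            p = e@empiricalP, direction = e@direction,
            significant = e@significant)),
        domainOccupancy = occ,
        peakMethylation = lapply(pkMeth, function(x) list(
            meanPct = as.list(x$meanPct),
            tests = x$tests)),
        cloneComparison = cloneCmp)

    if (!is.null(outdir)) {
        say("writing outputs to ", outdir)
        Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
        writeBed6(frags, file.path(outdir, "fragments.bed"))
        for (sid in names(segs))
            writeDomainBed(segs[[sid]],
                           file.path(outdir, paste0("domains_", sid, ".bed")))
        writeBed6(skew, file.path(outdir, "gc_skew_blocks.bed"),
                  names = S4Vectors::mcols(skew)$sign)
        utils::write.table(cls@summary,
                           file.path(outdir, "peak_categories.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeCloneMatrix(koMat, file.path(outdir, "clones_ko.tsv"))
        writeCloneMatrix(scMat, file.path(outdir, "clones_scramble.tsv"))
        jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             force = TRUE)
    }
    invisible(list(genome = genome, annotation = anno, plans = plans,
                   extraPmds = extraPmds, samples = samples,
                   segmentations = segs, fragments = frags,
                   classification = cls, presence = pmx, drip = drip,
                   skew = skew, enrichment = enr, occupancy = occ,
                   peakMethylation = pkMeth,
                   clones = list(ko = koMat, scramble = scMat,
                                 comparison = cloneCmp),
                   summary = summary))
}
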