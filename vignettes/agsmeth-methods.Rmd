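---
title: "Methods: methylome domains, R-loop peak classification and Monte Carlo enrichment"
author: "agsmeth package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome domains, R-loop peak classification and Monte Carlo enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`agsmeth` implements the downstream computational analyses used to
characterize Aicardi-Goutières syndrome (AGS) fibroblast-style
experiments that pair whole-genome bisulfite sequencing (MethylC-seq)
with DRIP-seq R-loop mapping: methylome QC and quantification, hidden
Markov segmentation into highly and partially methylated domains
(HMDs/PMDs), restriction-fragment DRIP peak classification, Monte Carlo
feature-enrichment testing, GC-skew annotation, and bisulfite amplicon
clone analysis. Read trimming, alignment and peak calling are upstream
of this package: inputs are per-cytosine call tables, genome FASTA and
interval (BED) files.

Because the motivating data type is low-coverage patient sequencing
that cannot be regenerated at desk scale, every stage is paired with a
synthetic-data generator that plants known ground truth. The package's
tests are therefore *property* tests: they check that each method
recovers what was planted, at the tolerances the sampling models imply.

# The methylome model

A per-cytosine call table records, for each cytosine on each strand,
its context (`CG`, `CHG`, `CHH`) and methylated/total read counts.
Processing follows the standard WGBS conventions:

* **Strand combining.** The two cytosines of a CpG dyad (forward C at
  position $p$, reverse C at $p + 1$) are merged into one CpG unit with
  summed counts. Counts are conserved exactly; unpaired records pass
  through.
* **Conversion rate.** Mammalian non-CpG methylation is negligible, so
  the bisulfite conversion rate is estimated as
  $\sum(\mathrm{total} - \mathrm{meth}) / \sum \mathrm{total}$ over
  CHG + CHH records.
* **Coverage filter.** CpG units with coverage below 4x, or above the
  99.9th percentile of the sample's own coverage distribution
  (linear-interpolation percentile), are discarded — the standard guard
  against under-covered sites and PCR stacks. The upper percentile is a
  property of the *unfiltered* sample: `MethylomeSample` records the
  bounds at first application and re-applying the filter is a no-op.
  Recomputing the percentile on already-filtered data would not be
  idempotent (the new percentile can fall below the retained maximum),
  which is why the bounds are frozen rather than recomputed.
* **Regional methylation.** The default statistic is the
  coverage-weighted ratio $100\sum m_i / \sum t_i$ over CpGs in the
  region. At 3-8x coverage, per-site percentages are dominated by
  sampling noise, so the weighted ratio is the default and the
  mean-of-sites mode is exposed as an option.
* **Metaplots** pool read counts per bin across all anchors
  (TSS or TTS, orientation-aware, minus-strand offsets mirrored).
  Pooling sites weights each CpG observation equally; per-anchor
  averaging (each gene weighted equally) is available via `perGene`.

The paired comparison between an AGS sample and control uses the
one-sided Wilcoxon signed-rank test with the alternative that the AGS
sample is *less* methylated. For up to 25 informative pairs the exact
null distribution of the positive-rank sum is computed by dynamic
programming over the (average) ranks — this remains exact when absolute
differences tie, a case that arises naturally when comparing per-site
percentages. Larger samples use the normal approximation with
continuity and tie correction.

# HMD/PMD segmentation

PMDs are megabase-scale blocks of intermediate (~25-55%) methylation
characteristic of fibroblasts and cancers; HMDs are the highly
methylated (~60-100%) remainder. Segmentation uses a two-state HMM:

* **Observations**: non-overlapping 1-kb windows of coverage-weighted
  methylation; windows without covered CpGs emit a distinct missing
  symbol. 1 kb resolves the 25-kb training regions while keeping
  enough CpGs per window (~10-40 at a few-fold coverage) for a stable
  window value.
* **Emissions**: each state's emission distribution is a discrete pmf
  over K = 20 equal bins of [0, 1] plus the missing symbol, trained by
  add-one smoothing on windows inside stratified training regions:
  random 25-kb regions whose weighted methylation falls in 25-55%
  (PMD pool) or 60-100% (HMD pool). Regions in the 55-60% gap are
  left unlabeled. The missing symbol gets equal probability in both
  states, so uncovered windows are decoded purely from their context.
  Discrete emissions mirror the classic StochHMM-style architecture
  and keep training closed-form.
* **Transitions** are fixed, not Baum-Welch-fitted: the self-transition
  probability is $1 - w / L$ with window size $w$ and expected domain
  length $L = 100$ kb, encoding domain-scale persistence. Only the
  emissions are trained (by the strata above), matching the procedure
  this design follows.
* **Decoding** is exact Viterbi in log space, ties broken toward HMD;
  runs of equal state become domains; domains shorter than 10 kb are
  absorbed into the flanking domain with the closer mean methylation,
  and same-label neighbors merge, so the final segmentation alternates
  labels and conserves covered bp.

Training-pool defaults: up to 500 regions per stratum, at least 200
(`minPool`), with a draw budget of 50 x `nRegions`; failure to fill a
pool is an explicit error naming the empty stratum (a uniformly
methylated genome has no PMD stratum to learn from).

On synthetic methylomes with planted PMDs (mean 0.40, 30% of a 10-Mb
genome) and HMDs (mean 0.85) at 10x coverage, the bp-level Jaccard
between called and true PMDs exceeds 0.99 (the acceptance suite
requires >= 0.90). Recovery degrades as the HMD-PMD separation
shrinks; with the default Beta site-level dispersion of 30 the window
distributions of the two states are well separated.

# DRIP peak classification on restriction fragments

DRIP resolution is set by the restriction digest, not sonication, so
the unit of peak presence is the restriction fragment. The default
cocktail is HindIII, EcoRI, BsrGI, XbaI and SspI — the standard DRIP
digestion set; `digestGenome` scans recognition sites (palindromic
sites counted once; non-palindromic sites are scanned on both strands)
and cuts at the enzyme's offset, yielding fragments that tile each
chromosome exactly.

A fragment is peak-positive when some called peak covers at least a
fraction (default 0.25) of the *shorter* of fragment and peak, so short
fragments inside broad peaks are captured; a 1-bp rule is available via
`minOverlapFraction = 0`. Replicates merge by set union. Classification
follows the stacked-bar-plot rules: **common** = positive in control
and at least one AGS sample; **control-unique** = control only;
**AGS-unique** per subtype = positive in that subtype and absent from
control (a fragment may be unique to several subtypes — it is reported
per subtype and counted once in the combined AGS-specific union);
**absent** otherwise. Whether AGS-unique should also exclude other AGS
subtypes is ambiguous in the source material; the absent-from-control
definition is used and recorded in the summary metadata.

# Monte Carlo enrichment

The enrichment statistic for a peak category versus a genomic feature
is the pooled percent length overlap,
$100 \cdot \mathrm{bp}(Q \cap F) / \mathrm{bp}(Q)$ (a mean of per-peak
percentages is available; pooled bp matches the "percent base-pair
overlap" convention). The null model replaces every unique peak with a
length-matched interval drawn from the **common peak set**: a donor
peak is chosen with probability proportional to its number of valid
start positions and the start uniformly within it, so all placements
are equally likely and the shuffle controls for the composition of
R-loop-forming sequence rather than raw genome background. With $n$
shuffles the empirical p-value is $(1 + k)/(1 + n)$ where $k$ counts
null replicates at least as extreme in the tested direction; at the
default $n = 500$ the smallest attainable p is $1/501 \approx 0.002$,
which is why the significance rule is `p < 0.002` *and* fold change vs
common deviating more than 20% from 1.

Direction handling matters for calibration: the default
(`alternative = "auto"`) reports the one-sided p in the observed
direction, which is the conventional way to annotate an enrichment
table but — like any post-hoc sided test — rejects at about twice the
nominal rate under the null. When the test itself is the object of
interest (calibration experiments, planted-bias detection), a
pre-specified direction (`"enriched"` or `"depleted"`) gives a
calibrated test: under the shuffle null the rejection rate at
$\alpha = 0.05$ over 200 simulated datasets falls in the 2-9% band the
acceptance suite checks. Genome-average fold changes
(`foldChangeVsGenome`, used for PMD chromatin-mark location analysis)
reuse the same machinery with uniform genome-wide placement.

# GC-skew blocks

A deliberately simple windowed caller stands in for full HMM-based
skew annotation: skew $(G - C)/(G + C)$ is computed in 500-bp windows
every 100 bp, windows with $|skew| \ge 0.1$ of consistent sign are
merged, and each window in a run contributes its 100-bp step quantum
(a run of $k$ windows spans $k \cdot 100$ bp), with blocks under
300 bp dropped. At these "low-stringency" thresholds roughly 15% of
windows in skew-free sequence exceed the cutoff by chance; requiring a
sustained run and counting step quanta is what keeps the null coverage
several-fold lower (the tests bound it, and verify that planted skew
blocks are recovered nearly completely). Overlap of peak categories
with skew blocks is reported peak-count-based ("% of peaks overlapping
a block"); percent *length* overlap against arbitrary features is the
separate `percentLengthOverlap` statistic.

# Bisulfite amplicon clones

Clone analysis reproduces the lollipop-plot computation: each Sanger
clone is globally aligned to its reference amplicon (free end gaps;
the substitution matrix scores clone T against reference C as a match,
since conversion is expected), and every reference CpG is called
methylated (C), unmethylated (T) or missing (gap/other). Clone QC uses
the non-CpG conversion rate (clones under 95% excluded — standard
bisulfite practice; configurable) and an alignment identity floor
evaluated away from cytosines. Per-site percent methylation is
methylated over (methylated + unmethylated), missing calls excluded;
condition comparisons (e.g. RNASEH2A knockout vs scramble) pair sites
across conditions per amplicon and use the one-sided signed-rank test.
Pairing is per locus by default; pooling loci is possible by
concatenating site vectors.

# The synthetic-data generator

The generator emulates the features of the real data that the methods
actually exploit, with everything else simplified:

* **Genome**: i.i.d. bases at a target GC fraction (default 0.42,
  mammalian-like), with optional planted GC-skew blocks that tilt
  P(G) - P(C).
* **Methylome**: per-CpG latent methylation drawn from a Beta centered
  on the planted domain mean with concentration 30 — a pure binomial
  at the domain mean would make segmentation unrealistically easy;
  site-level heterogeneity is what makes window values overlap between
  states. Coverage is Poisson (default mean 5, in the few-fold range
  of low-coverage WGBS; zero-coverage sites drop out), split
  binomially between strands. Bisulfite conversion failures (default
  0.5%) make unmethylated cytosines read as C; CHG/CHH sites are
  emitted unmethylated apart from conversion failures, and may be
  subsampled for speed without bias.
* **DRIP peaks**: each fragment independently draws a truth category
  (common / control-unique / unique-per-subtype / absent); unique-peak
  placement can be biased toward features (e.g. intergenic space or
  sample-specific PMDs) by a midpoint weight, which is how enrichment
  and hypomethylation signatures are planted. Two replicates per
  sample with independent dropout.
* **Clones**: bisulfite images of a reference amplicon under planted
  per-site methylation probabilities.

All randomness flows from one master seed through named substreams
(`substreamSeed`), so any stage can be re-run alone with identical
results and whole runs are bit-for-bit reproducible.

What the generator does *not* model — alignment error, M-bias,
copy-number variation, SNPs, read-level structure — bounds what
passing tests show: they validate the statistical machinery and its
implementation, not robustness to upstream artifacts of real
sequencing data.

# Numerical choices and problem sizes

* Coordinates are 1-based closed internally (the GRanges convention);
  BED/bedGraph outputs are 0-based half-open and call tables use
  0-based positions.
* Viterbi ties break toward HMD; domain means exclude missing windows;
  percentile cuts use type-7 (linear interpolation) quantiles.
* The end-to-end study in `runPipeline` defaults to a 5-Mb two-
  chromosome genome with one AGS-like sample (extra PMDs planted on
  25% of HMD segments, unique peaks biased 4x into them), sized so a
  full run takes well under a minute while every planted signature is
  detected with large margins. The acceptance experiments use a 10-Mb
  genome for segmentation recovery, 200 simulated datasets for Monte
  Carlo calibration, and 100 simulations for clone-comparison power.

# Known limitations

* The two-state discrete HMM is a documented stand-in for the original
  StochHMM topology, which is not fully specified in the source
  material; training strata and the trained-emissions/fixed-transitions
  split are preserved.
* The GC-skew caller approximates low-stringency skew annotation
  without an HMM; its defaults trade sensitivity for a controlled
  false-positive floor as described above.
* Empirical p-values cannot go below 1/(n+1); claims at the 0.002
  threshold with 500 shuffles are boundary claims by construction.
* Fragment-level peak presence discards sub-fragment signal structure,
  exactly as in the fragment-based protocol it models.
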