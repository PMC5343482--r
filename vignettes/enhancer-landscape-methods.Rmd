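---
title: "Methods: differential enhancer landscape analysis from ChIP-seq tags"
author: "enhancerscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential enhancer landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`enhancerscape` implements a complete cis-regulatory analysis of histone-mark
ChIP-seq in a two-condition, replicated design: wild-type cells versus cells
in which a chromatin regulator (for example a SWI/SNF subunit) has been
inactivated. The pipeline consumes aligned-tag tables — one row per distinct
(chromosome, 5' position, strand) with a multiplicity — and produces a
catalog of promoters and enhancers, differential H3K27ac signal corrected
for immunoprecipitation efficiency, super-enhancer and transcribed-region
annotations, GC-corrected transcription-factor motif enrichment in
signal-losing enhancers, and enhancer-to-gene expression linkage with gene
ontology enrichment.

All interval arithmetic uses `GenomicRanges`/`IRanges`, so coordinates are
1-based and closed throughout; BED input/output converts at the boundary.
Genome bins of width `w` are `[i*w + 1, (i+1)*w]`.

# Tag preprocessing

Each aligned read is represented by the single base at half the typical
fragment size (default 160 bp, so a shift of 80 bp) downstream of its
5' end, which places the signal at the fragment center. Spurious regions
are blacklisted per input sample as the 1 kb bins whose tag count exceeds
the mean plus three standard deviations over *all* genome bins,
zero-coverage bins included; the population SD (divide by N) is used, which
is both deterministic on tiny test genomes and indistinguishable from the
sample SD at genome scale. Blacklists from several input samples are
unioned. Library complexity is the number of distinct strand-aware
positions divided by the number of mapped tags; batches below 90%
complexity are deduplicated to one read per position.

# Region-of-enrichment calling and reproducibility

Enriched regions are called by a transparent windowed Poisson-z statistic:
chromosomes are tiled in 500 bp windows, the expected IP count per window
is the input count (plus a pseudocount of 0.5, to avoid zero expectations)
scaled by the IP/input library-size ratio, and windows with
$z = (\mathrm{obs} - \mathrm{exp})/\sqrt{\mathrm{exp}} \ge 4$ are merged
when adjacent. The window size and threshold are exposed as parameters.

Reproducibility filtering keeps the base pairs covered by calls from at
least two distinct samples and merges them. The same rule is applied to the
H3K4me3 union used for element classification when replicated H3K4me3
samples are available, because isolated single-sample windows otherwise
scatter false promoter-proximity signals across the genome.

For replicate concordance the package also calls point peaks (local maxima
of the Gaussian-smoothed IP-minus-input profile, thresholded at an
empirical FDR of 0.05 obtained from a position-permuted null), matches
peaks between replicates within 90 bp (greedy nearest-first, one-to-one;
unmatched peaks receive signal 0 on the missing side), and scores
irreproducibility with a two-component EM mixture on rank-transformed
signal pairs: a correlated bivariate normal (reproducible) against an
independent standard normal (irreproducible). The per-pair posterior of
the noise component plays the role of an irreproducible discovery rate; an
experiment passes when the number of sub-threshold pairs for true
replicates exceeds half that of pooled-and-split pseudoreplicates. The
mixture is a deliberately simple analog of published copula-based IDR
estimators; the pass/fail contract, not numerical equivalence, is the
tested behavior, and the estimator is pluggable.

# Element classification

Active TSSs are those overlapping an H3K4me3 region in any condition.
An H3K27ac region overlapping both an active TSS and an H3K4me3 region is
a promoter; one further than 1 kb from any H3K4me3 region *and* further
than 2 kb from any active TSS is an enhancer; everything else is ambiguous
and excluded from element-specific analyses. Distances are minimal bp
separations (0 when overlapping, adjacent intervals have distance 0).

# Signal, fold-change and IP-efficiency correction

Region signal is reads-in-region per million mapped reads plus a
pseudocount of 1. Enrichment is IP signal over input signal. Fold-change
between conditions is the ratio of IP signals only — input is deliberately
omitted because ratios of ratios inflate variance.

Two ChIP libraries normalized by library size are comparable only when
their IP efficiencies (pulled-down to background fragment ratio) match.
Because chromatin-mark levels at the bulk of promoters are stable under
the perturbations considered, any constant offset of the promoter
log-fold-change distribution is attributed to efficiency. The mode of that
distribution is estimated by Gaussian kernel density (Silverman's
rule-of-thumb bandwidth) evaluated on a 0.01 log2-unit grid over [-3, 3],
and each sample receives the multiplicative factor $2^{-\mathrm{mode}}$
relative to the wild-type sample of its replicate pair. The mode, not the
median or mean, is used because the sensitive-enhancer tail is strongly
asymmetric. Factors are fitted pairwise within replicate pairs; the
pipeline reports them per sample. The correction is applied only to marks
with a stable reference class (H3K27ac via promoters); all other samples
are library-size normalized only.

# Super-enhancers

H3K27ac regions are stitched when separated by at most 12.5 kb edge to
edge (single-linkage closure). TSS-proximal regions are not removed;
instead each stitched region's signal is computed only on the portions not
intersecting H3K4me3 regions, which removes the promoter contribution that
otherwise produces false super-enhancers around active TSS clusters.
Signal is input-subtracted IP RPM floored at zero. With both the rank axis
and the signal axis scaled to [0, 1], the cutoff sits where the discrete
slope of the ranked-signal curve first exceeds 1; regions strictly above
the cutoff signal are super-enhancers. Regions whose masked signal
intervals have zero width are excluded from the ranking.

# Transcribed regions

PolII and input tags are counted in 100 bp bins and segmented under a
binomial likelihood: within a segment the case count is binomial in the
case+control total with a constant success probability. The objective is
$-2\log L + \lambda \cdot 2\log N$ per breakpoint, with $N$ the total read
count (the number of binomial observations) and the factor 2 counting the
two quantities each breakpoint introduces — its location and a new
segment rate; standard BIC penalties that ignore the breakpoint location
are known to over-segment changepoint models, and calibration on
homogeneous Poisson tracks confirmed the heavier penalty is required for
the segmentation to collapse to a single segment in the absence of signal.
The exact optimum is found by dynamic programming (bounded lookback of
5,000 bins to stay linear on long chromosomes); ties break toward longer
segments so that the $\lambda = 0$ limit yields one segment per change in
the bin-level ratio. Segments with library-size normalized mean log2
enrichment above 0.1 are transcribed.

# Motif analysis

PWMs are built from aligned site sequences with a pseudo-count of 0.5 per
cell, read and written in MEME minimal format. The scanner scores both
strands with summed log2 probability-over-background ratios and assigns
each match an exact p-value from the null score distribution, computed by
dynamic-programming convolution on a 0.001-bit grid (log-odds floored at
-20 bits). To transfer a motif map across genomes, a p-value cutoff is
chosen as the largest threshold yielding at most the reference map's match
count, dropping entire tie groups that would overshoot.

Enhancers are classed by fold-change: with replicates, sensitive means
more than 2x reduction in each replicate and more than 4x reduction on
geometric average, insensitive means less than 2x change in each replicate
and less than 1.5x on average; with a single comparison the thresholds are
2x (sensitive) and within 1/1.5–1.5x (insensitive), with the direction of
interest (gain or loss) set by a flag.

Raw sensitive/insensitive motif-count ratios are confounded with motif GC
content because region GC differs between the classes. A lowess curve
(span 0.3, 3 robustness iterations) of the log count ratio (pseudocount 1)
against motif GC models the confound across all motifs; the expected
sensitive count is the insensitive count times the curve at the motif's
GC, and enrichment is observed over expected. Because of the pseudocount,
uniform count rescaling leaves enrichments unchanged only up to
O(1/count) terms; the tests assert stability rather than exact
invariance. Motif similarity is the maximal Pearson correlation of the
flattened matrices over ungapped offsets up to 3 columns in both
orientations, padding unaligned columns with 0.25.

# Enhancer-gene linkage and GO

Each enhancer is linked to the closest active TSS within 100 kb; links
closer than 5 kb are retained but excluded from expression comparisons,
which use the 5–100 kb band. Expression change is
$\log_2((\mathrm{mut}+5)/(\mathrm{wt}+5))$ on normalized gene-level counts
with cuffdiff-like status filtering. Enhancers fall into four fold-change
groups (loss > 3x, loss 1.5–3x, change < 1.5x, gain > 1.5x; boundary
values go to the milder group), and group expression distributions are
summarized by quartiles with 1.5 x IQR whiskers and compared by two-sided
Welch t-tests. Sensitive enhancers for GO purposes require mutant/WT
change below 1 in each replicate and geometric mean below 1/2.
GO enrichment is an upper-tail hypergeometric test per term against a
configurable universe (all enhancer-linked genes, or all expressed genes),
with Benjamini-Hochberg q-values.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with explicit seeds everywhere and no global random state:

* background fragments arrive as a Poisson process (default 0.004 tags/bp,
  the coverage a deeply sequenced library gives a desk-scale genome);
* TSS-proximal sites carry H3K4me3 and H3K27ac, TSS-distal sites H3K27ac
  only; each site spans 1 kb and the total IP tag rate at a site is
  background x enrichment fold (default 25, so roughly 100 tags per site —
  typical for strong acetylation peaks) x condition fold-change;
* a configurable fraction of distal sites (default 30%) is sensitive and
  drops to a fold-change of 0.25 in mutant conditions;
* IP efficiency multiplies only the enriched (pulled-down) fraction,
  leaving the background admixture constant — exactly the distortion that
  defeats plain library-size normalization and that the promoter-mode
  correction must invert. Efficiencies for simulated experiments are drawn
  uniformly from [0.6, 1.4];
* fragment centers are converted to 5' tags at +/- half fragment size on a
  random strand, so preprocessing reverses the construction;
* the motif landscape assigns each distal site a local GC (sensitive sites
  shifted up, insensitive down, by 0.04 per unit confound strength) and
  couples motif placement rates to the product of motif GC and site GC
  deviations; at confound strength 0 placement is uniform;
* expression tables couple each gene's true log2 change to the mean
  enhancer log2 fold-change of its assigned (nearest) distal sites, with
  negative-binomial counts whose dispersion-zero limit is exact.

The default defaults (site depth, fold-changes, efficiency range, replicate
structure: two replicates of three conditions) were chosen once as the
realistic operating point of the assay and drive both the unit tests and
the acceptance checks. Problem sizes in the test-suite were chosen so the
whole analysis runs comfortably on one CPU: the end-to-end demonstration
uses two 2 Mb chromosomes with 150 promoter and 150 distal sites and
completes in well under five minutes; the efficiency-recovery experiment
uses four 15 Mb chromosomes with 2,000 promoters and 4,000 distal sites.

What the generator does *not* emulate — mappability structure, fragment
length variation, copy-number variation, chromatin-state autocorrelation,
sequence-driven Poisson over-dispersion — limits what passing tests show
about real data: the pipeline's statistical contracts are verified, but
thresholds such as z >= 4 or the blacklist multiplier may need adjustment
for real genomes.

# Numerical choices and degenerate inputs

* RoE calling: input pseudocount 0.5; zero-input-total errors.
* Efficiency fitting requires at least 50 promoters (configurable); a
  degenerate (constant) log-ratio distribution snaps the mode to the grid.
* The ranked-signal cutoff is undefined when all signals are equal (no
  point has slope above 1) — no super-enhancers are flagged; fewer than
  three rankable regions warns and flags none.
* Segmentation errors on an all-zero control track; the homogeneous track
  collapses to a single segment.
* Smoothing kernels are truncated at four bandwidths; profiles default to
  sigma 100 bp sampled every 10 bp.
* Peak matching breaks distance ties toward the lower coordinate, making
  the greedy matching deterministic.
* The count-matching cutoff treats "at most the target" as binding and
  discards whole tie groups that would overshoot; the opposite ("at
  least") reading would retain them.

# Known limitations

The IDR analog is not numerically interchangeable with copula-based
estimators. The BIC segmentation is a defined analog of read-count
segmentation tools, not a reimplementation. Cross-pair consistency of the
per-sample efficiency factors is reported as a diagnostic, not enforced:
with pairwise fitting the two wild-type replicates each serve as their
pair's reference. GO enrichment treats the term-gene map as flat and does
not propagate the ontology graph.
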