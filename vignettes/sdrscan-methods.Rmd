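---
title: "Detecting male-specific genomic regions from resequencing depth"
author: "sdrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting male-specific genomic regions from resequencing depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(sdrscan)
  library(GenomicRanges)
})
```

## The problem

In many fishes with genetic sex determination there is no morphologically
distinct sex chromosome; instead one sex carries a sex-determination region
(SDR) — a stretch of sequence present on only one haplotype. In an XY/XX
system the Y-linked region is *hemizygous*: a male carries one copy, a
female none. Whole-genome resequencing of males and females mapped to a
common reference then leaves a characteristic depth signature. Writing the
autosomal (diploid) depth as $D$, the expectation inside a Y-hemizygous
region is

$$
\mathbb{E}[\text{depth}] \approx
\begin{cases}
D/2 & \text{males (one copy instead of two)} \\
\approx 0 & \text{females (no copy; residual cross-mapping only)}
\end{cases}
$$

while both sexes sit at $D$ elsewhere. `sdrscan` turns that signature into
a tested detection procedure, and packages the surrounding quality-control
computations such a study needs: assembly contiguity statistics with
telomere detection at contig ends, and CpG methylation summaries including
methylation-dependent restriction-enzyme (methyl-RAD) site models, since
sex comparisons of this kind are typically run alongside epigenomic
profiling of the same animals.

Everything is exercisable on synthetic data: the package ships a generator
that plants hemizygous regions into a toy genome and draws per-base depth
and per-read CpG calls with the statistical structure the detector assumes.

## The detection procedure

Detection is a two-pass scan.

**Pass 1 — discovery at 50-kb resolution.** Per-base depth for each sample
is averaged in non-overlapping 50-kb windows (the terminal window of each
sequence is truncated and divides by its actual width). Each sample is then
normalized by its genome-wide *median* window coverage, putting the diploid
level at 1 regardless of library size; the median is robust to the SDR
itself, which occupies a small fraction of the genome. For every window a
Welch (unequal-variance) two-sample *t*-test compares male versus female
normalized coverages, and Benjamini–Hochberg adjustment is applied across
all windows genome-wide. A window is flagged male-specific when three
conditions hold:

1. $q \le \alpha$ (default $\alpha = 0.05$),
2. male mean > female mean (direction), and
3. female mean $\le$ 0.5 × the female autosomal level (magnitude).

Significance alone would also catch female-biased or merely noisy windows;
the direction and magnitude gates encode the hemizygosity model. The
discovery-stage magnitude gate is deliberately loose (half-depletion): a
50-kb window that only partially overlaps a true region — e.g. 20 kb of SDR
in a 50-kb window leaves the female mean near 0.6 — must survive discovery
so that refinement can trim it. A strict gate here would make any region
shorter than ~90% of a window undiscoverable. Runs of adjacent flagged
windows are merged into coarse regions; a run never extends across a
non-flagged window, so a male-specific complex interrupted by a
non-sex-specific stretch stays split into parts. Regions shorter than
10 kb are dropped.

**Pass 2 — refinement at 1-kb resolution.** Each coarse region, extended by
one coarse window on both sides, is re-binned on an absolute 1-kb grid. A
bin is kept when its normalized female mean is $\le$ 0.10 *and* its
normalized male mean is $\ge$ 0.25 — the strict hemizygosity gate, applied
where there is enough signal per bin to afford it. Maximal runs of passing
bins become the refined regions, the 10-kb minimum is re-applied, and each
refined region receives a least-squares regression of male mean coverage
against bin midpoint (slope ≈ 0 and intercept ≈ 0.5 are what a clean
hemizygous region should show; a sloped fit is a warning sign of a
collapsed repeat or copy-number gradient rather than simple hemizygosity).
The two-pass design reconciles a block-based discovery scan with region
sizes that are not multiples of the block: refined boundaries land within
one bin of the truth, and called lengths like 41, 19 or 12 kb are
representable.

Finally, candidate regions can be intersected with marker loci (BED) —
previously mapped sex-linked markers falling inside a called region are the
usual external validation — and summarised as a per-sequence kb table.

### Choices fixed by convention

* **Welch, two-sided.** Between a hemizygous (male) and an absent (female)
  signal the group variances differ by construction, so the
  unequal-variance form is the safe default; direction is enforced by the
  post-gate rather than by a one-sided test.
* **Zero-variance windows.** Both groups constant and equal gives $t = 0$,
  $p = 1$; constant and unequal gives $p = 0$ and the window is flagged
  (subject to the gates). This avoids NaN propagation while keeping
  obviously discriminating windows.
* **Coordinates.** In R, intervals live in `GRanges` (1-based, closed).
  BED input/output is 0-based half-open and converted at the boundary;
  depth TSVs are 1-based as emitted by standard depth callers.

## The synthetic-data generator

`SimConfig()` holds the study conditions; its defaults are the conditions
under which the package's own tests run: a 2-Mb genome over two sequences
(GC 0.37), a planted 300-kb and a planted 40-kb hemizygous region, five
males and five females at mean depth 40, male in-region factor 0.5 and
female in-region factor 0.02 (residual cross-mapping rather than exactly
zero). Per-base counts are negative binomial with dispersion 0.2
(`dispersion = 0` gives the Poisson limit); the dispersion default is a
free choice — per-sample depth variance is rarely reported — exposed in the
configuration. Telomeric ends carry exact tandem `TTAGGG` arrays (reverse
complement `CCCTAA` on left ends) written over the terminal bases so that
planted-region coordinates are unaffected. CpG methylation is drawn
per site from a bimodal mixture (Beta around a low mode 0.05 and a high
mode 0.95, weights 0.4/0.6 so that slightly more than half of sites are
methylated, as typically observed in vertebrate genomes), then per-read
flags are Bernoulli draws at the site frequency.

```{r, eval = FALSE}
cfg <- SimConfig()            # the standard study conditions
study <- simulateStudy(cfg)   # genome + truth + depth tracks + CpG calls
writeSimulation(study, "sim") # FASTA, BED, TSVs, JSON sidecar
```

What the generator deliberately does **not** emulate: spatial
autocorrelation of real coverage (mappability, GC bias, repeats), read-level
artifacts, alignment errors, decayed or interrupted telomere arrays, and
the fragment-size physics of real enzyme digestion. Passing tests therefore
demonstrate that the procedure is correct *under its stated model* — exact
boundary recovery (Jaccard ≈ 1) on synthetic data is the model's best case,
and real data with mappability structure will do worse, particularly at
repeat-rich boundaries. The t-test's tolerance to overdispersion is
exercised (dispersion 0.2), but clustered artifacts that mimic depleted
female coverage (e.g. female-specific reference gaps) are exactly the kind
of signal the marker intersection step is there to guard against.

## Assembly statistics and telomeres

`contigStats()` computes N50/N90 with the common cumulative convention
(sort lengths descending, accumulate until $\ge$ half resp. 90% of the
total; stated explicitly because the convention is often left implicit),
gap statistics as maximal runs of `N`, and GC over non-N bases.
`foldChange()` and `anchoringRate()` reproduce the derived arithmetic of
assembly reports — improvement ratios new/old for N50, reduction ratios
old/new for gap length, anchoring percentages — rounded to 2 decimals as
printed; zero denominators yield `NA`, never infinity.

`findTelomeres()` scans the first/last 10 kb of every sequence for the
vertebrate telomere motif (`TTAGGG` at right ends, `CCCTAA` at left ends),
counting non-overlapping occurrences left-to-right. Interruptions within
the scan window are allowed — the criterion is high copy number (default
$\ge$ 10), not a perfect tandem array. In a 10-kb window of random sequence
the expected motif count is ~2, so the threshold of 10 gives a per-end
false-flag probability on the order of $10^{-4}$; the null is verified
empirically in the test suite (100 GC-matched 100-kb sequences, zero
flags). A direct end-scan can miss heavily decayed telomeres that
repeat-annotation pipelines would still report; that discrepancy is
accepted, not tuned away.

## CpG methylation

`enumerateCpG()` reports every plus-strand `CG` dinucleotide once, at the C
position. `methylFrequency()` aggregates per-read calls into per-site
(total, methylated, frequency) and removes sites with fewer than 10
supporting reads — low-coverage sites are the dominant source of
false-positive frequency estimates. The retention rule is
`total_reads >= 10` (a stated removal of "fewer than 10" and a stated
retention of "more than 10" cannot both be strict; $\ge 10$ is the
consistent resolution and is applied uniformly).

The methylation-dependent enzymes used by methyl-RAD assays are modelled as
recognition motifs with a methylatable-C offset: `FspEI` as `CC` with the
second C methylatable, `MspJI` as `CNNR` with the first. Both strands are
scanned (IUPAC codes honoured in the motif, `N` in the genome never
matches) and every tag is reported at its methylatable C in plus-strand
coordinates. The published assay descriptions do not pin down the
recognition sequences precisely, so the models are configuration-driven
(`enzymeModel("custom", motif =, offset =)`) and the defaults are not tuned
to reproduce any published tag count. `overlapSites()` asks what fraction
of tags coincide with a retained CpG site, mapping minus-strand tags to the
plus-strand C of the symmetric CpG when the genome has one. Site tables
themselves are always keyed by the plus-strand C — per-read calls reference
that position directly, so both strands' evidence is already pooled there
and no separate strand-merging step exists to configure.

## The differential-methylation screen

Real methyl-RAD comparisons fit per-site negative-binomial dispersions
(edgeR's qCML). `dmsTest()` instead implements a deliberately simple,
desk-verifiable screen in the same decision role: pool counts within sex,
condition on the pooled site total, and test the male share against the
male share of the summed library sizes with a two-sided exact binomial test
(the conditioning *is* the library-size/CPM normalization); BH-adjust and
report sites at FDR < 0.01 after removing sites with pooled total below 10.

The exact conditional test is calibrated under Poisson sampling, and the
tag-count simulator is therefore Poisson by default: on a 1,000-site null
the screen yields essentially zero discoveries (verified over 20
replicates), and a 4-fold spiked effect at 20 reads/site is recovered with
full power. Under *overdispersed* counts (`dispersion > 0` in
`simulateSiteCounts()`) the pooled binomial test is anticonservative —
between-sample variability masquerades as signal — which is precisely why
the field fits NB dispersion for such data. This is a known, documented
limitation of the simple screen: its false-discovery control should be
trusted only as far as the Poisson approximation holds, and findings on
real tag data should be confirmed with a dispersion-aware model.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while staying comfortably
interactive: the standard 2-Mb recovery simulation (5v5 at 40×), twenty
1-Mb null replicates for specificity, twenty 1,000-site null replicates for
the DMS screen, one hundred random instances per brute-force oracle
comparison (window means, Welch statistics, N50/L50, CpG and enzyme-site
scans, all agreeing within $10^{-9}$ or exactly), and one hundred
GC-matched 100-kb sequences for the telomere null. Genome-scale inputs
change none of the algorithms — only the window counts.

## Known limitations

* Coverage is modelled per base i.i.d.; real depth is autocorrelated, so
  effective per-window sample sizes are smaller than the simulation's and
  real boundary precision will be worse than the 1-bin recovery seen here.
* The detector assumes exactly two sexes with $\ge 2$ samples each and an
  XY-type (male-hemizygous) signature; a ZW system requires swapping the
  labels.
* The DMS screen ignores overdispersion (see above).
* Telomere detection is a direct motif scan; decayed arrays may be missed.
* Mapping-quality filtering (e.g. MAPQ $\ge$ 20) is expected to happen
  upstream of the depth TSVs and is documented, not re-applied, here.
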