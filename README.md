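# sdrscan

Coverage-based detection of male-specific (sex-determination) regions from
male/female whole-genome resequencing, with the assembly-QC and CpG
methylation summaries that accompany such a study.

Many fishes (and other taxa) with an XY/XX genetic sex-determination system
have no cytologically distinct sex chromosome — only a sex-determination
region (SDR) carried on the Y haplotype. Because that region is
**hemizygous**, resequencing males and females against a common reference
leaves a depth signature: writing the autosomal diploid depth as *D*, a
Y-hemizygous interval sits near *D*/2 in males and near 0 in females, while
everything else sits at *D* in both sexes. `sdrscan` is for geneticists
running exactly this comparison: it takes per-base depth tracks plus a
sample–sex table and returns tested, refined candidate regions.

The detector works in two passes:

1. **Discovery (50-kb windows).** Mean depth per window per sample,
   median-normalized per sample (autosomal level = 1); per-window Welch
   *t*-test of male vs female with Benjamini–Hochberg adjustment
   genome-wide; a window is flagged iff *q* ≤ 0.05, male mean > female
   mean, and the female mean is at most half the female autosomal level.
   Runs of adjacent flagged windows are merged — never across a non-flagged
   window — and runs shorter than 10 kb are dropped.
2. **Refinement (1-kb bins).** Around each coarse region, 1-kb bins are
   kept iff normalized female mean ≤ 0.10 and male mean ≥ 0.25 (the
   hemizygous expectation is ≈ 0 and ≈ 0.5); maximal runs become the
   refined regions, each with a least-squares fit of male coverage vs
   position (a clean hemizygous region has slope ≈ 0, intercept ≈ 0.5).

Alongside the detector the package provides: assembly contiguity statistics
(N50/L50, gaps, GC) with fold-change/anchoring report arithmetic; telomere
(`TTAGGG`/`CCCTAA`) detection at sequence ends; CpG enumeration and
methylation-frequency tables with a ≥ 10-read support filter; FspEI/MspJI
methylation-dependent enzyme site models and tag/CpG overlap; a per-site
differential-methylation screen (pooled exact conditional binomial, FDR
< 0.01); and a synthetic-data generator that plants hemizygous regions and
bimodal CpG methylation so the whole pipeline is testable offline.

## Worked example

Simulate the kind of data the detector expects — here a 900-kb toy genome
with a planted 150-kb and a planted 40-kb hemizygous region, five males and
five females at 40× — then run the two-pass scan:

```r
library(sdrscan)
library(GenomicRanges)

cfg <- SimConfig(
  seqLengths = c(chr1 = 600000L, chr2 = 300000L),
  regions = GRanges(c("chr1", "chr2"),
                    IRanges(c(200001, 120001), c(350000, 160000))),
  seed = 20210906L)
study <- simulateStudy(cfg)

wc      <- normalizeCoverage(windowCoverage(study$tracks, study$sex))
wt      <- testWindows(wc)
regions <- refineRegions(callRegions(wt), study$tracks, wc)
as.data.frame(regions)
#>   seqnames  start    end  width strand  maleMean femaleMean nBins        slope
#> 1     chr1 200001 350000 150000      * 0.5004779 0.02002178   150 2.633526e-09
#> 2     chr2 120001 160000  40000      * 0.5005750 0.02000784    40 7.227620e-09
#>   intercept
#> 1 0.4997537
#> 2 0.4995631
```

Both planted regions come back with exact boundaries. The normalized male
mean ≈ 0.50 and female mean ≈ 0.02 are the hemizygous signature itself
(one Y copy vs residual cross-mapping), and the near-zero slopes say the
coverage is flat across each region, as simple hemizygosity predicts.

The QC and methylation stages run from the same objects:

```r
tel <- findTelomeres(study$genome)
sprintf("telomeres: %d of %d ends", tel$detected, tel$totalEnds)
#> "telomeres: 4 of 4 ends"

freq <- methylFrequency(study$meth$calls, minReads = 10)
m <- S4Vectors::metadata(freq)
sprintf("CpG sites: %d, retained at >=10 reads: %d (%.1f%%)",
        m$nSites, m$nRetained, 100 * m$retainedFraction)
#> "CpG sites: 30822, retained at >=10 reads: 30415 (98.7%)"

summaryReport(regions = regions)$text[4:6]
#> ## Male-specific regions (kb per sequence)
#> chr1    150.0
#> chr2    40.0
```

`runPipeline(cfg, outdir)` chains all stages, writes deterministic
TSV/BED/JSON outputs stamped with a configuration hash, and logs per-stage
record counts. Real data enter through `readDepthTrack()` (3-column depth
TSV or 4-column bedGraph), `readSampleSheet()`, `readMarkers()` (BED) and
`readMethylCalls()`.

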