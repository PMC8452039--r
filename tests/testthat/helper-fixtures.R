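suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(Biostrings)
})

.fixture_cache <- new.env(parent = emptyenv())

# the standard study conditions: 2-Mb genome, planted 300-kb + 40-kb
# regions, 5 male / 5 female at 40x, NB dispersion 0.2, fixed seed
standard_study <- function() {
  if (is.null(.fixture_cache$study))
    .fixture_cache$study <- simulateStudy(SimConfig())
  .fixture_cache$study
}

standard_sdr <- function() {
  if (is.null(.fixture_cache$sdr)) {
    study <- standard_study()
    wc <- normalizeCoverage(windowCoverage(study$tracks, study$sex))
    wt <- testWindows(wc)
    coarse <- callRegions(wt)
    refined <- refineRegions(coarse, study$tracks, wc)
    .fixture_cache$sdr <- list(wc = wc, wt = wt, coarse = coarse,
                               refined = refined)
  }
  .fixture_cache$sdr
}

# build an RleList depth track from plain integer vectors
make_track <- function(...) {
  as(lapply(list(...), S4Vectors::Rle), "RleList")
}

# assemble a WindowCoverage directly from a coverage matrix
make_wc <- function(mat, sex, windowSize = 50000L, normFactor = 1) {
  windows <- GenomicRanges::tileGenome(
    c(chrT = nrow(mat) * windowSize), tilewidth = windowSize,
    cut.last.tile.in.chrom = TRUE)
  se <- SummarizedExperiment(
    assays = list(coverage = mat), rowRanges = windows,
    colData = S4Vectors::DataFrame(
      sex = sex, normFactor = rep(normFactor, length(sex)),
      row.names = colnames(mat)))
  S4Vectors::metadata(se)$windowSize <- windowSize
  new("WindowCoverage", se)
}

# window-test GRanges from a flag pattern (one sequence, 50-kb windows)
make_window_results <- function(flags, windowSize = 50000L,
                                maleMean = 0.5, femaleMean = 0.02) {
  n <- length(flags)
  gr <- GRanges("chrT", IRanges(start = (seq_len(n) - 1) * windowSize + 1,
                                width = windowSize))
  mcols(gr) <- S4Vectors::DataFrame(
    maleMean = ifelse(flags, maleMean, 1), femaleMean = ifelse(flags, femaleMean, 1),
    t = ifelse(flags, 50, 0), p = ifelse(flags, 1e-10, 0.8),
    q = ifelse(flags, 1e-9, 0.9), flag = as.logical(flags))
  S4Vectors::metadata(gr) <- list(windowSize = windowSize)
  gr
}
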