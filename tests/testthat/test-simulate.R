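test_that("flagged ends carry exact tandem telomere arrays", {
  cfg <- SimConfig(seqLengths = c(chrA = 20000L, chrB = 20000L),
                   regions = GRanges(),
                   telomereEnds = c("chrA:right", "chrB:left"),
                   telomereCopies = 30L, seed = 11L)
  g <- simulateGenome(cfg)
  tailA <- as.character(subseq(g$genome$chrA, 20000 - 180 + 1, 20000))
  expect_identical(tailA, paste(rep("TTAGGG", 30), collapse = ""))
  headB <- as.character(subseq(g$genome$chrB, 1, 180))
  expect_identical(headB, paste(rep("CCCTAA", 30), collapse = ""))
  # unflagged ends are not telomeric arrays
  headA <- as.character(subseq(g$genome$chrA, 1, 180))
  expect_false(identical(headA, paste(rep("CCCTAA", 30), collapse = "")))
})

test_that("gcFraction 0 yields AT-only background sequence", {
  cfg <- SimConfig(seqLengths = c(chrA = 5000L), regions = GRanges(),
                   gcFraction = 0, telomereEnds = character(), seed = 4L)
  g <- simulateGenome(cfg)
  freq <- Biostrings::alphabetFrequency(g$genome$chrA)
  expect_identical(sum(freq[c("G", "C")]), 0L)
  expect_identical(sum(freq[c("A", "T")]), 5000L)
})

test_that("identical config gives byte-identical files; seeds only change data", {
  cfg1 <- SimConfig(seqLengths = c(chrA = 30000L),
                    regions = GRanges("chrA", IRanges(10001, 22000)),
                    nMale = 2L, nFemale = 2L, meanDepth = 10, seed = 7L)
  cfg2 <- SimConfig(seqLengths = c(chrA = 30000L),
                    regions = GRanges("chrA", IRanges(10001, 22000)),
                    nMale = 2L, nFemale = 2L, meanDepth = 10, seed = 8L)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  d3 <- file.path(tempdir(), "sim_c")
  writeSimulation(simulateStudy(cfg1), d1)
  writeSimulation(simulateStudy(cfg1), d2)
  writeSimulation(simulateStudy(cfg2), d3)
  for (f in c("genome.fasta", "truth_regions.bed", "depth_M1.tsv",
              "methyl_calls.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  # different seed: different depth, identical truth regions
  expect_false(identical(unname(tools::md5sum(file.path(d1, "depth_M1.tsv"))),
                         unname(tools::md5sum(file.path(d3, "depth_M1.tsv")))))
  expect_identical(readLines(file.path(d1, "truth_regions.bed")),
                   readLines(file.path(d3, "truth_regions.bed")))
  # conservation: one BED row per planted region
  expect_length(readLines(file.path(d1, "truth_regions.bed")),
                length(cfg1@regions))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("planted regions out of bounds are rejected by name", {
  expect_error(
    SimConfig(seqLengths = c(chrA = 1000L),
              regions = GRanges("chrA", IRanges(500, 2000))),
    "out of bounds.*chrA")
  expect_error(
    SimConfig(seqLengths = c(chrA = 1000L),
              regions = GRanges("chrZ", IRanges(1, 10))),
    "unknown sequence")
})

test_that("depth generator hits its mean in the Poisson limit", {
  cfg <- SimConfig(seqLengths = c(chrA = 1000000L), regions = GRanges(),
                   nMale = 1L, nFemale = 1L, meanDepth = 40, dispersion = 0,
                   telomereEnds = character(), seed = 21L)
  g <- simulateGenome(cfg)
  d <- simulateDepth(g$genome, g$truth, cfg)
  for (sm in names(d$tracks)) {
    m <- mean(as.integer(d$tracks[[sm]]$chrA))
    expect_lt(abs(m - 40) / 40, 0.01)
  }
})

test_that("femaleFactor 0 forces zero female depth inside planted regions", {
  cfg <- SimConfig(seqLengths = c(chrA = 50000L),
                   regions = GRanges("chrA", IRanges(20001, 35000)),
                   nMale = 1L, nFemale = 1L, femaleFactor = 0,
                   telomereEnds = character(), seed = 5L)
  g <- simulateGenome(cfg)
  d <- simulateDepth(g$genome, g$truth, cfg)
  inside <- as.integer(d$tracks$F1$chrA)[20001:35000]
  expect_true(all(inside == 0L))
  expect_gt(mean(as.integer(d$tracks$F1$chrA)[1:20000]), 30)
})

test_that("zero requested samples is an error", {
  cfg <- SimConfig(seqLengths = c(chrA = 10000L), regions = GRanges(),
                   nMale = 0L, nFemale = 0L, telomereEnds = character())
  g <- simulateGenome(cfg)
  expect_error(simulateDepth(g$genome, g$truth, cfg), "at least one sample")
})

test_that("male inside/outside depth ratio converges to maleFactor", {
  study <- standard_study()
  reg <- study$truth$regions[1]  # the planted 300-kb region on chr1
  for (sm in c("M1", "M3")) {
    v <- as.integer(study$tracks[[sm]]$chr1)
    inside <- mean(v[start(reg):end(reg)])
    outside <- mean(v[-(start(reg):end(reg))])
    expect_lt(abs(inside / outside - 0.5), 0.05)
  }
})

test_that("methylation generator honours degenerate mixtures and truth", {
  # all sites from the low component with mode exactly 0
  cfg0 <- SimConfig(seqLengths = c(chrA = 20000L), regions = GRanges(),
                    telomereEnds = character(), methWeights = c(1, 0),
                    methModes = c(0, 0.95), seed = 31L)
  g <- simulateGenome(cfg0)
  m <- simulateMethylation(g$genome, cfg0)
  expect_true(all(m$truth$frequency == 0))
  expect_true(all(m$calls$methylated == 0L))
  # all sites fully methylated -> every read methylated
  cfg1 <- SimConfig(seqLengths = c(chrA = 20000L), regions = GRanges(),
                    telomereEnds = character(), methWeights = c(0, 1),
                    methModes = c(0, 1), seed = 32L)
  m1 <- simulateMethylation(simulateGenome(cfg1)$genome, cfg1)
  expect_true(all(m1$truth$frequency == 1))
  expect_true(all(m1$calls$methylated == 1L))
})

test_that("site frequency estimates concentrate at high coverage", {
  cfg <- SimConfig(seqLengths = c(chrA = 50000L), regions = GRanges(),
                   telomereEnds = character(), meanDepth = 1000,
                   dispersion = 0, seed = 33L)
  g <- simulateGenome(cfg)
  m <- simulateMethylation(g$genome, cfg)
  est <- methylFrequency(m$calls, minReads = 1L)
  key <- paste0(m$truth$seq, ":", m$truth$pos)
  truth <- stats::setNames(m$truth$frequency, key)
  err <- abs(est$frequency -
             truth[paste0(seqnames(est), ":", start(est))])
  expect_gte(mean(err <= 0.05), 0.95)
})

test_that("a CpG-free genome yields an empty methylation table with a warning", {
  cfg <- SimConfig(seqLengths = c(chrA = 1000L), regions = GRanges(),
                   gcFraction = 0, telomereEnds = character(), seed = 2L)
  g <- simulateGenome(cfg)
  expect_warning(m <- simulateMethylation(g$genome, cfg), "no CpG")
  expect_identical(nrow(m$calls), 0L)
})
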