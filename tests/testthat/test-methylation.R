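test_that("CpG enumeration reports each plus-strand CG once at its C", {
  sites <- enumerateCpG(DNAStringSet(c(s = "ACGCG")))
  expect_equal(start(sites), c(2, 4))
  sites2 <- enumerateCpG(DNAStringSet(c(s = "CGCGCG")))
  expect_equal(start(sites2), c(1, 3, 5))
  # N-containing dinucleotides are skipped
  sites3 <- enumerateCpG(DNAStringSet(c(s = "CNGCG")))
  expect_equal(start(sites3), 4)
})

test_that("CpG enumeration matches a character-scan oracle", {
  set.seed(17)
  for (rep in 1:20) {
    s <- random_dna(10000, gc = runif(1, 0.2, 0.7))
    sites <- enumerateCpG(DNAStringSet(c(x = s)))
    expect_identical(start(sites), cpg_oracle(s))
  }
})

test_that("methylation frequency applies the read-support filter", {
  calls <- data.frame(
    seq = rep("c", 21),
    pos = c(rep(10L, 12), rep(50L, 9)),
    read_id = paste0("r", 1:21),
    methylated = c(rep(1L, 6), rep(0L, 6), rep(1L, 9)))
  tab <- methylFrequency(calls, minReads = 10L)
  expect_length(tab, 1)          # the 9-read site never appears
  expect_equal(start(tab), 10)
  expect_equal(tab$total_reads, 12L)
  expect_equal(tab$frequency, 0.5)
  expect_equal(S4Vectors::metadata(tab)$retainedFraction, 0.5)
})

test_that("retained-site fraction equals a brute-force recount", {
  cfg <- SimConfig(seqLengths = c(chrA = 30000L), regions = GRanges(),
                   telomereEnds = character(), meanDepth = 12,
                   seed = 55L)
  g <- simulateGenome(cfg)
  m <- simulateMethylation(g$genome, cfg)
  tab <- methylFrequency(m$calls, minReads = 10L)
  cov <- table(paste0(m$calls$seq, ":", m$calls$pos))
  expect_equal(S4Vectors::metadata(tab)$nRetained, sum(cov >= 10))
  expect_equal(S4Vectors::metadata(tab)$nSites, length(cov))
  expect_true(all(tab$total_reads >= 10))
  expect_true(all(tab$frequency >= 0 & tab$frequency <= 1))
  expect_lte(sum(tab$methylated_reads), sum(tab$total_reads))
})

test_that("invalid methylated flags are rejected", {
  calls <- data.frame(seq = "c", pos = 1L, read_id = "r", methylated = 2L)
  expect_error(methylFrequency(calls), "0 or 1")
})

test_that("enzyme site models place the methylatable C on both strands", {
  fspei <- enzymeSites(DNAStringSet(c(s = "ACCT")), "FspEI")
  plus <- fspei[strand(fspei) == "+"]
  expect_equal(start(plus), 3)  # second C of the CC
  mspji <- enzymeSites(DNAStringSet(c(s = "CTTG")), "MspJI")
  expect_equal(start(mspji[strand(mspji) == "+"]), 1)  # C of CNNR
  # minus strand: plus-strand GG holds a CC on the minus strand
  rev <- enzymeSites(DNAStringSet(c(s = "AGGT")), "FspEI")
  expect_equal(start(rev), 2)
  expect_equal(as.character(strand(rev)), "-")
})

test_that("degenerate motif scans match the brute-force IUPAC oracle", {
  set.seed(23)
  for (enz in c("FspEI", "MspJI")) {
    model <- enzymeModel(enz)
    for (rep in 1:10) {
      s <- random_dna(10000, gc = 0.4)
      got <- enzymeSites(DNAStringSet(c(x = s)), enz)
      ora <- enzyme_oracle(s, model$motif, model$offset)
      expect_identical(start(got[strand(got) == "+"]), sort(ora$plus))
      expect_identical(start(got[strand(got) == "-"]), sort(ora$minus))
    }
  }
})

test_that("custom enzyme models are validated", {
  expect_error(enzymeModel("custom"), "motif and offset")
  expect_error(enzymeModel("custom", motif = "CXZ", offset = 0), "IUPAC")
  expect_error(enzymeModel("custom", motif = "CC", offset = 5), "inside")
  m <- enzymeModel("custom", motif = "YCG", offset = 1L)
  got <- enzymeSites(DNAStringSet(c(x = "TCGA")), m)
  expect_equal(start(got[strand(got) == "+"]), 2)
})

test_that("overlap handles the trivial extremes and strand mapping", {
  g <- DNAStringSet(c(x = "ACGTACGTCCGG"))
  cpg <- enumerateCpG(g)
  tagsAtCpG <- GRanges("x", IRanges(start(cpg), width = 1), strand = "+")
  expect_equal(overlapSites(tagsAtCpG, cpg)$percent, 100)
  # CpG-free sequence: FspEI tags exist but no CpG to hit
  g2 <- DNAStringSet(c(y = "ACCTACCTAA"))
  tags2 <- enzymeSites(g2, "FspEI")
  expect_gt(length(tags2), 0)
  expect_equal(overlapSites(tags2, enumerateCpG(g2))$percent, 0)
  # minus-strand tag at the G of a symmetric CpG maps to the plus C
  g3 <- DNAStringSet(c(z = "ACCGGT"))
  tags3 <- enzymeSites(g3, "FspEI")
  minus <- tags3[strand(tags3) == "-"]
  cpg3 <- enumerateCpG(g3)
  ov <- overlapSites(minus, cpg3)
  expect_equal(ov$overlapping, length(minus))
})

test_that("overlap percentage is invariant under tag permutation", {
  set.seed(29)
  g <- DNAStringSet(c(x = random_dna(20000, 0.5)))
  tags <- enzymeSites(g, "MspJI")
  cpg <- enumerateCpG(g)
  a <- overlapSites(tags, cpg)
  b <- overlapSites(tags[sample(length(tags))], cpg)
  expect_equal(a$percent, b$percent)
  expect_equal(a$overlapping, b$overlapping)
})

test_that("overlap summaries print to one decimal", {
  expect_equal(overlapSummary(999713, 1354625)$percent, 73.8)
  expect_equal(overlapSummary(1886723, 2613191)$percent, 72.2)
  expect_true(is.na(overlapSummary(0, 0)$percent))
})

test_that("differential methylation screen behaves at the extremes", {
  sim <- simulateSiteCounts(50, seed = 61L)
  same <- matrix(rep(sim$counts[, 1], 6), ncol = 6,
                 dimnames = list(rownames(sim$counts), names(sim$sex)))
  res <- dmsTest(same, sim$sex)
  expect_equal(attr(res, "nSignificant"), 0L)

  counts <- matrix(20L, nrow = 3, ncol = 6,
                   dimnames = list(paste0("s", 1:3), names(sim$sex)))
  counts[2, sim$sex == "male"] <- c(40L, 30L, 30L)
  counts[2, sim$sex == "female"] <- 0L
  res2 <- dmsTest(counts, sim$sex)
  i <- which(res2$site == "s2")
  lib <- colSums(counts)
  p0 <- sum(lib[sim$sex == "male"]) / sum(lib)
  expect_equal(res2$p[i], binom_oracle(100, 100, p0), tolerance = 1e-9)
  expect_true(res2$significant[i])
})

test_that("weakly covered sites are removed before testing", {
  sx <- c(M1 = "male", M2 = "male", F1 = "female", F2 = "female")
  counts <- matrix(c(2L, 30L), nrow = 2, ncol = 4,
                   dimnames = list(c("low", "high"), names(sx)))
  res <- dmsTest(counts, sx, minTotal = 10L)
  expect_identical(res$site, "high")
  expect_equal(attr(res, "nInput"), 2L)
  expect_equal(attr(res, "nTested"), 1L)
})

test_that("count matrix validation", {
  sx <- c("male", "male", "female", "female")
  expect_error(dmsTest(matrix(1.5, 2, 4), sx), "integer")
  expect_error(dmsTest(matrix(1L, 2, 3), c("male", "male", "female")),
               ">= 2 samples")
})

test_that("exact binomial p-values match the enumeration oracle broadly", {
  set.seed(37)
  for (rep in 1:50) {
    n <- sample(10:200, 1)
    x <- sample(0:n, 1)
    p <- runif(1, 0.2, 0.8)
    expect_equal(sdrscan:::.exactBinomP(x, n, p), binom_oracle(x, n, p),
                 tolerance = 1e-9)
  }
})
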