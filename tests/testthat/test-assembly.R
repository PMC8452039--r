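test_that("contiguity statistics handle degenerate and known inputs", {
  one <- DNAStringSet(c(a = paste(rep("A", 100), collapse = "")))
  s <- contigStats(one)
  expect_equal(s@nX[["N50"]], 100)
  expect_equal(s@lX[["L50"]], 1L)

  lens <- 1:10  # total 55; cumulative from the top reaches 27.5 at length 7
  seqs <- DNAStringSet(vapply(lens, function(n)
    paste(rep("C", n), collapse = ""), ""))
  names(seqs) <- paste0("s", lens)
  s10 <- contigStats(seqs)
  expect_equal(s10@nX[["N50"]], 7)
  ora <- n50_oracle(lens)
  expect_equal(s10@nX[["N50"]], ora$n)
  expect_equal(s10@lX[["L50"]], ora$l)
})

test_that("gap runs and GC fraction are counted over the right bases", {
  s <- contigStats(DNAStringSet(c(a = "ACGTNNNNACGT")))
  expect_equal(s@gapLength, 4)
  expect_equal(s@gapCount, 1L)
  expect_equal(s@gcFraction, 0.5)  # GC among the 8 non-N bases
  # multiple runs across sequences
  s2 <- contigStats(DNAStringSet(c(a = "NNACGTNN", b = "AANN")))
  expect_equal(s2@gapLength, 6)
  expect_equal(s2@gapCount, 3L)
})

test_that("N50 matches the brute-force oracle on random length multisets", {
  set.seed(42)
  for (rep in 1:200) {
    lens <- sample(1:500, sample(1:30, 1), replace = TRUE)
    seqs <- DNAStringSet(vapply(lens, function(n)
      paste(rep("G", n), collapse = ""), ""))
    names(seqs) <- paste0("s", seq_along(lens))
    s <- contigStats(seqs)
    o50 <- n50_oracle(lens, 0.5); o90 <- n50_oracle(lens, 0.9)
    expect_identical(s@nX[["N50"]], as.numeric(o50$n))
    expect_identical(s@lX[["L50"]], o50$l)
    expect_identical(s@nX[["N90"]], as.numeric(o90$n))
    # invariants: NX non-increasing in X, total >= largest >= N50
    expect_lte(s@nX[["N90"]], s@nX[["N50"]])
    expect_gte(s@largest, s@nX[["N50"]])
    expect_gte(s@totalLength, s@largest)
  }
})

test_that("GC and AT fractions sum to one over non-N bases", {
  set.seed(7)
  seqs <- DNAStringSet(c(a = random_dna(5000, gc = 0.37),
                         b = paste0(random_dna(1000, gc = 0.6), "NNNN")))
  s <- contigStats(seqs)
  af <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  at <- (af[["A"]] + af[["T"]]) / (s@totalLength - s@gapLength)
  expect_equal(s@gcFraction + at, 1, tolerance = 1e-12)
})

test_that("empty assemblies are rejected", {
  expect_error(contigStats(DNAStringSet()), "empty")
})

test_that("fold changes reproduce the printed report arithmetic", {
  expect_equal(foldChange(33.74e6, 83e3), 406.51)
  expect_equal(foldChange(33.74e6, 3.33e6), 10.13)
  expect_equal(foldChange(5500, 72713928, type = "reduction"), 13220.71)
  expect_equal(foldChange(5500, 11421027, type = "reduction"), 2076.55)
  expect_equal(foldChange(42, 42), 1)
  expect_equal(foldChange(42, 42, type = "reduction"), 1)
  expect_true(is.na(foldChange(10, 0)))
  expect_true(is.na(foldChange(0, 10, type = "reduction")))
})

test_that("anchoring percentages round as printed", {
  r <- anchoringRate(856.54e6, contigTotal = 857.04e6,
                     estimatedGenome = 884.62e6)
  expect_equal(r$pctOfContigs, 99.94)
  expect_equal(r$pctOfGenome, 96.83)
  expect_equal(anchoringRate(100, contigTotal = 100)$pctOfContigs, 100)
  expect_error(anchoringRate(200, contigTotal = 100), "exceeds")
})

test_that("constructed telomeric ends are always flagged", {
  left <- paste(rep("CCCTAA", 30), collapse = "")
  right <- paste(rep("TTAGGG", 30), collapse = "")
  set.seed(13)
  seqs <- DNAStringSet(c(
    both = paste0(left, random_dna(20000, 0.37), right),
    none = random_dna(20000, 0.37)))
  tel <- findTelomeres(seqs)
  ends <- tel$ends
  expect_true(ends$present[ends$seq == "both" & ends$side == "left"])
  expect_true(ends$present[ends$seq == "both" & ends$side == "right"])
  expect_gte(ends$copies[ends$seq == "both" & ends$side == "right"], 30)
  expect_equal(tel$totalEnds, 4L)
  expect_lte(tel$detected, tel$totalEnds)
})

test_that("short sequences clamp the scan window instead of erroring", {
  seqs <- DNAStringSet(c(tiny = paste(rep("TTAGGG", 12), collapse = "")))
  tel <- findTelomeres(seqs, scanWindow = 100000L)
  # whole sequence is scanned; the right end holds the TTAGGG array
  expect_true(tel$ends$present[tel$ends$side == "right"])
  expect_equal(tel$ends$copies[tel$ends$side == "right"], 12L)
})

test_that("interrupted arrays still reach high copy counts", {
  set.seed(3)
  s <- paste0(random_dna(5000, 0.37),
              paste(rep(c("TTAGGG", "TTAGGG", "ACGT"), 10), collapse = ""))
  tel <- findTelomeres(DNAStringSet(c(x = s)), minCopies = 15L)
  expect_true(tel$ends$present[tel$ends$side == "right"])
})

test_that("telomere motif validation rejects bad motifs", {
  seqs <- DNAStringSet(c(a = "ACGT"))
  expect_error(findTelomeres(seqs, motif = ""), "non-empty")
  expect_error(findTelomeres(seqs, motif = "TTAGGN"), "ACGT")
})
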