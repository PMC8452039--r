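#' Assembly contiguity and composition statistics
#'
#' N50/N90 use the common cumulative convention: sort sequences by
#' decreasing length, accumulate until the running sum first reaches at
#' least half (resp. 90%) of the total; NX is the length of the sequence
#' reaching the threshold and LX the number of sequences used. Gaps are
#' maximal runs of `N`; GC is computed over non-N bases (lowercase input is
#' treated as its uppercase base; soft-masking carries no meaning here).
#'
#' @param fasta a `DNAStringSet` or path to a FASTA file.
#' @return an [AssemblyStats-class] object.
#' @examples
#' contigStats(Biostrings::DNAStringSet(c(a = "ACGTNNNNACGT")))
#' @export
contigStats <- function(fasta) {
    seqs <- if (is.character(fasta)) readDNAStringSet(fasta) else fasta
    if (!length(seqs)) stop("empty FASTA: no sequences")
    len <- width(seqs)
    total <- sum(as.numeric(len))
    srt <- sort(len, decreasing = TRUE)
    csum <- cumsum(as.numeric(srt))
    nx <- c(N50 = 0, N90 = 0)
    lx <- c(L50 = 0L, L90 = 0L)
    for (x in c(50, 90)) {
        k <- which(csum >= total * x / 100)[1L]
        nx[[paste0("N", x)]] <- srt[k]
        lx[[paste0("L", x)]] <- k
    }
    af <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
    nN <- af[["N"]]
    gc <- (af[["G"]] + af[["C"]]) / (total - nN)
    nHits <- vmatchPattern("N", seqs)
    gaps <- lapply(seq_along(seqs), function(i) reduce(nHits[[i]]))
    new("AssemblyStats",
        nSequences = length(seqs),
        totalLength = total,
        nX = nx, lX = lx,
        largest = max(len),
        gcFraction = gc,
        gapLength = sum(vapply(gaps, function(g) sum(width(g)), 0)),
        gapCount = sum(vapply(gaps, length, 0L)),
        seqLengths = stats::setNames(as.numeric(len), names(seqs)))
}

#' Fold change between two assembly metrics
#'
#' `"improvement"` reports new/old (e.g. N50 went up), `"reduction"` reports
#' old/new (e.g. total gap length went down). Rounded to 2 decimals as
#' printed in assembly reports. A zero denominator yields `NA` (undefined),
#' never infinity.
#'
#' @param new,old positive scalars (new assembly first).
#' @param type `"improvement"` or `"reduction"`.
#' @return fold change rounded to 2 decimals, or `NA`.
#' @examples
#' foldChange(33.74e6, 83e3)                      # N50 improvement
#' foldChange(5500, 72713928, type = "reduction") # gap reduction
#' @export
foldChange <- function(new, old, type = c("improvement", "reduction")) {
    type <- match.arg(type)
    den <- if (type == "improvement") old else new
    if (is.na(den) || den == 0) return(NA_real_)
    round(if (type == "improvement") new / old else old / new, 2)
}

#' Anchoring percentages of a scaffolded assembly
#'
#' Fraction of contig sequence anchored into chromosome-level scaffolds, and
#' fraction of the estimated genome size covered; both as percentages
#' rounded to 2 decimals.
#'
#' @param anchored bases anchored to chromosomes.
#' @param contigTotal total contig bases (optional).
#' @param estimatedGenome estimated genome size in bases (optional).
#' @return list with `pctOfContigs` and `pctOfGenome` (NA when the
#'   corresponding denominator was not given).
#' @examples
#' anchoringRate(856.54e6, contigTotal = 857.04e6,
#'               estimatedGenome = 884.62e6)
#' @export
anchoringRate <- function(anchored, contigTotal = NA, estimatedGenome = NA) {
    if (anchored <= 0) stop("anchored length must be positive")
    if (!is.na(contigTotal)) {
        if (contigTotal <= 0) stop("contigTotal must be positive")
        if (anchored > contigTotal)
            stop("anchored length exceeds total contig length")
    }
    if (!is.na(estimatedGenome) && estimatedGenome <= 0)
        stop("estimatedGenome must be positive")
    list(pctOfContigs = if (is.na(contigTotal)) NA_real_
             else round(100 * anchored / contigTotal, 2),
         pctOfGenome = if (is.na(estimatedGenome)) NA_real_
             else round(100 * anchored / estimatedGenome, 2))
}

# non-overlapping left-to-right occurrence count of a motif
.countNonOverlapping <- function(subject, motif) {
    m <- matchPattern(motif, subject)
    if (!length(m)) return(0L)
    s <- start(m); e <- end(m)
    keep <- logical(length(s))
    lastEnd <- 0L
    for (i in seq_along(s)) {
        if (s[i] > lastEnd) { keep[i] <- TRUE; lastEnd <- e[i] }
    }
    sum(keep)
}

#' Scan sequence ends for telomeric repeats
#'
#' Right ends are scanned for the vertebrate telomere motif (default
#' `TTAGGG`), left ends for its reverse complement (`CCCTAA`), within
#' `scanWindow` bases of the end (clamped to the sequence length when
#' shorter). Counting is non-overlapping left-to-right; interruptions within
#' the scan window are allowed — the criterion is high copy number, not a
#' perfect tandem array. An end is called telomeric when it holds at least
#' `minCopies` copies.
#'
#' @param fasta `DNAStringSet` or FASTA path.
#' @param motif telomere repeat unit, uppercase ACGT (default `"TTAGGG"`).
#' @param scanWindow bases scanned at each end (default 10000).
#' @param minCopies copy-number threshold (default 10).
#' @return list with `ends` (data.frame: seq, side, copies, present),
#'   `detected` and `totalEnds` (= 2 x number of sequences).
#' @export
findTelomeres <- function(fasta, motif = "TTAGGG", scanWindow = 10000L,
                          minCopies = 10L) {
    seqs <- if (is.character(fasta)) readDNAStringSet(fasta) else fasta
    if (!nzchar(motif) || grepl("[^ACGT]", motif))
        stop("motif must be a non-empty uppercase ACGT string")
    rcmotif <- as.character(reverseComplement(DNAString(motif)))
    rows <- lapply(seq_along(seqs), function(i) {
        s <- seqs[[i]]
        w <- min(scanWindow, length(s))
        leftCopies <- .countNonOverlapping(subseq(s, 1L, w), rcmotif)
        rightCopies <- .countNonOverlapping(
            subseq(s, length(s) - w + 1L, length(s)), motif)
        data.frame(seq = rep(names(seqs)[i], 2L),
                   side = c("left", "right"),
                   copies = c(leftCopies, rightCopies))
    })
    ends <- do.call(rbind, rows)
    ends$present <- ends$copies >= minCopies
    list(ends = ends, detected = sum(ends$present),
         totalEnds = 2L * length(seqs))
}
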