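#' Enumerate plus-strand CpG sites
#'
#' Every `CG` dinucleotide on the plus strand, reported once at the position
#' of the C (1-based `GRanges` coordinates). Dinucleotides containing N are
#' never matched.
#'
#' @param fasta `DNAStringSet` or FASTA path.
#' @return width-1 `GRanges` at the C of each CpG.
#' @examples
#' enumerateCpG(Biostrings::DNAStringSet(c(s = "ACGCG")))  # positions 2, 4
#' @export
enumerateCpG <- function(fasta) {
    seqs <- if (is.character(fasta)) readDNAStringSet(fasta) else fasta
    hits <- vmatchPattern("CG", seqs)
    starts <- lapply(seq_along(seqs), function(i) start(hits[[i]]))
    out <- GRanges(factor(rep(names(seqs), lengths(starts)),
                          levels = names(seqs)),
                   IRanges(start = unlist(starts), width = 1L))
    GenomeInfoDb::seqlengths(out) <- width(seqs)
    out
}

#' Summarise per-read methylation calls into per-site frequencies
#'
#' Aggregates per-read calls to (total reads, methylated reads, frequency)
#' per CpG site and applies the read-support filter: sites covered by fewer
#' than `minReads` reads are removed as unreliable. A histogram of the
#' retained site frequencies and the retention fraction are attached as
#' metadata.
#'
#' @param calls per-read calls: `data.table`/data.frame with columns `seq`,
#'   `pos` (1-based C of the plus-strand CpG), `read_id`, `methylated`
#'   (0/1), e.g. from [readMethylCalls()] or [simulateMethylation()].
#' @param minReads minimum read support per site (default 10).
#' @param histBreaks breakpoints for the frequency histogram summary.
#' @return `GRanges` of retained sites with `total_reads`,
#'   `methylated_reads` and `frequency`; `metadata()` carries `nSites`,
#'   `nRetained`, `retainedFraction` and `histogram`.
#' @export
methylFrequency <- function(calls, minReads = 10L,
                            histBreaks = seq(0, 1, by = 0.05)) {
    dt <- data.table::as.data.table(calls)
    need <- c("seq", "pos", "methylated")
    if (!all(need %in% names(dt)))
        stop("calls need columns: ", paste(need, collapse = ", "))
    if (nrow(dt) && !all(dt$methylated %in% c(0L, 1L)))
        stop("methylated flag must be 0 or 1")
    agg <- dt[, .(total_reads = .N, methylated_reads = sum(methylated)),
              by = .(seq, pos)]
    data.table::setorder(agg, seq, pos)
    nSites <- nrow(agg)
    keep <- agg[total_reads >= minReads]
    out <- GRanges(keep$seq, IRanges(start = keep$pos, width = 1L),
                   total_reads = keep$total_reads,
                   methylated_reads = keep$methylated_reads,
                   frequency = keep$methylated_reads / keep$total_reads)
    h <- if (nrow(keep)) graphics::hist(out$frequency, breaks = histBreaks,
                                        plot = FALSE)
         else list(breaks = histBreaks, counts = integer(length(histBreaks) - 1L))
    metadata(out) <- list(
        nSites = nSites, nRetained = nrow(keep),
        retainedFraction = if (nSites) nrow(keep) / nSites else NA_real_,
        minReads = as.integer(minReads),
        histogram = list(breaks = h$breaks, counts = h$counts))
    out
}

#' Recognition model of a methylation-dependent restriction enzyme
#'
#' Built-in models: `FspEI` recognises `CC` with the methylatable C at the
#' second position; `MspJI` recognises `CNNR` (R = A/G) with the
#' methylatable C at the first position. `offset` is the 0-based position of
#' the methylatable C within the motif. Custom motifs may use IUPAC codes.
#'
#' @param enzyme `"FspEI"`, `"MspJI"`, or `"custom"`.
#' @param motif,offset recognition motif and methyl-C offset for
#'   `"custom"`.
#' @return list with `enzyme`, `motif`, `offset`.
#' @export
enzymeModel <- function(enzyme = c("FspEI", "MspJI", "custom"),
                        motif = NULL, offset = NULL) {
    enzyme <- match.arg(enzyme)
    model <- switch(enzyme,
        FspEI = list(enzyme = "FspEI", motif = "CC", offset = 1L),
        MspJI = list(enzyme = "MspJI", motif = "CNNR", offset = 0L),
        custom = list(enzyme = "custom", motif = motif,
                      offset = as.integer(offset)))
    if (is.null(model$motif) || is.null(model$offset))
        stop("a custom model needs both motif and offset")
    if (grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                     collapse = "")), model$motif))
        stop("motif contains characters outside the IUPAC alphabet: ",
             model$motif)
    if (model$offset < 0L || model$offset >= nchar(model$motif))
        stop("offset must index a position inside the motif")
    model
}

#' Scan a genome for enzyme tag sites
#'
#' Both strands are scanned for the enzyme's recognition motif; each match
#' contributes one tag at its methylatable C, reported in plus-strand
#' coordinates (for minus-strand matches, the plus-strand position the
#' methyl-C pairs with) with the match strand recorded.
#'
#' @param fasta `DNAStringSet` or FASTA path.
#' @param enzyme enzyme name or a model list from [enzymeModel()].
#' @return `GRanges` (width 1, stranded) of tag positions with an `enzyme`
#'   column.
#' @examples
#' enzymeSites(Biostrings::DNAStringSet(c(s = "ACCT")), "FspEI")
#' @export
enzymeSites <- function(fasta, enzyme = "FspEI") {
    seqs <- if (is.character(fasta)) readDNAStringSet(fasta) else fasta
    model <- if (is.list(enzyme)) enzyme else enzymeModel(enzyme)
    motif <- DNAString(model$motif)
    w <- length(motif)
    fwd <- vmatchPattern(motif, seqs, fixed = "subject")
    rev <- vmatchPattern(reverseComplement(motif), seqs, fixed = "subject")
    per <- lapply(seq_along(seqs), function(i) {
        fpos <- start(fwd[[i]]) + model$offset
        rpos <- start(rev[[i]]) + (w - 1L - model$offset)
        list(pos = c(fpos, rpos),
             strand = rep(c("+", "-"), c(length(fpos), length(rpos))))
    })
    n <- vapply(per, function(p) length(p$pos), 0L)
    out <- GRanges(factor(rep(names(seqs), n), levels = names(seqs)),
                   IRanges(start = unlist(lapply(per, `[[`, "pos")),
                           width = 1L),
                   strand = unlist(lapply(per, `[[`, "strand")))
    GenomeInfoDb::seqlengths(out) <- width(seqs)
    out$enzyme <- model$enzyme
    sort(out, ignore.strand = TRUE)
}

#' Percentage summary of an overlap count
#'
#' @param overlapping,total counts.
#' @return list with `overlapping`, `total` and `percent` (1 decimal, as
#'   printed in cross-platform comparisons; `NA` when `total` is 0).
#' @examples
#' overlapSummary(999713, 1354625)
#' @export
overlapSummary <- function(overlapping, total) {
    list(overlapping = overlapping, total = total,
         percent = if (total > 0) round(100 * overlapping / total, 1)
                   else NA_real_)
}

#' Overlap of enzyme tags with retained CpG sites
#'
#' A tag overlaps when its methylatable-C position coincides with a retained
#' CpG site. Minus-strand tags are first mapped to the plus-strand C of the
#' symmetric CpG (position - 1) when the genome has a CpG there, else kept
#' at their own position.
#'
#' @param tags `GRanges` from [enzymeSites()].
#' @param cpg retained CpG site `GRanges` from [methylFrequency()] (or
#'   [enumerateCpG()]).
#' @param allCpG optional `GRanges` of all genomic CpG sites used to decide
#'   symmetric-CpG mapping; defaults to `cpg`.
#' @return list with `overlapping`, `total`, `percent` (1 decimal) and
#'   `venn` (tag-only / shared / cpg-only site counts).
#' @export
overlapSites <- function(tags, cpg, allCpG = NULL) {
    if (is.null(allCpG)) allCpG <- cpg
    key <- function(gr) paste0(seqnames(gr), ":", start(gr))
    cpgKeys <- unique(key(cpg))
    allKeys <- unique(key(allCpG))
    pos <- start(tags)
    minus <- as.logical(strand(tags) == "-")
    shiftKey <- paste0(seqnames(tags), ":", pos - 1L)
    mapped <- ifelse(minus & shiftKey %in% allKeys, pos - 1L, pos)
    mappedKey <- paste0(seqnames(tags), ":", mapped)
    ov <- mappedKey %in% cpgKeys
    s <- overlapSummary(sum(ov), length(tags))
    s$venn <- list(tagOnly = length(unique(mappedKey[!ov])),
                   shared = length(unique(mappedKey[ov])),
                   cpgOnly = sum(!cpgKeys %in% mappedKey))
    s
}

# two-sided exact binomial p-value (stats::binom.test)
.exactBinomP <- function(x, n, p) {
    if (n == 0L) return(1)
    stats::binom.test(x, n, p)$p.value
}

#' Per-site differential-methylation screen
#'
#' For each tag site, male and female read counts are pooled across samples
#' and compared with a two-sided exact binomial test conditional on the
#' pooled site total, with success probability equal to the male share of
#' the summed library sizes (this conditioning is the library-size, i.e.
#' counts-per-million, normalization). Sites with pooled total below
#' `minTotal` are removed first as too weakly covered to test. P-values are
#' BH-adjusted across retained sites; the significant set is `q < alphaFdr`.
#'
#' @param counts integer matrix, sites x samples (rownames = site ids).
#' @param sex character vector (`"male"`/`"female"`) per column; >= 2
#'   samples per sex.
#' @param alphaFdr FDR threshold (default 0.01).
#' @param minTotal minimum pooled reads per tested site (default 10).
#' @return data.frame per retained site: pooled counts, CPM per sex, `p`,
#'   `q`, `significant`; attributes `nInput`, `nTested`, `nSignificant`.
#' @export
dmsTest <- function(counts, sex, alphaFdr = 0.01, minTotal = 10L) {
    if (!is.matrix(counts)) counts <- as.matrix(counts)
    if (any(counts != floor(counts)) || any(counts < 0))
        stop("counts must be non-negative integers")
    if (length(sex) != ncol(counts))
        stop("one sex label per sample column is required")
    if (sum(sex == "male") < 2L || sum(sex == "female") < 2L)
        stop("need >= 2 samples per sex")
    lib <- colSums(counts)
    if (any(lib == 0)) stop("sample(s) with zero library size")
    maleLib <- sum(lib[sex == "male"])
    femaleLib <- sum(lib[sex == "female"])
    p0 <- maleLib / (maleLib + femaleLib)
    malePooled <- rowSums(counts[, sex == "male", drop = FALSE])
    femalePooled <- rowSums(counts[, sex == "female", drop = FALSE])
    nInput <- nrow(counts)
    keep <- malePooled + femalePooled >= minTotal
    m <- malePooled[keep]; f <- femalePooled[keep]
    pv <- vapply(seq_along(m),
                 function(i) .exactBinomP(m[i], m[i] + f[i], p0),
                 numeric(1))
    q <- stats::p.adjust(pv, method = "BH")
    out <- data.frame(
        site = if (!is.null(rownames(counts))) rownames(counts)[keep]
               else as.character(which(keep)),
        malePooled = m, femalePooled = f,
        maleCPM = 1e6 * m / maleLib, femaleCPM = 1e6 * f / femaleLib,
        p = pv, q = q, significant = q < alphaFdr,
        row.names = NULL)
    attr(out, "nInput") <- nInput
    attr(out, "nTested") <- sum(keep)
    attr(out, "nSignificant") <- sum(out$significant)
    attr(out, "alphaFdr") <- alphaFdr
    out
}
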