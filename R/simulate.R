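#' Generate a toy genome with planted male-specific regions and telomeres
#'
#' Draws i.i.d. background sequence at the configured GC fraction, then
#' writes a tandem telomere array over the terminal bases of every flagged
#' end: `TTAGGG` units at right ends, their reverse complement `CCCTAA` at
#' left ends. Sequence lengths equal `seqLengths(config)` exactly, so
#' planted-region coordinates are unaffected by telomere placement.
#'
#' @param config a [SimConfig].
#' @return list with `genome` (a `DNAStringSet`) and `truth` (list with
#'   `regions`, a sorted `GRanges` of planted male-specific intervals, and
#'   `telomereEnds`, the flagged ends).
#' @examples
#' g <- simulateGenome(SimConfig(seqLengths = c(chrA = 20000L),
#'     regions = GRanges(), telomereEnds = "chrA:right"))
#' Biostrings::subseq(g$genome$chrA, 20000 - 5)
#' @export
simulateGenome <- function(config) {
    validObject(config)
    set.seed(config@seed)
    sl <- config@seqLengths
    bases <- c("A", "T", "G", "C")
    prob <- c(rep((1 - config@gcFraction) / 2, 2),
              rep(config@gcFraction / 2, 2))
    seqs <- lapply(names(sl), function(sn) {
        x <- sample(bases, sl[[sn]], replace = TRUE, prob = prob)
        telo <- config@telomereCopies * 6L
        if (telo > 0L && telo <= sl[[sn]]) {
            if (paste0(sn, ":right") %in% config@telomereEnds)
                x[(sl[[sn]] - telo + 1L):sl[[sn]]] <-
                    rep(c("T", "T", "A", "G", "G", "G"), config@telomereCopies)
            if (paste0(sn, ":left") %in% config@telomereEnds)
                x[1:telo] <- rep(c("C", "C", "C", "T", "A", "A"),
                                 config@telomereCopies)
        }
        paste(x, collapse = "")
    })
    genome <- DNAStringSet(unlist(seqs))
    names(genome) <- names(sl)
    truthRegions <- sort(config@regions)
    GenomeInfoDb::seqlevels(truthRegions) <- names(sl)
    GenomeInfoDb::seqlengths(truthRegions) <- unname(sl)
    list(genome = genome,
         truth = list(regions = truthRegions,
                      telomereEnds = config@telomereEnds))
}

# per-base mean vector for one sample sex on one sequence
.depthMu <- function(config, seqname, len, sex) {
    mu <- rep(config@meanDepth, len)
    reg <- config@regions[seqnames(config@regions) == seqname]
    fac <- if (sex == "male") config@maleFactor else config@femaleFactor
    for (i in seq_along(reg))
        mu[start(reg)[i]:end(reg)[i]] <- config@meanDepth * fac
    mu
}

.rdepth <- function(n, mu, dispersion) {
    if (dispersion <= 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate per-base depth tracks for all samples
#'
#' Per-base counts are negative-binomial with the configured mean and
#' dispersion (Poisson when `dispersion = 0`). Outside planted regions both
#' sexes share the autosomal mean; inside them the mean is scaled by
#' `maleFactor` for males and `femaleFactor` for females, the XY hemizygous
#' signature the detector looks for.
#'
#' @param genome `DNAStringSet` (only lengths/names are used).
#' @param truth truth list from [simulateGenome()] (regions must lie on the
#'   genome).
#' @param config the same [SimConfig].
#' @return list with `tracks` (named list, one `RleList` of per-base depth
#'   per sample) and `sex` (named character vector).
#' @export
simulateDepth <- function(genome, truth, config) {
    validObject(config)
    if (config@nMale + config@nFemale < 1L)
        stop("at least one sample is required (nMale + nFemale >= 1)")
    reg <- truth$regions
    if (length(reg) && !all(as.character(seqnames(reg)) %in% names(genome)))
        stop("truth regions reference sequences absent from the genome")
    set.seed(config@seed + 1L)
    sl <- stats::setNames(width(genome), names(genome))
    sx <- sampleSexOf(config)
    tracks <- lapply(names(sx), function(sm) {
        perSeq <- lapply(names(sl), function(sn) {
            mu <- .depthMu(config, sn, sl[[sn]], sx[[sm]])
            Rle(.rdepth(sl[[sn]], mu, config@dispersion))
        })
        names(perSeq) <- names(sl)
        methods::as(perSeq, "RleList")
    })
    names(tracks) <- names(sx)
    list(tracks = tracks, sex = sx)
}

#' Simulate per-read CpG methylation calls
#'
#' Enumerates plus-strand CpG sites on the genome, draws each site's true
#' methylation frequency from the configured bimodal mixture (Beta around a
#' low or a high mode; a mode of exactly 0 or 1 is returned exactly), draws
#' site coverage around `meanDepth`, and emits one row per read with a
#' Bernoulli(site frequency) methylated flag.
#'
#' @param genome `DNAStringSet`.
#' @param config a [SimConfig].
#' @return list with `calls` (`data.table`: seq, pos (1-based C of the CpG),
#'   read_id, methylated in \{0,1\}) and `truth` (data.frame: seq, pos,
#'   frequency, coverage). A genome without any CpG yields empty tables and
#'   a warning.
#' @export
simulateMethylation <- function(genome, config) {
    validObject(config)
    set.seed(config@seed + 2L)
    sites <- enumerateCpG(genome)
    if (length(sites) == 0L) {
        warning("genome contains no CpG site; methylation output is empty")
        return(list(
            calls = data.table::data.table(seq = character(), pos = integer(),
                read_id = character(), methylated = integer()),
            truth = data.frame(seq = character(), pos = integer(),
                frequency = numeric(), coverage = integer())))
    }
    n <- length(sites)
    comp <- sample(c(1L, 2L), n, replace = TRUE, prob = config@methWeights)
    mode <- config@methModes[comp]
    conc <- config@methConcentration
    freq <- ifelse(mode <= 0, 0, ifelse(mode >= 1, 1, NA_real_))
    mid <- is.na(freq)
    if (any(mid))
        freq[mid] <- stats::rbeta(sum(mid), mode[mid] * conc,
                                  (1 - mode[mid]) * conc)
    cov <- .rdepth(n, config@meanDepth, config@dispersion)
    meth <- stats::rbinom(n, cov, freq)
    keep <- cov > 0L
    sq <- as.character(seqnames(sites))
    ps <- start(sites)
    calls <- data.table::data.table(
        seq = rep(sq[keep], cov[keep]),
        pos = rep(ps[keep], cov[keep]),
        read_id = paste0("r", rep(which(keep), cov[keep]), "_",
                         sequence(cov[keep])),
        methylated = unlist(lapply(which(keep), function(i)
            c(rep(1L, meth[i]), rep(0L, cov[i] - meth[i])))))
    list(calls = calls,
         truth = data.frame(seq = sq, pos = ps, frequency = freq,
                            coverage = cov))
}

#' Simulate a null (or spiked) site-by-sample tag count matrix
#'
#' Counts for a methylation-dependent-enzyme tag quantification: Poisson per
#' site and sample around `meanCount` by default, matching the
#' conditional-binomial sampling model under which [dmsTest()] is exact.
#' Setting `dispersion > 0` draws negative-binomial counts instead,
#' emulating the overdispersion of real tag libraries — under which a pooled
#' exact conditional test is anticonservative (the reason dispersion-fitting
#' NB frameworks exist for such data; see the methods vignette).
#' `effectSites` rows get their male-sample mean multiplied by `effectFold`
#' (1 = pure null).
#'
#' @param nSites number of tag sites.
#' @param nMale,nFemale samples per sex.
#' @param meanCount mean reads per site per sample.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param effectSites integer indices of differentially methylated sites.
#' @param effectFold fold-change applied to male means at `effectSites`.
#' @param seed integer seed.
#' @return list with `counts` (integer matrix, sites x samples) and `sex`.
#' @export
simulateSiteCounts <- function(nSites, nMale = 3L, nFemale = 3L,
                               meanCount = 20, dispersion = 0,
                               effectSites = integer(), effectFold = 1,
                               seed = 1L) {
    set.seed(seed)
    sx <- c(rep("male", nMale), rep("female", nFemale))
    names(sx) <- c(paste0("M", seq_len(nMale)), paste0("F", seq_len(nFemale)))
    mu <- matrix(meanCount, nSites, length(sx))
    if (length(effectSites))
        mu[effectSites, sx == "male"] <- meanCount * effectFold
    counts <- matrix(.rdepth(length(mu), as.vector(mu), dispersion),
                     nSites, length(sx),
                     dimnames = list(paste0("site", seq_len(nSites)),
                                     names(sx)))
    list(counts = counts, sex = sx)
}

#' Run the whole generator
#'
#' Convenience wrapper: genome + truth, depth tracks, methylation calls.
#'
#' @param config a [SimConfig].
#' @return list with `config`, `genome`, `truth`, `tracks`, `sex`, `meth`.
#' @export
simulateStudy <- function(config) {
    g <- simulateGenome(config)
    d <- simulateDepth(g$genome, g$truth, config)
    m <- simulateMethylation(g$genome, config)
    list(config = config, genome = g$genome, truth = g$truth,
         tracks = d$tracks, sex = d$sex, meth = m)
}
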