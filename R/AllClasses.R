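#' @import methods
#' @importFrom data.table data.table fread fwrite setnames setorder
#'   as.data.table rbindlist .N .SD
#' @importFrom BiocGenerics start end width strand sort order
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<- Rle
#' @importFrom IRanges IRanges Views viewMeans viewSums reduce
#' @importFrom GenomicRanges GRanges seqnames tileGenome findOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<-
#'   rowRanges colData colData<-
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   vmatchPattern matchPattern countPattern letterFrequency subseq
#'   readDNAStringSet writeXStringSet
NULL

#' Simulation configuration for an XY hemizygous-depth study
#'
#' Holds every parameter of the synthetic-data generator: the toy genome
#' (sequence names/lengths, GC content, telomeric ends), the planted
#' male-specific regions, the resequencing design (numbers of male and female
#' samples, mean autosomal depth, negative-binomial dispersion, per-sex depth
#' factors inside planted regions) and the CpG methylation mixture.
#'
#' Defaults describe the standard study conditions used throughout the
#' package's tests: a 2-Mb two-sequence genome with a planted 300-kb and a
#' planted 40-kb hemizygous region, five males and five females at 40x mean
#' depth with dispersion 0.2, male in-region depth factor 0.5 and female
#' in-region factor 0.02.
#'
#' @slot seqLengths named integer vector of sequence lengths (bases).
#' @slot gcFraction proportion of G+C in generated background sequence.
#' @slot regions `GRanges` of planted male-specific (Y-hemizygous) intervals.
#' @slot telomereEnds character vector of flagged ends, `"<seq>:left"` or
#'   `"<seq>:right"`; each flagged end receives a tandem telomere array.
#' @slot telomereCopies integer; TTAGGG units appended per flagged end.
#' @slot nMale,nFemale sample counts per sex.
#' @slot meanDepth mean autosomal per-base depth (diploid).
#' @slot maleFactor,femaleFactor depth multipliers inside planted regions for
#'   male and female samples (hemizygous XY expectation: 0.5 and ~0).
#' @slot dispersion negative-binomial overdispersion of per-base counts;
#'   `0` gives the Poisson limit.
#' @slot methWeights length-2 mixture weights (low, high) for site-level
#'   methylation frequencies.
#' @slot methModes length-2 modes of the low/high methylation components.
#' @slot methConcentration Beta concentration around each mode.
#' @slot seed integer seed fixing all generator output.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    seqLengths = "integer",
    gcFraction = "numeric",
    regions = "GRanges",
    telomereEnds = "character",
    telomereCopies = "integer",
    nMale = "integer",
    nFemale = "integer",
    meanDepth = "numeric",
    maleFactor = "numeric",
    femaleFactor = "numeric",
    dispersion = "numeric",
    methWeights = "numeric",
    methModes = "numeric",
    methConcentration = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    sl <- object@seqLengths
    if (length(sl) < 1L || is.null(names(sl)) || any(!nzchar(names(sl))))
        msg <- c(msg, "seqLengths must be a named vector with >= 1 sequence")
    if (any(sl < 1L)) msg <- c(msg, "all sequence lengths must be positive")
    if (object@gcFraction < 0 || object@gcFraction > 1)
        msg <- c(msg, "gcFraction must lie in [0, 1]")
    reg <- object@regions
    if (length(reg)) {
        bad <- !(as.character(seqnames(reg)) %in% names(sl))
        if (any(bad)) {
            msg <- c(msg, sprintf("planted region on unknown sequence: %s",
                paste(as.character(seqnames(reg))[bad], collapse = ", ")))
        } else {
            lim <- sl[as.character(seqnames(reg))]
            oob <- start(reg) < 1L | end(reg) > lim
            if (any(oob))
                msg <- c(msg, sprintf(
                    "planted region out of bounds: %s:%d-%d",
                    as.character(seqnames(reg))[oob][1L],
                    start(reg)[oob][1L], end(reg)[oob][1L]))
        }
        if (length(reduce(reg, min.gapwidth = 0L)) != length(reg))
            msg <- c(msg, "planted regions must be non-overlapping")
    }
    for (fld in c("maleFactor", "femaleFactor"))
        if (slot(object, fld) < 0 || slot(object, fld) > 1)
            msg <- c(msg, sprintf("%s must lie in [0, 1]", fld))
    if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (object@nMale < 0L || object@nFemale < 0L)
        msg <- c(msg, "sample counts must be non-negative")
    if (length(object@methWeights) != 2L || any(object@methWeights < 0) ||
        abs(sum(object@methWeights) - 1) > 1e-8)
        msg <- c(msg, "methWeights must be two non-negative weights summing to 1")
    if (length(object@methModes) != 2L || any(object@methModes < 0) ||
        any(object@methModes > 1))
        msg <- c(msg, "methModes must be two values in [0, 1]")
    te <- object@telomereEnds
    if (length(te)) {
        parts <- strsplit(te, ":", fixed = TRUE)
        ok <- vapply(parts, function(p) length(p) == 2L &&
            p[1L] %in% names(sl) && p[2L] %in% c("left", "right"), logical(1))
        if (!all(ok))
            msg <- c(msg, "telomereEnds entries must be '<seq>:left' or '<seq>:right'")
    }
    if (length(msg)) msg else TRUE
})

#' Window-by-sample coverage container
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' fixed-width genomic windows tiling the genome (last window of each
#' sequence truncated), whose single assay `"coverage"` holds mean per-base
#' depth per window and sample, and whose `colData` carries the sample sex
#' (`"male"`/`"female"`) and per-sample normalization factor. The window
#' width is stored in `metadata(x)$windowSize`.
#'
#' @exportClass WindowCoverage
setClass("WindowCoverage", contains = "RangedSummarizedExperiment")

setValidity("WindowCoverage", function(object) {
    msg <- character()
    if (!"coverage" %in% names(assays(object)))
        msg <- c(msg, "assay 'coverage' is required")
    cd <- colData(object)
    if (!"sex" %in% names(cd))
        msg <- c(msg, "colData must contain a 'sex' column")
    else if (!all(cd$sex %in% c("male", "female")))
        msg <- c(msg, "sex labels must be 'male' or 'female'")
    if (!"normFactor" %in% names(cd))
        msg <- c(msg, "colData must contain a 'normFactor' column")
    if (is.null(metadata(object)$windowSize))
        msg <- c(msg, "metadata windowSize is required")
    if ("coverage" %in% names(assays(object)) &&
        any(assay(object, "coverage") < 0, na.rm = TRUE))
        msg <- c(msg, "coverage values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Assembly contiguity and composition statistics
#'
#' @slot nSequences number of sequences.
#' @slot totalLength total assembly length in bases.
#' @slot nX named numeric, NX lengths (e.g. `N50`, `N90`) in bases.
#' @slot lX named integer, LX counts.
#' @slot largest length of the longest sequence.
#' @slot gcFraction G+C fraction among non-N bases.
#' @slot gapLength total bases inside N-runs.
#' @slot gapCount number of maximal N-runs.
#' @slot seqLengths named vector of per-sequence lengths.
#' @exportClass AssemblyStats
setClass("AssemblyStats", representation(
    nSequences = "integer",
    totalLength = "numeric",
    nX = "numeric",
    lX = "integer",
    largest = "numeric",
    gcFraction = "numeric",
    gapLength = "numeric",
    gapCount = "integer",
    seqLengths = "numeric"
))

setMethod("show", "AssemblyStats", function(object) {
    cat("AssemblyStats\n")
    cat(sprintf("  sequences : %d (largest %s bp)\n", object@nSequences,
        format(object@largest, big.mark = ",")))
    cat(sprintf("  total     : %s bp\n", format(object@totalLength, big.mark = ",")))
    for (x in names(object@nX))
        cat(sprintf("  %s / L%s : %s bp / %d\n", x, sub("^N", "", x),
            format(object@nX[[x]], big.mark = ","), object@lX[[paste0("L", sub("^N", "", x))]]))
    cat(sprintf("  GC        : %.4f (non-N bases)\n", object@gcFraction))
    cat(sprintf("  gaps      : %s bp in %d run(s)\n",
        format(object@gapLength, big.mark = ","), object@gapCount))
    invisible(object)
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat(sprintf("  genome    : %d sequence(s), %s bp, GC %.2f\n",
        length(object@seqLengths), format(sum(object@seqLengths), big.mark = ","),
        object@gcFraction))
    cat(sprintf("  planted   : %d male-specific region(s), %s bp total\n",
        length(object@regions), format(sum(width(object@regions)), big.mark = ",")))
    cat(sprintf("  design    : %d male / %d female at %.1fx (dispersion %.2f)\n",
        object@nMale, object@nFemale, object@meanDepth, object@dispersion))
    cat(sprintf("  SDR depth : male x%.2f, female x%.2f\n",
        object@maleFactor, object@femaleFactor))
    cat(sprintf("  seed      : %d\n", object@seed))
    invisible(object)
})
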