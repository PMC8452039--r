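#' Build a simulation configuration
#'
#' Constructor for [SimConfig-class]. The defaults are the package's
#' standard study conditions: a 2-Mb genome split over two sequences with a
#' planted 300-kb region on `chr1` and a planted 40-kb region on `chr2`,
#' resequenced in five males and five females at 40x mean depth with
#' negative-binomial dispersion 0.2. Inside planted regions male depth is
#' halved (Y-hemizygous) and female depth drops to 2% of autosomal (residual
#' cross-mapping rather than exactly zero).
#'
#' @param seqLengths named integer vector of sequence lengths.
#' @param gcFraction background G+C fraction.
#' @param regions `GRanges` of planted male-specific intervals (1-based,
#'   closed, as usual for `GRanges`).
#' @param telomereEnds character, ends receiving telomere arrays
#'   (`"<seq>:left"` / `"<seq>:right"`); default all ends of all sequences.
#' @param telomereCopies TTAGGG units appended per flagged end.
#' @param nMale,nFemale per-sex sample counts.
#' @param meanDepth mean autosomal per-base depth.
#' @param maleFactor,femaleFactor in-region depth multipliers per sex.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param methWeights,methModes,methConcentration site-level methylation
#'   mixture: a site is drawn from the low component with probability
#'   `methWeights[1]`, then its frequency is Beta-distributed around the
#'   component mode with the given concentration (a mode of exactly 0 or 1
#'   yields that frequency exactly).
#' @param seed integer seed; fixes every generated artifact bit-for-bit.
#' @return a validated `SimConfig` object.
#' @examples
#' cfg <- SimConfig(seqLengths = c(chrA = 100000L), regions = GRanges())
#' cfg
#' @export
SimConfig <- function(seqLengths = c(chr1 = 1500000L, chr2 = 500000L),
                      gcFraction = 0.37,
                      regions = GRanges(c("chr1", "chr2"),
                          IRanges(start = c(500001L, 137001L),
                                  end = c(800000L, 177000L))),
                      telomereEnds = as.character(vapply(names(seqLengths),
                          function(s) paste0(s, c(":left", ":right")),
                          character(2))),
                      telomereCopies = 30L,
                      nMale = 5L, nFemale = 5L,
                      meanDepth = 40,
                      maleFactor = 0.5, femaleFactor = 0.02,
                      dispersion = 0.2,
                      methWeights = c(0.4, 0.6),
                      methModes = c(0.05, 0.95),
                      methConcentration = 10,
                      seed = 20210906L) {
    sl <- seqLengths
    storage.mode(sl) <- "integer"
    new("SimConfig",
        seqLengths = sl,
        gcFraction = gcFraction,
        regions = regions,
        telomereEnds = as.character(telomereEnds),
        telomereCopies = as.integer(telomereCopies),
        nMale = as.integer(nMale), nFemale = as.integer(nFemale),
        meanDepth = meanDepth,
        maleFactor = maleFactor, femaleFactor = femaleFactor,
        dispersion = dispersion,
        methWeights = methWeights, methModes = methModes,
        methConcentration = methConcentration,
        seed = as.integer(seed))
}

#' @describeIn SimConfig sample identifiers implied by the design
#'   (`M1..Mn`, `F1..Fn`).
#' @param config a `SimConfig`.
#' @export
sampleNamesOf <- function(config) {
    c(if (config@nMale) paste0("M", seq_len(config@nMale)),
      if (config@nFemale) paste0("F", seq_len(config@nFemale)))
}

#' @describeIn SimConfig named sex vector (`"male"`/`"female"`) per sample.
#' @export
sampleSexOf <- function(config) {
    sx <- c(rep("male", config@nMale), rep("female", config@nFemale))
    names(sx) <- sampleNamesOf(config)
    sx
}

# JSON-serialisable view of a config (sidecar + hashing)
configAsList <- function(config) {
    list(
        seqLengths = as.list(config@seqLengths),
        gcFraction = config@gcFraction,
        regions = if (length(config@regions)) data.frame(
            seq = as.character(seqnames(config@regions)),
            start = start(config@regions), end = end(config@regions))
            else data.frame(),
        telomereEnds = config@telomereEnds,
        telomereCopies = config@telomereCopies,
        nMale = config@nMale, nFemale = config@nFemale,
        meanDepth = config@meanDepth,
        maleFactor = config@maleFactor, femaleFactor = config@femaleFactor,
        dispersion = config@dispersion,
        methWeights = config@methWeights,
        methModes = config@methModes,
        methConcentration = config@methConcentration,
        seed = config@seed)
}
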