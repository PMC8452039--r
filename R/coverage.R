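#' Aggregate per-base depth into fixed windows
#'
#' Tiles the genome with fixed-width windows (the last window of each
#' sequence is truncated to the sequence end) and computes, for every sample,
#' the mean per-base depth in each window: window sum divided by the actual
#' window width, so truncated terminal windows are handled correctly.
#'
#' @param tracks named list of per-sample `RleList` depth tracks (e.g. from
#'   [simulateDepth()] or [readDepthTrack()]); all tracks must share one
#'   coordinate frame.
#' @param sex named character vector (`"male"`/`"female"`) per sample;
#'   names must match `names(tracks)`.
#' @param windowSize window width in bases (>= 1000; default 50000).
#' @return a [WindowCoverage-class] with assay `"coverage"`, per-sample sex
#'   and unit normalization factors in `colData`, and the window size in
#'   `metadata`.
#' @export
windowCoverage <- function(tracks, sex, windowSize = 50000L) {
    windowSize <- as.integer(windowSize)
    if (windowSize < 1000L) stop("windowSize must be >= 1000 bases")
    if (!length(tracks)) stop("no depth tracks given")
    if (is.null(names(tracks)) || !all(names(tracks) %in% names(sex)))
        stop("every track needs a sex label")
    sex <- sex[names(tracks)]
    sl <- vapply(tracks[[1L]], length, 0L)
    for (sm in names(tracks)) {
        sli <- vapply(tracks[[sm]], length, 0L)
        if (!identical(names(sli), names(sl)) || !identical(unname(sli), unname(sl)))
            stop("track '", sm, "' does not share the common coordinate frame")
    }
    windows <- tileGenome(sl, tilewidth = windowSize,
                          cut.last.tile.in.chrom = TRUE)
    mat <- vapply(names(tracks), function(sm) {
        unlist(lapply(names(sl), function(sn) {
            w <- windows[seqnames(windows) == sn]
            viewMeans(Views(tracks[[sm]][[sn]],
                            start = start(w), end = end(w)))
        }), use.names = FALSE)
    }, numeric(length(windows)))
    if (!is.matrix(mat))   # single-window genomes collapse to a vector
        mat <- matrix(mat, nrow = length(windows),
                      dimnames = list(NULL, names(tracks)))
    se <- SummarizedExperiment(
        assays = list(coverage = mat),
        rowRanges = windows,
        colData = DataFrame(sex = unname(sex), normFactor = rep(1, length(sex)),
                            row.names = names(tracks)))
    metadata(se)$windowSize <- windowSize
    methods::new("WindowCoverage", se)
}

#' @describeIn windowCoverage sample sex labels of a `WindowCoverage`.
#' @param x a `WindowCoverage`.
#' @export
sampleSex <- function(x) stats::setNames(colData(x)$sex, colnames(x))

#' @describeIn windowCoverage per-sample normalization factors.
#' @export
normFactors <- function(x) stats::setNames(colData(x)$normFactor, colnames(x))

#' Normalize window coverage across samples
#'
#' Divides each sample's window coverages by that sample's genome-wide
#' median window coverage, putting every sample on a scale where the
#' autosomal (diploid) level is ~1. With `method = "none"` all factors are 1
#' (useful when the sequencing design already equalizes depth).
#'
#' @param x a [WindowCoverage-class].
#' @param method `"median"` (default) or `"none"`.
#' @return a `WindowCoverage` with scaled coverage and recorded factors.
#' @export
normalizeCoverage <- function(x, method = c("median", "none")) {
    method <- match.arg(method)
    mat <- assay(x, "coverage")
    if (!length(mat)) stop("empty coverage matrix")
    if (method == "none") {
        colData(x)$normFactor <- rep(1, ncol(x))
        return(x)
    }
    med <- apply(mat, 2L, stats::median, na.rm = TRUE)
    zero <- colSums(mat, na.rm = TRUE) == 0
    if (any(zero))
        stop("sample(s) with all-zero coverage: ",
             paste(colnames(x)[zero], collapse = ", "))
    if (any(med <= 0))
        stop("sample(s) with non-positive median window coverage: ",
             paste(colnames(x)[med <= 0], collapse = ", "))
    assays(x)$coverage <- sweep(mat, 2L, med, "/")
    colData(x)$normFactor <- unname(med)
    x
}

# Welch two-sample t-test with the package's degenerate-variance convention:
# both groups constant and equal -> t = 0, p = 1; constant and unequal ->
# t = +/-Inf, p = 0 (an obviously discriminating window is kept, not NaN'd).
.welch <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
        if (mx == my) return(c(t = 0, p = 1))
        return(c(t = sign(mx - my) * Inf, p = 0))
    }
    ht <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
    if (is.null(ht)) {
        if (isTRUE(all.equal(mx, my))) return(c(t = 0, p = 1))
        return(c(t = sign(mx - my) * Inf, p = 0))
    }
    c(t = unname(ht$statistic), p = ht$p.value)
}

#' Per-window male/female coverage test
#'
#' Welch's (unequal-variance) two-sample t-test of male vs female normalized
#' coverage in every window, with Benjamini-Hochberg adjustment across all
#' windows genome-wide. A window is flagged male-specific when it is
#' significant (`q <= alpha`), male coverage exceeds female coverage, and
#' female coverage is depleted below `femaleMaxFrac` times the genome-wide
#' median female window coverage (~1 after normalization). The discovery
#' gate is deliberately loose (default 0.5: at least half-depleted in
#' females) so that windows only partially covered by a male-specific region
#' survive to the 1-kb refinement stage, where the strict hemizygosity gate
#' is applied.
#'
#' @param x a normalized [WindowCoverage-class]; both sexes need >= 2
#'   samples.
#' @param alpha BH false-discovery-rate threshold (default 0.05).
#' @param femaleMaxFrac discovery-stage female depletion gate (default 0.5).
#' @return `GRanges` of the windows with metadata columns `maleMean`,
#'   `femaleMean`, `t`, `p`, `q` and `flag`.
#' @export
testWindows <- function(x, alpha = 0.05, femaleMaxFrac = 0.5) {
    sx <- sampleSex(x)
    if (sum(sx == "male") < 2L || sum(sx == "female") < 2L)
        stop("need >= 2 samples per sex (variance undefined otherwise)")
    mat <- assay(x, "coverage")
    mcol <- mat[, sx == "male", drop = FALSE]
    fcol <- mat[, sx == "female", drop = FALSE]
    stats <- t(vapply(seq_len(nrow(mat)),
                      function(i) .welch(mcol[i, ], fcol[i, ]),
                      c(t = 0, p = 0)))
    maleMean <- rowMeans(mcol)
    femaleMean <- rowMeans(fcol)
    q <- stats::p.adjust(stats[, "p"], method = "BH")
    # reference female autosomal level: exactly 1 once per-sample median
    # normalization has run; otherwise estimated by the genome-wide median
    femaleRef <- if (all(normFactors(x) == 1)) stats::median(femaleMean)
                 else 1

    flag <- q <= alpha & maleMean > femaleMean &
        femaleMean <= femaleMaxFrac * femaleRef
    out <- rowRanges(x)
    mcols(out) <- DataFrame(maleMean = maleMean, femaleMean = femaleMean,
                            t = unname(stats[, "t"]), p = unname(stats[, "p"]),
                            q = unname(q), flag = unname(flag))
    metadata(out) <- list(windowSize = metadata(x)$windowSize,
                          alpha = alpha, femaleMaxFrac = femaleMaxFrac,
                          femaleRef = femaleRef)
    out
}
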