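#' Merge flagged windows into coarse candidate regions
#'
#' Maximal runs of adjacent flagged windows on one sequence are merged into
#' candidate male-specific regions; a run is never extended across a
#' non-flagged window, so a male-specific complex interrupted by a
#' non-sex-specific stretch stays split. Regions shorter than
#' `minRegionLength` are dropped.
#'
#' @param results window test `GRanges` from [testWindows()], in genome
#'   order.
#' @param minRegionLength minimum region length in bases (default 10000).
#' @return `GRanges` of coarse regions with `nSupportWindows`, `maleMean`
#'   and `femaleMean` (width-weighted over member windows).
#' @export
callRegions <- function(results, minRegionLength = 10000L) {
    if (!methods::is(results, "GRanges"))
        stop("results must be a GRanges of window test results")
    if (!identical(BiocGenerics::order(results), seq_along(results)))
        stop("window results must be ordered by genome coordinate")
    if (is.null(results$flag)) stop("results lack a 'flag' column")
    flagged <- results[results$flag]
    if (!length(flagged)) {
        out <- GRanges()
        mcols(out) <- DataFrame(nSupportWindows = integer(),
                                maleMean = numeric(), femaleMean = numeric())
        return(out)
    }
    reg <- reduce(flagged, min.gapwidth = 1L)
    reg <- reg[width(reg) >= minRegionLength]
    if (length(reg)) {
        hits <- findOverlaps(reg, flagged)
        idx <- S4Vectors::queryHits(hits)
        w <- width(flagged)[S4Vectors::subjectHits(hits)]
        mm <- flagged$maleMean[S4Vectors::subjectHits(hits)]
        fm <- flagged$femaleMean[S4Vectors::subjectHits(hits)]
        mcols(reg) <- DataFrame(
            nSupportWindows = as.integer(tabulate(idx, length(reg))),
            maleMean = as.numeric(tapply(w * mm, idx, sum) /
                                  tapply(w, idx, sum)),
            femaleMean = as.numeric(tapply(w * fm, idx, sum) /
                                    tapply(w, idx, sum)))
    } else {
        mcols(reg) <- DataFrame(nSupportWindows = integer(),
                                maleMean = numeric(), femaleMean = numeric())
    }
    reg
}

# per-sample normalized mean coverage of arbitrary bins on one sequence
.binMeans <- function(tracks, nf, seqname, starts, ends) {
    vapply(names(tracks), function(sm) {
        viewMeans(Views(tracks[[sm]][[seqname]],
                        start = starts, end = ends)) / nf[[sm]]
    }, numeric(length(starts)))
}

#' Refine coarse regions at fine (1-kb) resolution
#'
#' Each coarse region, extended by one coarse window on both sides, is cut
#' into fine bins on an absolute `refineWindow` grid. A bin is classified
#' male-specific when its normalized female mean is at most `femaleMaxFrac`
#' and its normalized male mean at least `maleMinFrac` (the hemizygous XY
#' expectation is ~0 and ~0.5). Maximal runs of passing bins are re-merged,
#' the minimum length is re-applied, and each resulting region ("part" of
#' its parent complex) gets a least-squares regression of male mean coverage
#' against bin midpoint.
#'
#' @param regions coarse `GRanges` from [callRegions()].
#' @param tracks named list of per-sample `RleList` depth tracks.
#' @param x the [WindowCoverage-class] the regions were called from (source
#'   of sex labels, normalization factors and the coarse window size).
#' @param refineWindow fine bin width in bases; must divide the coarse
#'   window size (default 1000).
#' @param femaleMaxFrac maximum normalized female coverage inside a
#'   male-specific bin (default 0.10).
#' @param maleMinFrac minimum normalized male coverage (default 0.25).
#' @param minRegionLength minimum refined region length (default 10000).
#' @return `GRanges` of refined regions with `maleMean`, `femaleMean`,
#'   `nBins`, `slope` and `intercept` (per-part fit; slope in normalized
#'   coverage per base).
#' @export
refineRegions <- function(regions, tracks, x, refineWindow = 1000L,
                          femaleMaxFrac = 0.10, maleMinFrac = 0.25,
                          minRegionLength = 10000L) {
    refineWindow <- as.integer(refineWindow)
    ws <- metadata(x)$windowSize
    if (refineWindow > ws)
        stop("refineWindow must not exceed the coarse window size")
    if (ws %% refineWindow != 0L)
        stop("refineWindow must divide the coarse window size evenly")
    empty <- GRanges()
    mcols(empty) <- DataFrame(maleMean = numeric(), femaleMean = numeric(),
                              nBins = integer(), slope = numeric(),
                              intercept = numeric())
    if (!length(regions)) return(empty)
    sx <- sampleSex(x)
    nf <- normFactors(x)
    sl <- vapply(tracks[[1L]], length, 0L)
    found <- list()
    for (i in seq_along(regions)) {
        sn <- as.character(seqnames(regions)[i])
        s <- max(1L, start(regions)[i] - ws)
        e <- min(sl[[sn]], end(regions)[i] + ws)
        bs <- seq.int(((s - 1L) %/% refineWindow) * refineWindow + 1L, e,
                      by = refineWindow)
        be <- pmin(bs + refineWindow - 1L, sl[[sn]])
        m <- .binMeans(tracks, nf, sn, bs, be)
        maleMean <- rowMeans(m[, sx == "male", drop = FALSE])
        femaleMean <- rowMeans(m[, sx == "female", drop = FALSE])
        pass <- femaleMean <= femaleMaxFrac & maleMean >= maleMinFrac
        if (!any(pass)) next
        runs <- reduce(IRanges(start = bs[pass], end = be[pass]),
                       min.gapwidth = 1L)
        runs <- runs[width(runs) >= minRegionLength]
        for (j in seq_along(runs)) {
            inRun <- bs >= start(runs)[j] & be <= end(runs)[j]
            mid <- (bs[inRun] + be[inRun]) / 2
            fit <- stats::lm.fit(cbind(1, mid),
                                 maleMean[inRun])$coefficients
            gr <- GRanges(factor(sn, levels = names(sl)), runs[j])
            mcols(gr) <- DataFrame(maleMean = mean(maleMean[inRun]),
                                   femaleMean = mean(femaleMean[inRun]),
                                   nBins = sum(inRun),
                                   slope = unname(fit[2L]),
                                   intercept = unname(fit[1L]))
            found[[length(found) + 1L]] <- gr
        }
    }
    if (!length(found)) return(empty)
    out <- do.call(c, found)
    GenomeInfoDb::seqlevels(out) <- names(sl)
    out <- sort(out)
    # adjacent coarse regions can rediscover the same run via their
    # side extensions; keep one copy
    out[!duplicated(paste(seqnames(out), start(out), end(out)))]
}

#' Intersect candidate regions with marker loci
#'
#' Overlap in the usual interval sense (a marker touching a region by a
#' single base counts). Each region is annotated with the ids of its
#' overlapping markers; the summary counts markers hitting any region.
#'
#' @param regions `GRanges` of candidate regions.
#' @param markers `GRanges` of marker loci with a `name` column (e.g. from
#'   [readMarkers()]).
#' @return list with `regions` (annotated with a `markerHits`
#'   `CharacterList` column and `nMarkers`) and `summary`
#'   (`markersHit`, `markersTotal`, `fraction`; the fraction is `NA` when
#'   there are no markers).
#' @export
intersectMarkers <- function(regions, markers) {
    nm <- if (!is.null(markers$name)) markers$name
          else paste0("marker", seq_along(markers))
    hits <- findOverlaps(regions, markers, ignore.strand = TRUE)
    lst <- split(nm[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits),
                        levels = seq_along(regions)))
    regions$markerHits <- unname(IRanges::CharacterList(lst))
    regions$nMarkers <- unname(lengths(regions$markerHits))
    hit <- length(unique(S4Vectors::subjectHits(hits)))
    list(regions = regions,
         summary = list(markersHit = hit,
                        markersTotal = length(markers),
                        fraction = if (length(markers)) hit / length(markers)
                                   else NA_real_))
}

#' Per-region Jaccard overlap between truth and calls
#'
#' For each truth interval, the Jaccard index between it and the union of
#' calls on its sequence: intersection length over union length, using the
#' call fragments overlapping that truth interval.
#'
#' @param truth,calls `GRanges`.
#' @return numeric vector, one Jaccard value per truth interval.
#' @export
regionJaccard <- function(truth, calls) {
    vapply(seq_along(truth), function(i) {
        tr <- truth[i]
        ov <- calls[S4Vectors::subjectHits(
            findOverlaps(tr, calls, ignore.strand = TRUE))]
        if (!length(ov)) return(0)
        inter <- sum(width(GenomicRanges::pintersect(
            rep(tr, length(ov)), ov)))
        uni <- sum(width(reduce(c(GRanges(seqnames(tr), IRanges::ranges(tr)),
                                  GRanges(seqnames(ov), IRanges::ranges(ov))))))
        inter / uni
    }, numeric(1))
}
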