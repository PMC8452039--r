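#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates the stages end-to-end with one configuration: simulate
#' (genome + truth + depth + methylation), window coverage and
#' normalization, per-window testing, region calling and refinement,
#' assembly statistics and telomere scan, CpG methylation-frequency
#' summarisation, enzyme-site overlap, the differential-methylation screen
#' on a simulated tag count matrix, and the summary report. Every tabular
#' output is written deterministically, and the JSON report embeds an MD5
#' hash of the configuration for provenance, so re-running with the same
#' configuration reproduces byte-identical outputs. Per-stage record counts
#' (windows tested/flagged, regions before/after refinement, sites
#' before/after the read-support filter) are logged via `message()`.
#'
#' @param config a [SimConfig] driving the simulation.
#' @param outdir output directory.
#' @param stages character subset of
#'   `c("sdr", "assembly", "methylation", "dms")`; the simulation and
#'   report always run.
#' @param windowSize,refineWindow,minRegionLength,alpha SDR-stage parameters
#'   (see [testWindows()], [callRegions()], [refineRegions()]).
#' @param flagFemaleMaxFrac,femaleMaxFrac,maleMinFrac discovery-stage and
#'   refinement-stage hemizygosity gates.
#' @param minReads CpG read-support filter (see [methylFrequency()]).
#' @param enzymes enzyme models to scan (names for [enzymeModel()]).
#' @param dmsSites,dmsAlpha differential-methylation screen size and FDR.
#' @param normalize normalize window coverage by per-sample medians.
#' @return list with all stage results and `paths` of written files.
#' @export
runPipeline <- function(config = SimConfig(), outdir,
                        stages = c("sdr", "assembly", "methylation", "dms"),
                        windowSize = 50000L, refineWindow = 1000L,
                        minRegionLength = 10000L, alpha = 0.05,
                        flagFemaleMaxFrac = 0.5, femaleMaxFrac = 0.10,
                        maleMinFrac = 0.25, minReads = 10L,
                        enzymes = c("FspEI", "MspJI"),
                        dmsSites = 1000L, dmsAlpha = 0.01,
                        normalize = TRUE) {
    stages <- match.arg(stages, several.ok = TRUE)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    res <- list(config = config)
    paths <- character()

    params <- list(windowSize = windowSize, refineWindow = refineWindow,
                   minRegionLength = minRegionLength, alpha = alpha,
                   flagFemaleMaxFrac = flagFemaleMaxFrac,
                   femaleMaxFrac = femaleMaxFrac, maleMinFrac = maleMinFrac,
                   minReads = minReads, enzymes = enzymes,
                   dmsSites = dmsSites, dmsAlpha = dmsAlpha,
                   normalize = normalize, stages = stages)
    cfgJson <- file.path(outdir, "config.json")
    jsonlite::write_json(c(configAsList(config), params), cfgJson,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfgHash <- unname(tools::md5sum(cfgJson))
    paths["config"] <- cfgJson

    message("stage simulate: generating study (seed ", config@seed, ")")
    study <- simulateStudy(config)
    res$study <- study

    if ("sdr" %in% stages) {
        wc <- windowCoverage(study$tracks, study$sex, windowSize)
        if (normalize) wc <- normalizeCoverage(wc)
        wt <- testWindows(wc, alpha = alpha,
                          femaleMaxFrac = flagFemaleMaxFrac)
        message("stage sdr: ", length(wt), " windows tested, ",
                sum(wt$flag), " flagged")
        coarse <- callRegions(wt, minRegionLength)
        refined <- refineRegions(coarse, study$tracks, wc, refineWindow,
                                 femaleMaxFrac, maleMinFrac, minRegionLength)
        message("stage sdr: ", length(coarse), " coarse region(s) -> ",
                length(refined), " refined region(s)")
        res$windows <- wc; res$windowTests <- wt
        res$coarseRegions <- coarse; res$regions <- refined
        wdt <- data.table::data.table(
            seq = as.character(seqnames(wt)), start = start(wt) - 1L,
            end = end(wt), maleMean = wt$maleMean,
            femaleMean = wt$femaleMean, t = wt$t, p = wt$p, q = wt$q,
            flag = wt$flag)
        paths["windows"] <- file.path(outdir, "windows.tsv")
        data.table::fwrite(wdt, paths[["windows"]], sep = "\t")
        paths["regions_bed"] <- file.path(outdir, "regions.bed")
        rtracklayer::export(refined, paths[["regions_bed"]], format = "BED")
        rdt <- data.table::data.table(
            seq = as.character(seqnames(refined)), start = start(refined) - 1L,
            end = end(refined), length = width(refined),
            maleMean = refined$maleMean, femaleMean = refined$femaleMean,
            nBins = refined$nBins, slope = refined$slope,
            intercept = refined$intercept)
        paths["regions_tsv"] <- file.path(outdir, "regions.tsv")
        data.table::fwrite(rdt, paths[["regions_tsv"]], sep = "\t")
    }

    if ("assembly" %in% stages) {
        res$assemblyStats <- contigStats(study$genome)
        res$telomeres <- findTelomeres(study$genome)
        message("stage assembly: N50 ", res$assemblyStats@nX[["N50"]],
                " bp; telomeres at ", res$telomeres$detected, "/",
                res$telomeres$totalEnds, " ends")
        paths["telomeres"] <- file.path(outdir, "telomeres.tsv")
        data.table::fwrite(res$telomeres$ends, paths[["telomeres"]],
                           sep = "\t")
    }

    if ("methylation" %in% stages) {
        freq <- methylFrequency(study$meth$calls, minReads)
        message("stage methylation: ", metadata(freq)$nRetained, "/",
                metadata(freq)$nSites, " CpG sites retained at >= ",
                minReads, " reads")
        res$methylFreq <- freq
        allCpG <- enumerateCpG(study$genome)
        res$enzymeOverlap <- lapply(stats::setNames(enzymes, enzymes),
            function(e) {
                tags <- enzymeSites(study$genome, e)
                overlapSites(tags, freq, allCpG = allCpG)
            })
        fdt <- data.table::data.table(
            seq = as.character(seqnames(freq)), pos = start(freq),
            total_reads = freq$total_reads,
            methylated_reads = freq$methylated_reads,
            frequency = freq$frequency)
        paths["methyl_sites"] <- file.path(outdir, "methyl_sites.tsv")
        data.table::fwrite(fdt, paths[["methyl_sites"]], sep = "\t")
    }

    if ("dms" %in% stages) {
        sim <- simulateSiteCounts(dmsSites, seed = config@seed + 3L)
        res$dms <- dmsTest(sim$counts, sim$sex, alphaFdr = dmsAlpha)
        message("stage dms: ", attr(res$dms, "nTested"), " sites tested, ",
                attr(res$dms, "nSignificant"), " significant at FDR < ",
                dmsAlpha)
        paths["dms"] <- file.path(outdir, "dms.tsv")
        data.table::fwrite(data.table::as.data.table(res$dms),
                           paths[["dms"]], sep = "\t")
    }

    rep <- summaryReport(
        regions = res$regions, assemblyStats = res$assemblyStats,
        telomeres = res$telomeres, overlaps = res$enzymeOverlap,
        dms = res$dms, configHash = cfgHash)
    paths["report_json"] <- file.path(outdir, "report.json")
    jsonlite::write_json(rep$json, paths[["report_json"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["report_txt"] <- file.path(outdir, "report.txt")
    writeLines(rep$text, paths[["report_txt"]])
    res$report <- rep
    res$paths <- paths
    res
}

#' Build the paper-style summary report
#'
#' Assembles, from whichever stage outputs are present: the per-sequence
#' male-specific kb table (sorted by descending kb, with an explicit zero
#' row when no region was called), the assembly statistic rows with
#' fold-change lines, the telomere totals, and the enzyme/CpG overlap
#' percentages (1 decimal; folds and anchoring use 2).
#'
#' @param regions refined region `GRanges` (or `NULL`).
#' @param assemblyStats an [AssemblyStats-class] (or `NULL`).
#' @param telomeres result of [findTelomeres()] (or `NULL`).
#' @param overlaps named list of [overlapSites()] results (or `NULL`).
#' @param dms result of [dmsTest()] (or `NULL`).
#' @param previousN50,previousGap optional named numeric vectors of earlier
#'   assemblies' scaffold N50 / gap length, used for fold-change lines.
#' @param configHash provenance string embedded in the report.
#' @return list with `json` (plain list) and `text` (character lines).
#' @export
summaryReport <- function(regions = NULL, assemblyStats = NULL,
                          telomeres = NULL, overlaps = NULL, dms = NULL,
                          previousN50 = NULL, previousGap = NULL,
                          configHash = NA_character_) {
    json <- list(configHash = configHash)
    text <- c("# sdrscan summary report",
              paste0("config-hash: ", configHash))

    if (!is.null(regions)) {
        if (length(regions)) {
            kb <- tapply(width(regions), as.character(seqnames(regions)), sum) / 1000
            tab <- data.frame(seq = names(kb), kb = round(unname(kb), 1))
            tab <- tab[order(-tab$kb, tab$seq), , drop = FALSE]
            rownames(tab) <- NULL
        } else {
            tab <- data.frame(seq = "(none)", kb = 0)
        }
        json$maleSpecificKb <- tab
        text <- c(text, "", "## Male-specific regions (kb per sequence)",
                  sprintf("%s\t%.1f", tab$seq, tab$kb))
    }

    if (!is.null(assemblyStats)) {
        a <- assemblyStats
        json$assembly <- list(
            nSequences = a@nSequences, totalLength = a@totalLength,
            N50 = a@nX[["N50"]], L50 = a@lX[["L50"]],
            N90 = a@nX[["N90"]], L90 = a@lX[["L90"]],
            largest = a@largest, gcPercent = round(100 * a@gcFraction, 2),
            gapLength = a@gapLength, gapCount = a@gapCount)
        text <- c(text, "", "## Assembly",
                  sprintf("sequences\t%d", a@nSequences),
                  sprintf("total (bp)\t%.0f", a@totalLength),
                  sprintf("N50 (bp)\t%.0f", a@nX[["N50"]]),
                  sprintf("largest (bp)\t%.0f", a@largest),
                  sprintf("gap length (bp)\t%.0f", a@gapLength),
                  sprintf("GC (%%)\t%.2f", 100 * a@gcFraction))
        if (!is.null(previousN50)) {
            folds <- vapply(previousN50,
                            function(o) foldChange(a@nX[["N50"]], o),
                            numeric(1))
            json$assembly$n50Fold <- as.list(folds)
            text <- c(text, sprintf("N50 fold vs %s\t%.2f",
                                    names(folds), folds))
        }
        if (!is.null(previousGap)) {
            folds <- vapply(previousGap,
                            function(o) foldChange(a@gapLength, o,
                                                   type = "reduction"),
                            numeric(1))
            json$assembly$gapReduction <- as.list(folds)
            text <- c(text, sprintf("gap reduction vs %s\t%.2f",
                                    names(folds), folds))
        }
    }

    if (!is.null(telomeres)) {
        json$telomeres <- list(detected = telomeres$detected,
                               totalEnds = telomeres$totalEnds)
        text <- c(text, "", sprintf("## Telomeres: %d of %d ends",
                                    telomeres$detected, telomeres$totalEnds))
    }

    if (!is.null(overlaps)) {
        json$overlap <- lapply(overlaps, function(o)
            o[c("overlapping", "total", "percent")])
        text <- c(text, "", "## Enzyme tag / CpG overlap",
                  vapply(names(overlaps), function(e) sprintf(
                      "%s\t%d / %d (%.1f%%)", e,
                      overlaps[[e]]$overlapping, overlaps[[e]]$total,
                      overlaps[[e]]$percent), character(1)))
    }

    if (!is.null(dms)) {
        json$dms <- list(tested = attr(dms, "nTested"),
                         significant = attr(dms, "nSignificant"),
                         alphaFdr = attr(dms, "alphaFdr"))
        text <- c(text, "", sprintf(
            "## DMS screen: %d significant of %d tested (FDR < %.2g)",
            attr(dms, "nSignificant"), attr(dms, "nTested"),
            attr(dms, "alphaFdr")))
    }

    list(json = json, text = text)
}
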