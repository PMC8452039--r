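#' Write one per-base depth track as a TSV
#'
#' Three columns, no header: sequence id, 1-based position, depth. Every
#' position is emitted, including zeros, so downstream window sums need no
#' imputation.
#'
#' @param track an `RleList` of per-base depth, one element per sequence.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDepthTrack <- function(track, path) {
    dt <- data.table::rbindlist(lapply(names(track), function(sn) {
        v <- as.integer(track[[sn]])
        data.table::data.table(seq = sn, pos = seq_along(v), depth = v)
    }))
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read a per-base depth track
#'
#' Accepts the 3-column depth-caller dialect (sequence, 1-based position,
#' depth) or a 4-column bedGraph (sequence, 0-based start, end, depth).
#' Positions absent from the file get depth 0.
#'
#' @param path TSV/bedGraph file.
#' @param seqlengths named vector of sequence lengths defining the
#'   coordinate frame (e.g. from a FASTA index or `width()` of the genome).
#' @return an `RleList` of per-base depth, one element per sequence in
#'   `seqlengths`.
#' @export
readDepthTrack <- function(path, seqlengths) {
    dt <- data.table::fread(path, header = FALSE)
    if (!ncol(dt) %in% c(3L, 4L))
        stop("depth track must have 3 (depth TSV) or 4 (bedGraph) columns: ",
             path)
    if (ncol(dt) == 4L) {
        data.table::setnames(dt, c("seq", "start0", "end", "depth"))
        dt <- dt[, {
            p <- (start0 + 1L):end
            list(pos = p, depth = rep(depth, length(p)))
        }, by = .(seq, start0, end)][, .(seq, pos, depth)]
    } else {
        data.table::setnames(dt, c("seq", "pos", "depth"))
    }
    unknown <- setdiff(unique(dt$seq), names(seqlengths))
    if (length(unknown))
        stop("depth track references unknown sequence id(s): ",
             paste(unknown, collapse = ", "))
    if (anyDuplicated(dt, by = c("seq", "pos")))
        stop("duplicate positions in depth track: ", path)
    if (dt[, any(pos < 1L | pos > seqlengths[seq])])
        stop("depth track positions outside sequence bounds: ", path)
    out <- lapply(names(seqlengths), function(sn) {
        v <- integer(seqlengths[[sn]])
        sub <- dt[seq == sn]
        v[sub$pos] <- sub$depth
        Rle(v)
    })
    names(out) <- names(seqlengths)
    methods::as(out, "RleList")
}

#' Read a sample sheet
#'
#' TSV with header columns `sample`, `sex` (`male`/`female`) and `path`
#' (depth track per sample).
#'
#' @param path sample sheet file.
#' @return data.frame with validated columns.
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "sex", "path")
    if (!all(need %in% names(df)))
        stop("sample sheet needs columns: ", paste(need, collapse = ", "))
    if (!all(df$sex %in% c("male", "female")))
        stop("sample sheet sex labels must be 'male' or 'female'")
    if (anyDuplicated(df$sample))
        stop("duplicate sample ids in sample sheet")
    df
}

#' Read per-read CpG methylation calls
#'
#' TSV with header columns `seq`, `pos` (1-based C of the plus-strand CpG),
#' `read_id`, `methylated` (0/1).
#'
#' @param path calls file.
#' @return a `data.table` of calls.
#' @export
readMethylCalls <- function(path) {
    dt <- data.table::fread(path, header = TRUE)
    need <- c("seq", "pos", "read_id", "methylated")
    if (!all(need %in% names(dt)))
        stop("methylation calls need columns: ", paste(need, collapse = ", "))
    dt
}

#' Read marker loci from a BED file
#'
#' Minimal BED reader (chrom, 0-based start, end, optional name); malformed
#' lines are reported with their line number.
#'
#' @param path BED file.
#' @return `GRanges` with a `name` metadata column.
#' @export
readMarkers <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(GRanges(name = character(0)))
    recs <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
        s <- suppressWarnings(as.integer(f[2L]))
        e <- suppressWarnings(as.integer(f[3L]))
        if (is.na(s) || is.na(e) || s < 0L || e <= s)
            stop(sprintf("malformed BED line %d: bad interval [%s, %s)",
                         i, f[2L], f[3L]))
        list(seq = f[1L], start = s, end = e,
             name = if (length(f) >= 4L) f[4L] else sprintf("marker%d", i))
    })
    GRanges(vapply(recs, `[[`, "", "seq"),
            IRanges(start = vapply(recs, `[[`, 0L, "start") + 1L,
                    end = vapply(recs, `[[`, 0L, "end")),
            name = vapply(recs, `[[`, "", "name"))
}

#' Write a full simulated study to disk
#'
#' Emits the genome FASTA, the truth-region BED, one depth TSV per sample,
#' the per-read methylation call TSV, the truth methylation table and a JSON
#' sidecar echoing the complete configuration.
#'
#' @param study output of [simulateStudy()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(study, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        genome = file.path(outdir, "genome.fasta"),
        truth_regions = file.path(outdir, "truth_regions.bed"),
        methyl_calls = file.path(outdir, "methyl_calls.tsv"),
        methyl_truth = file.path(outdir, "methyl_truth.tsv"),
        sample_sheet = file.path(outdir, "samples.tsv"),
        config = file.path(outdir, "config.json"))
    writeXStringSet(study$genome, paths[["genome"]])
    rtracklayer::export(study$truth$regions, paths[["truth_regions"]],
                        format = "BED")
    data.table::fwrite(study$meth$calls, paths[["methyl_calls"]], sep = "\t")
    data.table::fwrite(study$meth$truth, paths[["methyl_truth"]], sep = "\t")
    depthPaths <- vapply(names(study$tracks), function(sm) {
        p <- file.path(outdir, sprintf("depth_%s.tsv", sm))
        writeDepthTrack(study$tracks[[sm]], p)
        p
    }, character(1))
    utils::write.table(
        data.frame(sample = names(study$sex), sex = unname(study$sex),
                   path = unname(depthPaths)),
        paths[["sample_sheet"]], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(configAsList(study$config), paths[["config"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(paths, depthPaths))
}
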