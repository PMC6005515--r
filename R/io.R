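## Tabular IO: tab-separated UTF-8 count tables with a header row and guide
## ids in the first column; comma-separated sample sheets and plate tables.

#' Read and write guide library annotation TSVs
#'
#' Columns: guide_id, gene, sequence, is_ntc.
#'
#' @param path file path.
#' @return [readGuideLibrary()] a \linkS4class{GuideLibrary};
#'   [writeGuideLibrary()] invisibly, the path.
#' @export
readGuideLibrary <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("guide_id", "gene")
    if (!all(need %in% colnames(df)))
        stop("library file needs columns guide_id and gene")
    guideLibrary(df$guide_id, df$gene,
                 sequence = if ("sequence" %in% colnames(df)) df$sequence
                            else NA_character_)
}

#' @rdname readGuideLibrary
#' @param library a \linkS4class{GuideLibrary}.
#' @export
writeGuideLibrary <- function(library, path) {
    utils::write.table(as.data.frame(library), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a guide count table plus sample sheet into a ScreenExperiment
#'
#' The count TSV has guide ids in its first column and one integer column
#' per sample; the sample sheet CSV has columns sample, replicate, arm,
#' day. Rows for guides absent from the library are dropped with a
#' warning; malformed or negative count cells and samples missing from the
#' sheet are hard errors naming the offender.
#'
#' @param count_path count TSV path.
#' @param samplesheet_path sample sheet CSV path.
#' @param library_path library TSV path, or a \linkS4class{GuideLibrary}.
#' @return A \linkS4class{ScreenExperiment}.
#' @export
readCounts <- function(count_path, samplesheet_path, library_path) {
    raw <- utils::read.delim(count_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (ncol(raw) < 2) stop("count table needs at least one sample column")
    ids <- as.character(raw[[1]])
    for (j in seq(2, ncol(raw))) {
        v <- raw[[j]]
        num <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(num) | num < 0 | num != round(num))
        if (length(bad))
            stop(sprintf(
                "invalid count at row '%s', column '%s': '%s'",
                ids[bad[1]], colnames(raw)[j], v[bad[1]]))
        raw[[j]] <- as.integer(num)
    }
    cts <- as.matrix(raw[, -1, drop = FALSE])
    rownames(cts) <- ids
    sheet <- utils::read.csv(samplesheet_path, stringsAsFactors = FALSE)
    lib <- if (is(library_path, "GuideLibrary")) library_path
           else readGuideLibrary(library_path)
    ScreenExperiment(cts, sheet, lib)
}

#' @rdname readCounts
#' @param se a \linkS4class{ScreenExperiment}.
#' @param samplesheet_path optional; when given the sample sheet CSV is
#'   written alongside the counts.
#' @export
writeCounts <- function(se, count_path, samplesheet_path = NULL) {
    df <- data.frame(guide_id = rownames(se), counts(se),
                     check.names = FALSE)
    utils::write.table(df, count_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(samplesheet_path)) {
        sheet <- data.frame(sample = colnames(se),
                            replicate = screenReplicates(se),
                            arm = screenArms(se), day = screenDays(se))
        utils::write.csv(sheet, samplesheet_path, row.names = FALSE,
                         quote = FALSE)
    }
    invisible(count_path)
}

#' Discard guides with too few reads over all samples
#'
#' Retains exactly the guides whose count total across all samples is at
#' least \code{min_total}; a guide with 9 reads overall is discarded at
#' the default threshold of 10, one with exactly 10 is kept. Applied once,
#' before normalization. Idempotent, and indifferent to sample order.
#'
#' @param se a \linkS4class{ScreenExperiment}.
#' @param min_total minimum summed count (default 10).
#' @return The filtered \linkS4class{ScreenExperiment}; the ids of the
#'   removed guides are in \code{metadata(.)$removed_guides}.
#' @export
filterLowCountGuides <- function(se, min_total = 10) {
    stopifnot(is(se, "ScreenExperiment"))
    keep <- rowSums(counts(se)) >= min_total
    out <- se[keep, ]
    metadata(out)$removed_guides <- rownames(se)[!keep]
    out
}
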