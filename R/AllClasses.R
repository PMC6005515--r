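#' @importFrom methods new validObject is as setValidity callNextMethod
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

NTC_GENE_LABEL <- "NTC"

#' GuideLibrary: the guide-to-gene map of a pooled CRISPR library
#'
#' A \linkS4class{DFrame} subclass holding one row per guide with columns
#' \code{guide_id} (unique), \code{gene} (the label \code{"NTC"} groups
#' non-targeting controls), \code{sequence} (spacer, may be \code{NA}) and
#' \code{is_ntc}. The library defines the universe over which gene-level
#' aggregation happens.
#'
#' @seealso [guideLibrary()], [simulateLibrary()]
#' @exportClass GuideLibrary
setClass("GuideLibrary", contains = "DFrame")

setValidity("GuideLibrary", function(object) {
    need <- c("guide_id", "gene", "sequence", "is_ntc")
    if (!all(need %in% colnames(object)))
        return(paste("missing columns:",
                     paste(setdiff(need, colnames(object)), collapse = ", ")))
    if (anyDuplicated(object$guide_id))
        return("guide_id values must be unique")
    if (!is.logical(object$is_ntc) || anyNA(object$is_ntc))
        return("is_ntc must be logical without NAs")
    if (!identical(unname(object$is_ntc),
                   unname(object$gene == NTC_GENE_LABEL)))
        return("is_ntc must be TRUE exactly when gene == \"NTC\"")
    seqs <- object$sequence
    ok <- is.na(seqs) | grepl("^[ACGT]*$", seqs)
    if (!all(ok))
        return("sequence must use the DNA alphabet {A,C,G,T}")
    TRUE
})

#' Construct a GuideLibrary
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param gene character vector of target genes; use \code{"NTC"} for
#'   non-targeting controls.
#' @param sequence optional spacer sequences (\code{NA} allowed).
#' @param is_ntc logical; defaults to \code{gene == "NTC"}.
#' @return A \linkS4class{GuideLibrary}.
#' @examples
#' guideLibrary(c("g1", "g2", "ntc1"), c("KRAS", "KRAS", "NTC"))
#' @export
guideLibrary <- function(guide_id, gene,
                         sequence = NA_character_,
                         is_ntc = gene == NTC_GENE_LABEL) {
    df <- DataFrame(guide_id = as.character(guide_id),
                    gene = as.character(gene),
                    sequence = rep_len(as.character(sequence),
                                       length(guide_id)),
                    is_ntc = as.logical(is_ntc))
    rownames(df) <- df$guide_id
    new("GuideLibrary", df)
}

#' @describeIn guideLibrary guide identifiers
#' @param x a \code{GuideLibrary}
#' @export
guideIds <- function(x) x$guide_id

#' @describeIn guideLibrary target gene per guide
#' @export
targetGenes <- function(x) x$gene

#' @describeIn guideLibrary logical NTC flag per guide
#' @export
isNTC <- function(x) x$is_ntc

setMethod("show", "GuideLibrary", function(object) {
    cat(sprintf("GuideLibrary with %d guides (%d genes, %d NTC)\n",
                nrow(object),
                length(unique(object$gene[!object$is_ntc])),
                sum(object$is_ntc)))
    callNextMethod()
})

#' ScreenExperiment: guide counts with screen sample metadata
#'
#' A \linkS4class{SummarizedExperiment} subclass for pooled-screen count
#' data: a \code{"counts"} assay of non-negative integers (guides x
#' samples), \code{colData} columns \code{replicate}, \code{arm} and
#' \code{day}, and \code{rowData} columns \code{gene} and \code{is_ntc}
#' carried over from the \linkS4class{GuideLibrary}.
#'
#' @seealso [ScreenExperiment()], [simulateScreen()], [readCounts()]
#' @exportClass ScreenExperiment
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
    if (!"counts" %in% assayNames(object))
        return("assay \"counts\" is required")
    cts <- assay(object, "counts")
    if (anyNA(cts) || any(cts < 0))
        return("counts must be non-negative and free of NAs")
    if (any(cts != round(cts)))
        return("counts must be integers")
    need <- c("replicate", "arm", "day")
    if (!all(need %in% colnames(colData(object))))
        return(paste("colData must contain:", paste(need, collapse = ", ")))
    if (!all(c("gene", "is_ntc") %in% colnames(rowData(object))))
        return("rowData must contain gene and is_ntc")
    TRUE
})

#' Construct a ScreenExperiment
#'
#' @param counts integer matrix, guides x samples, rownames = guide ids,
#'   colnames = sample names.
#' @param sampleInfo data.frame with one row per sample and columns
#'   \code{sample}, \code{replicate}, \code{arm}, \code{day}.
#' @param library a \linkS4class{GuideLibrary} covering the count rows.
#'   Count rows for guides absent from the library are dropped with a
#'   warning.
#' @return A \linkS4class{ScreenExperiment}.
#' @export
ScreenExperiment <- function(counts, sampleInfo, library) {
    stopifnot(is.matrix(counts), !is.null(rownames(counts)),
              !is.null(colnames(counts)))
    if (!is(library, "GuideLibrary"))
        stop("'library' must be a GuideLibrary")
    sampleInfo <- as.data.frame(sampleInfo)
    if (!all(c("sample", "replicate", "arm", "day") %in% colnames(sampleInfo)))
        stop("sampleInfo needs columns sample, replicate, arm, day")
    missing <- setdiff(colnames(counts), sampleInfo$sample)
    if (length(missing))
        stop("samples in counts missing from sample sheet: ",
             paste(missing, collapse = ", "))
    unknown <- setdiff(rownames(counts), guideIds(library))
    if (length(unknown)) {
        warning(length(unknown), " count rows for guides absent from the ",
                "library were dropped: ",
                paste(utils::head(unknown, 5), collapse = ", "),
                if (length(unknown) > 5) ", ..." else "")
        counts <- counts[setdiff(rownames(counts), unknown), , drop = FALSE]
    }
    rownames(sampleInfo) <- sampleInfo$sample
    sampleInfo <- sampleInfo[colnames(counts), , drop = FALSE]
    lib <- library[match(rownames(counts), guideIds(library)), , drop = FALSE]
    rd <- DataFrame(gene = lib$gene, is_ntc = lib$is_ntc,
                    row.names = rownames(counts))
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(sampleInfo[, c("replicate", "arm", "day"),
                                       drop = FALSE]),
        rowData = rd)
    new("ScreenExperiment", se)
}

#' @describeIn ScreenExperiment the integer count matrix
#' @param object a \code{ScreenExperiment}
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "ScreenExperiment",
          function(object) assay(object, "counts"))

#' @describeIn ScreenExperiment treatment arm per sample
#' @export
screenArms <- function(object) as.character(colData(object)$arm)

#' @describeIn ScreenExperiment harvest day per sample
#' @export
screenDays <- function(object) as.numeric(colData(object)$day)

#' @describeIn ScreenExperiment replicate (infection) id per sample
#' @export
screenReplicates <- function(object) as.character(colData(object)$replicate)

setMethod("show", "ScreenExperiment", function(object) {
    cat(sprintf(
        "ScreenExperiment: %d guides x %d samples (arms: %s; days: %s)\n",
        nrow(object), ncol(object),
        paste(unique(screenArms(object)), collapse = "/"),
        paste(sort(unique(screenDays(object))), collapse = ",")))
    callNextMethod()
})
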