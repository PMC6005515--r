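#' Count guides in amplicon FASTQ reads by exact spacer match
#'
#' Stands in for full read alignment: each read is searched for an exact,
#' forward-strand occurrence of a library spacer within a configurable
#' offset window. A read matching exactly one guide increments that
#' guide's count; reads matching two or more guides are discarded as
#' ambiguous; reads matching none are tallied as unmapped. Gzipped input
#' is read transparently.
#'
#' @param fastq_path FASTQ(.gz) path.
#' @param library a \linkS4class{GuideLibrary}; all sequences must be
#'   present, equal length, and unique (duplicates make exact matching
#'   ambiguous by construction and are an error).
#' @param spacer_window integer c(start, end) 1-based window of read
#'   positions the spacer may start at; NULL searches the whole read.
#' @return A named list: \code{counts} (named integer vector per guide),
#'   \code{ambiguous} and \code{unmapped} read tallies.
#' @examples
#' lib <- guideLibrary(c("a", "b"), c("G1", "G2"),
#'                     sequence = c("ACGTACGTACGTACGTACG",
#'                                  "TTTTACGTACGTACGTACG"))
#' @export
countGuidesFromFastq <- function(fastq_path, library,
                                 spacer_window = NULL) {
    stopifnot(is(library, "GuideLibrary"))
    seqs <- library$sequence
    if (anyNA(seqs)) stop("library sequences must all be present")
    if (length(unique(nchar(seqs))) != 1L)
        stop("library sequences must have equal length")
    if (anyDuplicated(seqs))
        stop("duplicate guide sequences in library: exact matching ",
             "would be ambiguous")
    reads <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
    if (!is.null(spacer_window)) {
        stopifnot(length(spacer_window) == 2, spacer_window[1] >= 1)
        end <- pmin(Biostrings::width(reads),
                    spacer_window[2] + nchar(seqs[1]) - 1L)
        start <- pmin(spacer_window[1], Biostrings::width(reads))
        reads <- Biostrings::subseq(reads, start = start, end = end)
    }
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
    hits <- Biostrings::vwhichPDict(pd, reads)
    nhit <- lengths(hits)
    cts <- integer(nrow(library))
    names(cts) <- guideIds(library)
    one <- unlist(hits[nhit == 1L], use.names = FALSE)
    if (length(one)) {
        tab <- tabulate(one, nbins = nrow(library))
        cts <- cts + tab
    }
    list(counts = cts,
         ambiguous = sum(nhit >= 2L),
         unmapped = sum(nhit == 0L))
}
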