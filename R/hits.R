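#' Gene-level median log fold-change
#'
#' Aggregates guide-level LFCs to one value per gene: the median over the
#' gene's surviving guides (midpoint of the two central values for even
#' counts). Genes whose guides were all filtered upstream are omitted
#' with a warning. Non-targeting controls are aggregated as one "NTC"
#' pseudo-gene for QC.
#'
#' @param guide_stats a data.frame/DataFrame with columns guide_id, gene
#'   and lfc (e.g. from [guideStats()]).
#' @param library a \linkS4class{GuideLibrary}; defines the gene universe.
#' @return A [S4Vectors::DataFrame] with gene, n_guides, median_lfc,
#'   is_ntc.
#' @export
geneMedianLfc <- function(guide_stats, library) {
    gs <- as.data.frame(guide_stats)
    stopifnot(all(c("guide_id", "lfc") %in% colnames(gs)))
    gene <- targetGenes(library)[match(gs$guide_id, guideIds(library))]
    if (anyNA(gene))
        stop("guide(s) absent from library: ",
             paste(utils::head(gs$guide_id[is.na(gene)], 3),
                   collapse = ", "))
    med <- tapply(gs$lfc, gene, stats::median)
    n <- tapply(gs$lfc, gene, length)
    allGenes <- unique(targetGenes(library))
    lost <- setdiff(allGenes, names(med))
    if (length(lost))
        warning(length(lost), " gene(s) with no surviving guides omitted")
    DataFrame(gene = names(med), n_guides = as.integer(n),
              median_lfc = as.numeric(med),
              is_ntc = names(med) == NTC_GENE_LABEL)
}

#' Call enriched and depleted genes at a median-LFC cutoff
#'
#' Strict inequalities: enriched genes have median_lfc > cutoff, depleted
#' median_lfc < -cutoff; a gene sitting exactly on the cutoff is not a
#' hit. The cutoff is in log2 units, so the conventional ">2-fold" rule is
#' cutoff = 1. The NTC pseudo-gene is excluded from both sets.
#'
#' @param results gene-level results from [geneMedianLfc()].
#' @param cutoff positive log2 cutoff (default 1.0).
#' @return list(enriched =, depleted =) character vectors of gene names.
#' @export
callHits <- function(results, cutoff = 1.0) {
    stopifnot(cutoff > 0)
    res <- as.data.frame(results)
    res <- res[res$gene != NTC_GENE_LABEL, , drop = FALSE]
    list(enriched = res$gene[res$median_lfc > cutoff],
         depleted = res$gene[res$median_lfc < -cutoff])
}

#' Cross-arm overlap of hit sets
#'
#' Venn partition of enriched and depleted hit sets across treatment
#' arms: per direction, the genes shared by all arms and the genes
#' exclusive to each arm, with counts.
#'
#' @param hits_by_arm named list (one element per arm) of [callHits()]
#'   results.
#' @return Nested list per direction: \code{shared}, \code{exclusive}
#'   (per arm) memberships and \code{counts}.
#' @export
armOverlap <- function(hits_by_arm) {
    stopifnot(length(hits_by_arm) >= 2, !is.null(names(hits_by_arm)))
    arms <- names(hits_by_arm)
    perDirection <- function(direction) {
        sets <- lapply(hits_by_arm, `[[`, direction)
        shared <- Reduce(intersect, sets)
        exclusive <- lapply(seq_along(sets), function(i)
            setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE)))
        names(exclusive) <- arms
        list(shared = shared, exclusive = exclusive,
             counts = c(shared = length(shared),
                        vapply(exclusive, length, integer(1))))
    }
    list(enriched = perDirection("enriched"),
         depleted = perDirection("depleted"))
}

#' Squared Pearson correlation between two screens' guide LFCs
#'
#' Concordance of two screens over their shared guides, as the squared
#' Pearson correlation (invariant to affine rescaling of either input,
#' insensitive to sign).
#'
#' @param lfc_a,lfc_b named numeric vectors of per-guide LFCs.
#' @return R-squared in [0, 1].
#' @export
concordanceR2 <- function(lfc_a, lfc_b) {
    if (is.null(names(lfc_a)) || is.null(names(lfc_b)))
        stop("lfc vectors must be named by guide id")
    shared <- intersect(names(lfc_a), names(lfc_b))
    a <- lfc_a[shared]; b <- lfc_b[shared]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3)
        stop("need at least 3 shared guides with finite values")
    stats::cor(a[ok], b[ok])^2
}
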