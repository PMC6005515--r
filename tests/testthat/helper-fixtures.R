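## Shared fixture builders: everything is generated in code at test time.

smallConfig <- function(n_genes = 50, guides_per_gene = 4, n_ntc = 8,
                        arms = c("vehicle", "MEKi"), days = c(0, 21),
                        coverage = 1000, dispersion = 0.05, seed = 1L,
                        ...) {
    simConfig(n_genes = n_genes, guides_per_gene = guides_per_gene,
              n_ntc = n_ntc, arms = arms, days = days,
              coverage = coverage, dispersion = dispersion, seed = seed,
              ...)
}

## a simulated screen with optional planted sensitizers (delta < 0 in the
## drug arm for the first `n_sensitizers` genes)
plantedScreen <- function(config = smallConfig(), n_sensitizers = 0,
                          delta = -0.1) {
    lib <- simulateLibrary(config)
    genes <- unique(targetGenes(lib)[!isNTC(lib)])
    eff <- effectTable(genes, arms = config@arms[-1])
    if (n_sensitizers > 0)
        eff@delta[seq_len(n_sensitizers), ] <- delta
    list(library = lib, effects = eff,
         experiment = simulateScreen(lib, eff, config),
         sensitizers = if (n_sensitizers > 0)
             genes[seq_len(n_sensitizers)] else character(0))
}

## deterministic toy count matrix with known guide totals
toyCountFiles <- function(dir, counts = NULL) {
    if (is.null(counts)) {
        counts <- matrix(c(5L, 4L,   # total 9: filtered at 10
                           6L, 4L,   # total 10: kept
                           100L, 200L),
                         nrow = 3, byrow = TRUE,
                         dimnames = list(c("g1", "g2", "g3"),
                                         c("s1", "s2")))
    }
    lib <- guideLibrary(rownames(counts),
                       gene = ifelse(grepl("^NTC", rownames(counts)),
                                     "NTC", paste0("G_",
                                                   rownames(counts))))
    sheet <- data.frame(sample = colnames(counts),
                        replicate = "rep1",
                        arm = c("vehicle",
                                rep("MEKi", ncol(counts) - 1)),
                        day = 21)
    cp <- file.path(dir, "counts.tsv")
    sp <- file.path(dir, "sheet.csv")
    lp <- file.path(dir, "library.tsv")
    utils::write.table(data.frame(guide_id = rownames(counts), counts),
                       cp, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(sheet, sp, row.names = FALSE, quote = FALSE)
    writeGuideLibrary(lib, lp)
    list(counts = cp, sheet = sp, library = lp, matrix = counts,
         lib = lib)
}

## write a minimal FASTQ embedding given spacer sequences at an offset
writeFastq <- function(path, inserts, offset = 5) {
    lines <- unlist(lapply(seq_along(inserts), function(i) {
        read <- paste0(substr("ACGTACGTACGTACGTACGT", 1, offset - 1),
                       inserts[i], "TGCA")
        c(sprintf("@read%d", i), read, "+",
          paste(rep("I", nchar(read)), collapse = ""))
    }))
    writeLines(lines, path)
    path
}
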