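mkStats <- function(lfcs, genes) {
    data.frame(guide_id = sprintf("g%04d", seq_along(lfcs)),
               lfc = lfcs, gene = genes)
}
mkLib <- function(stats) guideLibrary(stats$guide_id, stats$gene)

test_that("gene medians follow the midpoint rule", {
    st <- mkStats(c(-2, -1, 0, 1, rep(-1.3, 8)),
                  c(rep("A", 4), rep("B", 8)))
    res <- geneMedianLfc(st, mkLib(st))
    df <- as.data.frame(res)
    expect_equal(df$median_lfc[df$gene == "A"], -0.5)
    expect_equal(df$median_lfc[df$gene == "B"], -1.3)
    expect_equal(df$n_guides[df$gene == "A"], 4L)
})

test_that("medians match a sort-based brute force on 500 random genes", {
    set.seed(31)
    genes <- rep(sprintf("G%03d", 1:500), each = 8)
    lfcs <- rnorm(4000)
    st <- mkStats(lfcs, genes)
    res <- as.data.frame(geneMedianLfc(st, mkLib(st)))
    bruteMedian <- function(x) {
        s <- sort(x); n <- length(s)
        if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    }
    oracle <- vapply(split(lfcs, genes), bruteMedian, numeric(1))
    expect_equal(res$median_lfc[match(names(oracle), res$gene)],
                 unname(oracle), tolerance = 1e-15)
    ## |median| never exceeds the gene's largest |guide lfc|
    maxAbs <- vapply(split(lfcs, genes), function(x) max(abs(x)),
                     numeric(1))
    expect_true(all(abs(oracle) <= maxAbs))
})

test_that("genes with no surviving guides are omitted with a warning", {
    st <- mkStats(c(1, 1), c("A", "A"))
    lib <- guideLibrary(c(st$guide_id, "gx"), c("A", "A", "B"))
    expect_warning(res <- geneMedianLfc(st, lib), "no surviving")
    expect_false("B" %in% as.data.frame(res)$gene)
    ## the NTC pseudo-gene is reported when NTC guides survive
    st2 <- mkStats(c(0.1, -0.1, 2), c("NTC", "NTC", "A"))
    res2 <- as.data.frame(geneMedianLfc(st2, mkLib(st2)))
    expect_true("NTC" %in% res2$gene)
    expect_true(res2$is_ntc[res2$gene == "NTC"])
})

test_that("hit calls use strict cutoffs and exclude the NTC pseudo-gene", {
    st <- mkStats(c(rep(1.0, 3), rep(1.2, 3), rep(-0.5, 3), rep(-2, 3),
                    rep(1.4, 2)),
                  c(rep(c("atCut", "up", "mild", "down"), each = 3),
                    rep("NTC", 2)))
    res <- geneMedianLfc(st, mkLib(st))
    h1 <- callHits(res, 1.0)
    expect_setequal(h1$enriched, "up")          # 1.0 itself is not a hit
    expect_setequal(h1$depleted, "down")
    expect_false("NTC" %in% c(h1$enriched, h1$depleted))
    h05 <- callHits(res, 0.5)
    expect_setequal(h05$enriched, c("up", "atCut"))
    expect_setequal(h05$depleted, "down")       # -0.5 is not below -0.5
    expect_error(callHits(res, 0), "cutoff > 0")
})

test_that("hit calling is monotone in the cutoff", {
    set.seed(32)
    st <- mkStats(rnorm(800, sd = 1), rep(sprintf("G%03d", 1:100), 8))
    res <- geneMedianLfc(st, mkLib(st))
    cuts <- c(0.25, 0.5, 1.0, 1.5)
    hs <- lapply(cuts, function(ct) callHits(res, ct))
    for (i in seq_len(length(cuts) - 1)) {
        expect_true(all(hs[[i + 1]]$enriched %in% hs[[i]]$enriched))
        expect_true(all(hs[[i + 1]]$depleted %in% hs[[i]]$depleted))
    }
})

test_that("permuting guide-gene labels destroys planted hits", {
    scr <- plantedScreen(smallConfig(n_genes = 150, seed = 33),
                         n_sensitizers = 10, delta = -0.15)
    se <- filterLowCountGuides(scr$experiment)
    gs <- guideStats(se, "MEKi")
    res <- geneMedianLfc(gs, scr$library)
    h <- callHits(res, 1.0)
    expect_gte(length(h$depleted), 8)
    set.seed(1)
    perm <- gs
    perm$lfc <- sample(perm$lfc)
    hPerm <- callHits(geneMedianLfc(perm, scr$library), 1.0)
    nGenes <- length(unique(targetGenes(scr$library)))
    expect_lte(length(hPerm$enriched) + length(hPerm$depleted),
               ceiling(0.01 * nGenes))
})

test_that("arm overlap partitions hit sets correctly", {
    hA <- list(enriched = c("a", "b"), depleted = c("x", "y", "z"))
    ## identical sets: everything shared
    ov <- armOverlap(list(MEKi = hA, ERKi = hA))
    expect_setequal(ov$enriched$shared, c("a", "b"))
    expect_equal(unname(ov$enriched$counts),
                 c(2, 0, 0))
    ## disjoint sets: nothing shared
    hB <- list(enriched = c("c"), depleted = c("w"))
    ov2 <- armOverlap(list(MEKi = hA, ERKi = hB))
    expect_length(ov2$depleted$shared, 0)
    expect_setequal(ov2$depleted$exclusive$MEKi, c("x", "y", "z"))
    expect_setequal(ov2$depleted$exclusive$ERKi, "w")
    ## subset structure: no ERKi-exclusive genes
    hSub <- list(enriched = "a", depleted = c("x", "y"))
    ov3 <- armOverlap(list(MEKi = hA, ERKi = hSub))
    expect_length(ov3$depleted$exclusive$ERKi, 0)
    expect_setequal(ov3$depleted$exclusive$MEKi, "z")
    expect_error(armOverlap(list(MEKi = hA)), "length")
})

test_that("ERKi effects nested in MEKi effects give no ERKi-exclusive hits", {
    cfg <- smallConfig(n_genes = 80, arms = c("vehicle", "MEKi", "ERKi"),
                       seed = 34)
    lib <- simulateLibrary(cfg)
    genes <- unique(targetGenes(lib)[!isNTC(lib)])
    eff <- effectTable(genes, arms = c("MEKi", "ERKi"))
    eff@delta[1:8, "MEKi"] <- -0.15      # MEKi-only sensitizers
    eff@delta[1:4, "ERKi"] <- -0.15      # ERKi effects are a subset
    se <- filterLowCountGuides(simulateScreen(lib, eff, cfg))
    hits <- lapply(c(MEKi = "MEKi", ERKi = "ERKi"), function(a)
        callHits(geneMedianLfc(guideStats(se, a), lib), 1.0))
    ov <- armOverlap(hits)
    expect_length(ov$depleted$exclusive$ERKi, 0)
    expect_setequal(ov$depleted$shared, genes[1:4])
})

test_that("concordance R2 is affine-invariant and needs 3 shared guides", {
    set.seed(35)
    a <- setNames(rnorm(50), sprintf("g%02d", 1:50))
    expect_equal(concordanceR2(a, a), 1.0)
    expect_equal(concordanceR2(a, -2 * a), 1.0)
    expect_equal(concordanceR2(a, 3 * a + 5), 1.0)
    b <- setNames(rnorm(50), names(a))
    r2 <- concordanceR2(a, b)
    expect_equal(r2, cor(a, b)^2)
    expect_error(concordanceR2(a[1:2], a[1:2]), "3 shared")
    expect_error(concordanceR2(unname(a), unname(a)), "named")
})

test_that("twin screens of one effect table are concordant (R2 > 0.8)", {
    cfg1 <- smallConfig(n_genes = 120, guides_per_gene = 4, seed = 36)
    cfg2 <- cfg1; cfg2@seed <- 37L
    lib <- simulateLibrary(cfg1)
    genes <- unique(targetGenes(lib)[!isNTC(lib)])
    eff <- effectTable(genes, arms = "MEKi")
    set.seed(38)
    ## effect sizes spanning LFCs of roughly -3..+1.5 at day 21
    eff@delta[, "MEKi"] <- c(runif(30, -0.15, 0.07), rep(0, 90))
    lfcOf <- function(cfg) {
        se <- filterLowCountGuides(simulateScreen(lib, eff, cfg))
        gs <- guideStats(se, "MEKi")
        setNames(gs$lfc, gs$guide_id)
    }
    expect_gt(concordanceR2(lfcOf(cfg1), lfcOf(cfg2)), 0.8)
})
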