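## small normalized matrix with two 3-sample conditions
mkNormed <- function(n = 200, sd = 0.2, seed = 10, means = NULL) {
    set.seed(seed)
    if (is.null(means)) means <- runif(n, 2, 12)
    y <- matrix(rnorm(n * 6, mean = means, sd = sd), n, 6,
                dimnames = list(sprintf("g%03d", 1:n),
                                paste0("s", 1:6)))
    list(y = y, design = rep(c("vehicle", "MEKi"), each = 3))
}

test_that("homoskedastic data get near-constant precision weights", {
    d <- mkNormed(n = 3000, sd = 0.3)
    w <- voomWeights(d$y, d$design)
    expect_lt(max(abs(w / stats::median(w) - 1)), 0.10)
})

test_that("weights track abundance when variance falls with the mean", {
    ## counts-like heteroskedasticity: sd decreasing in the mean
    set.seed(11)
    n <- 800
    means <- seq(1, 12, length.out = n)
    sds <- 1 / sqrt(2^means * 1e-2)
    y <- matrix(rnorm(n * 6, mean = means, sd = sds), n, 6)
    w <- voomWeights(y, rep(c("a", "b"), each = 3))
    rho <- stats::cor(means, rowMeans(w), method = "spearman")
    expect_gt(rho, 0.9)
})

test_that("identical guides get identical weights; tiny inputs error", {
    y <- matrix(rep(c(1, 2, 3, 7, 8, 9), each = 100), 100, 6)
    rownames(y) <- sprintf("g%d", 1:100)
    w <- voomWeights(y, rep(c("a", "b"), each = 3))
    expect_equal(max(apply(w, 2, function(col) diff(range(col)))), 0)
    expect_error(voomWeights(y[1:3, ], rep(c("a", "b"), each = 3)),
                 "4 guides")
    expect_error(voomWeights(y, c("a", "a", "a", "a", "a", "b")),
                 "at least 2 samples")
})

test_that("unit-weight contrast equals the textbook pooled two-sample fit", {
    d <- mkNormed(n = 50, sd = 0.5, seed = 12)
    fit <- fitContrast(d$y, weights = NULL, design = d$design,
                       treatment = "MEKi", control = "vehicle")
    jt <- d$design == "MEKi"; jc <- !jt
    lfcOracle <- rowMeans(d$y[, jt]) - rowMeans(d$y[, jc])
    s2Oracle <- (apply(d$y[, jt], 1, var) * 2 +
                 apply(d$y[, jc], 1, var) * 2) / 4
    expect_equal(fit$lfc, unname(lfcOracle), tolerance = 1e-12)
    expect_equal(fit$s2, unname(s2Oracle), tolerance = 1e-12)
    expect_equal(fit$df, rep(4L, 50))
    expect_equal(fit$v, rep(1 / 3 + 1 / 3, 50), tolerance = 1e-12)
    ## treatment identical to control: lfc exactly 0
    y2 <- cbind(d$y[, jc], d$y[, jc])
    fit0 <- fitContrast(y2, NULL, d$design, "MEKi", "vehicle")
    expect_equal(fit0$lfc, rep(0, 50))
    expect_error(fitContrast(d$y, NULL, d$design, "ERKi", "vehicle"),
                 "ERKi")
})

test_that("a planted 2-fold depletion is recovered within 0.1 log2", {
    ## high coverage, no sequencing overdispersion: the fit should land
    ## on the planted effect guide by guide
    scr <- plantedScreen(smallConfig(n_genes = 100, coverage = 20000,
                                     dispersion = 0, seed = 13),
                         n_sensitizers = 5, delta = -1 / 21)
    se <- filterLowCountGuides(scr$experiment)
    gs <- guideStats(se, "MEKi")
    planted <- gs$gene %in% scr$sensitizers
    expect_lt(max(abs(gs$lfc[planted] - (-1))), 0.1)
    expect_lt(abs(mean(gs$lfc[planted]) - (-1)), 0.05)
})

test_that("moderated t reduces to its analytic limits", {
    d <- mkNormed(n = 300, sd = 0.4, seed = 14)
    fit <- fitContrast(d$y, NULL, d$design, "MEKi", "vehicle")
    ## d0 = 0: ordinary t
    m0 <- moderateT(fit, d0 = 0, s02 = 1)
    tOrd <- fit$lfc / sqrt(fit$s2 * fit$v)
    expect_equal(m0$t_mod, tOrd, tolerance = 1e-10)
    ## d0 = Inf: z against the prior variance
    mInf <- moderateT(fit, d0 = Inf, s02 = 0.16)
    expect_equal(mInf$t_mod, fit$lfc / sqrt(0.16 * fit$v),
                 tolerance = 1e-10)
    expect_equal(mInf$p, 2 * pnorm(-abs(mInf$t_mod)), tolerance = 1e-12)
    ## all-zero variances are an error
    fitz <- fit; fitz$s2[] <- 0
    expect_error(moderateT(fitz), "zero")
})

test_that("estimated hyperparameters agree with the limma cross-check", {
    skip_if_not_installed("limma")
    d <- mkNormed(n = 1000, sd = 0.4, seed = 15)
    fit <- fitContrast(d$y, NULL, d$design, "MEKi", "vehicle")
    mod <- moderateT(fit)
    sq <- limma::squeezeVar(fit$s2, df = fit$df)
    expect_equal(mod$d0[1], sq$df.prior, tolerance = 1e-6)
    expect_equal(mod$s02[1], sq$var.prior, tolerance = 1e-6)
    expect_equal(mod$s2_post, sq$var.post, tolerance = 1e-8)
})

test_that("moderation shrinks extreme variances toward the trend", {
    d <- mkNormed(n = 600, sd = 0.4, seed = 16)
    fit <- fitContrast(d$y, NULL, d$design, "MEKi", "vehicle")
    mod <- moderateT(fit)
    tOrd <- fit$lfc / sqrt(fit$s2 * fit$v)
    expect_gt(stats::cor(abs(mod$t_mod), abs(tOrd),
                         method = "spearman"), 0)
    ## posterior variances are strictly between s2 and the prior
    lo <- pmin(fit$s2, mod$s02[1]); hi <- pmax(fit$s2, mod$s02[1])
    expect_true(all(mod$s2_post >= lo - 1e-12 &
                    mod$s2_post <= hi + 1e-12))
    expect_true(all(mod$fdr >= mod$p))
})

test_that("BH adjustment follows the hand step-up computation", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    expect_equal(bhFdr(0.2), 0.2)
    set.seed(17)
    p <- runif(50)
    n <- length(p); o <- order(p, decreasing = TRUE)
    oracle <- pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
    expect_equal(bhFdr(p), oracle)
})

test_that("NTC guides behave null in a neutral screen", {
    scr <- plantedScreen(smallConfig(n_genes = 250, n_ntc = 40,
                                     seed = 18))
    se <- filterLowCountGuides(scr$experiment)
    gs <- guideStats(se, "MEKi")
    expect_lt(abs(mean(gs$lfc[gs$is_ntc])), 0.05)
    expect_lt(abs(mean(gs$lfc)), 0.05)
})
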