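## Precision weights and empirical-Bayes moderated statistics for the
## treatment-vs-control guide abundance contrast, implemented from the
## mean-variance-trend / scaled-F moment-matching definitions.

#' Mean-variance trend precision weights
#'
#' Fits, per guide, the residual standard deviation around its condition
#' means, smooths sqrt(sd) against the guide's average log2-CPM with
#' lowess, and converts the trend into per-observation inverse-variance
#' weights: weight = predicted(sqrt-sd at the observation's fitted
#' log-CPM)^-4, clamped to [1e-6, 1e6]. Guides whose residual degrees of
#' freedom are zero get the trend value at their abundance.
#'
#' @param normed log2-CPM matrix (guides x samples), e.g. from [logCPM()].
#' @param design character/factor of condition labels, one per sample;
#'   every condition needs at least 2 samples.
#' @param span lowess smoother span (default 0.5).
#' @return Numeric weight matrix, same dimensions as \code{normed}.
#' @export
voomWeights <- function(normed, design, span = 0.5) {
    normed <- as.matrix(normed)
    design <- as.factor(design)
    if (nrow(normed) < 4)
        stop("need at least 4 guides to fit the mean-variance trend")
    if (any(table(design) < 2))
        stop("every condition needs at least 2 samples")
    fitted <- matrix(0, nrow(normed), ncol(normed),
                     dimnames = dimnames(normed))
    for (g in levels(design)) {
        j <- design == g
        fitted[, j] <- rowMeans(normed[, j, drop = FALSE])
    }
    dfres <- ncol(normed) - nlevels(design)
    sdres <- sqrt(rowSums((normed - fitted)^2) / dfres)
    amean <- rowMeans(normed)
    sqs <- sqrt(sdres)
    lw <- stats::lowess(amean, sqs, f = span)
    predSq <- function(x) {
        y <- stats::approx(lw$x, lw$y, xout = x, rule = 2,
                           ties = "ordered")$y
        pmax(y, 1e-3)
    }
    w <- predSq(fitted)^(-4)
    w <- matrix(pmin(pmax(w, 1e-6), 1e6), nrow(normed), ncol(normed),
                dimnames = dimnames(normed))
    w
}

#' Weighted least-squares condition contrast per guide
#'
#' For each guide, the log2 fold-change is the weighted difference of
#' condition means (treatment minus control) on the log2-CPM scale; s2 is
#' the weighted residual variance on n - 2 degrees of freedom; v is the
#' unscaled variance of the contrast (1/sum(w_treat) + 1/sum(w_ctrl)).
#'
#' @param normed log2-CPM matrix.
#' @param weights per-observation weight matrix (same shape), or NULL for
#'   unit weights.
#' @param design condition labels per sample.
#' @param treatment,control the two condition labels to contrast.
#' @return data.frame with guide_id, lfc, s2, df, v, mean_log_cpm.
#' @export
fitContrast <- function(normed, weights = NULL, design, treatment,
                        control) {
    normed <- as.matrix(normed)
    design <- as.character(design)
    for (cond in c(treatment, control))
        if (!cond %in% design)
            stop("condition absent from design: ", cond)
    sel <- design %in% c(treatment, control)
    y <- normed[, sel, drop = FALSE]
    d <- design[sel]
    w <- if (is.null(weights)) matrix(1, nrow(y), ncol(y))
         else as.matrix(weights)[, sel, drop = FALSE]
    jt <- d == treatment; jc <- d == control
    swt <- rowSums(w[, jt, drop = FALSE])
    swc <- rowSums(w[, jc, drop = FALSE])
    mt <- rowSums(w[, jt, drop = FALSE] * y[, jt, drop = FALSE]) / swt
    mc <- rowSums(w[, jc, drop = FALSE] * y[, jc, drop = FALSE]) / swc
    fittedv <- matrix(0, nrow(y), ncol(y))
    fittedv[, jt] <- mt
    fittedv[, jc] <- mc
    df <- ncol(y) - 2L
    s2 <- if (df > 0) rowSums(w * (y - fittedv)^2) / df
          else rep(NA_real_, nrow(y))
    data.frame(guide_id = rownames(normed), lfc = mt - mc, s2 = s2,
               df = df, v = 1 / swt + 1 / swc,
               mean_log_cpm = rowMeans(normed),
               stringsAsFactors = FALSE, row.names = NULL)
}

## Invert the trigamma function by Newton iteration on 1/trigamma
## (monotone and nearly linear), as used for scaled-F moment matching.
trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:75) {
        tri <- psigamma(x, 1)
        dif <- tri * (1 - tri / y) / psigamma(x, 2)
        x <- x + dif
        if (-dif / x < 1e-10) break
    }
    x
}

## Moment-match log s2 to a scaled F / scaled chi-square prior:
## returns d0 (prior df, possibly Inf) and s02 (prior variance).
estimateVarPrior <- function(s2, df) {
    ok <- is.finite(s2) & s2 > 0 & df > 0
    if (sum(ok) < 10)
        stop("need >= 10 guides with positive residual variance and df")
    z <- log(s2[ok])
    dfok <- rep_len(df, length(s2))[ok]
    e <- z - digamma(dfok / 2) + log(dfok / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1) -
        mean(trigamma(dfok / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s02 <- mean(s2[ok])
    }
    list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t statistics
#'
#' Shrinks each guide's residual variance toward a prior estimated by
#' moment-matching the scaled-F distribution of log s2 (digamma/trigamma
#' inversion): s2_post = (d0 * s0^2 + df * s2) / (d0 + df), t_mod =
#' lfc / sqrt(s2_post * v), two-sided p on d0 + df degrees of freedom
#' (normal limit when d0 is infinite). If the hyperparameter estimate
#' fails (near-constant s2), a bounded conventional prior d0 = 4,
#' s0^2 = median(s2) is used with a warning.
#'
#' @param fit data.frame from [fitContrast()] (columns lfc, s2, df, v).
#' @param d0,s02 optional forced hyperparameters (bypass estimation);
#'   d0 = 0 reproduces the ordinary t, d0 = Inf the z statistic against
#'   the prior variance.
#' @return \code{fit} with columns s2_post, t_mod, p, fdr, d0, s02
#'   appended.
#' @export
moderateT <- function(fit, d0 = NULL, s02 = NULL) {
    stopifnot(all(c("lfc", "s2", "df", "v") %in% colnames(fit)))
    if (all(!is.finite(fit$s2) | fit$s2 == 0))
        stop("all residual variances are zero; nothing to moderate")
    if (is.null(d0) || is.null(s02)) {
        hp <- tryCatch(estimateVarPrior(fit$s2, fit$df),
                       error = function(e) {
                           warning("variance prior estimation failed (",
                                   conditionMessage(e),
                                   "); falling back to d0 = 4, ",
                                   "s0^2 = median(s2)")
                           list(d0 = 4,
                                s02 = stats::median(fit$s2, na.rm = TRUE))
                       })
        if (is.null(d0)) d0 <- hp$d0
        if (is.null(s02)) s02 <- hp$s02
    }
    s2post <- if (is.infinite(d0)) rep_len(s02, nrow(fit))
              else (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
    tmod <- fit$lfc / sqrt(s2post * fit$v)
    dft <- d0 + fit$df
    p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(tmod))
         else 2 * stats::pt(-abs(tmod), df = dft)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    out <- fit
    out$s2_post <- s2post
    out$t_mod <- tmod
    out$p <- p
    out$fdr <- bhFdr(p)
    out$d0 <- d0
    out$s02 <- s02
    out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment (monotone, capped at
#' 1), applied across all guides within a contrast.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length.
#' @export
bhFdr <- function(p) stats::p.adjust(p, method = "BH")

#' Per-guide differential abundance for a screen contrast
#'
#' The full guide-level pipeline for one treatment-vs-control contrast at
#' one harvest day: TMM factors, log2-CPM, mean-variance precision
#' weights, weighted contrast fit, empirical-Bayes moderation and BH FDR.
#'
#' @param se a \linkS4class{ScreenExperiment} (already low-count
#'   filtered).
#' @param treatment treatment arm label.
#' @param control control arm label (default "vehicle").
#' @param day analysis day (default 21).
#' @param prior_count,span,logratio_trim,abs_trim tuning knobs passed to
#'   [logCPM()], [voomWeights()] and [tmmFactors()].
#' @return A [S4Vectors::DataFrame] with guide_id, gene, is_ntc, contrast,
#'   lfc, s2, df, t_mod, p, fdr, mean_log_cpm.
#' @export
guideStats <- function(se, treatment, control = "vehicle", day = 21,
                       prior_count = 0.5, span = 0.5,
                       logratio_trim = 0.30, abs_trim = 0.05) {
    stopifnot(is(se, "ScreenExperiment"))
    sel <- screenDays(se) == day & screenArms(se) %in% c(treatment, control)
    if (!any(screenArms(se)[sel] == treatment))
        stop("no samples for treatment arm '", treatment, "' at day ", day)
    if (!any(screenArms(se)[sel] == control))
        stop("no samples for control arm '", control, "' at day ", day)
    sub <- se[, sel]
    fac <- tmmFactors(sub, logratio_trim = logratio_trim,
                      abs_trim = abs_trim)
    lc <- logCPM(sub, factors = fac, prior_count = prior_count)
    design <- screenArms(sub)
    w <- voomWeights(lc, design, span = span)
    fit <- fitContrast(lc, w, design, treatment = treatment,
                       control = control)
    mod <- moderateT(fit)
    DataFrame(guide_id = mod$guide_id,
              gene = rowData(se)$gene[match(mod$guide_id, rownames(se))],
              is_ntc = rowData(se)$is_ntc[match(mod$guide_id,
                                                rownames(se))],
              contrast = sprintf("%s_vs_%s_d%g", treatment, control, day),
              lfc = mod$lfc, s2 = mod$s2, df = mod$df, t_mod = mod$t_mod,
              p = mod$p, fdr = mod$fdr, mean_log_cpm = mod$mean_log_cpm)
}
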