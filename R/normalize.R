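## TMM compositional normalization, implemented from the trimmed-mean-of-
## M-values definition (the standard published defaults: 30% M trim, 5% A
## trim, 75th-percentile reference rule).

## per-sample 75th percentile of the count fraction
f75 <- function(cts) {
    apply(cts, 2, function(x) stats::quantile(x, 0.75) / sum(x))
}

tmmPairFactor <- function(x, ref, logratio_trim, abs_trim) {
    x <- as.numeric(x); ref <- as.numeric(ref)  # avoid int overflow in Nx*x
    Nx <- sum(x); Nr <- sum(ref)
    keep <- x > 0 & ref > 0
    x <- x[keep]; r <- ref[keep]
    M <- log2((x / Nx) / (r / Nr))
    A <- 0.5 * log2((x / Nx) * (r / Nr))
    ## delta-method binomial variance of M; precision weight is 1/v
    v <- (Nx - x) / (Nx * x) + (Nr - r) / (Nr * r)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (!length(M) || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_trim) + 1;      hiS <- n + 1 - loS
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loL & rM <= hiL & rA >= loS & rA <= hiS
    if (!any(keep)) return(1)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' TMM normalization factors
#'
#' Computes one factor per sample as 2 to the weighted trimmed mean of
#' M-values against a reference sample (the sample whose 75th-percentile
#' count fraction is closest to the mean across samples), with guides
#' zero in either member of a pair excluded pairwise and precision
#' weights from the delta-method binomial variances. Factors are rescaled
#' to geometric mean 1. Multiplying a factor by the library size gives
#' the effective library size used by [logCPM()].
#'
#' @param se a \linkS4class{ScreenExperiment} or a count matrix.
#' @param logratio_trim fraction of extreme M-values trimmed on each side
#'   (default 0.30).
#' @param abs_trim fraction of extreme A-values trimmed on each side
#'   (default 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmmFactors <- function(se, logratio_trim = 0.30, abs_trim = 0.05) {
    cts <- if (is(se, "ScreenExperiment")) counts(se) else as.matrix(se)
    tot <- colSums(cts)
    if (any(tot <= 0))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(cts)[tot <= 0], collapse = ", "))
    q <- f75(cts)
    ref <- which.min(abs(q - mean(q)))
    f <- vapply(seq_len(ncol(cts)), function(j)
        tmmPairFactor(cts[, j], cts[, ref], logratio_trim, abs_trim),
        numeric(1))
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(cts)
    f
}

#' Log2 counts per million with a prior count
#'
#' \code{log2((count + prior) / (factor * total + 2 * prior) * 1e6)}:
#' normalized, moderated log abundance per guide and sample, monotone in
#' the count and invariant (up to prior-count effects) to sequencing
#' depth.
#'
#' @param se \linkS4class{ScreenExperiment} or count matrix.
#' @param factors per-sample normalization factors (default: [tmmFactors()]).
#' @param prior_count pseudo-count stabilizing low counts (default 0.5).
#' @return Numeric matrix of log2-CPM values, same dimensions as the
#'   counts.
#' @export
logCPM <- function(se, factors = tmmFactors(se), prior_count = 0.5) {
    cts <- if (is(se, "ScreenExperiment")) counts(se) else as.matrix(se)
    tot <- colSums(cts)
    eff <- factors[colnames(cts)]
    if (anyNA(eff)) eff <- rep_len(factors, ncol(cts))
    log2(t((t(cts) + prior_count) /
           (eff * tot + 2 * prior_count)) * 1e6)
}
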