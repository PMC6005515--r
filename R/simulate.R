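#' SimulationConfig: the stated world of a simulated pooled screen
#'
#' Defaults mirror the screen this package models: a druggable-genome
#' library of 2194 genes with 8 guides each plus 40 non-targeting controls,
#' three independent replicate infections at 1000x coverage, a vehicle arm
#' and two inhibitor arms (MEKi, ERKi), and harvests at 0/4/7/14/21 days
#' with day 0 as the shared reference.
#'
#' @slot n_genes number of targeted genes.
#' @slot guides_per_gene guides per targeted gene.
#' @slot n_ntc number of non-targeting control guides.
#' @slot n_replicates independent replicate infections.
#' @slot arms arm labels; the first is the vehicle/control arm.
#' @slot days harvest days, strictly increasing from 0.
#' @slot coverage expected reads per guide per sample.
#' @slot dispersion negative-binomial dispersion (variance = mu + disp*mu^2);
#'   0 gives Poisson counts.
#' @slot bottleneck_cells_per_guide expected cells per guide at infection;
#'   \code{Inf} disables the bottleneck.
#' @slot seed integer master seed; per replicate/arm/day draws come from
#'   named sub-streams so enumeration order never changes them.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
    n_genes = "numeric", guides_per_gene = "numeric", n_ntc = "numeric",
    n_replicates = "numeric", arms = "character", days = "numeric",
    coverage = "numeric", dispersion = "numeric",
    bottleneck_cells_per_guide = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    if (object@n_genes < 1 || object@guides_per_gene < 1)
        return("n_genes and guides_per_gene must be positive")
    if (object@n_ntc < 0) return("n_ntc must be non-negative")
    if (object@n_replicates < 1) return("n_replicates must be positive")
    if (length(object@arms) < 1 || anyDuplicated(object@arms))
        return("arms must be non-empty and unique")
    d <- object@days
    if (length(d) < 1 || d[1] != 0 || is.unsorted(d, strictly = TRUE))
        return("days must be strictly increasing and start at 0")
    if (object@coverage <= 0) return("coverage must be > 0")
    if (object@dispersion < 0) return("dispersion must be >= 0")
    if (object@bottleneck_cells_per_guide <= 0)
        return("bottleneck_cells_per_guide must be > 0")
    TRUE
})

#' Construct a SimulationConfig
#'
#' @param n_genes,guides_per_gene,n_ntc library composition.
#' @param n_replicates replicate infections.
#' @param arms arm labels (first = vehicle/control).
#' @param days harvest days (first must be 0).
#' @param coverage expected reads per guide per sample.
#' @param dispersion negative-binomial dispersion.
#' @param bottleneck_cells_per_guide infection bottleneck size per guide.
#' @param seed master seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(n_genes = 10, guides_per_gene = 4, n_ntc = 2)
#' @export
simConfig <- function(n_genes = 2194, guides_per_gene = 8, n_ntc = 40,
                      n_replicates = 3,
                      arms = c("vehicle", "MEKi", "ERKi"),
                      days = c(0, 4, 7, 14, 21),
                      coverage = 1000, dispersion = 0.05,
                      bottleneck_cells_per_guide = 1000, seed = 1L) {
    new("SimulationConfig", n_genes = n_genes,
        guides_per_gene = guides_per_gene, n_ntc = n_ntc,
        n_replicates = n_replicates, arms = arms, days = days,
        coverage = coverage, dispersion = dispersion,
        bottleneck_cells_per_guide = bottleneck_cells_per_guide,
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0(
        "SimulationConfig: %d genes x %d guides + %d NTC, %d replicates\n",
        "  arms: %s | days: %s | coverage %gx, dispersion %g, seed %d\n"),
        object@n_genes, object@guides_per_gene, object@n_ntc,
        object@n_replicates, paste(object@arms, collapse = "/"),
        paste(object@days, collapse = ","), object@coverage,
        object@dispersion, object@seed))
})

#' EffectTable: planted per-gene growth effects
#'
#' Growth is exponential in log2 units per day. Each gene carries a base
#' fitness \code{phi} (applied in every arm) and an interaction
#' \code{delta[gene, arm]} (extra log2/day in a drug arm; a sensitizer has
#' delta < 0). Each drug arm carries a global growth penalty \code{gamma}
#' applied to all cells. NTC guides and the control arm always have zero
#' effect.
#'
#' @param genes character vector of gene names.
#' @param phi named or positional numeric base fitness per gene (log2/day).
#' @param delta numeric matrix genes x drug arms (log2/day) or NULL for
#'   all-zero; rownames/colnames recommended.
#' @param gamma named numeric drug-arm growth penalty (log2/day) or NULL.
#' @param arms drug arm labels delta/gamma refer to.
#' @return An \code{EffectTable} (S4).
#' @examples
#' effectTable(c("KRAS", "MAPK7"), phi = c(0, 0),
#'             delta = matrix(c(-0.1, -0.2), 2, 1,
#'                            dimnames = list(NULL, "MEKi")),
#'             arms = "MEKi")
#' @exportClass EffectTable
#' @export effectTable
setClass("EffectTable", representation(
    genes = "character", phi = "numeric", delta = "matrix",
    gamma = "numeric"))

setValidity("EffectTable", function(object) {
    n <- length(object@genes)
    if (length(object@phi) != n) return("phi must have one value per gene")
    if (nrow(object@delta) != n) return("delta must have one row per gene")
    if (length(object@gamma) != ncol(object@delta))
        return("gamma must have one value per delta column (drug arm)")
    if (anyDuplicated(object@genes)) return("genes must be unique")
    TRUE
})

effectTable <- function(genes, phi = 0, delta = NULL, gamma = NULL,
                        arms = character()) {
    genes <- as.character(genes)
    phi <- rep_len(phi, length(genes))
    if (is.null(delta))
        delta <- matrix(0, length(genes), length(arms),
                        dimnames = list(genes, arms))
    if (is.null(colnames(delta)) && length(arms) == ncol(delta))
        colnames(delta) <- arms
    if (is.null(gamma)) gamma <- setNames(numeric(ncol(delta)),
                                          colnames(delta))
    if (is.null(names(gamma))) names(gamma) <- colnames(delta)
    names(phi) <- genes
    rownames(delta) <- genes
    new("EffectTable", genes = genes, phi = phi, delta = delta,
        gamma = gamma)
}

setMethod("show", "EffectTable", function(object) {
    cat(sprintf(
        "EffectTable: %d genes, drug arms: %s (%d with phi != 0, %d with any delta != 0)\n",
        length(object@genes), paste(colnames(object@delta), collapse = "/"),
        sum(object@phi != 0), sum(rowSums(object@delta != 0) > 0)))
})

## Deterministic named sub-streams off the master seed: a small polynomial
## hash of the labels, kept below 2^31 so set.seed() accepts it.  The hash,
## not enumeration order, decides each stream's draws.
subSeed <- function(seed, ...) {
    lab <- paste(c(...), collapse = "/")
    h <- as.double(seed) %% 2147483629
    for (k in utf8ToInt(lab)) h <- (h * 131 + k) %% 2147483629
    as.integer(h)
}

withStream <- function(seed, labels, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(subSeed(seed, labels))
    expr
}

#' Simulate a guide library
#'
#' Generates \code{n_genes * guides_per_gene} targeting guides named
#' \code{gene0001_g1, ...} plus \code{n_ntc} non-targeting controls, with
#' random distinct 19-nt spacer sequences.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GuideLibrary}.
#' @examples
#' lib <- simulateLibrary(simConfig(n_genes = 3, guides_per_gene = 4,
#'                                  n_ntc = 2))
#' nrow(lib)  # 14
#' @export
simulateLibrary <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    genes <- sprintf("gene%04d", seq_len(config@n_genes))
    gid <- as.vector(t(outer(genes, seq_len(config@guides_per_gene),
                             function(g, i) sprintf("%s_g%d", g, i))))
    gene <- rep(genes, each = config@guides_per_gene)
    if (config@n_ntc > 0) {
        gid <- c(gid, sprintf("NTC_g%d", seq_len(config@n_ntc)))
        gene <- c(gene, rep(NTC_GENE_LABEL, config@n_ntc))
    }
    seqs <- withStream(config@seed, c("library"), {
        repeat {
            s <- vapply(seq_along(gid), function(i)
                paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE),
                      collapse = ""), character(1))
            if (!anyDuplicated(s)) break
        }
        s
    })
    guideLibrary(gid, gene, sequence = seqs)
}

## expected relative abundance at day t for one replicate's p0
relAbundance <- function(p0, rate, t) {
    w <- p0 * 2^(rate * t)
    w / sum(w)
}

#' Simulate a pooled sensitizer screen
#'
#' Each replicate draws its day-0 guide distribution from a multinomial
#' infection bottleneck of \code{bottleneck_cells_per_guide * n_guides}
#' cells over a uniform library. Guide abundance then evolves
#' deterministically in expectation: relative abundance at day t is
#' proportional to \code{p0 * 2^((phi + delta_arm + gamma_arm) * t)}.
#' Sequencing counts are negative-binomial with mean
#' \code{coverage * n_guides * p(t)} and the configured dispersion
#' (Poisson when dispersion is 0). The day-0 sample is drawn once per
#' replicate and shared by all arms, mirroring a screen's D0 reference.
#'
#' @param library a \linkS4class{GuideLibrary}.
#' @param effects an \code{EffectTable}; genes absent from it get zero
#'   effect.
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ScreenExperiment} with samples named
#'   \code{rep\{r\}_\{arm\}_d\{day\}} (day 0 under the control arm label).
#' @export
simulateScreen <- function(library, effects, config) {
    stopifnot(is(library, "GuideLibrary"), is(effects, "EffectTable"),
              is(config, "SimulationConfig"))
    validObject(config)
    n <- nrow(library)
    arms <- config@arms
    ctrl <- arms[1]
    days <- config@days
    later <- days[days > 0]

    phi <- ifelse(isNTC(library), 0,
                  unname(effects@phi[targetGenes(library)]))
    phi[is.na(phi)] <- 0
    delta <- matrix(0, n, length(arms), dimnames = list(NULL, arms))
    gidx <- match(targetGenes(library), effects@genes)
    for (a in intersect(arms[-1], colnames(effects@delta))) {
        d <- effects@delta[, a][gidx]
        d[is.na(d) | isNTC(library)] <- 0
        delta[, a] <- d
    }
    gamma <- setNames(numeric(length(arms)), arms)
    g <- effects@gamma[intersect(names(effects@gamma), arms)]
    gamma[names(g)] <- g

    sampleNames <- character(0)
    meta <- list()
    cols <- list()
    depth <- config@coverage * n
    drawCounts <- function(mu, labels) withStream(config@seed, labels, {
        if (config@dispersion == 0) stats::rpois(n, mu)
        else stats::rnbinom(n, mu = mu, size = 1 / config@dispersion)
    })
    for (r in seq_len(config@n_replicates)) {
        p0 <- withStream(config@seed, c("bottleneck", r), {
            if (is.finite(config@bottleneck_cells_per_guide)) {
                cells <- as.vector(stats::rmultinom(
                    1, round(config@bottleneck_cells_per_guide * n),
                    rep(1 / n, n)))
                cells / sum(cells)
            } else rep(1 / n, n)
        })
        nm <- sprintf("rep%d_%s_d0", r, ctrl)
        sampleNames <- c(sampleNames, nm)
        meta[[nm]] <- data.frame(sample = nm, replicate = paste0("rep", r),
                                 arm = ctrl, day = 0)
        cols[[nm]] <- drawCounts(depth * p0, c("counts", r, ctrl, 0))
        for (a in arms) {
            rate <- phi + delta[, a] + gamma[a]
            for (t in later) {
                nm <- sprintf("rep%d_%s_d%g", r, a, t)
                sampleNames <- c(sampleNames, nm)
                meta[[nm]] <- data.frame(sample = nm,
                                         replicate = paste0("rep", r),
                                         arm = a, day = t)
                mu <- depth * relAbundance(p0, rate, t)
                cols[[nm]] <- drawCounts(mu, c("counts", r, a, t))
            }
        }
    }
    cts <- do.call(cbind, cols)
    dimnames(cts) <- list(guideIds(library), sampleNames)
    storage.mode(cts) <- "integer"
    ScreenExperiment(cts, do.call(rbind, meta), library)
}

#' Simulate an arrayed validation plate
#'
#' Generates well-level viability values for guides under vehicle and drug
#' across passages, with known true effects. NTC/vehicle wells have mean 1;
#' a guide's vehicle wells have mean \code{1/f_guide_true}; NTC/drug wells
#' \code{1/f_drug_true}; and each guide's drug wells are placed so the true
#' combination score (observed minus predicted fraction inhibition) equals
#' \code{bliss_gap} exactly. Multiplicative lognormal noise with the given
#' coefficient of variation is applied per well.
#'
#' @param f_guide_true named positive vector, true guide-alone fraction
#'   inhibition per guide.
#' @param f_drug_true positive scalar, true drug-alone fraction inhibition.
#' @param bliss_gap numeric, true combination score per guide (recycled).
#' @param noise_cv well-level coefficient of variation (>= 0).
#' @param n_passages number of serial passages (default 4).
#' @param wells_per_cell replicate wells per (guide, condition, passage).
#' @param seed integer seed.
#' @return data.frame with columns \code{well}, \code{guide_id},
#'   \code{condition} (\code{vehicle}/\code{drug}), \code{passage},
#'   \code{value}; NTC wells carry \code{guide_id == "NTC"}.
#' @export
simulatePlate <- function(f_guide_true, f_drug_true, bliss_gap = 0,
                          noise_cv = 0, n_passages = 4,
                          wells_per_cell = 1, seed = 1L) {
    stopifnot(all(f_guide_true > 0), f_drug_true > 0, noise_cv >= 0)
    guides <- names(f_guide_true)
    if (is.null(guides)) guides <- sprintf("guide%02d",
                                           seq_along(f_guide_true))
    bliss_gap <- rep_len(bliss_gap, length(f_guide_true))
    f_combo <- unname(f_guide_true) * f_drug_true + bliss_gap
    if (any(f_combo <= 0))
        stop("bliss_gap implies non-positive combined fraction inhibition")
    means <- rbind(
        data.frame(guide_id = NTC_GENE_LABEL, condition = "vehicle",
                   mean = 1),
        data.frame(guide_id = guides, condition = "vehicle",
                   mean = 1 / unname(f_guide_true)),
        data.frame(guide_id = NTC_GENE_LABEL, condition = "drug",
                   mean = 1 / f_drug_true),
        data.frame(guide_id = guides, condition = "drug",
                   mean = 1 / f_combo))
    grid <- merge(means,
                  expand.grid(passage = seq_len(n_passages),
                              wellrep = seq_len(wells_per_cell)))
    grid <- grid[order(grid$passage, grid$condition, grid$guide_id,
                       grid$wellrep), ]
    sdlog <- sqrt(log1p(noise_cv^2))
    vals <- withStream(as.integer(seed), "plate", {
        if (noise_cv == 0) grid$mean
        else grid$mean * stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2,
                                       sdlog = sdlog)
    })
    data.frame(well = sprintf("w%04d", seq_len(nrow(grid))),
               guide_id = grid$guide_id, condition = grid$condition,
               passage = grid$passage, value = vals,
               stringsAsFactors = FALSE)
}
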