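#' Run configuration for the end-to-end screen pipeline
#'
#' A validated list of paths and analysis settings. \code{counts},
#' \code{samplesheet} and \code{library} may be omitted when a
#' \linkS4class{SimulationConfig} is supplied, in which case the pipeline
#' simulates its own inputs.
#'
#' @param outdir output directory.
#' @param counts,samplesheet,library input file paths (or NULL to
#'   simulate).
#' @param day analysis day (default 21).
#' @param control control arm label (default "vehicle").
#' @param cutoffs hit cutoffs in log2 units (default c(1.0, 0.5)).
#' @param min_total low-count filter threshold (default 10).
#' @param seed integer seed for any simulation.
#' @param sim optional \linkS4class{SimulationConfig}.
#' @param effects optional \code{EffectTable} for simulation.
#' @return A validated list of class "screen_run_config".
#' @export
runConfig <- function(outdir, counts = NULL, samplesheet = NULL,
                      library = NULL, day = 21, control = "vehicle",
                      cutoffs = c(1.0, 0.5), min_total = 10, seed = 1L,
                      sim = NULL, effects = NULL) {
    stopifnot(length(day) == 1, all(cutoffs > 0), min_total >= 0)
    simulate <- is.null(counts)
    if (simulate && is.null(sim)) sim <- simConfig(seed = seed)
    structure(list(outdir = outdir, counts = counts,
                   samplesheet = samplesheet, library = library,
                   day = day, control = control, cutoffs = cutoffs,
                   min_total = min_total, seed = as.integer(seed),
                   sim = sim, effects = effects, simulate = simulate),
              class = "screen_run_config")
}

#' @rdname runConfig
#' @param path JSON file with scalar config fields (paths, day, control,
#'   cutoffs, min_total, seed).
#' @export
readRunConfig <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(runConfig, x[intersect(names(x),
        c("outdir", "counts", "samplesheet", "library", "day",
          "control", "cutoffs", "min_total", "seed"))])
}

writeTsv <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the full screen analysis pipeline
#'
#' Orchestrates simulate (optional) -> read -> low-count filter ->
#' normalize/test per drug arm -> gene-level aggregation -> hit calling
#' at each cutoff -> cross-arm overlap, writing one per-guide TSV per
#' arm, a combined per-gene TSV, an overlap TSV and a JSON run manifest
#' recording the seed, settings and guide counts at each stage.
#' Identical config and inputs produce byte-identical outputs.
#'
#' @param config from [runConfig()].
#' @return Invisibly, a list with the \code{ScreenExperiment}, per-arm
#'   guide stats, gene results, hits, overlap and the manifest.
#' @export
runScreenPipeline <- function(config) {
    stopifnot(inherits(config, "screen_run_config"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    if (config$simulate) {
        lib <- stage("simulate", simulateLibrary(config$sim))
        eff <- config$effects
        if (is.null(eff))
            eff <- effectTable(unique(targetGenes(lib)[!isNTC(lib)]),
                               arms = config$sim@arms[-1])
        se <- stage("simulate", simulateScreen(lib, eff, config$sim))
        writeGuideLibrary(lib, file.path(config$outdir, "library.tsv"))
        writeCounts(se, file.path(config$outdir, "counts.tsv"),
                    file.path(config$outdir, "samplesheet.csv"))
    } else {
        se <- stage("read", readCounts(config$counts,
                                       config$samplesheet,
                                       config$library))
        lib <- guideLibrary(rownames(se), rowData(se)$gene)
    }
    nIn <- nrow(se)
    sef <- stage("filter", filterLowCountGuides(se, config$min_total))
    nRemoved <- length(metadata(sef)$removed_guides)
    stopifnot(nIn == nRemoved + nrow(sef))  # stage conservation

    arms <- setdiff(unique(screenArms(sef)), config$control)
    day <- config$day
    gstats <- list(); generes <- list(); hits <- list()
    for (a in arms) {
        gs <- stage("test", guideStats(sef, treatment = a,
                                       control = config$control,
                                       day = day))
        gstats[[a]] <- gs
        writeTsv(gs, file.path(config$outdir,
                               sprintf("guide_stats_%s.tsv", a)))
        gr <- stage("aggregate", geneMedianLfc(gs, lib))
        generes[[a]] <- gr
        hits[[a]] <- lapply(stats::setNames(config$cutoffs,
                                            paste0("cutoff_",
                                                   config$cutoffs)),
                            function(ct) callHits(gr, ct))
    }
    geneTab <- Reduce(function(x, y) merge(x, y, by = "gene"),
                      lapply(arms, function(a) {
                          df <- as.data.frame(generes[[a]])
                          names(df)[names(df) == "median_lfc"] <-
                              paste0("median_lfc_", a)
                          names(df)[names(df) == "n_guides"] <-
                              paste0("n_guides_", a)
                          df[names(df) != "is_ntc"]
                      }))
    geneTab <- geneTab[order(geneTab$gene), , drop = FALSE]
    writeTsv(geneTab, file.path(config$outdir, "gene_results.tsv"))

    overlap <- NULL
    if (length(arms) >= 2) {
        primary <- paste0("cutoff_", config$cutoffs[1])
        overlap <- stage("overlap", armOverlap(
            lapply(hits, `[[`, primary)))
        ovTab <- do.call(rbind, lapply(names(overlap), function(dir) {
            o <- overlap[[dir]]
            rbind(
                if (length(o$shared))
                    data.frame(direction = dir, partition = "shared",
                               gene = o$shared) else NULL,
                do.call(rbind, lapply(names(o$exclusive), function(a)
                    if (length(o$exclusive[[a]]))
                        data.frame(direction = dir,
                                   partition = paste0(a, "_only"),
                                   gene = o$exclusive[[a]]) else NULL)))
        }))
        if (is.null(ovTab))
            ovTab <- data.frame(direction = character(),
                                partition = character(),
                                gene = character())
        writeTsv(ovTab, file.path(config$outdir, "arm_overlap.tsv"))
    }

    manifest <- list(
        seed = config$seed, day = day, control = config$control,
        cutoffs = config$cutoffs, min_total = config$min_total,
        arms = arms, guides_in = nIn, guides_filtered_out = nRemoved,
        guides_tested = nrow(sef),
        hit_counts = lapply(hits, function(h) lapply(h, function(x)
            c(enriched = length(x$enriched),
              depleted = length(x$depleted)))))
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(experiment = sef, guide_stats = gstats,
                   gene_results = generes, hits = hits,
                   overlap = overlap, manifest = manifest))
}
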