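#' Fraction inhibition
#'
#' The inhibition ratio f = control / treatment: f > 1 means the
#' treatment reduced growth or abundance, f = 1 no effect. A
#' non-positive treatment value is an error unless a floor \code{eps} is
#' supplied, in which case the value is clamped and the result flagged
#' censored (see [comboScore()]).
#'
#' @param control_value,treatment_value positive reals (vectorized).
#' @param eps optional positive floor replacing non-positive treatment
#'   values.
#' @return Numeric vector of inhibition fractions.
#' @examples
#' fractionInhibition(1000, 500)  # 2
#' @export
fractionInhibition <- function(control_value, treatment_value,
                               eps = NULL) {
    if (any(control_value <= 0))
        stop("control values must be positive")
    bad <- treatment_value <= 0
    if (any(bad)) {
        if (is.null(eps))
            stop("non-positive treatment value; supply eps to clamp")
        treatment_value[bad] <- eps
    }
    control_value / treatment_value
}

#' Bliss-style drug x gene combination score
#'
#' From the four condition means (no-guide/vehicle, guide/vehicle,
#' no-guide/drug, guide/drug) computes the single-effect inhibition
#' fractions, the multiplicative (Bliss-independent) prediction
#' f_combo_predicted = f_guide * f_drug, the observed combined
#' inhibition, and their gap delta = f_combo_observed -
#' f_combo_predicted. delta > 0 means stronger-than-multiplicative
#' killing (a sensitizer), delta < 0 a rescue. The score is invariant to
#' rescaling all four values by a common positive constant.
#'
#' @param ntc_vehicle,guide_vehicle,ntc_drug,guide_drug positive
#'   condition means (vectorized over guides).
#' @param eps optional floor for non-positive values; clamped scores are
#'   flagged \code{censored}.
#' @param id optional unit identifier column.
#' @param passage optional passage index column.
#' @return data.frame with id, passage, f_guide, f_drug,
#'   f_combo_observed, f_combo_predicted, delta, censored.
#' @examples
#' comboScore(1000, 500, 400, 100)  # delta = +5
#' @export
comboScore <- function(ntc_vehicle, guide_vehicle, ntc_drug, guide_drug,
                       eps = NULL, id = NA_character_,
                       passage = NA_integer_) {
    vals <- cbind(ntc_vehicle, guide_vehicle, ntc_drug, guide_drug)
    censored <- apply(vals <= 0, 1, any)
    if (any(censored) && is.null(eps))
        stop("non-positive condition value; supply eps to clamp")
    f_guide <- fractionInhibition(ntc_vehicle, guide_vehicle, eps)
    f_drug <- fractionInhibition(ntc_vehicle, ntc_drug, eps)
    f_obs <- fractionInhibition(ntc_vehicle, guide_drug, eps)
    f_pred <- f_guide * f_drug
    data.frame(id = id, passage = passage, f_guide = f_guide,
               f_drug = f_drug, f_combo_observed = f_obs,
               f_combo_predicted = f_pred, delta = f_obs - f_pred,
               censored = censored, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Score an arrayed validation assay
#'
#' Averages replicate wells per (guide, condition, passage) cell, scores
#' each guide against the NTC wells of its passage with [comboScore()],
#' and summarizes genes as the arithmetic mean of their guides' deltas
#' per passage. Passages lacking an NTC cell in either condition are
#' skipped with a warning. Non-positive well means are floored at half
#' the smallest positive value on the plate (scores flagged censored).
#'
#' @param plate data.frame from [simulatePlate()] or a plate CSV:
#'   columns guide_id, condition (vehicle/drug), passage, value; NTC
#'   wells carry guide_id "NTC".
#' @param geneMap named character vector guide_id -> gene, or a
#'   \linkS4class{GuideLibrary}; guides absent from it keep their own id
#'   as gene.
#' @return list with \code{guide_scores} (data.frame, one row per guide
#'   x passage) and \code{gene_scores} (gene x passage matrix of mean
#'   deltas, heat-map ready).
#' @export
scoreArrayedAssay <- function(plate, geneMap = NULL) {
    stopifnot(all(c("guide_id", "condition", "passage", "value") %in%
                  colnames(plate)))
    if (is(geneMap, "GuideLibrary"))
        geneMap <- stats::setNames(targetGenes(geneMap), guideIds(geneMap))
    pos <- plate$value[plate$value > 0]
    eps <- if (length(pos)) min(pos) / 2 else 1e-6
    cellMeans <- stats::aggregate(value ~ guide_id + condition + passage,
                                  data = plate, FUN = mean)
    guides <- setdiff(unique(cellMeans$guide_id), NTC_GENE_LABEL)
    rows <- list()
    for (p in sort(unique(cellMeans$passage))) {
        cm <- cellMeans[cellMeans$passage == p, ]
        pick <- function(g, cond) {
            v <- cm$value[cm$guide_id == g & cm$condition == cond]
            if (length(v)) v[1] else NA_real_
        }
        nv <- pick(NTC_GENE_LABEL, "vehicle")
        nd <- pick(NTC_GENE_LABEL, "drug")
        if (is.na(nv) || is.na(nd)) {
            warning("passage ", p, " lacks NTC wells in both conditions; ",
                    "skipped")
            next
        }
        gv <- vapply(guides, pick, numeric(1), cond = "vehicle")
        gd <- vapply(guides, pick, numeric(1), cond = "drug")
        ok <- !is.na(gv) & !is.na(gd)
        if (!any(ok)) next
        rows[[length(rows) + 1L]] <-
            comboScore(rep(nv, sum(ok)), gv[ok], rep(nd, sum(ok)),
                       gd[ok], eps = eps, id = guides[ok], passage = p)
    }
    guide_scores <- do.call(rbind, rows)
    gene <- if (is.null(geneMap)) guide_scores$id
            else ifelse(is.na(geneMap[guide_scores$id]),
                        guide_scores$id, geneMap[guide_scores$id])
    agg <- stats::aggregate(guide_scores$delta,
                            by = list(gene = gene,
                                      passage = guide_scores$passage),
                            FUN = mean)
    genes <- sort(unique(agg$gene))
    passages <- sort(unique(agg$passage))
    gm <- matrix(NA_real_, length(genes), length(passages),
                 dimnames = list(genes, paste0("passage", passages)))
    gm[cbind(match(agg$gene, genes), match(agg$passage, passages))] <-
        agg$x
    list(guide_scores = guide_scores, gene_scores = gm)
}

#' Combination score from pooled screen counts
#'
#' Applies the inhibition-ratio algebra to normalized (CPM) pooled-screen
#' abundances, using the aggregate non-targeting-control abundance as the
#' no-guide reference. Writing R(g, arm, day) for a guide's CPM divided
#' by the NTC aggregate CPM in the same sample (replicate-averaged):
#' f_guide = R(g, vehicle, 0) / R(g, vehicle, day); f_drug =
#' NTC CPM(vehicle, day) / NTC CPM(drug arm, day); f_combo_observed =
#' f_drug * R(g, vehicle, 0) / R(g, drug arm, day). The drug's absolute
#' growth penalty is invisible in compositional counts, so f_drug is the
#' NTC ratio proxy; with this convention the NTC pseudo-guide (unit id
#' "NTC") has delta identically 0. A guide with zero raw counts in any
#' needed cell is flagged censored.
#'
#' @param se a \linkS4class{ScreenExperiment}.
#' @param guides guide ids to score, or "NTC" for the pseudo-guide;
#'   default all targeting guides.
#' @param arm drug arm label.
#' @param day harvest day (default 21).
#' @param control control arm label (default "vehicle").
#' @param prior_count pseudo-count for the CPM transform.
#' @return data.frame as [comboScore()], one row per guide, plus arm and
#'   day columns.
#' @export
pooledComboScore <- function(se, guides = NULL, arm, day = 21,
                             control = "vehicle", prior_count = 0.5) {
    stopifnot(is(se, "ScreenExperiment"))
    fac <- tmmFactors(se)
    cpm <- 2^logCPM(se, factors = fac, prior_count = prior_count)
    ntc <- rowData(se)$is_ntc
    if (!any(ntc)) stop("no NTC guides in the experiment")
    cellMean <- function(a, d) {
        j <- screenArms(se) == a & screenDays(se) == d
        if (!any(j)) stop("no samples for arm '", a, "' at day ", d)
        rowMeans(cpm[, j, drop = FALSE])
    }
    m0 <- cellMean(control, 0)
    mv <- cellMean(control, day)
    md <- cellMean(arm, day)
    rawZero <- function(a, d) {
        j <- screenArms(se) == a & screenDays(se) == d
        rowSums(counts(se)[, j, drop = FALSE]) == 0
    }
    zero <- rawZero(control, 0) | rawZero(control, day) | rawZero(arm, day)
    n0 <- sum(m0[ntc]); nv <- sum(mv[ntc]); nd <- sum(md[ntc])
    if (is.null(guides)) guides <- rownames(se)[!ntc]
    ntcPseudo <- guides == NTC_GENE_LABEL
    R0 <- Rv <- Rd <- numeric(length(guides))
    R0[ntcPseudo] <- Rv[ntcPseudo] <- Rd[ntcPseudo] <- 1
    gi <- match(guides[!ntcPseudo], rownames(se))
    if (anyNA(gi))
        stop("guide(s) not in experiment: ",
             paste(utils::head(guides[!ntcPseudo][is.na(gi)], 3),
                   collapse = ", "))
    R0[!ntcPseudo] <- m0[gi] / n0
    Rv[!ntcPseudo] <- mv[gi] / nv
    Rd[!ntcPseudo] <- md[gi] / nd
    f_drug <- nv / nd
    f_guide <- R0 / Rv
    f_obs <- f_drug * R0 / Rd
    censored <- logical(length(guides))
    censored[!ntcPseudo] <- zero[gi]
    data.frame(id = guides, arm = arm, day = day,
               f_guide = f_guide, f_drug = f_drug,
               f_combo_observed = f_obs,
               f_combo_predicted = f_guide * f_drug,
               delta = f_obs - f_guide * f_drug,
               censored = censored,
               stringsAsFactors = FALSE, row.names = NULL)
}
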