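# poolscreen

Analysis of pooled CRISPR knockout **drug-sensitizer screens** in R.

In a sensitizer screen, a cell population carrying a genome-scale (or
druggable-genome) guide RNA library is split into a vehicle arm and one or
more drug arms. Guides whose target knockout cooperates with the drug
deplete specifically in the drug arm; guides conferring resistance enrich.
`poolscreen` takes the guide-level count tables such a screen produces and
carries them through to gene-level hit calls and drug x gene interaction
scores. It is written for functional-genomics analysts running or
validating MAPK-pathway-style sensitizer screens, and for method testing:
a built-in simulator generates screens with known planted effects so every
stage can be checked by parameter recovery.

## What it computes

- **Import and filtering** — TSV count tables with a sample sheet
  (replicate, arm, day), optional exact-match guide counting from
  amplicon FASTQ, and the standard low-count filter (a guide with fewer
  than 10 reads summed over all samples is discarded).
- **Differential guide abundance** — TMM normalization factors, log2
  counts-per-million, mean-variance-trend precision weights, a weighted
  treatment-vs-control contrast at the analysis day (default day 21),
  and empirical-Bayes moderated t statistics with BH FDR. The moderated
  variance is `s2_post = (d0*s0^2 + df*s2) / (d0 + df)` with `(d0, s0^2)`
  estimated by moment-matching the scaled-F distribution of `log s2`;
  `t_mod = lfc / sqrt(s2_post * v)`. All of this is implemented in the
  package (the installed edgeR/limma serve only as cross-check oracles in
  the test suite).
- **Gene-level hit calling** — per-gene median LFC over surviving guides,
  enriched/depleted calls at strict log2 cutoffs (default 1.0 and 0.5),
  cross-arm Venn overlap, and screen-to-screen concordance as squared
  Pearson correlation.
- **Combination scoring** — the Bliss-style interaction gap. With
  fraction inhibition `f = value_control / value_treatment`:
  `f_combo_predicted = f_guide * f_drug` and
  `delta = f_combo_observed - f_combo_predicted`; `delta > 0` means
  stronger-than-multiplicative killing (a sensitizer). Implemented for
  arrayed viability plates and, via NTC-normalized CPM, for pooled
  counts.
- **Simulators** — a negative-binomial pooled-screen generator
  (exponential log2-per-day growth, multinomial infection bottleneck,
  shared day-0 reference, per-gene fitness and per-arm interaction
  effects) and an arrayed-plate generator with a planted combination
  gap. Both are seed-deterministic via named sub-streams.

## Worked example

Simulate a 200-gene screen with five planted sensitizers
(`delta = -0.1` log2/day in the MEKi arm), filter, test day 21 MEKi vs
vehicle, and call hits:

```r
library(poolscreen)
cfg <- simConfig(n_genes = 200, guides_per_gene = 8, n_ntc = 40,
                 arms = c("vehicle", "MEKi"), days = c(0, 21), seed = 7)
lib <- simulateLibrary(cfg)
eff <- effectTable(unique(targetGenes(lib)[!isNTC(lib)]), arms = "MEKi")
eff@delta[1:5, "MEKi"] <- -0.1
se  <- filterLowCountGuides(simulateScreen(lib, eff, cfg))
gs  <- guideStats(se, treatment = "MEKi")
res <- geneMedianLfc(gs, lib)
head(as.data.frame(res[order(res$median_lfc), ]), 6)
#>       gene n_guides median_lfc is_ntc
#> 1 gene0004        8  -2.158296  FALSE
#> 2 gene0001        8  -2.142148  FALSE
#> 3 gene0003        8  -2.121636  FALSE
#> 4 gene0002        8  -2.002895  FALSE
#> 5 gene0005        8  -1.975292  FALSE
#> 6 gene0078        8  -0.281398  FALSE
callHits(res, cutoff = 1.0)$depleted
#> [1] "gene0001" "gene0002" "gene0003" "gene0004" "gene0005"
```

The five planted genes sit at median LFC near the expected
`-0.1 * 21 = -2.1`, cleanly separated from the null genes (next at
-0.28), and are exactly the depleted set at the 2-fold cutoff.

Combination scoring from four condition means (no-guide/vehicle,
guide/vehicle, no-guide/drug, guide/drug):

```r
comboScore(1000, 500, 400, 100)
#>   f_guide f_drug f_combo_observed f_combo_predicted delta
#> 1       2    2.5               10                 5     5
```

The guide alone inhibits 2-fold, the drug alone 2.5-fold; multiplicative
independence predicts 5-fold, 10-fold is observed, so the interaction
gap is +5 (cooperative killing).

The end-to-end driver is `runScreenPipeline(runConfig(...))`, which
writes per-guide and per-gene TSVs, an arm-overlap TSV and a JSON run
manifest, byte-identically for a fixed seed.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on a
simulated druggable-genome-scale screen (2194 genes x 8 guides + 40
non-targeting controls, three arms, planted sensitizer and resistance
genes), reports progress to stderr and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/poolscreen-methods.Rmd` documents the statistical model, the
simulator's assumptions, parameter defaults, numerical choices and known
limitations.
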