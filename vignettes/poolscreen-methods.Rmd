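---
title: "poolscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poolscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

# Scope

`poolscreen` analyses pooled CRISPR knockout drug-sensitizer screens:
guide count tables from a multi-arm, multi-day screen are carried through
normalization, moderated differential guide abundance, gene-level median
log-fold-change (LFC) hit calling, cross-arm overlap, and a Bliss-style
drug x gene combination score. A simulator with known planted effects
provides the verification surface. This vignette records the statistical
model, the defaults and why they were chosen, the numerical decisions,
and what the simulation-based tests do and do not establish.

# The differential-abundance model

## Normalization

Library depth and composition are normalized by trimmed-mean-of-M-values
(TMM) factors, computed from the definition: for sample $k$ against a
reference sample $r$ (the sample whose 75th-percentile count fraction is
closest to the mean of those), guide-wise log-ratios
$M_g = \log_2\frac{x_{gk}/N_k}{x_{gr}/N_r}$ and average abundances
$A_g$ are formed over guides non-zero in both samples; the most extreme
30% of $M$ and 5% of $A$ are trimmed on each side; and the factor is
$2$ to the precision-weighted mean of the surviving $M_g$, with weights
the inverse delta-method binomial variances. Factors are rescaled to
geometric mean 1. These trim fractions and the reference rule are the
standard published defaults; the test suite checks agreement with the
independent edgeR implementation to 1e-8 on overdispersed data.

Counts become moderated log2 counts-per-million,
$\log_2\!\big(\frac{x + p}{fN + 2p}\cdot 10^6\big)$ with prior count
$p = 0.5$ (units: pseudo-reads). The prior bounds the transform at zero
counts; its effect is below 0.01 log2 at counts over 100, which is why
depth-invariance tests use that tolerance.

## Precision weights

Count data are heteroskedastic on the log scale (variance falls with the
mean). Following the mean-variance-trend approach, each guide's residual
standard deviation about its condition means is computed, $\sqrt{sd}$ is
smoothed against the guide's average log2-CPM with `lowess`
(span 0.5), and each observation receives weight
$\widehat{\sqrt{sd}}^{-4}$ evaluated at its fitted value, clamped to
$[10^{-6}, 10^6]$. The span is a smoothness/locality compromise; at
fewer than 4 guides the trend is unfittable and the function refuses.
The trend prediction is linearly interpolated between lowess knots and
held constant beyond the observed abundance range, and is floored at
$10^{-3}$ so weights cannot blow up at the high-abundance end.

## The contrast and moderation

The paper-style analysis contrasts the treatment arm against the vehicle
arm **at the same day** (default 21); day 0 is retained as the shared
reference for representation QC and for the pooled combination score,
not the test. Per guide, a weighted least-squares difference of
condition means gives the LFC; the weighted residual variance $s^2$ has
$n - 2$ degrees of freedom. Replicates are independent infections and
are treated as independent observations; with only two conditions per
fit no blocking term is used.

Variances are then shrunk by empirical Bayes: assuming
$s^2 \mid \sigma^2 \sim \sigma^2 \chi^2_{df}/df$ with a scaled inverse
chi-square prior ($d_0$, $s_0^2$), the posterior variance is
$s^2_{post} = (d_0 s_0^2 + df\, s^2)/(d_0 + df)$ and
$t_{mod} = \mathrm{lfc}/\sqrt{s^2_{post}\, v}$ is referred to a t
distribution on $d_0 + df$ degrees of freedom. $(d_0, s_0^2)$ are
estimated by moment-matching the log-variances (digamma/trigamma
inversion, with Newton iteration for the trigamma inverse). Two
numerical branches matter:

- if the method-of-moments trigamma estimate is non-positive (variances
  essentially constant), $d_0 = \infty$ and $s_0^2$ is the arithmetic
  mean of the $s^2$, and p-values use the normal limit;
- if estimation fails outright (fewer than 10 usable guides), a bounded
  conventional prior $d_0 = 4$, $s_0^2 = \mathrm{median}(s^2)$ is used
  with a warning.

The forced limits $d_0 = 0$ (ordinary t) and $d_0 = \infty$ (z against
the prior variance) are exposed for testing. P-values are two-sided; BH
FDR is computed across all guides within a contrast, not per gene.

# Hit calling

Gene summaries are the **median** of the gene's surviving guide LFCs —
one fitted LFC per guide from the contrast, not per-replicate medians —
with the even-count median defined as the midpoint of the two central
values. The guide LFCs entering the median are the moderated-pipeline
(voom-style) LFCs; raw count-ratio LFCs can be formed from the CPM
matrix if wanted, but the fitted LFC is what the statistics describe.
Hits use strict inequalities: enriched if median LFC $> c$, depleted if
$< -c$, so a gene exactly at the cutoff is not a hit ("more than
2-fold" reads as strict). Defaults $c = 1.0$ (2-fold) and $c = 0.5$ are
both reported by the pipeline. Non-targeting controls are aggregated as
one "NTC" pseudo-gene for QC and excluded from hit sets. Cross-arm
structure is summarized as a Venn partition (shared vs arm-exclusive
genes per direction), and screen-to-screen concordance as the squared
Pearson correlation of shared-guide LFCs.

# Combination scoring

Fraction inhibition is the plain ratio $f = \text{control}/\text{treatment}$
($f > 1$ = inhibition), kept exactly in that orientation rather than
converted to $1 - \text{viability}$. Under Bliss-style multiplicative
independence the combined effect should satisfy
$f_{combo} = f_{guide} \cdot f_{drug}$; the interaction score is
$\delta = f^{obs}_{combo} - f_{guide} f_{drug}$, which is exactly zero
for multiplicative quadruples (an algebraic identity, exact to floating
point) and invariant to rescaling all wells by a common constant.

Decisions where the procedure was genuinely open:

- **Replicate wells are averaged before ratios** (ratios of means, not
  means of ratios): near-zero wells otherwise dominate. The residual
  Jensen bias of a ratio of noisy means is second order (about
  $cv^2/n_{wells}$ relative) and is covered by the Monte-Carlo
  tolerance in the tests.
- **Non-positive well values** are floored at half the smallest
  positive value on the plate (configurable), and the affected scores
  flagged `censored` rather than silently dropped.
- **Gene summaries** are the arithmetic mean of the gene's guide deltas
  per passage.
- **siRNA plates** are scored with identical formulas.

For **pooled counts** the same algebra is applied to CPM with the
aggregate NTC abundance as the no-guide reference. Compositional counts
cannot see the drug's absolute growth penalty (everything is relative
within a sample), so the drug-alone term uses the NTC CPM ratio
vehicle/drug as a proxy and the observed combination term is scaled by
the same factor. With this convention the NTC pseudo-guide's delta is
identically zero, neutral guides are centred at zero, and a planted
sensitizer's delta is positive — the three behaviours the score must
have — while the absolute magnitude of $f_{drug}$ is *not* estimable
from pooled data and should not be interpreted.

# The simulator's stated world

Defaults mirror a druggable-genome sensitizer screen: 2194 genes x 8
guides + 40 non-targeting controls, 3 independent infections, arms
vehicle/MEKi/ERKi, harvests at 0/4/7/14/21 days, 1000x coverage.
Growth is exponential in log2 units **per day** (the screen's natural
clock; passaging every ~3 days is absorbed into the rate). Guide
abundance per replicate starts from a multinomial infection bottleneck
(default 1000 cells per guide — the maintained representation), evolves
deterministically in expectation as
$p_g(t) \propto p_g(0)\, 2^{(\varphi_g + \delta_{g,a} + \gamma_a) t}$,
and is read out with negative-binomial noise (single global dispersion
0.05, the conventional screen-count overdispersion; 0 gives Poisson).
The day-0 sample is drawn once per replicate and shared by the arms, as
a screen's D0 reference is. Sequencing depth per sample defaults to
coverage x library size, an assumption, since harvest-depth is rarely
reported. Randomness is split into named streams keyed on
(purpose, replicate, arm, day) hashed together with the master seed, so
enumeration order cannot change draws and runs are byte-reproducible.

The arrayed-plate generator places well means so that the *true*
combination score equals the requested gap exactly, then applies
mean-preserving lognormal noise with the requested CV. Its test world
uses quadruplicate wells and modest (1.5-fold) single-agent effects —
the regime of a typical 96-well validation plate — so that the ratio
estimator's Jensen bias stays well inside Monte-Carlo error.

What the simulator does **not** model: Cas9 cutting-efficiency
heterogeneity, multi-infection at high MOI, guide-specific off-targets,
PCR jackpotting beyond the NB dispersion, and cell-line context effects.
A green parameter-recovery test therefore establishes that the pipeline
recovers effects *under this generative model*, not that a real screen
is free of those artifacts.

# Interfaces and conventions

Counts are TSV (guide ids first column, samples named
`rep{r}_{arm}_d{day}`), sample sheets CSV, libraries TSV. Run
configuration files are JSON (`readRunConfig`); JSON was chosen over
YAML because the installed R stack provides a JSON parser and no YAML
one, and the config is flat scalars either way. The pipeline driver is
an R function (`runScreenPipeline`) rather than a shell entry point:
the package's users drive analyses from R, and every stage is an
exported, composable function. The low-count filter (total across
**all** samples < 10, strict) is applied once, before normalization;
per-screen rather than per-arm filtering is the literal reading of the
usual methods wording and keeps the tested guide set identical across
arms. FASTQ guide counting is exact-match, forward strand, within a
configurable offset window — amplicon reads have fixed structure, and
mismatch-tolerant alignment is out of scope.

# Known limitations

- Only the two-condition contrast is implemented; no trajectory
  modeling over the intermediate days and no general design-matrix
  interface.
- No RRA-style or permutation gene p-values: gene calls are median-LFC
  cutoffs by design.
- The pooled combination score's drug term is a compositional proxy
  (see above).
- Hyperparameter estimation needs ~10+ guides; tiny screens fall back
  to the fixed prior.
- Printed hit counts from any specific published screen depend on
  unreleased raw data and are not reproduction targets for this
  package's tests.
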