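---
title: "Scoring two-drug synergy: CDI screens, median-effect CI/DRI, and xenograft trials"
author: "SynergyScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring two-drug synergy: CDI screens, median-effect CI/DRI, and xenograft trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynergyScreen)
```

## The problem

Basal-like (largely triple-negative) breast cancers usually carry an
overactive PI3K pathway — through activating *PIK3CA* mutations, *PIK3CA*
amplification, or *PTEN* loss — yet PI3K inhibitors such as alpelisib
(BYL-719) fail as single agents at tolerable doses. The practical question
is which second drug turns a PI3K inhibitor into a durable combination.
Answering it takes a chain of quantitative steps: normalize plate-reader
viabilities against vehicle controls; screen a drug library with and without
the anchor compound and score each pairing; confirm candidate pairs with a
rigorous fixed-ratio dose-response analysis; and finally test whether the
synergy survives in tumor-bearing animals. SynergyScreen implements that
chain, together with the expression arm used to characterize the models
(gene-signature scoring, clustering, single-cell QC, signature-restricted
PCA) and a simulation layer that generates every input type with known
ground truth.

## Viability normalization

Raw luminescence signals (one well per row) are normalized per model:
replicate signals of each (compound, dose) condition are averaged and
divided by the mean vehicle signal,

$$\mathrm{viability\ (\%)} = 100 \times
  \frac{\overline{S}_{\text{condition}}}{\overline{S}_{\text{vehicle}}}.$$

If blank wells are present their mean is subtracted from every signal first;
signals that fall below zero after blank subtraction are clipped to zero
with a warning, since they can only be instrument noise. Whether blanks and
outlier wells were used in any given assay is a lab-protocol detail, so both
behaviours are driven entirely by the data: blanks are used when present and
skipped otherwise. Viability is a *percent* (0–100, values above 100
allowed) at every I/O boundary and a *fraction* (0–1) inside all synergy
arithmetic; `percentToFraction()` / `fractionToPercent()` are the single
conversion point.

## The coefficient of drug interaction (CDI)

For a one-dose combination with single-agent viability fractions $v_A$,
$v_B$ and combination viability $v_{AB}$,

$$\mathrm{CDI} = \frac{v_{AB}}{v_A\, v_B}.$$

Under Bliss independence (the two drugs acting through unrelated mechanisms)
$v_{AB} = v_A v_B$ and CDI $= 1$; CDI below 1 is synergy. Classification
follows the screening convention:

| CDI | label |
|---|---|
| $< 0.7$ | significantly synergistic |
| $0.7 \le \mathrm{CDI} < 1 - \tau$ | synergistic |
| $|\mathrm{CDI} - 1| \le \tau$ | additive |
| $> 1 + \tau$ | antagonistic |

The additive band half-width $\tau$ (default 0.05) exists because an exact
CDI of 1 has measure zero in real data; a heat map that paints cells
"additive" is implicitly using a band. The 0.7 cutoff for significant
synergism is the screening hit threshold. Two numerical details matter:

* the bands are assigned by a sequential partition so that floating-point
  arithmetic cannot open gaps at the band edges;
* when $v_A v_B$ falls below a small floor (default $10^{-4}$) the ratio is
  meaningless and the CDI is returned as `NA` rather than a number.

`anchorScreen()` applies this per compound for a library screened alone and
with a fixed anchor. Compounds whose *single-agent* viability is already
below 0.1 (configurable) are flagged `single_agent_effective` and excluded
from synergy calls — a drug that kills on its own (YM-155 and digoxin are
the classic examples in anchor screens) leaves no dynamic range in which
synergy could be demonstrated, and calling it "not synergistic" would be
misleading. Hits are intersected across models with
`synergyIntersection()`, which also returns exclusive Venn-region counts.
Replicate screens are scored on replicate means; a per-replicate CDI with a
one-sample test against 1 is possible in principle but the primary labels
use the threshold, since a screening hit call should not depend on the
replicate structure of a particular plate layout.

## Median-effect analysis, CI and DRI

The confirmation step uses the mass-action median-effect model. For a drug
with dose $D$, fraction affected $f_a$ (one minus viability fraction) and
unaffected fraction $f_u = 1 - f_a$,

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m,$$

with $D_m$ the median-effect dose and $m$ the sigmoidicity. The fit is
unweighted least squares on the linearized form
$\log_{10}(f_a/f_u) = m\,\log_{10} D - m \log_{10} D_m$ — the convention of
the classical CompuSyn software, kept deliberately (no robust regression)
so results are comparable with the large CompuSyn literature. Before
linearization $f_a$ is clipped into $[0.005, 0.995]$; values outside
$(0, 1)$ — viability above vehicle — are clipped with a warning rather than
dropped, so the design stays balanced. A non-positive fitted slope marks
the fit as *flagged* rather than failing silently: downstream evaluation of
a flagged fit is an error.

A fixed-ratio mixture is treated as a single drug dosed by *total*
concentration, fitted the same way. At any fraction affected, the
combination index and dose-reduction indices are

$$\mathrm{CI}(f_a) = \frac{d_A}{D_{x,A}(f_a)} + \frac{d_B}{D_{x,B}(f_a)},
\qquad
\mathrm{DRI}_i(f_a) = \frac{D_{x,i}(f_a)}{d_i},$$

where $D_{x,i}(f_a) = D_{m,i}\,(f_a/f_u)^{1/m_i}$ is the single-agent dose
producing $f_a$ and $(d_A, d_B)$ is the ratio split of the mixture dose
producing the same $f_a$. The two-term (mutually exclusive) CI is the
default; `exclusive = FALSE` adds the non-exclusive third term
$d_A d_B / (D_{x,A} D_{x,B})$. `ciDriProfile()` evaluates both on a default
grid of 99 points ($f_a = 0.01 \dots 0.99$) and marks the range of interest
$f_a \ge 0.75$: combinations are called when CI drops below one — or DRI
rises above one — at high effect, because clinical dosing aims at high
fractional kill.

### A structural limitation worth knowing

Loewe additivity and the median-effect mixture model coincide *exactly*
only when the two drugs share the slope $m$; then the additive mixture is
itself a median-effect curve and CI $\equiv 1$ (the package reproduces this
to $\sim 10^{-10}$). When the slopes differ, the additive surface is not a
median-effect curve, the mixture fit is an approximation ($r$ slightly
below 1), and CI computed through that fit deviates from 1 even for a truly
additive combination — in simulations with $m \in [0.8, 2.5]$ the deviation
reaches $\approx 0.2$ at the grid extremes. This is a property of the
method itself, inherited from its standard software implementations, not of
this package. Consequences: the package's additive-calibration checks use
matched-slope drug pairs, and single CI values close to 1 from drugs with
very different slopes should be read cautiously (the "at least one ratio
with CI clearly below one at high $f_a$" reading is robust; CI $= 0.95$ vs
$1.05$ is not).

## In-vivo synergy

Tumor size is length $\times$ width in mm² (the conventional caliper
product; protocols sometimes print it as "volume", but it is dimensionally
an area and is treated as such here). For a four-arm trial (vehicle, drug
A, drug B, combination), each arm's mean final size is expressed relative
to vehicle, $r_g = \bar S_g / \bar S_{\mathrm{vehicle}}$, and

$$\mathrm{CDI}_{\mathrm{vivo}} = \frac{r_{AB}}{r_A\, r_B},$$

classified with the same bands as in vitro. "Final" is the last trial day,
and animals without a measurement on that day are excluded (per-protocol);
`carryForward = TRUE` substitutes each animal's last observation instead.
The CDI uses group means over independent animals (a `center = "median"`
option exists); arms are independent, so no pairing is meaningful.
`finalMeasureAnova()` runs the companion one-way ANOVA on final sizes with
Tukey HSD over all arm pairs; the comparisons of interest (each single
agent versus the combination) are read from the full pairwise table. A
degenerate trial in which all arms are identical returns $p = 1$ rather
than failing on a zero-variance fit.

## Expression arm

* **Signature scores** — the score of a signature in a sample is the plain
  mean of Log2 TPM over the signature genes present in the matrix. Genes
  absent from the matrix are dropped with a warning and the mean runs over
  the intersection; this keeps scores comparable when different annotation
  builds lose a handful of symbols. Single genes ride along as one-gene
  signatures.
* **Clustering and similarity** — profiles are clustered with average
  linkage on the correlation distance $1 - r$, rows and columns
  independently (`stats::hclust` underneath; validated against a naive
  $O(n^3)$ agglomeration in the tests). `profileSimilarity()` reports the
  full Pearson matrix and the count of negative pairs out of
  $\binom{k}{2}$. It takes whatever profile set is supplied — if 13
  signatures are scored alongside one extra profile, the summary simply
  covers $\binom{14}{2} = 91$ pairs.
* **Single-cell QC** — per sample (never pooled across samples), cells are
  removed when `nFeature` or `nCount` sits more than 3 raw MADs from the
  sample median in either direction, or when `percent_mt` exceeds
  $\min(\mathrm{median} + 3\,\mathrm{MAD},\ 25)$, the mitochondrial median
  and MAD being computed only over cells at or below 50% mitochondrial
  content. The MAD is the *raw* median absolute deviation — no 1.4826
  normal-consistency factor — because the rule is a rank-based fence, not a
  variance estimate; `madConstant` restores the scaling if wanted.
  Comparisons are strict, so a degenerate sample of identical cells keeps
  everything.
* **Signature-restricted PCA** — PCA of cells on the centered, scaled
  submatrix of signature genes (e.g. a 100-gene PI3K activity signature)
  instead of the most-variable-gene default; the embedding then orders
  cells by pathway activity rather than by global variance. Scaling to unit
  variance is the default so no single high-expression gene dominates;
  `scale = FALSE` turns it off.
* **Antibody arrays** — each probe is normalized to its own background and
  then to the mean of the positive-control probes normalized to theirs,
  which cancels global exposure; fold changes are ratios of normalized
  values between treated and control membranes.

## The simulation layer defines the study conditions

Every generator is a pure function of `(seed, scenario, entity)`: each
simulated entity (compound, animal, sample) draws from its own RNG stream,
so enlarging a simulation never perturbs existing draws, and a fixed seed
reproduces byte-identical tables. Noise is multiplicative log-normal (mean
1, given CV) throughout — viabilities and tumor sizes are positive,
scale-dependent quantities. Defaults encode the study conditions:

* **Dose-response** (`simDoseResponse`) — 8 doses per curve at $\sqrt 2$
  escalation from $D_m/2$ to $\approx 5.7\,D_m$, triplicate wells, 5% CV.
  The escalation is deliberately skewed toward high effect: synergy calls
  live at $f_a \ge 0.75$, and the low-$f_a$ flank contributes little
  information per well (a 5% viability error at $f_a = 0.1$ is a 50%
  relative error in $f_a$).
* **Combination surfaces** (`simCombinationSurface`) — Bliss
  ($v_{AB} = v_A v_B$), Loewe (additivity identity solved for $f_a$ by
  bisection to $10^{-10}$), or `interaction(kappa)`: a Loewe surface whose
  dose axis is rescaled so the combination achieves at dose $D$ what
  additivity achieves at $D/\kappa$ — $\kappa < 1$ plants synergy and the
  measured CI equals $\kappa$ for matched-slope drugs.
* **Anchor screens** (`simAnchorScreen`) — a 516-compound library by
  default, one dose per compound (screening doses are a per-library
  choice); non-planted compounds combine under exact Bliss independence,
  planted hits draw a true CDI in $[0.3, 0.65]$, and lethal compounds sit
  below 5% viability. The anchor-alone viability is averaged over
  `anchorReplicates` wells (default 8 per-compound replicates' worth),
  reflecting that the anchor control occupies wells on every assay plate —
  its measurement error is shared by every compound's CDI, so an anchor
  measured only once would shift the whole screen's CDI distribution
  coherently.
* **Tumor trials** (`simTumorTrial`) — exponential growth from ~50 mm² at
  0.08/day, 8 animals per arm, measurements three times a week for four
  weeks, treatment from day 7, 15% between-animal baseline CV and 10%
  measurement CV (typical caliper variability). Single-agent arms scale the
  post-treatment growth rate; the combination arm is constructed so its
  relative final size is the *product* of the single-arm relative sizes
  times a synergy factor $\sigma$ — growth rates add where final-size
  effects multiply — making the expected in-vivo CDI exactly $\sigma$.
* **Expression cohorts** (`simExpressionCohort`) — per-gene baselines
  uniform on 2–8 Log2 TPM, signature genes shifted by planted per-sample
  effects, Gaussian residual noise; the planted per-sample means are
  returned as ground truth.
* **Cell QC metrics** (`simCellQcMetrics`) — baseline cells are drawn
  multiplicatively but *bounded*: uniform within ±2 raw MADs of the sample
  center. A heavy-tailed baseline (e.g. unbounded log-normal) would place
  a few percent of healthy cells beyond any 3-MAD fence, making "the filter
  removes exactly the planted outliers" unattainable as a statement about
  ground truth; the bounded baseline trades tail realism for an exact
  oracle. Outliers are planted at ≥ 6.5 raw MADs on `nCount` (both
  directions) and at 30–45% mitochondrial content.

### What passing the synthetic suites does and does not show

The generators emulate the *structure* of the study's data — median-effect
curves, Bliss/Loewe surfaces, exponential growth, block-correlated
signatures — under clean noise models. Calibration results (CI $\equiv 1$
on additive surfaces, mean CDI $= 1$ on independent screens, in-vivo CDI
$= \sigma$) validate the estimators' correctness and internal consistency.
They do not certify behaviour under real-data pathologies: non-monotone
dose-response (flagged, not modelled), plate edge effects, heteroscedastic
counts, cell-cycle structure in expression, or drop-out in animal cohorts
beyond the per-protocol/carry-forward switch.

## Problem sizes and numerical settings

The shipped test and acceptance runs use: 100 seeds × (8 doses × 3
replicates) for median-effect recovery (median relative error of both
parameters is the statistic, against a two-stage exhaustive grid-search
oracle); 6 random matched-slope Loewe scenarios on 41-point CI grids; a
200-compound Bliss screen with 8 replicates; 200 replicate tumor trials per
synergy level; 50 random 6–10-profile clustering instances against the
naive oracle; 20 seeded QC simulations of 500 cells with 15 planted
outliers. Key tolerances: Loewe bisection $10^{-10}$; fa clipping bounds
$[0.005, 0.995]$; CDI denominator floor $10^{-4}$; additive band
$\tau = 0.05$; QC fences 3 raw MADs with a 25% mitochondrial ceiling.
These are the package's defaults, stated here so that deviations in user
analyses are conscious choices.

## Known limitations

* CI/DRI are limited to two-drug fixed-ratio designs; no confidence
  intervals on CI are provided (the algebraic CompuSyn estimator is out of
  scope), and no isobologram graphics beyond the profile tables.
* CDI is the only reference model for one-dose screens; Bliss/HSA/ZIP
  response-surface scores for checkerboard designs are out of scope.
* The in-vivo CDI inherits the usual caveat of ratio-of-means statistics in
  small arms (n = 8): its sampling error is substantial, which is why the
  calibration statements are about means over many replicate trials.
* Expression inputs are consumed as Log2 TPM / log-normalized counts;
  alignment, quantification, subtype calling and graph clustering belong to
  upstream tools.
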