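---
title: "Blood gene profiling of STEMI and NSTEMI: methods and design"
author: "stemiProfiles maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood gene profiling of STEMI and NSTEMI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemiProfiles)
```

# The problem

ST-elevation and non-ST-elevation myocardial infarction (STEMI/NSTEMI) are
clinically distinguished by ECG, but the blood transcriptome carries
condition-specific signal: transcripts leak from damaged myocardium into the
circulation and are cleared over days. This package implements a pipeline
that (i) merges several blood expression studies on their common gene
universe, (ii) ranks genes by a simple fold statistic and a layered
evidence score combining literature text-mining counts, DisGeNET
clinical-trial scores and expression folds, (iii) selects high-score gene
profiles per condition, assembles score-weighted interaction networks and
runs local over-representation enrichment, and (iv) uses sigma-metric
laboratory quality-control arithmetic to estimate *how long after MI* a
gene profile remains measurable — the time cut-off point.

Every stage is exercisable without downloads through a synthetic study
generator with planted, known effects.

# The model, stage by stage

## Fold statistic

Expression values are treated as log-scale (log2-like) intensities, so the
per-gene contrast statistic is an additive difference. The centered-sum
form

$$\mathrm{Fold}_g \;=\; \frac{\sum (x^{case}_g - \bar{x}^{ctl}_g)}{n_{case}}
 \;-\; \frac{\sum (x^{ctl}_g - \bar{x}^{ctl}_g)}{n_{ctl}}$$

has an identically zero second term (the control values are centered at
their own mean), so it collapses to
$\bar{x}^{case}_g - \bar{x}^{ctl}_g$. `geneFold()` implements both forms
(`form = "literal"` / `"mean-difference"`) and the test suite verifies
their equality to 1e-12; this also documents *why* folds of magnitude
~0.4 are meaningful on this scale. No variance moderation or shrinkage is
applied: the statistic is a plain mean difference by design.

## Batch harmonization

Source studies enter as separate batches. The correction in
`correctBatch()` is a per-gene, per-batch affine (location-scale)
transform anchored on the control samples: after correction each batch's
control mean equals the pooled control mean and each batch's control SD
equals the *pooled within-batch* control SD. Two deliberate choices:

* **Control anchoring.** Batches differ systematically in group
  composition (some carry only acute cases, some only follow-up samples),
  so anchoring on all samples would absorb genuine group effects into the
  batch estimate. Batches without a control arm can be corrected with
  `anchored = FALSE`.
* **Pooled within-batch SD as the scale target.** Targeting the grand SD
  of the concatenated controls is *not* idempotent when batch sizes
  differ (the grand SD of already-harmonized batches is a
  degrees-of-freedom-weighted mixture); the pooled within-batch SD makes
  `correctBatch(correctBatch(x)) == correctBatch(x)` exact, which the
  tests assert at 1e-9.

Genes with zero within-batch anchor variance pass through shift-only
correction. Surrogate-variable estimation is intentionally out of scope;
the contract the downstream stages rely on is only that expression ranges
of different studies are aligned, and the `method` argument leaves room
for an SVA-like plug-in.

## Score algebra

Three layers, all additive and dimensionless:

* **Experiment score** = DisGeNET score + text-mining score. Literature
  report counts are normalized onto the DisGeNET scale as
  `count / max(count) * max(disgenet)`. The exact normalization used in
  the original analyses of this kind is not standardized; this mapping is
  the package default, is recorded in the output, and degenerates
  sensibly (equal counts give every gene the maximal text score; all-zero
  counts give zero).
* **Expression score** = primary fold + mean fold over the enrichment
  datasets *in which the gene appears*. With full coverage over three
  enrichment studies this is the classical "+ sum/3"; with partial
  coverage the divisor is the number of covering tables and the gene is
  flagged `"partial"` rather than dropped.
* **Final score** = experiment + expression, on the union universe;
  evidence missing on either side contributes 0 and is flagged. The
  `ScoreTable` validity method enforces both additivity identities at
  1e-12, so a corrupted table cannot be constructed.

## Percentile and centile selection

Heatmap genes are selected at fold percentiles (> 99.5 for high, < 0.25
for low); network membership at score centiles (> 25 / < 25). Both use
the linear-interpolation percentile (the common "type 7" estimator) with
*strict* inequalities at the cutoff, and the realized cutoffs are stored
in the `HighLowSelection` so every selection is auditable. Boundary
conventions: a constant vector selects nothing (with a warning); centile
0 "above" and centile 100 "below" keep every gene, since nothing lies
strictly beyond the extremes of its own distribution.

Profiles use the same strict convention ("score > 12", "fold > 0.4"):
boundary genes are excluded, and `subProfileByFold()` tags the resulting
fold-level sub-profile.

## Networks and enrichment

`buildNetwork()` weights nodes by final score and edges by the mean of
the two endpoints' experiment scores multiplied by the supplied
interaction weight; the combination rule is an explicit, replaceable
function argument because upstream sources only state that edge strength
should reflect the experiment score. Interaction retrieval and layout are
presentation concerns and are out of scope — the module consumes any
3-column edge list (STRING exports qualify).

`oraEnrich()` is an exact upper-tail hypergeometric test per gene set
(sets first intersected with the universe; empty intersections skipped)
with Benjamini–Hochberg adjustment across sets. The adjusted value plays
the role of the "E-value < 0.05" enrichment call. Reproducing specific
E-values of web enrichment services is not attempted: those depend on
server-side library versions.

## Sigma-metric time cut-offs

The laboratory QC model is
$TE_a = SE + RE$, $SE = \mathrm{Bias} + \Delta SE$, $RE = CV + \Delta RE$,
giving $TE_a = \mathrm{Bias} + (\Delta SE + Z)\,CV$ at $P_{fr} = 5\%$
($Z = 1.96$), and $\Sigma = (TE - \mathrm{Bias})/CV$, so
$\Sigma(TE_a(d)) = d + Z$ identically (tested at 1e-12).

The probability of error detection uses a separate detection-limit
quantile: $P_{ed}(d) = \Phi(d - L)$. The default $L = 3$ (a 3-SD control
rule) is chosen because the canonical printed triples
$(\Delta SE, P_{ed}) = (2, 16\%), (3, 50\%), (4, 84\%)$ are exactly
$\Phi(\Delta SE - 3)$ rounded — they are *not* consistent with $L = Z =
1.96$. Both quantiles are independent `SigmaParams` fields, so either
convention can be requested; the package does not silently resolve the
inconsistency, it parameterizes it.

`findCutoff()` iterates rounds $k = 0, 1, \dots$: the acute fold profile
is shifted by $k \cdot CV$ per gene and compared to the 7-day reference
profile with a two-tailed two-sample t test (pooled-variance Student by
default, Welch by flag — the choice matters little on equal-sized gene
panels and pooled is the classical default). The cut-off round $k^*$ is
the first with $p \ge \alpha$; the result carries $P_{ed}(k^*)$ and, via
a user-supplied mapping, the time in days. Two conventions:

* Exactly identical profiles (zero variance, zero difference) return
  $p = 1$: "no detectable difference" rather than an undefined 0/0.
* The round-to-days mapping is **not** a formula. The established mapping
  for these blood panels (dSE 2 → 1 day, 3 → 3 days, 4 → 2 days) is not
  monotone, so it ships verbatim as the `dayMapping("reported")` preset
  and the user must opt into any mapping explicitly.
* Per-gene default CV: the SD of the gene's case-group expression divided
  by $\sqrt{n}$ — the standard error of the fold — since the procedure
  nowhere defines which imprecision to add; the choice is explicit and
  replaceable.
* In `runPipeline()` the CV increments are applied to whichever of the
  two profiles lies lower, since the shift is additive and the t test is
  label-symmetric; starting above the reference and shifting further up
  can never produce overlap.

The search precondition — that the 7-day and 30-day profiles do not
differ significantly — is checkable with `overlapTest()`; per-gene
temporal drift with `profileTrend()` (closed-form simple regression with
slope t test; constant series return slope 0, p = 1).

# The synthetic study generator

`generateStudyBundle()` emulates the five-study design the pipeline
targets, on one shared gene universe with one batch label per study:

| dataset | groups (samples) | emulates |
|---|---|---|
| acute | control 7, STEMI 7, NSTEMI 10 | acute blood array study |
| follow-up | control 6, day7 18, day30 18 | 7/30-day follow-up study |
| enrichment 1 | control 48, MI 49 | large MI/control study |
| enrichment 2 | control 11, MI 6 | small MI/control study |
| enrichment 3 | control 3, MI 3 | minimal MI/control study |

The acute and enrichment group sizes mirror the published study designs;
the follow-up study is generated *with* a small control arm (a generator
design choice — the real analogue has none) so the control-anchored
harmonization contract can be exercised end to end; control-free batches
are still supported through `anchored = FALSE`.

The value model is `(baseline + batch shift + planted effect + noise) *
batch scale`: Gaussian i.i.d. noise (default SD 0.3 expression units, a
realistic residual spread for log2 array data), Gaussian per-batch
location shifts, uniform per-batch scale factors. Default planted effects
(`plantedEffects()`) are ±1.2 units for 10 up- and 6 down-regulated genes
per condition, echoed at ×0.4 on day 7, ×0.1 on day 30 and ×0.5 in the
pooled-MI enrichment groups — a decaying time course consistent with
transcript clearance from blood. Evidence tables are *coupled to the
truth by a knob*, not by a mechanistic literature model (none exists):
for a configurable fraction of planted genes (default 0.8) report counts
and DisGeNET scores increase with planted effect magnitude, and a
configurable fraction is wired together in the edge list.

One global seed drives everything; each sub-generator derives a child
seed, so components are reproducible in isolation and a bundle is
byte-identical under a fixed configuration.

**What passing tests show — and what they do not.** The generator's
Gaussian location-scale world is exactly the world the correction and
fold statistics assume, so parameter-recovery results (e.g. ≥ 90 %
recovery of planted high-fold genes at effect ≥ 3× noise SD with 10
samples per group, and > 99 % removal of control-sample batch sum of
squares) certify internal correctness of the pipeline, not performance on
real microarray data, where batch effects are not affine, noise is
heteroskedastic, and probe effects exist. Probe-level simulation and
RNA-seq count models are deliberately out of scope;
`collapseProbes()` handles pre-existing probe-level tables (mean default
— order-independent; max-variance alternative).

# Problem sizes and numerical conventions

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own validation sizes: 2 000-gene universes, 10 samples per
acute group, 1 000-replicate oracle comparisons for the percentile and
fold identities, 2 000-query null calibration for enrichment, and
200-replicate Monte-Carlo checks for the cut-off null (bounds stated with
3 Monte-Carlo standard errors). The published heatmap gene counts
(69/45 high/low STEMI, 68/36 NSTEMI) arise from full GEO series under an
SVA configuration that is not recoverable from public text and are
therefore not desk-scale reproduction targets; the percentile machinery
that produced them is instead validated against brute-force oracles and
planted truth.

Other conventions, collected: gene identifiers are uppercased HGNC-style
symbols, matched case-insensitively across tables; duplicate undirected
edges merge by maximum weight and self-loops are rejected at parse time;
TSV is UTF-8, tab-delimited, '.'-decimal; merging ≥ 2 datasets requires
disjoint sample identifiers (no silent suffixing).

# Known limitations

* The batch model removes only affine per-batch distortions; surrogate
  variables, empirical-Bayes shrinkage and nonlinear normalization are
  out of scope by design.
* The evidence generator is a coupling heuristic, so evidence-integration
  results validate bookkeeping (flags, union universes, normalization)
  rather than any literature-mining model.
* The text-mining normalization and the choice of score vector for the
  25-centile network filter are genuinely underdetermined upstream; both
  are explicit arguments with documented defaults rather than hidden
  guesses.
* Whether the overlap t test should pair genes is unknown upstream; the
  implemented test is unpaired (paired vectors of equal panels can be
  compared by differencing externally).
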