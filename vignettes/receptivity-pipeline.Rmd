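---
title: "Staging endometrial receptivity from uterine-fluid RNA-seq: models and design"
author: "fluidERT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging endometrial receptivity from uterine-fluid RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidERT)
```

## The problem and the modelling stance

The endometrium is receptive to an implanting embryo only during a short
window (the window of implantation, WOI), normally around day LH+7 of a
natural cycle. A displaced WOI — an endometrium still pre-receptive or
already post-receptive on the expected day — is a plausible cause of
implantation failure, and a transfer can in principle be re-timed if the
displacement is detected. `fluidERT` implements a noninvasive test of that
state from RNA-seq of aspirated uterine fluid, staged into three classes:
pre-receptive (PR, sampled LH+5), receptive (RE, LH+7) and post-receptive
(PO, LH+9).

Every stage of the pipeline is an explicit statistical model with stated
assumptions. This vignette records those models, the tunable parameters and
their defaults, what the cohort simulator does and does not emulate, and
the design decisions taken where more than one reasonable choice existed.

## Expression model and normalization

Input is a gene × sample matrix of fragment counts (with transcript
lengths) or FPKM. FPKM is computed as
$$\mathrm{FPKM}_{gs} = \frac{c_{gs}\cdot 10^9}{N_s\, L_g},$$
with the library size $N_s$ taken as the column sum of the count matrix —
the totals of upstream alignment are not available to this package, and the
column sum makes the transform exactly invertible, which the unit tests
exploit. Analysis happens on $\log_2(\mathrm{FPKM} + 1)$: the pseudocount
of 1 keeps zeros finite, maps absent genes to exactly 0, and is
configurable.

Library QC is a simple two-gate filter (minimum genes detected, minimum
total fragments). Uterine-fluid libraries are built from nanogram-scale
RNA and failures occur; the gate's thresholds are deliberately loose
defaults (5,000 genes; 100,000 fragments) because no principled universal
cutoff exists — users should set them relative to their gene universe (the
orchestrator uses a fraction of `nGenes`). A failed library propagates
through the pipeline as `detection_failed`, never as a silent omission.

## Per-gene inference

For each gene the log2 values are decomposed as
$$Y_{gij} = \mu_g + T_{gi} + S_{gj} + \varepsilon_{gij},$$
with $T$ a cycle-protocol (natural vs. hormone-replacement) term and $S$
the three-level stage term. Although the decomposition reads as a
random-effects statement, the test statistic is the fixed-effects F ratio
$F = MS_{stage}/MS_{error}$ — for a balanced design without interaction
the two coincide, and the fixed-effects fit is exact, fast and assumption
light. The treatment term is dropped automatically when the protocol
column is constant (an all-natural-cycle training cohort); when fitted,
the stage sum of squares is the stage-last (type II) sum of squares.

Implementation is vectorized: residual sums of squares come from one QR
projection shared by all genes, so 15,000 genes fit in well under a
second. Degenerate genes are flagged rather than tested: zero total
variance gives $p = 1$ (`constant`), zero residual variance with non-zero
separation gives $p = 0$ with an infinite-F sentinel (`zero_residual`);
both are excluded from marker candidacy.

Multiplicity is handled by Benjamini–Hochberg q-values (`bhFDR()`, a thin
validating wrapper over the standard step-up). Two thresholds coexist by
design: volcano classification uses the raw ANOVA p (cutoffs p < 0.05,
fold change 2, boundary inclusive on $|\log_2 FC| \ge 1$), while the
DEG call that feeds the network and marker stages uses q < 0.05. Both are
configuration fields, and which genes were called is always reported, not
implied.

Post hoc pairwise stage comparisons use the Tukey–Kramer studentized-range
statistic
$$q_{ij} = \frac{|\bar y_i - \bar y_j|}{\sqrt{(MS_e/2)(1/n_i + 1/n_j)}}$$
with $k = 3$ groups and the ANOVA error df; p-values come from the
studentized-range distribution (`ptukey`), which the test suite checks
against a $10^6$-draw Monte-Carlo simulation of the null.

## Co-expression modules and hubs

The network stage is a compact re-implementation of weighted co-expression
analysis with fully specified, deterministic behavior:

* adjacency $a_{ij} = |\mathrm{cor}(g_i, g_j)|^\beta$ (unsigned, default)
  or $((1+\mathrm{cor})/2)^\beta$ (signed), $\beta = 6$;
* topological overlap
  $\omega_{ij} = (l_{ij} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$ with
  $l_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$;
* average-linkage clustering of $1-\omega$ with a **static** cut; clusters
  below `minModuleSize` (30) become grey. Static cutting (rather than
  dynamic tree cutting) keeps the algorithm fully specified and
  reproducible to the byte.
* module eigengene = first principal component of the standardized module
  expression, unit norm, sign-oriented so its mean correlation with
  members is positive; module–stage relation = Pearson correlation of the
  eigengene with the ordinal code PR = 1 < RE = 2 < PO = 3 (receptivity
  progresses along an ordered axis, so an ordinal code is the natural
  one-degree-of-freedom summary);
* hub gene = member maximizing intramodular connectivity
  $k^{within}_i = \sum_{j \in M, j\ne i} a_{ij}$, ties broken
  lexicographically. The grey pseudo-module's "hub" is reported but never
  enters the marker panel.

The default cut height is 0.9 on the $1-\omega$ scale. This is a
considered deviation from the 0.25 sometimes quoted in co-expression
workflows: 0.25 is the height used for *merging module eigengenes*
(correlation > 0.75), not for cutting the gene dendrogram. On TOM
dissimilarity even a tight planted block (within-module correlation 0.9 at
$\beta = 6$) sits at heights around 0.5, so a 0.25 cut would label
everything grey; between-module heights concentrate near 1.0, so 0.9
separates real blocks from noise with a wide margin.

## Marker panel

Candidates are genes significant in **all three** pairwise Tukey tests at
`alpha` (0.05) — a conjunctive rule that selects genes able to distinguish
every pair of stages, not merely one extreme pair. A random forest on the
candidates yields both importance measures, and the panel takes the top
`panelSize` (default 87) genes by mean decrease accuracy subject to
membership in the top `2 * panelSize` by mean decrease Gini (pure accuracy
order fills any shortfall). The dual-rank rule honours both importance
measures, is deterministic, and makes the panel size a parameter rather
than a magic constant. Non-grey module hubs are then appended as
additional markers; a hub that already earned a panel place on importance
is not double-counted. Mean decrease accuracy is reported scaled by its
standard error (the conventional display); the raw unscaled permutation
importance is available for calibration work, where its null distribution
is centered at zero.

## Classifier, call rule, WOI readout

The classifier of record is a 500-tree random forest (sqrt features per
split, no class weighting — the training design is balanced) over the
panel, with the class order fixed at PR/RE/PO. Probabilities are
out-of-forest vote fractions. The call rule applies a single threshold to
the maximum class probability: call the argmax class if it reaches
$\tau = 0.6$, else `NO_CALL`; $\tau$ must exceed 1/3, and raising it can
only turn calls into no-calls (a tested monotonicity invariant). On
transfer-day samples the stage call is interpreted as the WOI status:
RE → normal, PR → delayed, PO → advanced, NO_CALL → indeterminate,
failed libraries → detection_failed.

Cross-validation is 10-fold and **patient-grouped**: each training patient
contributes three stage-labelled samples, and letting them straddle folds
would leak patient-level signal into the test folds. A flag restores naive
per-sample folding for comparison. Sensitivity, specificity, PPV and NPV
are macro one-vs-rest averages over the three classes — a reported
definition, since single-number multiclass summaries are otherwise
ambiguous. Linear discriminant projection onto the two leading axes is
provided for visualization only; a ridge fallback handles singular
within-class scatter.

One calibration subtlety is worth recording: under label permutation the
patient-grouped argmax null does not sit exactly at 1/3. With class totals
fixed, a fold's test composition is anti-correlated with its training
composition, and the forest tracks the training majority, biasing permuted
accuracy slightly *below* chance (measured ≈ 0.305 at the default design
over 40 permutations). The permutation-null tests therefore assert the
absence of above-chance inflation (the leakage symptom) at 3 Monte-Carlo
standard errors, plus agreement with chance within 0.05 absolute, rather
than a two-sided 3-SE equality with 1/3 that a correct implementation
would fail half the time.

## Clinical association

WOI calls versus pregnancy outcomes form a 2×2 table (normal = RE call;
displaced pools PR and PO; indeterminate and detection-failed samples are
excluded and listed). Inference is the two-sided Fisher exact test under
the sum-of-smaller-probabilities convention — all tables with the observed
margins whose hypergeometric probability does not exceed the observed
table's (to a $10^{-7}$ relative tolerance) contribute — implemented by
direct enumeration and cross-checked against an independent
implementation in the test suite. The odds ratio is the sample ratio
$ad/bc$ with explicit `infinite` / `zero` / `undefined` flags for
zero-cell patterns, rather than a conditional-MLE estimate. Per-row rates
use the analyzable denominators; the overall cohort rate deliberately uses
the full enrolled denominator including failures, matching how such
cohorts are reported. The companion over-representation test is a plain
upper-tail hypergeometric with fold enrichment $(k/n)/(K/N)$ and BH
adjustment across sets.

## The cohort simulator

The simulator exists so that every downstream stage is testable against a
known truth. It realizes exactly the additive decomposition the ANOVA
assumes, on the log2 scale:

* baselines $\mu_g \sim N(3, 1.5^2)$ — a broad, realistic spread of
  log2(FPKM+1) abundances;
* planted stage-associated genes (`nDEG`, default 864 of 15,000) receive
  i.i.d. normal per-stage offsets, centered across PR/RE/PO, with SD
  `stageEffectSD` = 2.0 log2 units;
* four planted co-expression modules (100/75/50/30 genes, disjoint from
  the DEG set) each carry a latent factor $f_m \sim N(0,1)$ per sample;
  members load on it with loadings uniform in
  $[0.6, 1.4] \times$ `moduleFactorSD` (2.0), and one member per module is
  boosted to `hubLoadingBoost` (1.5) times the largest loading, making it
  the maximum-connectivity gene by construction;
* residual noise $\varepsilon \sim N(0, 1.0^2)$; an optional per-protocol
  treatment offset (SD 0, training cohorts being all natural-cycle);
* optional negative-binomial count emission: expected fragments are the
  FPKM-inverted means at ~5 million fragments per library, with constant
  dispersion 0.05 — the round trip counts → FPKM → log2 correlates > 0.95
  with the latent matrix;
* a single-timepoint validation cohort (22 samples) with hidden true
  stages (default 14% PR / 86% RE), Bernoulli pregnancy outcomes at 0.78
  given a receptive endometrium and 0 given a displaced one, and
  optionally one forced library failure (expression zeroed outside 5% of
  genes) to exercise the detection-failure path.

Identical configuration and seed reproduce the output byte-for-byte, and
the truth ledger (DEG identities, offsets, module membership, loadings,
hubs, validation stages and outcomes) is returned alongside the data.

Three noise parameters deserve their rationale. With a residual SD of 0.5
log2 units, module-member correlations saturate above 0.95 and the hub's
connectivity margin over the runner-up falls inside correlation-estimation
noise — the hub would be planted but undetectable in principle, defeating
the parameter's purpose. A residual SD of 1.0 matches the noise of
low-input, amplification-based uterine-fluid libraries better and leaves
within-module correlations in the 0.6–0.9 range typical of strong
co-expression modules. The stage-effect SD is kept at twice the residual
SD, giving planted effects mostly in the 1–4 fold-change range, and the
hub boost of 1.5 gives the hub an analytic connectivity margin of ~20%,
several standard errors at the design's 144 samples.

What the simulator does **not** emulate: patient-level random effects
(samples within a patient are conditionally independent given stage),
amplification and batch artifacts beyond the protocol term, count
over-dispersion heterogeneity across genes, correlated module-and-DEG
structure (planted modules are stage-independent and disjoint from the DEG
set, so module–stage correlations on simulated data are null; the
module–stage correlation machinery is instead validated on constructed
monotone fixtures), and any read-level process. Passing tests on this
generator therefore demonstrate correctness of the algorithms under their
own assumptions — not clinical performance on real cohorts, which can only
be established on real data.

## Problem sizes and tolerances

The test and acceptance workloads use a scaled cohort — 48 patients × 3
samples, 3,000 genes with 200 planted DEGs — chosen so the whole suite
runs in minutes while every rate being estimated (recovery, FDP, module
ARI, hub recovery, CV accuracy) retains the sample sizes that matter
(patients and samples are at full design size; only the gene universe is
scaled). Exact algebraic identities are tested at 1e-10 to 1e-12 relative;
enumeration-based tests (Fisher, BH) exactly; Monte-Carlo comparisons at 3
simulation standard errors; calibration statements (KS uniformity at
α = 0.01, FDP ≤ 0.10 at q < 0.05, chance-level permuted accuracy) at the
conventional thresholds stated inline.

## Known limitations

* The classifier, panel and thresholds are validated on synthetic data;
  numbers like a cross-validated accuracy of ~100% on the default
  simulation reflect the planted effect sizes, not expected clinical
  accuracy.
* Marker selection is not nested inside cross-validation by default (the
  panel is fixed before folding); on synthetic data the optimism this
  induces is negligible because effects are strong, but the flag exists
  and real-data use should prefer nested selection.
* The Fisher test's sum-of-smaller-probabilities convention is one of
  several two-sided conventions; it is stated, tested, and matches the
  common statistical-software default.
* Static tree cutting trades the adaptivity of dynamic cutting for exact
  reproducibility; very heterogeneous module tightness may require tuning
  `cutHeight`.
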