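# fluidERT

Endometrial receptivity staging from uterine-fluid transcriptomes.

Successful embryo implantation requires transferring the embryo inside the
window of implantation (WOI), the short interval — around day LH+7 of a
natural cycle — in which the endometrium is receptive. In some IVF patients
the WOI is displaced (still pre-receptive, or already post-receptive, on the
expected day), and a transfer timed to the population average fails.
`fluidERT` implements a noninvasive receptivity test built on RNA-seq of
aspirated uterine fluid: instead of an endometrial biopsy, a few microliters
of fluid collected just before transfer are profiled and classified into one
of three receptivity stages — pre-receptive (PR, LH+5), receptive (RE,
LH+7), post-receptive (PO, LH+9) — and the call is read out as a normal,
delayed or advanced WOI.

The package is aimed at reproductive-medicine bioinformaticians: it
implements the full analysis pipeline as reusable, tested components, plus a
cohort simulator so every stage can be exercised and validated without
patient data.

## The method

Starting from a gene × sample expression matrix (fragment counts or FPKM)
with stage-timed samples from natural-cycle patients:

1. **Normalization** — FPKM<sub>gs</sub> = count<sub>gs</sub> · 10⁹ /
   (N<sub>s</sub> · L<sub>g</sub>), then log₂(FPKM + 1).
2. **Stage-associated genes** — a per-gene ANOVA of the additive model
   Y<sub>gij</sub> = μ<sub>g</sub> + T<sub>gi</sub> + S<sub>gj</sub> +
   ε<sub>gij</sub> (T: cycle-protocol term, dropped when constant; S: the
   three-level stage term), testing F = MS<sub>stage</sub>/MS<sub>error</sub>
   with Benjamini–Hochberg q-values, pairwise log₂ fold changes and volcano
   classes (p < 0.05, fold change 2).
3. **Co-expression modules** — a weighted network on the stage-associated
   genes: soft-power adjacency a<sub>ij</sub> = |cor|<sup>β</sup> (β = 6),
   topological overlap ω<sub>ij</sub> = (l<sub>ij</sub> + a<sub>ij</sub>) /
   (min(k<sub>i</sub>,k<sub>j</sub>) + 1 − a<sub>ij</sub>), average-linkage
   clustering of 1 − ω, module eigengenes, module–stage correlations, and
   one hub gene per module by maximal intramodular connectivity
   (kWithin).
4. **Marker panel** — genes significant in *all three* pairwise Tukey HSD
   comparisons are ranked by a random forest's two importance measures
   (mean decrease accuracy, mean decrease Gini); the top 87 plus the
   non-grey module hubs form the signature.
5. **Classifier** — a random forest over the panel predicts PR/RE/PO; a
   sample is called only when its maximum class probability reaches
   τ = 0.6, otherwise `NO_CALL`. Performance is estimated by 10-fold
   patient-grouped cross-validation; an LDA projection visualizes class
   separation.
6. **Clinical readout** — RE on transfer day ⇒ normal WOI, PR ⇒ delayed,
   PO ⇒ advanced; WOI calls are associated with pregnancy outcomes by a
   two-sided Fisher exact test (sum-of-smaller-probabilities convention)
   on the normal-vs-displaced × outcome 2×2 table.

A generic hypergeometric over-representation test for annotation gene sets
and a YAML-configured end-to-end orchestrator (`runPipeline()`) round out
the toolkit.

## Worked example

Simulate a training cohort with the default study design (48 patients × 3
stage-timed samples; here 3,000 genes with 200 stage-associated), build the
test, and apply it to a 22-sample transfer-day validation cohort:

```r
library(fluidERT)

cfg    <- simulationConfig(nGenes = 3000, nDEG = 200, seed = 1)
cohort <- simulateTrainingCohort(cfg)
cohort$dataset
#> ReceptivityExperiment: 3000 genes x 144 samples [log2 scale]
#>   stages: PR=48 RE=48 PO=48 unknown=0
#>   patients: 48

stats <- geneANOVA(cohort$dataset)
deg   <- rownames(stats)[stats$q_value < 0.05 & is.na(stats$degenerate)]
length(deg)
#> [1] 202

modules <- coexpressionModules(cohort$dataset, deg)
panel   <- selectMarkers(cohort$dataset, stats, modules,
                         panelSize = 87, seed = 1)
model   <- trainERT(cohort$dataset, panel$gene, tau = 0.6, seed = 1)
crossValidate(cohort$dataset, panel$gene, k = 10, seed = 1)
#> 10-fold cross-validation (seed 1)
#>   mean accuracy 100.0%, sensitivity 100.0%, specificity 100.0%, ...

va   <- simulateValidationCohort(cfg, cohort$truth, nQCFail = 1)
qc   <- qcFilter(va$dataset, minGenesDetected = 600, minTotal = 0)
pred <- predictReceptivity(model, va$dataset,
                           failedSamples = qc$report$sample_id[!qc$report$pass])
table(pred$woi)
#>          delayed detection_failed           normal
#>                3                1               18

pred$outcome <- sampleInfo(va$dataset)$outcome
outcomeAssociation(pred)
#>                 pregnant not_pregnant
#>   normal_WOI          13            5
#>   displaced_WOI        0            3
#> normal-WOI rate 72.2%, displaced-WOI rate 0.0%, overall 59.1% (n=22 enrolled)
#> Fisher exact two-sided p = 0.04211, OR = Inf (infinite)
#> excluded: V001 (detection_failed)
```

Of 22 enrolled samples one library fails QC; 18 of the 21 analyzable
samples are called receptive (normal WOI) and 3 delayed. No displaced-WOI
patient conceives, versus 72% of normal-WOI patients — the exact test puts
that contrast at p = 0.042.

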