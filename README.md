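# metaboresponse

Statistical workflow for comparing the metabolomic effects of weight-loss
interventions in paired multi-platform studies. The package is written for
analysts of four-arm designs — a saline infusion control (SAL), a combined
GLP-1/oxyntomodulin/PYY infusion (GOP), a very low-calorie diet (VLCD) and
Roux-en-Y gastric bypass surgery (RYGB) — where every subject is profiled at
baseline and after four weeks in plasma and/or urine across several LC-MS
and NMR assay platforms, and the question is which arms change which
metabolites, and how congruent those changes are.

## What it computes

**Per-feature mixed models.** Each feature is modelled on the log scale as

```
log(y) ~ timepoint * group + (1 | subject)
```

with a subject random intercept, fitted by REML profiled over the variance
ratio (closed form for complete balanced pairs, Brent search with Woodbury
block inversion otherwise). Pairwise timepoint-by-group interaction
contrasts — the excess within-subject log change of one arm over another —
are tested with Wald *t* statistics (containment df) and controlled by
Benjamini–Hochberg FDR at 5% within each (platform grouping × pair) family.
A confounder-adjusted variant adds `timepoint:group:factor` terms for a
clinical delta (weight, glucose, insulin, triglycerides, cholesterol), and
a subject-bootstrap power simulation asks how discoveries scale with arm
size.

**Fold-change PCA.** Per-subject log2(week 4 / baseline) matrices,
SVD-based PCA with deterministic sign conventions, and per-component
one-way ANOVA plus pairwise Welch tests across arms.

**PLS with permutation validation.** NIPALS PLS1 of a metabolite block
against a clinical factor, cross-validated Q²Ŷ (7-fold, arm-stratified),
validity gates Q²Ŷ > 0.15 and permutation *p* < 0.01 against 1000
mismatched-response refits, and empirical per-feature weight selection at
*p* < 0.05 in valid models.

**Congruence and chain matching.** Pearson correlations of mean log2 fold
changes between every intervention pair; categorisation of features as
shared / uniquely significant / nonsignificant; per-feature clinical
correlations; and exact acyl-chain matching of free fatty acids to
acylcarnitines, phosphatidylcholines (sn-2), lysophospholipids and
ceramides/sphingomyelins (N-acyl), with per-class co-variation of
intervention effects.

**Synthetic studies with known ground truth.** Because analyses of this
design are rarely accompanied by deposited patient-level data, the package
ships a generator (`simulate_study()`) that reproduces the full design —
arm sizes 11/14/22/21, paired samples, subject random intercepts,
log-normal intensities, class-signed caloric-restriction effect templates
with configurable VLCD–RYGB congruence, and clinically linked features —
so every stage is testable end to end.

## Worked example

```r
library(metaboresponse)

sim  <- simulate_study(n_features = 300, seed = 2024)
scan <- lme_scan(sim$study)                 # LME + contrasts + BH
percent_significant(scan)
#>  group_a group_b n_features n_significant percent_significant
#>      GOP     SAL        300             0             0.00000
#>     VLCD     SAL        300            71            23.66667
#>     RYGB     SAL        300            69            23.00000
```

No feature passes FDR for the hormone infusion, while roughly a quarter of
the features respond to either caloric-restriction arm — the generator's
GOP arm is null by default, and `frac_affected = 1/3` of features carry
VLCD/RYGB effects, of which the scan recovers the detectable share.

```r
fc   <- compute_fold_changes(sim$study)     # per-subject log2 fold changes
cong <- pairwise_congruence(mean_fold_changes(fc), scan)
subset(cong$pairwise, group_a == "VLCD" & group_b == "RYGB")
#>  group_a group_b         r             p   n
#>     VLCD    RYGB 0.8946128 2.873579e-106 300
```

The mean fold changes of the two caloric-restriction arms correlate at
r ≈ 0.89 — the generator draws their effect vectors at correlation 0.9, and
the estimate is mildly attenuated by measurement noise.

```r
head(scan$contrasts[order(scan$contrasts$q),
                    c("feature_id", "group_a", "estimate_log2", "q")], 3)
#>  feature_id group_a estimate_log2            q
#>   feat_0097    VLCD      2.301687 5.311087e-19
#>   feat_0009    VLCD      1.841322 7.408000e-18
#>   feat_0009    RYGB      1.771063 1.310725e-16
```

`estimate_log2` is the interaction contrast converted to log2 units: the
top feature roughly quintupled (2.3 log2 units) more under VLCD than under
saline.

The whole workflow — simulation or CSV input, fold-change PCA, mixed
models, PLS, congruence, chain matching, CSV outputs with provenance
headers and a report — runs from one configuration:

```r
res <- run_pipeline(default_config(seed = 1, out_dir = "out"))
```

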