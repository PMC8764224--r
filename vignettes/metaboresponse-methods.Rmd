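---
title: "Statistical methods behind metaboresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind metaboresponse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboresponse)
```

`metaboresponse` implements the statistical workflow of a four-arm paired
metabolomic intervention study: a saline infusion control (SAL), a combined
GLP-1/oxyntomodulin/PYY infusion (GOP), a very low-calorie diet (VLCD) and
Roux-en-Y gastric bypass (RYGB), each subject sampled at baseline and after
four weeks in plasma and/or urine across several LC-MS and NMR assay
platforms. This vignette is the package's own account of the models and the
choices behind them.

## The mixed model

Every feature is modelled on the natural-log scale with a subject random
intercept:

$$\log y_{it} = \beta_0 + \beta_t\,\mathrm{week4}_t
  + \boldsymbol\beta_g^\top G_i + \boldsymbol\beta_{tg}^\top (\mathrm{week4}_t \times G_i)
  + b_i + \varepsilon_{it},
  \qquad b_i \sim N(0, \sigma_b^2),\ \varepsilon_{it} \sim N(0, \sigma_e^2).$$

The treatment-coded design uses SAL and baseline as reference levels, so the
timepoint-by-group interaction coefficients are directly the excess
within-subject log change of each active arm over the control; the pairwise
Wald contrast of two interaction coefficients is the quantity reported per
feature. Estimation is REML, profiled over the variance ratio
$\lambda = \sigma_b^2/\sigma_e^2$:

* **Closed form for complete balanced pairs.** When every subject has
  exactly one baseline and one week-4 sample, the likelihood factorises into
  independent within-subject (differences) and between-subject (sums)
  strata, each an ordinary linear model. The stratum residual mean squares
  give $\hat\sigma_e^2$ and $\hat\sigma_b^2$ exactly, and the whole
  per-feature scan vectorises into a handful of matrix operations. If the
  between-subject estimate would be negative, the code falls back to the
  profiled path, which handles the $\sigma_b^2 = 0$ boundary.
* **Profiled REML in general.** For unbalanced designs (missing week-4
  samples, covariate-adjusted models) the REML criterion is minimised by
  Brent search over $\log\lambda$ on $[-15, 15]$ (tolerance $10^{-10}$),
  with $V^{-1} = (I + \lambda ZZ^\top)^{-1}$ applied through per-subject
  Woodbury identities, so no dense $n \times n$ matrix is ever formed. The
  boundary $\lambda = 0$ is always evaluated and wins ties.

The two paths agree to $10^{-8}$ on balanced data, and both agree with an
independent dense-GLS grid search and with `lme4`, which the test suite
asserts.

Inference uses Wald $t$ statistics with containment degrees of freedom
(subjects minus groups). At these arm sizes (11/14/22/21) containment df is
64, where the difference from Satterthwaite approximations is negligible;
the choice is recorded in the scan metadata so it is auditable. Estimates
are kept on the natural-log scale of the model and additionally reported in
log2 units (`estimate_log2 = estimate / log(2)`) so that figures and fold
changes share one display scale; the conversion is applied exactly once, in
`lme_scan()`.

False-discovery control is Benjamini–Hochberg at $\alpha = 0.05$, applied
within each (platform grouping × contrast pair) family, matching summaries
that report the percentage of significant features per data set per pair.
`bh_fdr()` delegates to `stats::p.adjust` and adds NA propagation; the test
suite verifies it against a literal step-up implementation.

### Confounder-adjusted models

The adjusted model appends timepoint:group:factor columns (one per arm) for
a per-subject clinical delta such as weight change. Columns that do not
increase the design rank — a factor that is constant within an arm, or
identically zero — are dropped with a warning. A feature that is significant
vs SAL unadjusted but not adjusted is flagged *confounder-sensitive*. This
three-way parametrisation leaves the main interaction contrasts defined
exactly as in the unadjusted model, which is what makes the flag
interpretable.

### Power simulation

`power_simulation()` asks how many features would pass FDR if the GOP arm
had been as large as the RYGB arm: target-arm subjects are resampled with
replacement to the target size, SAL is held fixed, and the full scan is
re-run per resample. Verbatim duplicates of a subject would shrink the
residual-variance estimate and make the null anti-conservative, so the
default `"smooth"` scheme adds fresh per-feature Gaussian noise (at the
residual SD estimated from the original within-group paired differences) to
every duplicate copy beyond the first; the copies then behave like new
patients near the resampled one. The scheme is a package design decision —
it is declared in the output, configurable (`scheme = "naive"` gives the
verbatim bootstrap), and intentionally conservative under the null.

## Fold-change PCA

Per-subject log2 fold changes (week 4 over baseline) are the substrate of
the unsupervised analysis. PCA is a thin SVD with mean-centering as the
default preprocessing — the minimal choice that leaves the fold-change units
interpretable; unit-variance and Pareto scaling are available. Missing cells
are imputed by feature-wise means *for this stage only* and flagged on the
result. Component signs follow a deterministic convention (the
largest-magnitude loading element of each component is positive), and
explained-variance ratios are computed against the total variance of the
preprocessed matrix so they remain valid for truncated decompositions.
Per-component group structure is tested with a one-way ANOVA plus pairwise
Welch $t$ tests, BH-adjusted within component; the ANOVA choice (rather than
a nonparametric test) is recorded in the output metadata.

## PLS against clinical factors

Associations between the metabolome and clinical deltas use NIPALS PLS1 on
centred, unit-variance-scaled data. PLS1 weights have a closed form per
component ($w \propto X^\top y$, then deflation), so the fit is fully
deterministic. Model quality is $Q^2\hat{Y} = 1 - \mathrm{PRESS}/\mathrm{TSS}$
from 7-fold cross-validation (the chemometrics convention), with centring
and scaling re-estimated on training folds only and folds stratified by
treatment arm when the whole cohort is modelled; fold assignment is
deterministic given the seed. The component count is chosen as the argmax
of cross-validated $Q^2$ over 1–5, with a fixed-count override.

Validity requires $Q^2\hat{Y} > 0.15$ **and** a permutation $p$-value below
0.01 against models refitted (including their cross-validation) on
permuted responses; with the default $B = 1000$ the add-one estimator
$(1 + \#\{Q^2_{null} \ge Q^2\})/(B+1)$ can resolve that threshold. Note that
$B$ must exceed 99 for validity to be attainable at all.

Feature selection compares each feature's component-1 weight against its
permutation-null distribution with the add-one estimator and keeps
`empirical_p < 0.05`, only in valid models. The comparison is made on the
**cross-covariance scale** ($X^\top y$ of the scaled data, the NIPALS weight
before unit normalisation). This matters: normalised weight vectors all have
unit norm, so permutation redistributes rather than shrinks weight
magnitude, and with many genuinely informative features no feature could
beat its null at a useful rate — the norm constraint caps the number of
features that can exceed the null 95th percentile at roughly
$p/q_{95}^2$ regardless of signal strength. On the covariance scale a
permuted model's weights collapse towards zero and the comparison becomes a
genuine association test. A signed one-sided variant is available by flag.

## Congruence and chain matching

Cross-intervention similarity is the Pearson correlation of per-feature
group mean log2 fold changes for every arm pair, with $t$-based 95%
intervals on the means. Features are categorised from the vs-SAL q-values:
*shared* when both VLCD and RYGB pass, *unique* to an arm when exactly one
passes, *nonsignificant* otherwise; the rare case of two significant arms
other than the VLCD/RYGB pair is counted as shared. Within-category
correlations are reported with `r = NA` below three features. Per-feature
clinical correlations use the $t$ transform of Pearson's $r$, unadjusted for
display masking at $p < 0.05$ (matching common figure conventions) with a BH
column alongside; the PLS machinery is the stricter arbiter.

A caution that the test suite quantifies: the two vs-SAL test statistics of
any feature share the SAL arm and are correlated (about 0.66 at these arm
sizes), so falsely "shared" features arise more often than independence
would suggest, at a rate that grows with the number of true discoveries
through the BH threshold. This is a property of the design, not of the
implementation.

Chain matching links each free fatty acid to complex lipids carrying the
identical (carbons, double bonds) chain: acylcarnitines and
lysophospholipids on their single chain, phosphatidylcholines on the sn-2
chain (taken from name order; sum-composition names are excluded rather than
guessed), ceramides and sphingomyelins on the N-acyl chain. Matching is
exact — no tolerance — and a very-long-chain flag (≥ C24) propagates from
the fatty acid so the divergent behaviour of C24:0/C26:0 species can be
isolated. Co-variation pools one point per match per intervention and
reports Pearson's $r$ per partner class, with lysophospholipid subclasses
both separate and pooled.

## The synthetic generator

Because the study's patient-level data are not deposited, every stage is
validated against `simulate_study()`, which generates the full design with
known ground truth: arm sizes 11/14/22/21, paired samples, log2-scale
intensities $y = \mu_f + b_i + \delta_{fg}\,\mathbf 1\{\text{week4}\} +
\varepsilon$, and per-subject clinical deltas with arm-specific means.
Defaults, chosen once as field-plausible values:

| parameter | default | meaning |
|---|---|---|
| `sigma_subject` | 0.5 | subject intercept SD, log2 units |
| `sigma_resid` | 0.3 | residual SD, log2 units (≈ 23% CV) |
| `baseline_mu_range` | 10–20 | per-feature mean log2 intensity |
| `frac_affected` | 1/3 | share of features with VLCD/RYGB effects |
| `effect_sd` | 0.75 | SD of bivariate-normal effect magnitudes |
| `congruence_rho` | 0.9 | VLCD–RYGB effect correlation |
| template magnitudes | 0.5 / 1.0 | log2 effects, keyed on the acyl chain |
| weight-delta means | −2/−4/−8/−10 kg | SAL/GOP/VLCD/RYGB |

The VLCD and RYGB effect vectors are drawn from a bivariate normal with the
requested correlation and multiplied by a per-feature sign common to both
arms; a common sign flip leaves the correlation between the vectors
unchanged, so the realised correlation tracks `congruence_rho` without
bias. GOP effects default to empty — the generator's null arm — and a
class-signed template (`caloric_restriction_template()`) encodes the
caloric-restriction signature: acylglycerols down, fatty acids and
acylcarnitines up, phospho- and lysophospholipids down, ketones and TCA
intermediates up, very-long-chain (≥ C24) fatty species flipped to down,
with RYGB-only decreases in BCAAs, tyrosine and caffeine metabolites and an
increase in TMAO. Template magnitudes are keyed on the terminal acyl chain
so that a fatty acid and the complex lipids it matches respond with a
common magnitude (chain-specific mobilization); the synthetic annotation
panel carries very-long chains in the fatty acid, acylcarnitine, ceramide
and sphingomyelin families but caps phospholipid and lysophospholipid
chains at C22, mirroring typical preannotated panel composition.

Ground-truth effects are realised from the effect specification's own seed,
separate from the measurement-noise seed, so studies simulated under
different noise seeds share identical true effects — which is what makes
seed-replicated operating-characteristic checks meaningful.

What the generator does *not* emulate: batch and run-order drift,
heteroscedastic or feature-correlated noise beyond the shared subject
intercept, missingness mechanisms, non-normal intensity distributions, and
platform-specific artefacts. Passing tests therefore demonstrate
correctness of the statistical machinery under the declared model, not
robustness to every failure mode of real spectra.

## Numerical and validation choices

* Intensities must be strictly positive; zeros are hard errors, never
  imputed. Optional `impute_half_min()` fills missing (not zero) values at
  half the per-feature minimum.
* The sample table, not matrix row order, is authoritative; rows are
  canonicalised by (subject, timepoint, biofluid) on construction.
* CSV round trips write values at `%.17g` so `read_study(write_study(x))`
  is bit-exact.
* All pipeline randomness flows from one root seed through fixed per-stage
  offsets; two runs with the same configuration and seed are byte-identical,
  and every output file carries the configuration hash and seed in a header
  comment.
* Validation problem sizes: the operating-characteristic checks run 100
  replicates of 500-feature studies at the cohort's arm sizes for FDR
  control, PCA separation and congruence recovery; 1000 features for
  parameter recovery and CI coverage; $B = 200$ permutations for the PLS
  validity and selection checks (100 seeds at 500 features); and
  ≤ 20-subject fixtures for the dense-GLS oracle comparisons. These sizes
  make the whole suite run in minutes on a single core while keeping
  Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Only a single random intercept is supported — no crossed or nested random
  effects, and only two timepoints.
* The power simulation estimates power against the *observed* effect
  profile of the study, as any resampling scheme must; under a true null it
  is conservative by design.
* Lipid shorthand parsing covers the FA/CAR/TG/PC/PE/LPA/LPC/LPE/LPI/Cer/SM
  grammar with `d`-prefixed sphingoid bases; ether lipids, plasmalogens and
  isomer-level annotations are out of scope, and unparseable names are kept
  (without a descriptor) rather than rejected.
* Whether fold-change congruence should use annotated features only is a
  genuine open choice; the default uses every feature in the grouping, and
  the platform-grouping argument provides the restriction when wanted.
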