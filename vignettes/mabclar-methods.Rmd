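---
title: "Subtyping convergence in ER-negative breast cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtyping convergence in ER-negative breast cancer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabclar)
```

## The scientific problem

Estrogen-receptor-negative breast cancers harbour an androgen-receptor-driven
luminal subgroup that two independent transcriptomic classifiers call by
different names: the TNBCtype family labels it **LAR** (luminal androgen
receptor) inside triple-negative disease, while the CIT-style six-class
scheme (lumA/lumB/lumC/mApo/basL/normL) labels it **mApo / MABC** (molecular
apocrine) across all ER-negative tumours, HER2-positive cases included.
`mabclar` implements the analysis toolkit for studying whether these two
calls converge on one molecular entity, and for calling that entity in
practice with a compact four-gene AR-target signature (*AR*, *FOXA1*,
*SPDEF*, *TFF3*) on either RNA-seq or RT-qPCR from FFPE material.

Because the motivating cohorts (METABRIC, TCGA, FUSCC and institutional
series) cannot be redistributed, the package ships a first-class synthetic
cohort generator that reproduces the latent structure those analyses assume,
with full ground truth, so that every pipeline stage can be validated by
parameter recovery.

## Correlation-to-centroid subtyping

`train_centroids()` / `classify_to_centroids()` implement the generic
machinery shared by the six-class and TNBC-type schemes:

1. expression is taken to log2(x + 1);
2. each signature gene is z-scored using mean and sd over the *training*
   samples; these statistics are frozen into the model and reused verbatim at
   classification time, so no test-set information leaks into the
   standardization;
3. a subtype centroid is the mean standardized profile of its training
   samples, column-centred (Pearson correlation is invariant to that
   centring, which merely fixes the centroid space at zero mean);
4. a sample's score for a subtype is the Pearson (optionally Spearman)
   correlation between its standardized signature vector and the centroid;
   the call is the argmax, with ties broken lexicographically by subtype name
   so that results are order-independent and reproducible;
5. a best correlation below `unclassified_threshold` (default 0.15) yields
   `UNCLASSIFIED`. The published classifiers acknowledge an unclassified
   state but publish no rule, so the threshold is an explicit, recorded
   parameter.

Correlation rather than Euclidean distance is used because the TNBC-type
family reports correlation coefficients, and because correlation makes the
classifier invariant to per-sample affine rescaling of the standardized
vector — a robustness the tests assert directly.

`convert_tnbc6_to_4()` maps six-subtype calls (BL1, BL2, M, LAR, IM, MSL)
to the four-subtype scheme by retaining the intrinsic subtype with the
highest coefficient; IM and MSL were retired from the original scheme after
they were shown to track infiltrating immune and stromal signal rather than
tumour-intrinsic biology, so reassignment to the best intrinsic centroid is
exactly the published revision. `second_best_subtype()` supports the
runner-up analysis used to show that discordant MABC tumours sit next to the
LAR centroid.

The published centroid weight matrices themselves are not redistributable;
the package therefore trains centroids from labelled data rather than
shipping them. This preserves every behaviour the analyses rely on
(scores, conversion, runner-up structure) while remaining self-contained.

## Concordance and diagnostics

`compute_overlap()` partitions a denominator population into MABC-LAR (both
positive), MABC-nonLAR, LAR-nonMABC and neither — the three-subgroup
structure of the convergence analysis — and the partition property (disjoint,
exhaustive) is property-tested on random call tables. `evaluate_confusion()`
excludes samples the gold standard could not classify *before* counting,
treats predicted `UNCLASSIFIED` as negative, and reports
sensitivity/specificity as percentages. An empty gold margin yields an
explicit `NA`, never a silent zero.

All printed proportions use **half-up rounding to one decimal**
(`proportion_pct()`): base R's banker's rounding would turn 15/16 into an
ambiguous 93.7/93.8 depending on binary representation, whereas the half-up
convention reproduces the published style of count ratios (56/83 = 67.5,
15/16 = 93.8). Chi-squared comparisons go through `chi2_proportions()`, a
thin wrapper over the standard test with Yates continuity correction ON by
default for 2x2 tables (the convention of the analysis environments these
studies use); the flag is exposed because the correction is a choice, not a
law. Welch's t-test is the default for continuous comparisons — a deliberate
deviation from the classical pooled "Student" wording, because Welch is the
robust modern default — and the pooled variant is one argument away for
strict replication.

## Pathway-activation flags

`flag_pathway_activation()` reduces an alteration table to per-sample
PI3K/AKT/mTOR activation: oncogenic mutation or amplification of *PIK3CA* or
*AKT1*, loss-of-function mutation or homozygous deletion of *PTEN*
(heterozygous loss never qualifies), or *ERBB2* amplification — with
low-level *ERBB2* gains explicitly non-qualifying, since gain and
amplification are biologically distinct copy-number states. Pathogenicity is
an input column (as produced by knowledge bases such as OncoKB), not a
lookup: the package never phones home. The four-way category
(erbb2_only / pi3k_only / both / none) supports mutually-exclusive versus
co-occurring tabulation, and is verified against a brute-force
set-membership oracle on random tables.

## Microenvironment scoring

`population_score()` is a deliberately small abstraction of marker-based
deconvolution tools: the mean of log2(x + 1) over a population's marker
genes (>= 3 required). It preserves every comparison the convergence
analysis makes (fibroblast enrichment in MABC-nonLAR, immune signal in
LAR-nonMABC) while keeping marker lists configurable, because the cited
tool's exact marker matrix is an external resource. Scores are comparable
between samples within a population, not across populations.
`cellularity_enrichment()` compares high-cellularity (> 70% tumour cell
content) proportions between groups, excluding and reporting
unknown-cellularity samples.

## The four-gene signature

**RT-qPCR form.** `relative_quantity()` implements 2^-dCT with replicate
averaging against a reference gene (*RPL37A*, validated for FFPE material);
duplicate discordance above 0.5 cycles is flagged but not rejected, since
the assay protocol runs duplicates without a published rejection rule. An
`Undetermined` well is carried as an explicit sentinel; a target gene that is
Undetermined in every replicate is treated as unexpressed (relative quantity
0 — the conservative reading; a max-CT substitution is available), while an
Undetermined *reference* is an error because no quantity is then defined.
`classify_qpcr()` applies the vote rule: MABC/LAR when at least 3 of the 4
targets strictly exceed their cut-offs (default *AR* > 5.0, *FOXA1* > 24,
*SPDEF* > 3, *TFF3* > 1.0 — the validated assay values; strict inequality
matches the published "greater-than" notation, so boundary values never
count). The published cut-offs are treated as free parameters in relative-
quantity units: their absolute scale is assay-calibration-specific, so
refitting on a local discovery set is the supported workflow.

**Cut-off derivation.** `select_cutoff_roc()` scans all midpoints between
consecutive sorted unique values plus two outer sentinels and returns the
cut-off maximising Youden J = sensitivity + specificity - 1, breaking ties
toward the larger cut-off (favouring specificity — for a rule-in diagnostic
signature the costlier error is a false positive). The ROC tool used to
derive the published cut-offs does not document its operating-point
criterion; Youden J is the standard default and the choice is isolated
behind this single function. The implementation is verified against an
exhaustive threshold scan and cross-checked against an independent ROC
library where available.

**RNA-seq form.** `make_rnaseq_features()` builds log2 ratios to *TBP* (a
pseudo-quantity of 0.01 guards zero FPKM without distorting expressed
genes; features are library-size invariant because the normaliser cancels),
and `train_forest()`/`predict_forest()` wrap a seeded random forest
(500 trees by default, sqrt-p features per split, unlimited depth —
conventional defaults, all configurable). The forest here is a validation
vehicle for the four features, not a novel statistic, so the package uses
the field-standard implementation and freezes its seed into the model for
bitwise reproducibility.

## The synthetic cohort generator

`generate_cohort()` emulates an ER-negative cohort with six latent classes:

| class | purity Beta | immune share | tumour-profile effects (log2) |
|---|---|---|---|
| MABC_core | (18, 3) | 0.50 | ar_targets +3 |
| MABC_HER2 | (18, 3) | 0.50 | ar_targets +3, erbb2_amplicon +2.5 |
| LAR_immune | (8, 6) | 0.85 | ar_targets +3 |
| MABC_stromal | (8, 6) | 0.15 | ar_targets +3 |
| basal | (12, 4) | 0.50 | basal_markers +2.5 |
| luminalC_like | (12, 4) | 0.50 | ar_targets +1, esr1_module +1.5 |

Per sample, log2 expression is a purity-weighted mixture of the class
tumour profile with immune and fibroblast compartment profiles (markers
shifted +4 log2), plus Normal(0, 0.5) noise, exponentiated to the linear
scale. Per-gene baselines are drawn once per cohort from Normal(5, 1) in
log2 space — no baseline distribution is published for the motivating
cohorts, so any positive-scale choice works and this one is recorded.
Housekeeping genes (*TBP*, *RPL37A*) never receive a class effect. The
default class mix (30/30/10/10/150/20) keeps LAR-truth prevalence near one
quarter of the TNBC-like subset, matching the published subtype landscape.
The luminalC_like class expresses the ESR1 module at an intermediate level
and the AR targets weakly, emulating the low-ESR1 luminal-C boundary tumours
that blur the MABC/lumC border; it is the designed source of false
positives. The immune- and fibroblast-rich MABC classes (lower purity,
skewed admixture) are the designed sources of false negatives — their
AR-target signal is diluted by the microenvironment exactly as in bulk
profiling of infiltrated tumours.

qPCR simulation inverts 2^-dCT: ct = ct_ref_base - log2(expr_g / expr_ref)
plus Normal(0, 0.25) per replicate (2 replicates), so zero-noise CTs
reproduce expression ratios exactly and the replicate-mean dCT noise has the
closed-form sd s·sqrt(2/n). PCR efficiencies are modelled as exactly 2 by
default because the emulated assay validates near-unit efficiencies
(1.01-1.07) on standard curves before using plain 2^-dCT; a strict mode
jitters a per-gene amplification factor inside that validated range.
Alterations are planted as independent per-sample Bernoulli events at
class-specific rates (ERBB2 amplification 0.95 in MABC_HER2, 0.10 in
LAR_immune, rare elsewhere), and HER2 IHC is positive exactly where an
ERBB2 amplification was planted.

**What the generator does not emulate:** batch and platform effects,
copy-number-driven expression coupling beyond the ERBB2 amplicon panel,
correlated noise between genes, read-level sampling, and intra-tumoral
subclonal mixtures. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under the stated generative model, not that the
signature's published operating characteristics transfer to any particular
real cohort.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery analyses at the
sizes the analyses were designed around: 100 samples per latent class for
centroid recovery (50/50 train/test split), a 300-sample cohort at ~35%
MABC/LAR-truth prevalence for the qPCR fit-then-evaluate loop, 1000 samples
for binomial rate recovery, and 2000 null replicates for Welch type-I
calibration. All randomized steps take explicit seeds; identical config and
seed reproduce cohorts bitwise. Ties are broken deterministically
(lexicographic for subtypes, larger-cut-off for ROC). Degenerate inputs —
empty cohorts, zero marginals, single-class training labels, missing
reference genes — raise errors rather than propagating NaN.

## Known limitations

- Cut-off recovery for the qPCR signature is sensitive to the purity
  distribution of the discordant classes: strongly diluted MABC/LAR samples
  can fall below fitted cut-offs, which is the same mechanism that produces
  discordant calls in real bulk data. The vote rule (3 of 4) buys back most,
  not all, of that loss.
- The centroid machinery models the published classifiers' *behaviour*
  (scores, conversion, runner-up analysis) but not their exact published
  weight matrices or gene lists, which are not redistributable.
- The microenvironment scores are marker means, not the cited
  deconvolution tool's full marker matrix; absolute score levels are not
  comparable across populations.
- Two published percentages are internally inconsistent with their printed
  counts (81.1 vs 18/22, 95.0 vs 112/118); the package always reports the
  value recomputed from counts.
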