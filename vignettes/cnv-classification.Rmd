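---
title: "Classifying the clinical significance of copy number variants"
author: "cnvclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the clinical significance of copy number variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Copy number variants (CNVs) — deletions and duplications of at least 50 bp —
are reliably detected by genome sequencing but hard to interpret: most calls
land in the uncertain zone between clearly benign polymorphism and clearly
pathogenic dosage change. `cnvclass` implements a complete workbench for
building, explaining and benchmarking three-class (benign / VUS /
pathogenic) CNV significance classifiers from flat annotation files:
feature annotation, ClinVar-style training-set curation, per-type model
selection and calibration, Shapley-value explanations, and a one-vs-rest
evaluation harness, plus a synthetic annotation-bundle generator so the
whole stack can be exercised and validated without any external downloads.

## The feature model

Each CNV is summarized by 17 features in six groups (one-hot groups expand
to one column per category):

* **Genomic position.** Distance in bp from the CNV to the centromere
  (nearest CNV boundary: end on the P arm, start on the Q arm) and to the
  telomere (farthest boundary), both clamped at zero. Arm assignment uses
  the CNV midpoint; a CNV centered inside the centromere gets centromere
  distance 0 and the nearer arm's telomere distance, since the per-arm
  formulas only apply off-centromere.
* **Composition.** GC fraction of the spanned sequence (case-insensitive,
  ambiguous bases excluded from the denominator) and total bp length.
* **Functional annotation.** Counts of overlapping genes (≥ 1 shared bp),
  diseases (summed over overlapping genes; a disease shared by two hit
  genes counts twice, so multi-gene hits are distinguished — the
  alternative, deduplicating across genes, would blur exactly the events
  the count exists to flag), exons (each padded ±10 bp to take in
  canonical splice regions), promoters (the 1,000 bp immediately upstream
  of each TSS, strand-aware), and pathogenic/likely-pathogenic short
  variant positions inside the CNV.
* **Population frequency.** The highest allele frequency across
  populations among database SV records of the same type (DEL/DUP) with at
  least 50% reciprocal overlap; 0 if none qualifies.
* **Conservation.** Per-base phyloP and phastCons scores are noisy and
  their raw extremes correlate with CNV size, so each base gets a centered
  moving average (default window 1,001 bp, odd so the window is
  symmetric; configurable) and the feature is the maximum of the smoothed
  curve inside the CNV. Bases without scores are excluded from each mean;
  a CNV with no scores in reach returns a sentinel 0 with a warning.
  `window = 1` degenerates to the raw in-interval maximum.
* **Dosage sensitivity.** Haploinsufficiency (HI) and triplosensitivity
  (TS) categorical evidence codes of overlapping curated regions are
  one-hot encoded and summed across regions; the minimum HI index, maximum
  pLI and minimum LOEUF among overlapping regions summarize gene-level
  loss intolerance. A CNV overlapping no region gets sentinels pointing in
  the loss-tolerant direction (HI index 100, pLI 0, LOEUF 2.0) — absence
  of curated evidence should not look like evidence of sensitivity. All
  sentinels are configurable.

Six right-skewed count features (genes, diseases, exons, promoters,
pathogenic SNVs, bp length) are mapped through `log1p` — natural log of
1 + x, finite at zero counts — and every feature is then min-max scaled
with statistics fitted on the training rows only. At prediction time,
values outside the training range clamp to [0, 1]; scaling behavior beyond
the fitted range is otherwise undefined and clamping prevents test-time
information from leaking into the transform.

Internally all coordinates are BED-convention 0-based half-open; VCF input
(1-based inclusive with an `END` tag) is converted at the reader boundary.
Abutting intervals do not overlap. Chromosome names are normalized
(leading `chr` stripped, `X`/`Y`/`MT` canonicalized) because resource
files mix dialects.

## Curation rules

Labeled variant tables are filtered in a fixed order: (1) drop records
that are not deletions or duplications; (2) collapse submitted labels —
any pathogenic or likely-pathogenic designation wins, otherwise any VUS
designation, otherwise all-benign/likely-benign; records that fit none of
these (e.g. "risk factor") are dropped as ambiguous; (3) among records
with identical (chromosome, start, end, type), keep one representative
when labels agree and drop the whole group when they conflict; (4) drop
records under 50 bp; (5) optionally drop records whose coordinates and
type exactly match a training-set entry (leakage guard). The duplicate key
includes the CNV type so a deletion is never merged with a co-located
duplication, and the group representative is chosen by record id so the
kept set is independent of input row order. The report tallies every rule
and conserves counts (input = kept + removed).

## Training, selection and calibration

Deletions and duplications get independent models: the same genomic lesion
has opposite dosage consequences in the two directions, and the feature
distributions differ. `cnv_classifier()` is the single fitting entry
point. It fits the feature transformer on the training rows, ranks a
pluggable architecture roster by stratified 5-fold cross-validated macro
F1 at default hyperparameters, runs a seeded randomized search (spaces
shipped in `inst/config/hyperparameters.yaml`) on the winner, and
calibrates: out-of-fold class probabilities are isotonically regressed
against the class indicators, one map per class, and calibrated scores are
renormalized onto the simplex. Folds are stratified so every class is
present in every fold — a requirement for both macro F1 and per-class
isotonic fits. Prediction returns the three calibrated probabilities and
the argmax label, with exact ties broken pathogenic > VUS > benign: when
the model genuinely cannot separate, the clinically conservative call is
the one that forces review.

The default roster holds eight common learners (random forest, gradient
boosted trees, CART, multinomial logistic, elastic-net multinomial, RBF
SVM, Gaussian naive Bayes, LDA). The selection machinery, not the roster
census, is the contract: any roster subset or extension with the same
adapter interface plugs in. The isotonic maps use a weighted
pool-adjacent-violators fit on tie-aggregated scores (base R's `isoreg`
is unweighted) with linear interpolation between knots and clamping at
the ends; one-vs-rest calibration with renormalization is used because
per-class monotone maps preserve each class's ranking — the property the
curve metrics measure — while a joint multinomial recalibration would
not decompose per class.

Everything is seeded: fold assignment, hyperparameter draws, and each
estimator's internal randomness, so a fixed seed reproduces model
metadata and predictions bit for bit.

## Explanations

`attribute()` produces per-class Shapley values on the pre-calibration
estimator output (calibration is a monotone per-class rescaling, so
attribution before it explains the ranking signal; attributing through
the isotonic step would fold calibration-set artifacts into per-feature
credit). For the random-forest architecture the package computes exact
path-dependent TreeSHAP — attributions satisfy local accuracy (base +
sum = model output) to machine precision — over a generic tree-ensemble
representation reconstructed from the fitted forest, with node covers
re-derived by routing the training matrix through the recorded splits.
Any other estimator falls back to seeded permutation sampling (antithetic
permutation pairs, default 256, against a fixed background set), which is
exact in the local-accuracy sense relative to the background mean.
Beeswarm and per-variant force plots export as static PNG/SVG, each with
a machine-readable TSV twin holding every plotted value, so downstream
checks parse tables rather than pixels.

## Evaluation harness

For each class, CNVs are ranked by the class score and swept over all
distinct thresholds (ties grouped): ROC AUC uses the trapezoid rule,
identical to Mann–Whitney pair counting with ties at half weight; PR AUC
uses the step-wise estimator with precision held right-continuous, which
avoids the optimism of linear interpolation between PR points. Binary
comparator tools that emit only a pathogenic score get a benign score as
its complement (1 − score); tools without continuous scores are excluded
from curve metrics but still enter the multi-class summary, after mapping
likely-pathogenic → pathogenic and likely-benign → benign. The
multi-class summary reports per-class one-vs-rest F1, macro (unweighted
mean) F1, accuracy, and the confusion matrix raw and row-normalized by
the actual-label totals.

## The synthetic workbench

`generate_bundle()` writes a complete miniature annotation bundle — by
default three 300 kb chromosomes with blockwise-varying GC, 45 genes with
2–8 exons and strand-assigned TSSs, a disease–gene map, dosage regions
over 35% of genes with concordant HI/TS categories and gene metrics,
pathogenic SNVs clustered in the exons of haploinsufficient genes,
conservation tracks with bumps over exons, and 120 SV frequency records a
third of which are common variants in a reserved gene desert. These sizes
keep a full simulate–train–evaluate cycle in the tens of seconds on one
core while leaving every feature with non-degenerate variation; they are
deliberately far from human genome scale, and allele frequencies make no
population-genetic claims.

`generate_labeled_cnvs()` draws CNVs to exact per-class quotas under a
deterministic rule built from in-scope features only: pathogenic iff the
CNV overlaps an HI category-3 region or spans ≥ τ exons at popmax < φ;
benign iff it is shorter than λ, matches a common SV record (popmax ≥ φ)
and touches no exon; VUS otherwise (defaults τ = 3, φ = 0.05, λ = 2,000,
recorded in the manifest). Each label then flips to a uniformly chosen
other class with probability ε; the pre-noise rule label is kept as
ground truth. Bundle and CNV sets take separate seeds so train and test
fixtures share annotations but never variants.

Because the rule uses only extracted features, a correct pipeline must
recover it: trained on one seeded fixture and evaluated on a disjoint one
the workbench reaches macro F1 ≥ 0.95, and at ε = 0.1 the observed
disagreement with the rule concentrates at 10%. Passing these checks
demonstrates that annotation, transformation, selection, calibration and
prediction compose correctly; it does not certify accuracy on real
ClinVar/DECIPHER data, whose label noise, class imbalance, assembly
artifacts and feature correlations the generator does not emulate.

## Numerical and degenerate-input choices

* Interval arithmetic is subtraction-only on half-open coordinates;
  overlap of intervals on different chromosomes is 0, never an error.
* A constant training column min-max scales to 0 rather than NaN.
* An all-ambiguous (N) sequence yields GC 0 with a warning.
* Conservation smoothing excludes missing bases from each window mean; a
  CNV with no scores in reach returns the sentinel with a warning.
* Isotonic calibrators degenerate to a constant map when the raw scores
  are all tied; renormalization guards against an all-zero calibrated row
  by falling back to the uniform distribution.
* Architecture CV scores that fail to fit (e.g. LDA on a zero-variance
  fold) score as missing and rank last rather than aborting the search.
* Dosage tables may carry unknown category codes: by default they join
  the vocabulary with a warning; strict mode makes them errors.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at 150
CNVs per class for training and testing (per-type models, 5-fold CV,
3-architecture roster, 25 hyperparameter draws) and measure the
label-noise contract at n = 3,000; the interval, smoothing and ROC
oracles run on 1,000+, 100 and 500+ randomized instances respectively.
These sizes were chosen so each check is statistically meaningful for the
property it tests while the whole suite stays desk-scale.

## Known limitations

* One assembly: no liftOver; all resources must share coordinates.
* The exact-TreeSHAP route currently covers the random-forest
  architecture; boosted trees attribute via permutation sampling.
* bigWig conservation input is out of scope; tracks load from
  bedGraph/wiggle text.
* The synthetic generator validates mechanics, not clinical performance;
  models intended for real interpretation must be retrained and validated
  on real labeled CNVs.
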