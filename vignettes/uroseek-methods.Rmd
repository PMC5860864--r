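---
title: "Urinary-cell mutation and aneuploidy calling: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urinary-cell mutation and aneuploidy calling: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical model behind each of the three urine assays, how the
decision thresholds are calibrated on healthy controls, what the
synthetic-cohort generator does and does not emulate, and the numerical
choices made where the method leaves room for them.

# The problem

Urothelial tumors — bladder cancer and upper-tract urothelial carcinoma —
shed cells directly into urine. Sequencing the DNA of those cells can
reveal two orthogonal classes of somatic alteration long before a tumor
is clinically evident: driver point mutations (here, regions of ten genes
amplified in one multiplex PCR plus the GC-rich TERT-promoter hotspots
g.1295228 / g.1295250 / g.1295242 in a separate singleplex PCR) and
chromosome-arm-level copy-number imbalance. The analytical challenge is
that true mutant fractions in urine DNA run from well under 1% up to 80%,
while PCR and sequencing errors occur at position-specific rates of
roughly 10^-4 — so calling requires molecular barcoding, per-position
empirical nulls, and thresholds calibrated directly on healthy controls.

# Mutation calling

## Counting and the statistic

Reads sharing a unique molecular identifier (UID) are collapsed into one
UID family, representing one template molecule. The mutant allele
frequency at a queried position is `MAF = mutant families / total
families`, a dimensionless template-level fraction. Each sample is
measured in two independent PCR wells per assay; a mutation is only ever
called when both wells show it.

Scoring a candidate mutation proceeds in four steps:

1. **Mutation-specific normalization.** `score = (MAF − location) /
   scale`, with location the median and scale the MAD (× 1.4826) of that
   mutation's MAFs across the control WBC panel. Robust statistics are
   used deliberately: the control panel itself could contain rare real
   signal or artifacts, and the caller is searching for exactly the kind
   of contamination that would corrupt a mean/SD. The scale is floored at
   `max(MAD·1.4826, 0.2/n, 10^-6)` (n = control observations for the
   mutation) so that positions with all-zero controls cannot produce
   infinite scores.
2. **Empirical p-value.** One-sided, add-one smoothed:
   `p = (1 + #{null ≥ score}) / (N + 1)` against the pooled null — the
   sorted normalized control values of *all* mutations and both control
   wells. Smoothing keeps p strictly positive, so downstream z-scores are
   finite; the minimum attainable p is `1/(N+1)` with N ≈ 23,700 under
   the default panel. The pooled null uses normalized (not raw) values:
   pooling raw MAFs would re-introduce the cross-position rate
   heterogeneity the normalization removes.
3. **UID-weighted Stouffer combination.** `z_i = Φ⁻¹(1 − p_i)` per well,
   combined as `Z = (w₁z₁ + w₂z₂)/√(w₁² + w₂²)`. The default weight is
   `w_i = √UID_i` — the variance of a proportion scales as `1/n`, so
   `√n` is the canonical information weight. A literal `w_i = UID_i`
   mode is available (`weighting = "linear"`), since "weighted by the
   number of UIDs" admits both readings; the choice barely matters when
   the two wells have comparable depth.
4. **Two criteria.** A both-well candidate is positive when *either* the
   difference statistic (two-well average MAF minus the per-mutation
   control maximum) exceeds `t_diff`, *or* `Z > t_z`. The difference
   criterion catches high-MAF mutations regardless of the shape of the
   null; the Stouffer criterion catches low-MAF mutations far out in a
   tight null.

Candidates require at least 2 mutant UID families in each well
(`min_mutant_families`, configurable). This is plumbing, not statistics:
it prevents tens of thousands of p-value computations on singleton
errors, and no singleton could survive the thresholds anyway.

## Threshold calibration

Both thresholds come from controls, not from tuning:

* `t_diff` is the highest MAF observed anywhere in the 188-sample control
  WBC panel — a global threshold, while the subtracted control maximum in
  the statistic itself is per-mutation. Both are implemented literally.
* `t_z` is set by scoring the 188 healthy-control *urines* end-to-end
  with thresholds disabled and taking the second-largest per-sample
  maximum Z. With positivity defined as strictly greater, exactly one
  control urine exceeds it — the single allowed false positive that fixes
  the operating point of the Stouffer criterion.

This construction makes "one positive in 188 controls" true by design on
the calibration panel; the meaningful check, run in the test suite, is
that *independent* 188-control panels drawn from the same error process
average well under 3 positives.

## The identity check

Thirty-one common SNPs on chromosomes 10 and 20 (26 primers in the wet
assay) guard against sample swaps between paired urine and tumor DNA.
Concordance is the fraction of matching genotypes among SNPs called in
both samples; a pair is flagged below 0.90 concordance or under 10
informative SNPs. The 0.90 cutoff is a package choice (no published
value): unrelated individuals share common-SNP genotypes at roughly
40–60%, identical samples above 95% even with genotyping error, so any
cutoff in the wide gap between works and 0.90 is conservative.

# Aneuploidy

## Arm z-scores

The repeat-amplicon assay counts reads at loci spread over the 39
non-acrocentric autosomal arms (all q arms plus the p arms of the
non-acrocentric chromosomes). Locus counts are converted to shares of
total depth — making every downstream quantity scale-free — summed per
arm, and standardized against the per-arm mean and SD of a euploid
control panel. The package default is a down-scaled uniform map of 100
loci per arm (3,900 total, configurable; the full-scale assay has
~38,000 unevenly distributed loci, and a real locus-to-arm map can be
supplied).

## Training set and classifier

Mirroring the training design of the original assay, the classifier is
trained on
3,150 synthetic aneuploid samples at low neoplastic fractions plus 677
euploid samples. Each is a *parametric resample* of the euploid control
panel: one multinomial draw around the pooled locus proportions at a
panel-sampled depth. An earlier implementation redrew counts from a
single parent profile; that doubles the multinomial noise relative to
both the euploid reference and any real test sample and distorted the
score calibration, so the pooled form is used. Aneuploid samples get 1–5
random arm events injected before the draw, each scaling the arm's
expected share by `(1 ± f/2)` for a single-copy gain/loss at neoplastic
fraction `f ~ U(0.005, 0.10)`; every synthetic row records its injected
arms and fraction.

The classifier is a radial-basis SVM (`e1071`, C = 1, features scaled
internally; linear kernel available) over the 39 arm z-scores. The
genome-wide aneuploidy score in [0, 1] is the SVM's cross-validated
Platt probability of the aneuploid class. The published score's exact
construction lives in an external method; this is a faithful
re-implementation surface, not a byte-level reproduction — the decision
rule, training design and threshold follow the original assay.

A sample is positive iff `score > 0.7` (strict) **and** at least one arm
is called gained or lost (`|z|` above the arm threshold). The arm
threshold is set at the 99th percentile of `|z|` over euploid training
arms — a 1% per-arm euploid call rate; no published arm-level cutoff
exists, and 1% keeps the expected number of spurious arm calls per
euploid sample (~0.4) comfortably below one while leaving genuine
single-arm events callable.

# The synthetic-cohort generator

The generator is the package's stand-in for real patient cohorts, for
which no per-sample data are publicly available: all pipeline
calibration and testing runs on cohorts whose truth is known by
construction.

**What it emulates, with the original UroSEEK study design as the
defaults:**

* 188 healthy-control urines and 188 control WBC panels (plus a separate
  94-sample WBC set for technical-specificity checks), each assayed in
  two wells per assay.
* UID-family depths log-normal with median 10,000 per amplicon per well
  (`uid_depth_meanlog/sdlog`).
* A two-level background error process: each queried position gets a
  fixed mean substitution rate (Gamma across positions, mean 10^-4,
  shape 2 — the cross-position heterogeneity that motivates per-mutation
  normalization), and each observation mixes that rate with a Gamma of
  shape 20 before a Poisson draw (~1.5× Poisson variance).
* Case urines: tumors carry at least one queried mutation with
  probability 0.95; mutated tumors shed assay-detectable DNA with
  probability 0.91; planted urine MAFs are log-normal with median 8%
  (multiplex) / 6% (TERT), truncated to [0.003, 0.8]. The two-stage
  tumor-then-shedding structure makes both false-negative modes —
  insufficient cells in urine versus no queried mutation in the tumor —
  arise naturally, in roughly the 62/38 proportion reported for such
  tests (0.95 and 0.91 give an expected 63/37 split among false
  negatives).
* Aneuploidy: 1–5 arm events per aneuploid tumor with the recurrent arms
  5q, 8q and 9p upweighted (canonical directions 8q/5q gain, 9p loss),
  at neoplastic fractions log-uniform over [0.002, 0.30]; locus counts
  multinomial with arm expectations scaled by `(1 ± nf/2)`.
* Cohort designs of 570 (175 cancers), 56 (all cancers) and 322 (187
  recurrences) patients, with exact case counts; cytology availability
  0.61 with category frequencies chosen to match the reported positive
  rates among cases; diagnosis delays Gamma-distributed (shape 0.55,
  scale 130 days) so mean lead time lands near 2–3 months with a small
  tail beyond one year.

**Parameters calibrated to the assay's reported detection limits.** Two
generator defaults have no published value and were set so the simulated
assays reproduce the two detection limits reported for the real ones,
rather than by convenience:

* the aneuploidy-assay depth (log-normal median 4×10^7 counts over 3,900
  loci) places a 1% neoplastic-fraction single-arm event at ~5 SD of
  arm-share noise, matching the reported ~1% neoplastic-cell floor for
  reliable aneuploidy detection;
* the background overdispersion (shape 20) keeps the empirical-null
  tails compatible with the assays' reported ability to detect mutant
  fractions down to 0.03% at 100,000-family depth.

Heavier overdispersion (e.g. shape 5) or shallower locus depth makes
those two reported limits unattainable in simulation, which is how the
defaults were pinned down.

**What it does not emulate** — and hence what passing tests do and do not
show about real data: no read-level errors or UID collapsing (input is
the family-count table), no PCR chemistry or GC bias, no clonal
hematopoiesis or age-related mosaicism in controls, no intratumoral
heterogeneity or private urine clones (urine mutations are always a
subset of tumor mutations, so simulated urine–tumor concordance is 100%
by construction), no sub-arm or focal copy-number events, and no
clinical covariates beyond labels. Performance numbers on synthetic
cohorts validate the *pipeline's calibration logic*, not the clinical
accuracy of the assay.

# Numerical choices and degenerate inputs

* All randomness flows from one integer seed through fixed per-purpose
  streams; identical configurations give bit-identical outputs, including
  written files. Per-position error rates and per-locus amplification
  weights are drawn once per configuration and shared by every sample, so
  "the assay" is constant within a study.
* MAF with zero total families is an error (the well is excluded and
  reported), never 0/0 = 0.
* Zero-denominator metrics (e.g. specificity of an all-case cohort) are
  reported `NA` with an `undefined` flag, never silently zeroed.
* Months are days / 30.44 throughout.
* Confidence intervals default to modified Wald (Agresti–Coull, z = 1.96):
  `p̃ = (x + z²/2)/(n + z²)`, half-width `z√(p̃(1−p̃)/(n+z²))`, clipped to
  [0, 1]. An exact Clopper–Pearson mode exists but is not the default;
  the modified-Wald form is the one whose printed intervals the test
  suite reproduces digit-for-digit.
* Equal per-sample maximum Z values during calibration would make the
  "exactly one" property a "at least one"; with continuous MAFs ties have
  probability zero and the test suite asserts the exact count.
* Reference and model persist as versioned JSON (the fitted SVM as a
  serialized payload inside the JSON archive); reloading reproduces
  scores to 10^-9 or better.

# Problem sizes

The test suite runs the full calibration design (188 + 188 controls,
63-position panel, 3,900 loci, 3,150 + 677 training samples) and
completes in about half a minute; held-out specificity uses 20
independent 188-control panels, detection curves 200 replicates per
fraction, and parameter-recovery checks ≥1,000 wells. The analysis
scripts simulate all three cohorts (948 patients) in a few minutes.
These sizes were chosen as the smallest at which the Monte-Carlo bands
in the tests are meaningful.

# Known limitations

* The genome-wide score is a calibrated SVM probability; absolute score
  values are not comparable to the external reference implementation,
  only the decision behavior is.
* The uniform 100-loci-per-arm map understates the arm-to-arm depth
  imbalance of the real repeat assay; supply a real `ArmMap` for
  realistic per-arm power.
* The generator's cytology is a label process, not an image-based
  diagnosis; combined-test numbers on synthetic cohorts inherit whatever
  category frequencies are configured.
* Indels and complex variants are out of scope; the caller is SNV-only,
  as is the spectrum summary.
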