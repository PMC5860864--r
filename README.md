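# uroseek

Non-invasive detection of urothelial cancer (bladder and upper-tract
urothelial carcinoma) from the DNA of cells shed into urine. This package
implements the full computational pipeline of a UroSEEK-style urine test
— three massively parallel sequencing assays combined by an OR rule —
together with a synthetic-cohort generator that reproduces the
statistical structure the pipeline assumes, so that every stage can be
calibrated, exercised and evaluated end to end without access to patient
data.

## Who it is for

Computational biologists building or benchmarking liquid-biopsy mutation
callers from UID (unique molecular identifier) family count data, and
biostatisticians evaluating urine-based diagnostic panels.

## The method

**Mutation calling (multiplex 10-gene assay and singleplex TERT-promoter
assay).** Each sample is assayed in two independent PCR wells. At a
queried position, the mutant allele frequency is the template-level
fraction

    MAF = mutant UID families / total UID families.

Because background error rates differ strongly across positions, each
observed MAF is normalized by the control distribution *for that same
mutation* (robust location and scale from a panel of 188 healthy WBC
samples), then converted to a one-sided empirical p-value against the
pooled null of all normalized control values. The two wells are combined
with a UID-weighted Stouffer Z:

    z_i = Φ⁻¹(1 − p_i),   Z = (w₁z₁ + w₂z₂) / √(w₁² + w₂²),   w_i = √UID_i.

A mutation present in both wells is called positive when either

* the *difference* criterion fires — the two-well average MAF exceeds the
  maximum control MAF for that mutation by more than `t_diff`, the highest
  MAF seen anywhere in the control WBC panel; or
* the *Stouffer* criterion fires — `Z > t_z`, with `t_z` calibrated so
  that exactly one of the 188 healthy-control urines scores positive.

**Aneuploidy.** A repeat-amplicon assay counts reads at thousands of L1
retrotransposon loci spread over the 39 non-acrocentric autosomal arms.
Per-arm representation (sum of locus shares) is standardized against a
euploid reference into 39 arm z-scores; a radial-basis SVM trained on
3,150 synthetic low-neoplastic-fraction aneuploid samples and 677 euploid
resamples maps each profile to a genome-wide aneuploidy score in [0, 1].
A sample is aneuploidy-positive when the score strictly exceeds 0.7 *and*
at least one arm is called gained or lost.

**Combination and evaluation.** A sample is UroSEEK-positive when any of
the three assays is positive; optionally the test is combined with urine
cytology (equivocal "atypical" readings do not count as positive).
Cohorts are evaluated with sensitivity/specificity/PPV/NPV and
modified-Wald (Agresti–Coull) 95% confidence intervals, lead time to
clinical diagnosis, urine–tumor mutation concordance, false-negative
attribution and mutation-spectrum summaries.

## Worked example

```r
library(uroseek)

cfg <- sim_config(seed = 1)                       # full study design
controls <- simulate_control_panels(cfg)          # 188 WBC + 188 urine controls
reference <- calibrate_from_controls(controls)
reference
#> Control reference: 63 mutations, 23688 pooled null values from 188 controls
#>   thresholds: t_diff = 0.001142 , t_z = 3.706

# one patient shedding a TP53 mutation at 8% MAF plus an 8q gain at 5%
# neoplastic fraction
patient <- simulate_patient(
  list(patient_id = "PT01",
       planted = data.frame(key = "chr17:7577065:A:T", fraction = 0.08),
       arm_events = data.frame(arm = "8q", type = "gain"),
       neoplastic_fraction = 0.05),
  cfg, seed = 99)

calls <- call_mutations(patient$mutations, reference)
subset(calls$calls, positive,
       select = c(key, gene, avg_maf, diff_stat, stouffer_z, triggering_criterion))
#>                 key gene    avg_maf  diff_stat stouffer_z triggering_criterion
#> 3 chr17:7577065:A:T TP53 0.08115225 0.08081142     5.5496                 both

training <- build_training_set(controls$urine_loci, cfg$arm_map, seed = 2)
model <- train_aneuploidy_model(training, seed = 2)
aneu <- score_aneuploidy(patient$loci, model)
sprintf("aneuploidy score %.3f, %d arm event(s), positive: %s",
        aneu$score, aneu$n_arm_events, aneu$positive)
#> "aneuploidy score 1.000, 3 arm event(s), positive: TRUE"
```

The planted 8% mutation is recovered at an average MAF of 8.1%, 0.081
above the control maximum for that position and 5.5 Stouffer SDs above
the pooled null, so both criteria fire; the 8q gain pushes the
genome-wide aneuploidy score to 1.0 with called arm events, and the
combined UroSEEK call is positive.

Diagnostic summaries use exact count arithmetic with modified-Wald
intervals — here the 2×2 table of a combined test on 339 patients with
40 cancers:

```r
diagnostic_metrics(confusion_counts(tp = 38, fp = 20, tn = 279, fn = 2))
#>        metric   x   n estimate lower upper undefined
#> 1 sensitivity  38  40    0.950 0.826 0.995     FALSE
#> 2 specificity 279 299    0.933 0.898 0.957     FALSE
#> 3         ppv  38  58    0.655 0.526 0.765     FALSE
#> 4         npv 279 281    0.993 0.973 1.000     FALSE
```

## The analysis workflow

The `analysis/` directory is a numbered, re-runnable account of the full
study on synthetic cohorts; each stage writes its tables under
`results/`:

1. `01_simulate_cohorts.R` — control panels and the three cohorts
   (570/175, 56/56, 322/187 patients/cancers).
2. `02_calibrate_reference.R` — control reference and the two thresholds.
3. `03_train_aneuploidy.R` — SVM training and the detection-limit curve.
4. `04_call_cohorts.R` — per-patient three-assay calls and combination.
5. `05_evaluate.R` — cohort performance tables, lead time, concordance,
   false-negative attribution, mutation spectra.

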