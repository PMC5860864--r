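# Shared fixtures, built once per test run. The default configuration is
# the full study design (188 + 188 controls, 3,900 loci, 3150 + 677
# aneuploidy training samples); everything downstream reuses these.

test_cfg <- sim_config(seed = 42L)
test_controls <- simulate_control_panels(test_cfg)
test_reference <- calibrate_from_controls(test_controls)
test_training <- build_training_set(test_controls$urine_loci, test_cfg$arm_map,
                                    seed = 7L)
test_model <- train_aneuploidy_model(test_training, seed = 7L)

# A small hand-made mutation well table: one patient, two assays, two wells.
make_patient_wells <- function(patient_id, key_tab) {
  # key_tab: data.frame key, assay, m1, m2, t1, t2 (mutant/total per well)
  parts <- strsplit(key_tab$key, ":", fixed = TRUE)
  do.call(rbind, lapply(1:2, function(w) {
    data.frame(
      patient_id = patient_id, assay = key_tab$assay, well = w,
      chrom = vapply(parts, `[[`, "", 1),
      pos = as.integer(vapply(parts, `[[`, "", 2)),
      ref = vapply(parts, `[[`, "", 3),
      alt = vapply(parts, `[[`, "", 4),
      gene = "GENE",
      mutant_uids = if (w == 1) key_tab$m1 else key_tab$m2,
      total_uids = if (w == 1) key_tab$t1 else key_tab$t2,
      key = key_tab$key,
      stringsAsFactors = FALSE
    )
  }))
}

# Brute-force empirical p-value oracle (add-one smoothed upper tail).
brute_pvalue <- function(score, null) (1 + sum(null >= score)) / (length(null) + 1)
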