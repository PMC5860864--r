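#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study data.
#
# Builds the healthy-control panels (188 control urines with euploid locus
# profiles, 188 reference WBC panels, 94 technical-specificity WBC panels)
# and the three patient cohorts with known truth: early detection
# (570 patients, 175 cancers), UTUC (56, all cancers) and surveillance
# (322, 187 recurrences). Everything is written as TSV under
# results/data/ and is bit-reproducible from the seed.

suppressPackageStartupMessages(library(uroseek))

seed <- 20180L
cfg <- sim_config(seed = seed)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating control panels (seed ", seed, ") ...")
controls <- simulate_control_panels(cfg)
write_mutation_table(controls$wbc, file.path(out, "controls_wbc.tsv"))
write_mutation_table(controls$urine, file.path(out, "controls_urine.tsv"))
write_mutation_table(controls$wbc_technical, file.path(out, "controls_wbc_technical.tsv"))
write_locus_matrix(controls$urine_loci, cfg$arm_map,
                   file.path(out, "controls_urine_loci.tsv"))

for (cohort in c("early_detection", "utuc", "surveillance")) {
  message("Simulating cohort: ", cohort)
  coh <- simulate_cohort(cfg, cohort)
  write_cohort(coh, file.path(out, cohort))
  message("  ", nrow(coh$truth), " patients, ", sum(coh$truth$is_cancer),
          " cancers, ", nrow(coh$mutations), " mutation-well rows")
}

message("Done. Data under ", out)
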