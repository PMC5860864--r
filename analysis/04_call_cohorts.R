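#!/usr/bin/env Rscript
# Stage 4 — run the three assays over every cohort and combine the calls.
#
# For each patient: two-well mutation calling against the calibrated
# reference (multiplex and TERT assays), SVM aneuploidy scoring of the
# locus profile, the OR combination, and cytology integration. Per-patient
# results go to results/<cohort>_results.tsv.

suppressPackageStartupMessages(library(uroseek))

reference <- load_control_reference("results/control_reference.json")
model <- load_aneuploidy_model("results/aneuploidy_model.json")

for (cohort in c("early_detection", "utuc", "surveillance")) {
  dir <- file.path("results/data", cohort)
  clinical <- read.delim(file.path(dir, "clinical_sheet.tsv"),
                         stringsAsFactors = FALSE)
  bundle <- list(
    mutations = read_mutation_table(file.path(dir, "mutation_wells.tsv")),
    loci = read_locus_matrix(file.path(dir, "locus_counts.tsv"))$counts,
    clinical = clinical
  )
  scored <- score_cohort(bundle, reference, model)
  out <- file.path("results", paste0(cohort, "_results.tsv"))
  write.table(scored$results, out, sep = "\t", quote = FALSE, row.names = FALSE)
  calls_out <- file.path("results", paste0(cohort, "_mutation_calls.tsv"))
  write.table(scored$mutation_calls[scored$mutation_calls$positive, ],
              calls_out, sep = "\t", quote = FALSE, row.names = FALSE)
  message(cohort, ": ", sum(scored$results$uroseek_positive), " of ",
          nrow(scored$results), " samples UroSEEK-positive -> ", out)
}
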