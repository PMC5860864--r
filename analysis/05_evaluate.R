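#!/usr/bin/env Rscript
# Stage 5 — cohort-level evaluation.
#
# Per cohort: 2x2 tables and sensitivity/specificity/PPV/NPV with
# modified-Wald 95% CIs for each assay, the OR combination and the
# combination with cytology; lead-time summary; urine-tumor mutation
# concordance; false-negative attribution; and the mutation spectrum of
# the positive calls. Tables land under results/tables/.

suppressPackageStartupMessages(library(uroseek))

reference <- load_control_reference("results/control_reference.json")
model <- load_aneuploidy_model("results/aneuploidy_model.json")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

for (cohort in c("early_detection", "utuc", "surveillance")) {
  dir <- file.path("results/data", cohort)
  truth <- read.delim(file.path(dir, "truth_table.tsv"), stringsAsFactors = FALSE)
  truth$collection_date <- as.Date(truth$collection_date)
  truth$diagnosis_date <- as.Date(truth$diagnosis_date)
  bundle <- list(
    mutations = read_mutation_table(file.path(dir, "mutation_wells.tsv")),
    loci = read_locus_matrix(file.path(dir, "locus_counts.tsv"))$counts,
    clinical = truth,
    truth = truth,
    tumor_mutations = read.delim(file.path(dir, "tumor_mutations.tsv"),
                                 stringsAsFactors = FALSE),
    cohort = cohort
  )
  scored <- score_cohort(bundle, reference, model)
  ev <- evaluate_cohort(scored, bundle)
  print(ev)

  tab <- do.call(rbind, lapply(names(ev$metrics), function(nm) {
    cbind(test = nm, ev$metrics[[nm]])
  }))
  write.table(tab, file.path("results/tables", paste0(cohort, "_performance.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(ev$concordance)) {
    message(sprintf("  urine-tumor concordance: %.0f%% of %d evaluable patients",
                    100 * ev$concordance$fraction, ev$concordance$n_evaluated))
  }
  if (!is.null(ev$fn_attribution) && ev$fn_attribution$n_false_negative > 0) {
    message(sprintf("  false negatives: %.0f%% insufficient cells, %.0f%% no queried mutation (n = %d)",
                    100 * ev$fn_attribution$fraction_insufficient_cells,
                    100 * ev$fn_attribution$fraction_no_queried_mutation,
                    ev$fn_attribution$n_false_negative))
  }
  pos <- scored$mutation_calls[scored$mutation_calls$positive, ]
  parts <- strsplit(pos$key, ":", fixed = TRUE)
  spec <- mutation_spectrum(data.frame(
    gene = pos$gene,
    ref = vapply(parts, `[[`, "", 3),
    alt = vapply(parts, `[[`, "", 4), stringsAsFactors = FALSE))
  write.table(spec$per_gene,
              file.path("results/tables", paste0(cohort, "_spectrum.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message("Evaluation tables written under results/tables/")
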