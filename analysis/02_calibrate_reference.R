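#!/usr/bin/env Rscript
# Stage 2 — build the control reference and calibrate the two thresholds.
#
# The per-mutation location/scale summaries and the pooled empirical null
# come from the 188 WBC panels; the difference threshold is the highest
# WBC MAF anywhere in the panel, and the Stouffer-Z threshold is set so
# that exactly one of the 188 healthy-control urines scores positive.

suppressPackageStartupMessages(library(uroseek))

data_dir <- "results/data"
wbc <- read_mutation_table(file.path(data_dir, "controls_wbc.tsv"))
urine <- read_mutation_table(file.path(data_dir, "controls_urine.tsv"))

reference <- calibrate_from_controls(list(wbc = wbc, urine = urine))
print(reference)
message(sprintf("difference threshold t_diff = %.3g (max WBC MAF)",
                reference$t_diff))
message(sprintf("Stouffer threshold   t_z    = %.3f", reference$t_z))
message(reference$calibration$n_exceeding,
        " of 188 calibration urines exceed t_z (the single allowed false positive)")

dir.create("results", showWarnings = FALSE)
save_control_reference(reference, "results/control_reference.json")
message("Reference saved to results/control_reference.json")
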