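Package: uroseek
Title: Urinary-Cell Mutation and Aneuploidy Calling for Urothelial Cancer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a urine-based liquid-biopsy calling pipeline for
    urothelial cancer detection from UID (unique molecular identifier)
    family count data: control-calibrated mutation calling with a
    mutation-specific empirical null and a UID-weighted Stouffer Z
    combination across duplicate PCR wells, arm-level aneuploidy scoring
    from repeat-amplicon locus counts with a support-vector-machine
    genome-wide score, the three-assay OR combination rule (optionally
    with cytology), and cohort-level diagnostic evaluation with
    modified-Wald confidence intervals. Includes a synthetic-cohort
    generator that reproduces the statistical structure the pipeline
    assumes, for calibration, benchmarking and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
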