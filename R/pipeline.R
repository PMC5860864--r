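# End-to-end convenience layer: calibrate once, then score whole cohorts
# and evaluate them. The analysis/ scripts, the test suite and the
# acceptance script all drive these functions.

#' Calibrate the mutation caller from control panels
#'
#' Builds the control reference from the WBC panel and calibrates both
#' decision thresholds (difference on the WBC maxima, Stouffer Z on the
#' healthy-control urines).
#'
#' @param controls A [simulate_control_panels()] result (or a list with
#'   `wbc` and `urine` mutation tables).
#' @param min_mutant_families Candidate floor.
#' @return A calibrated `control_reference`.
#' @export
calibrate_from_controls <- function(controls, min_mutant_families = 2L) {
  reference <- build_control_reference(controls$wbc)
  calibrate_thresholds(reference, controls$wbc, controls$urine,
                       min_mutant_families = min_mutant_families)
}

#' Score a full cohort with all three assays
#'
#' Runs mutation calling (multiplex + TERT) and aneuploidy scoring over a
#' cohort bundle and assembles the per-patient UroSEEK results.
#'
#' @param cohort A [simulate_cohort()] bundle (or a list with `mutations`,
#'   `loci`, `clinical`).
#' @param reference A calibrated `control_reference`.
#' @param model An `aneuploidy_model`.
#' @param min_mutant_families Candidate floor for mutation calling.
#' @return List with `results` (per-patient flags, see
#'   [uroseek_results()]), `mutation_calls` (per-candidate detail),
#'   `aneuploidy` (per-sample scores).
#' @export
score_cohort <- function(cohort, reference, model, min_mutant_families = 2L) {
  mut <- call_mutations(cohort$mutations, reference, min_mutant_families)
  aneu <- score_aneuploidy(cohort$loci, model)
  res <- uroseek_results(mut$samples, aneu, cohort$clinical)
  list(results = res, mutation_calls = mut$calls, aneuploidy = aneu)
}

#' Evaluate scored results against cohort truth
#'
#' Produces the cohort-level performance summary: per-assay and combined
#' 2x2 tables with sensitivity/specificity/PPV/NPV and modified-Wald CIs
#' (UroSEEK on all patients; UroSEEK-plus-cytology restricted to the
#' cytology-available subset), the lead-time summary, and — when truth
#' tumor mutations are available — urine-tumor concordance and
#' false-negative attribution for the mutation assays.
#'
#' @param scored A [score_cohort()] result.
#' @param cohort The cohort bundle it was scored from.
#' @return List of class `uroseek_evaluation` with elements `metrics`
#'   (named list of [diagnostic_metrics()] tables), `counts`,
#'   `lead_time`, `concordance`, `fn_attribution`.
#' @export
evaluate_cohort <- function(scored, cohort) {
  res <- scored$results
  truth <- cohort$truth
  flags <- c(multiplex = "multiplex_positive", tert = "tert_positive",
             aneuploidy = "aneuploidy_positive", uroseek = "uroseek_positive")
  counts <- lapply(flags, function(f) confusion_from_calls(res, truth, flag = f))
  has_cyt <- res$cytology != "unavailable"
  if (any(has_cyt)) {
    counts$combined_with_cytology <- confusion_from_calls(
      res[has_cyt, ], truth, flag = "combined_with_cytology_positive")
  }
  metrics <- lapply(counts, diagnostic_metrics)
  lead <- if (any(res$uroseek_positive & truth$is_cancer[
      match(res$patient_id, truth$patient_id)])) {
    lead_time_summary(res, truth)
  } else NULL
  concordance <- NULL
  fn_attr <- NULL
  if (!is.null(cohort$tumor_mutations)) {
    urine_pos <- scored$mutation_calls[scored$mutation_calls$positive, ]
    concordance <- tumor_urine_concordance(
      urine_pos[, c("patient_id", "key")], cohort$tumor_mutations)
    mut_pos_ids <- unique(urine_pos$patient_id)
    cancer_ids <- truth$patient_id[truth$is_cancer]
    fn_ids <- setdiff(cancer_ids, mut_pos_ids)
    fn_attr <- false_negative_attribution(fn_ids, cohort$tumor_mutations)
  }
  structure(list(metrics = metrics, counts = counts, lead_time = lead,
                 concordance = concordance, fn_attribution = fn_attr,
                 cohort = cohort$cohort),
            class = "uroseek_evaluation")
}

#' @export
print.uroseek_evaluation <- function(x, ...) {
  cat("UroSEEK evaluation - cohort '", x$cohort, "'\n", sep = "")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    sens <- m[m$metric == "sensitivity", ]
    spec <- m[m$metric == "specificity", ]
    fmt <- function(r) {
      if (r$undefined) "undefined" else
        sprintf("%.1f%% (%.1f-%.1f)", 100 * r$estimate, 100 * r$lower, 100 * r$upper)
    }
    cat(sprintf("  %-24s sens %s  spec %s\n", nm, fmt(sens), fmt(spec)))
  }
  if (!is.null(x$lead_time)) {
    cat(sprintf("  lead time: mean %.1f months; %d case(s) > 1 year\n",
                x$lead_time$mean_months, x$lead_time$n_over_12_months))
  }
  invisible(x)
}
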