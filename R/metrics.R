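# Cohort-level diagnostic evaluation: 2x2 tabulation, sensitivity /
# specificity / PPV / NPV with modified-Wald (Agresti-Coull) confidence
# intervals, lead time, urine-tumor concordance, false-negative attribution
# and mutation-spectrum summaries.

#' Confusion counts from calls and truth
#'
#' Standard 2x2 tabulation of a binary test against the truth label
#' (cancer developed/recurred within follow-up). Every call must have a
#' truth label; calls with `NA` test results (e.g. combined-with-cytology
#' on patients without cytology) are excluded first by the caller.
#'
#' @param calls data.frame with `patient_id` and a logical `positive`
#'   column (name configurable via `flag`).
#' @param truth data.frame with `patient_id` and logical `is_cancer`.
#' @param flag Name of the logical column in `calls` to evaluate.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`, `n`.
#' @export
confusion_from_calls <- function(calls, truth, flag = "positive") {
  i <- match(calls$patient_id, truth$patient_id)
  if (anyNA(i)) {
    stop("patient without truth label: ",
         paste(utils::head(calls$patient_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  pos <- calls[[flag]]
  if (anyNA(pos)) stop("NA test results; subset before tabulating", call. = FALSE)
  is_cancer <- truth$is_cancer[i]
  confusion_counts(tp = sum(pos & is_cancer), fp = sum(pos & !is_cancer),
                   tn = sum(!pos & !is_cancer), fn = sum(!pos & is_cancer))
}

#' Construct confusion counts directly
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cells < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  structure(as.list(cells), n = sum(cells), class = "confusion_counts")
}

#' Modified Wald (Agresti-Coull) binomial confidence interval
#'
#' Uses the adjusted proportion `p~ = (x + z^2/2) / (n + z^2)` and
#' half-width `z * sqrt(p~ (1 - p~) / (n + z^2))`, clipped to \[0, 1\].
#'
#' @param x Successes (0 <= x <= n).
#' @param n Trials (> 0).
#' @param z Normal quantile; 1.96 for a 95% interval.
#' @return Numeric vector `c(lower, upper)`.
#' @export
modified_wald_ci <- function(x, n, z = 1.96) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (x < 0 || x > n) stop("x must lie in [0, n]", call. = FALSE)
  p_tilde <- (x + z^2 / 2) / (n + z^2)
  half <- z * sqrt(p_tilde * (1 - p_tilde) / (n + z^2))
  c(lower = max(0, p_tilde - half), upper = min(1, p_tilde + half))
}

#' Diagnostic performance metrics with confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV from a 2x2 table, each with a 95%
#' confidence interval (modified Wald by default; `method = "exact"` gives
#' Clopper-Pearson via [stats::binom.test()]). Metrics with a zero
#' denominator are reported as `NA` and flagged `undefined`, never
#' silently zeroed.
#'
#' @param counts A [confusion_counts()] object.
#' @param conf_level Confidence level.
#' @param method `"modified_wald"` (default) or `"exact"`.
#' @return data.frame with `metric`, `x`, `n`, `estimate`, `lower`,
#'   `upper`, `undefined`; attribute `ci_method`.
#' @export
diagnostic_metrics <- function(counts, conf_level = 0.95,
                               method = c("modified_wald", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "confusion_counts"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  defs <- list(
    sensitivity = c(counts$tp, counts$tp + counts$fn),
    specificity = c(counts$tn, counts$tn + counts$fp),
    ppv = c(counts$tp, counts$tp + counts$fp),
    npv = c(counts$tn, counts$tn + counts$fn)
  )
  rows <- lapply(names(defs), function(m) {
    x <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0) {
      return(data.frame(metric = m, x = x, n = n, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_, undefined = TRUE,
                        stringsAsFactors = FALSE))
    }
    ci <- if (method == "modified_wald") unname(modified_wald_ci(x, n, z))
          else as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
    data.frame(metric = m, x = x, n = n, estimate = x / n,
               lower = ci[1], upper = ci[2], undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ci_method") <- method
  out
}

#' Lead time between a positive test and clinical diagnosis
#'
#' Months are days / 30.44.
#'
#' @param collection_date,diagnosis_date `Date` vectors;
#'   `diagnosis_date >= collection_date`.
#' @return Numeric vector of months.
#' @export
lead_time <- function(collection_date, diagnosis_date) {
  days <- as.numeric(diagnosis_date - collection_date)
  if (any(days < 0, na.rm = TRUE)) {
    stop("diagnosis precedes collection", call. = FALSE)
  }
  days / 30.44
}

#' Cohort lead-time summary
#'
#' Mean lead time over test-positive cases and the number of cases whose
#' positive test preceded diagnosis by more than a year.
#'
#' @param results Per-patient results with `patient_id` and a logical
#'   positivity `flag` column.
#' @param truth Truth table with `patient_id`, `is_cancer`,
#'   `collection_date`, `diagnosis_date`.
#' @param flag Positivity column name.
#' @return List with `mean_months`, `n_over_12_months`, `n_positive_cases`,
#'   `months` (vector).
#' @export
lead_time_summary <- function(results, truth, flag = "uroseek_positive") {
  i <- match(results$patient_id, truth$patient_id)
  sel <- results[[flag]] & truth$is_cancer[i]
  lt <- lead_time(truth$collection_date[i][sel], truth$diagnosis_date[i][sel])
  list(mean_months = mean(lt), n_over_12_months = sum(lt > 12),
       n_positive_cases = sum(sel), months = lt)
}

#' Urine-tumor mutation concordance
#'
#' A patient is concordant when at least one identical mutation key is
#' found in both the urine calls and the tumor. The cohort fraction is
#' computed over patients with at least one urine mutation and an
#' available tumor profile; patients without tumor data are excluded and
#' counted.
#'
#' @param urine_calls data.frame `patient_id`, `key` of positive urine
#'   mutations.
#' @param tumor_mutations data.frame `patient_id`, `key`.
#' @return List with `per_patient` (data.frame `patient_id`, `concordant`),
#'   `fraction`, `n_evaluated`, `n_no_tumor`.
#' @export
tumor_urine_concordance <- function(urine_calls, tumor_mutations) {
  ids <- unique(urine_calls$patient_id)
  has_tumor <- ids %in% tumor_mutations$patient_id
  conc <- vapply(ids, function(id) {
    u <- urine_calls$key[urine_calls$patient_id == id]
    t_ <- tumor_mutations$key[tumor_mutations$patient_id == id]
    length(intersect(u, t_)) > 0
  }, logical(1))
  per <- data.frame(patient_id = ids, has_tumor = has_tumor,
                    concordant = conc & has_tumor, stringsAsFactors = FALSE)
  n_eval <- sum(has_tumor)
  list(per_patient = per,
       fraction = if (n_eval > 0) sum(per$concordant) / n_eval else NA_real_,
       n_evaluated = n_eval, n_no_tumor = sum(!has_tumor))
}

#' Attribute false negatives of the mutation assays
#'
#' Splits urine-mutation-negative cancer patients into the two failure
#' modes of a genetic test: the tumor carries at least one queried
#' mutation but too few neoplastic cells reached the urine ("insufficient
#' cells"), or the tumor carries none of the queried mutations ("no
#' queried mutation"). The two fractions sum to 1.
#'
#' @param fn_ids Patient ids of false negatives.
#' @param tumor_mutations data.frame `patient_id`, `key` of panel
#'   mutations found in tumors.
#' @return List with `fraction_insufficient_cells`,
#'   `fraction_no_queried_mutation`, `n_false_negative`, `per_patient`.
#' @export
false_negative_attribution <- function(fn_ids, tumor_mutations) {
  if (length(fn_ids) == 0) {
    return(list(fraction_insufficient_cells = NA_real_,
                fraction_no_queried_mutation = NA_real_,
                n_false_negative = 0L, per_patient = NULL))
  }
  has_mut <- fn_ids %in% tumor_mutations$patient_id
  list(
    fraction_insufficient_cells = mean(has_mut),
    fraction_no_queried_mutation = mean(!has_mut),
    n_false_negative = length(fn_ids),
    per_patient = data.frame(patient_id = fn_ids,
                             cause = ifelse(has_mut, "insufficient_cells",
                                            "no_queried_mutation"),
                             stringsAsFactors = FALSE)
  )
}

#' Substitution-class spectrum of mutation calls
#'
#' Counts the six pyrimidine-referenced substitution classes (C>A, C>G,
#' C>T, T>A, T>C, T>G; purine-referenced changes are complemented into
#' them) and reports, per gene, the A:T>T:A transversion fraction — the
#' signature class of aristolochic-acid mutagenesis.
#'
#' @param calls data.frame with `gene`, `ref`, `alt` (single bases;
#'   non-SNV rows are skipped and counted).
#' @return List with `class_counts` (named vector over the six classes),
#'   `per_gene` (data.frame `gene`, `n`, `n_at_ta`, `fraction_at_ta`),
#'   `n_skipped`.
#' @export
mutation_spectrum <- function(calls) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  if (nrow(calls) == 0) {
    return(list(class_counts = stats::setNames(rep(0L, 6), classes),
                per_gene = data.frame(gene = character(0), n = integer(0),
                                      n_at_ta = integer(0),
                                      fraction_at_ta = numeric(0)),
                n_skipped = 0L))
  }
  snv <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1 &
    calls$ref %in% c("A", "C", "G", "T") & calls$alt %in% c("A", "C", "G", "T") &
    calls$ref != calls$alt
  skipped <- sum(!snv)
  calls <- calls[snv, ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- calls$ref; alt <- calls$alt
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[calls$ref[flip]]
  alt[flip] <- comp[calls$alt[flip]]
  cls <- paste0(ref, ">", alt)
  counts <- stats::setNames(integer(6), classes)
  tab <- table(cls)
  counts[names(tab)] <- as.integer(tab)
  per_gene <- do.call(rbind, lapply(split(cls, calls$gene), function(x) {
    data.frame(n = length(x), n_at_ta = sum(x == "T>A"),
               fraction_at_ta = mean(x == "T>A"))
  }))
  per_gene <- data.frame(gene = rownames(per_gene), per_gene,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(class_counts = counts, per_gene = per_gene, n_skipped = skipped)
}
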