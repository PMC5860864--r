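# Three-assay OR combination (the UroSEEK rule) and cytology integration.

#' Combine the three assay calls
#'
#' A sample is UroSEEK-positive when any one of the three assays —
#' ten-gene multiplex mutation, TERT-promoter mutation, aneuploidy — is
#' positive. No imputation: a missing (NA) assay call is an error.
#'
#' @param multiplex_positive,tert_positive,aneuploidy_positive Logical
#'   vectors (recycled to common length).
#' @return Logical vector of combined calls.
#' @export
combine_uroseek <- function(multiplex_positive, tert_positive, aneuploidy_positive) {
  n <- max(length(multiplex_positive), length(tert_positive),
           length(aneuploidy_positive))
  m <- rep_len(multiplex_positive, n)
  t_ <- rep_len(tert_positive, n)
  a <- rep_len(aneuploidy_positive, n)
  if (anyNA(m) || anyNA(t_) || anyNA(a)) {
    stop("missing assay call; all three assays are required (no imputation)",
         call. = FALSE)
  }
  m | t_ | a
}

#' Combine UroSEEK with cytology
#'
#' Positive iff UroSEEK is positive or cytology is read as positive.
#' Equivocal ("atypical") cytology does not count as positive. Patients
#' with unavailable cytology get `NA`: they belong in UroSEEK-only
#' metrics but are excluded from combined-test (cytology-subset) metrics.
#'
#' @param uroseek_positive Logical vector.
#' @param cytology Character vector in
#'   \{positive, atypical, negative, unavailable\}.
#' @return Logical vector (`NA` where cytology is unavailable).
#' @export
combine_with_cytology <- function(uroseek_positive, cytology) {
  valid <- c("positive", "atypical", "negative", "unavailable")
  if (!all(cytology %in% valid)) {
    stop("unknown cytology category: ",
         paste(unique(setdiff(cytology, valid)), collapse = ", "), call. = FALSE)
  }
  out <- uroseek_positive | cytology == "positive"
  out[cytology == "unavailable"] <- NA
  out
}

#' Assemble per-patient UroSEEK results for a cohort
#'
#' Runs the full decision layer over already-computed per-assay calls and
#' the clinical sheet, producing one row per patient with every flag.
#'
#' @param mutation_samples Per-(patient, assay) call table from
#'   [call_mutations()]`$samples` (assays `multiplex` and `tert`).
#' @param aneuploidy_calls data.frame `patient_id`, `score`, `positive`
#'   from [score_aneuploidy()] on a profile matrix.
#' @param clinical Clinical sheet with `patient_id` and `cytology`.
#' @return data.frame with per-assay flags, `uroseek_positive`,
#'   `cytology` and `combined_with_cytology_positive`.
#' @export
uroseek_results <- function(mutation_samples, aneuploidy_calls, clinical) {
  ids <- clinical$patient_id
  get_assay <- function(assay) {
    sub <- mutation_samples[mutation_samples$assay == assay, ]
    i <- match(ids, sub$patient_id)
    if (anyNA(i)) {
      stop("missing ", assay, " calls for: ",
           paste(utils::head(ids[is.na(i)]), collapse = ", "), call. = FALSE)
    }
    sub$positive[i]
  }
  multiplex <- get_assay("multiplex")
  tert <- get_assay("tert")
  ia <- match(ids, aneuploidy_calls$patient_id)
  if (anyNA(ia)) {
    stop("missing aneuploidy calls for: ",
         paste(utils::head(ids[is.na(ia)]), collapse = ", "), call. = FALSE)
  }
  aneu <- aneuploidy_calls$positive[ia]
  uro <- combine_uroseek(multiplex, tert, aneu)
  data.frame(
    patient_id = ids,
    multiplex_positive = multiplex,
    tert_positive = tert,
    aneuploidy_positive = aneu,
    aneuploidy_score = aneuploidy_calls$score[ia],
    uroseek_positive = uro,
    cytology = clinical$cytology,
    combined_with_cytology_positive = combine_with_cytology(uro, clinical$cytology),
    stringsAsFactors = FALSE
  )
}
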