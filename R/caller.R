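# UID-family mutation calling: mutation-specific normalization against a
# control panel, a pooled empirical null, UID-weighted Stouffer Z across the
# two PCR wells, and a control-calibrated two-criterion decision rule.

#' Mutant allele frequency from UID-family counts
#'
#' MAF = mutant UID families / total UID families. A UID family is the set
#' of reads sharing one molecular barcode, i.e. one template molecule, so
#' this is a template-level allele fraction.
#'
#' @param mutant_uid_families,total_uid_families Non-negative integer
#'   vectors; `total_uid_families` must be positive.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
compute_maf <- function(mutant_uid_families, total_uid_families) {
  if (any(total_uid_families <= 0)) {
    stop("undefined MAF: total_uid_families must be > 0 (exclude the well)",
         call. = FALSE)
  }
  if (any(mutant_uid_families < 0) || any(mutant_uid_families > total_uid_families)) {
    stop("mutant_uid_families must lie in [0, total_uid_families]", call. = FALSE)
  }
  mutant_uid_families / total_uid_families
}

#' Build the control reference for mutation-specific normalization
#'
#' Summarizes a control panel (by default the 188-individual WBC set) per
#' queried mutation: a robust location (median) and scale (MAD x 1.4826,
#' floored) of the control MAFs, the per-mutation maximum control MAF used
#' by the difference criterion, and the pooled empirical null — the sorted
#' vector of all normalized control values across every mutation and
#' control well. Both wells of every control contribute (they are
#' independent PCRs).
#'
#' @param control_obs Mutation well table for the controls (columns
#'   `patient_id`, `assay`, `well`, `mutant_uids`, `total_uids` and either
#'   `key` or `chrom`/`pos`/`ref`/`alt`).
#' @param min_scale Hard floor on the per-mutation scale.
#' @param scale_floor_constant The scale is floored at
#'   `max(scale, c / n_key, min_scale)` where `n_key` is the number of
#'   control observations for that mutation; guards against degenerate
#'   all-zero control distributions.
#' @return Object of class `control_reference` (thresholds unset; see
#'   [calibrate_thresholds()]).
#' @export
build_control_reference <- function(control_obs, min_scale = 1e-6,
                                    scale_floor_constant = 0.2) {
  control_obs <- ensure_key(control_obs)
  if (nrow(control_obs) == 0) stop("empty control set", call. = FALSE)
  maf <- compute_maf(control_obs$mutant_uids, control_obs$total_uids)
  keys <- control_obs$key
  loc <- tapply(maf, keys, stats::median)
  spread <- tapply(maf, keys, function(x) stats::mad(x, constant = 1.4826))
  nobs <- tapply(maf, keys, length)
  if (any(nobs < 2)) {
    stop("need >= 2 control observations per mutation; short keys: ",
         paste(utils::head(names(nobs)[nobs < 2]), collapse = ", "), call. = FALSE)
  }
  scale <- pmax(spread, scale_floor_constant / nobs, min_scale)
  maxmaf <- tapply(maf, keys, max)
  key_tab <- data.frame(key = names(loc), location = as.numeric(loc),
                        scale = as.numeric(scale), max_maf = as.numeric(maxmaf),
                        n_obs = as.integer(nobs), stringsAsFactors = FALSE)
  # panel-wide fallback for keys missing from the control panel
  fallback <- list(location = stats::median(maf),
                   scale = max(stats::mad(maf, constant = 1.4826),
                               scale_floor_constant / length(maf), min_scale))
  pooled <- sort((maf - key_tab$location[match(keys, key_tab$key)]) /
                   key_tab$scale[match(keys, key_tab$key)])
  structure(list(keys = key_tab, pooled_null = pooled, fallback = fallback,
                 t_diff = NA_real_, t_z = NA_real_,
                 n_controls = length(unique(control_obs$patient_id)),
                 calibration = NULL),
            class = "control_reference")
}

#' @export
print.control_reference <- function(x, ...) {
  cat("Control reference:", nrow(x$keys), "mutations,",
      length(x$pooled_null), "pooled null values from", x$n_controls, "controls\n")
  if (!is.na(x$t_diff)) cat("  thresholds: t_diff =", signif(x$t_diff, 4),
                            ", t_z =", signif(x$t_z, 4), "\n")
  else cat("  thresholds: not calibrated\n")
  invisible(x)
}

# Per-key location/scale/max with fallback for unseen keys.
key_params <- function(keys, reference) {
  i <- match(keys, reference$keys$key)
  loc <- reference$keys$location[i]
  sc <- reference$keys$scale[i]
  mx <- reference$keys$max_maf[i]
  miss <- is.na(i)
  if (any(miss)) {
    loc[miss] <- reference$fallback$location
    sc[miss] <- reference$fallback$scale
    mx[miss] <- max(reference$keys$max_maf)
  }
  list(location = loc, scale = sc, max_maf = mx)
}

#' Mutation-specific normalized score
#'
#' Centers and scales a MAF by the control location and robust spread for
#' the same mutation: `(maf - location) / scale`. Mutations absent from the
#' control panel fall back to the panel-wide pooled location/scale.
#'
#' @param maf Numeric vector of MAFs.
#' @param key Character vector of mutation keys (recycled).
#' @param reference A [build_control_reference()] object.
#' @return Dimensionless numeric scores.
#' @export
normalized_score <- function(maf, key, reference) {
  p <- key_params(key, reference)
  (maf - p$location) / p$scale
}

#' One-sided empirical p-value against the pooled null
#'
#' Add-one smoothed upper-tail p-value:
#' `p = (1 + #\{null >= score\}) / (N + 1)`. Smoothing keeps p strictly
#' positive so downstream z-scores are finite.
#'
#' @param score Numeric vector of normalized scores.
#' @param pooled_null Sorted numeric vector (or a `control_reference`).
#' @return p-values in (0, 1\].
#' @export
empirical_pvalue <- function(score, pooled_null) {
  if (inherits(pooled_null, "control_reference")) pooled_null <- pooled_null$pooled_null
  n <- length(pooled_null)
  if (n < 1) stop("pooled null is empty", call. = FALSE)
  # #{null >= s} = n - #{null < s}; findInterval(..., left.open=TRUE) counts
  # strictly-smaller elements of the sorted null
  n_lt <- findInterval(score, pooled_null, left.open = TRUE)
  (1 + (n - n_lt)) / (n + 1)
}

#' UID-weighted Stouffer combination of two wells
#'
#' Transforms each well's p-value to a z-score, `z_i = qnorm(1 - p_i)`, and
#' combines with weights `w_i`: `Z = (w1 z1 + w2 z2) / sqrt(w1^2 + w2^2)`.
#' The default weight is `sqrt(UID_i)` — the canonical information weight,
#' since the variance of a proportion scales as 1/n; `weighting = "linear"`
#' uses `w_i = UID_i` instead.
#'
#' @param p1,p2 Per-well p-values in (0, 1\].
#' @param uid1,uid2 Per-well total UID-family counts (> 0).
#' @param weighting `"sqrt"` (default) or `"linear"`.
#' @return Combined Z (numeric vector).
#' @export
stouffer_combine <- function(p1, p2, uid1, uid2, weighting = c("sqrt", "linear")) {
  weighting <- match.arg(weighting)
  if (any(p1 <= 0) || any(p2 <= 0) || any(p1 > 1) || any(p2 > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (any(uid1 <= 0) || any(uid2 <= 0)) stop("UID counts must be > 0", call. = FALSE)
  w1 <- if (weighting == "sqrt") sqrt(uid1) else uid1
  w2 <- if (weighting == "sqrt") sqrt(uid2) else uid2
  z1 <- stats::qnorm(1 - p1)
  z2 <- stats::qnorm(1 - p2)
  (w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2)
}

#' Difference criterion statistic
#'
#' Signed difference between the sample's average MAF and the maximum MAF
#' observed for the same mutation across the control panel.
#'
#' @param avg_maf Two-well average MAF.
#' @param key Mutation key(s).
#' @param reference A [build_control_reference()] object.
#' @return Signed difference in MAF units.
#' @export
difference_stat <- function(avg_maf, key, reference) {
  avg_maf - key_params(key, reference)$max_maf
}

# Score every candidate mutation of a well table: pairs wells 1 and 2 per
# (patient, key), applies the candidate floor, and computes all per-key
# statistics. Used both for calibration (thresholds disabled) and calling.
score_candidates <- function(obs, reference, min_mutant_families = 2L) {
  obs <- ensure_key(obs)
  w1 <- obs[obs$well == 1, ]
  w2 <- obs[obs$well == 2, ]
  id1 <- paste(w1$patient_id, w1$key, sep = "\r")
  id2 <- paste(w2$patient_id, w2$key, sep = "\r")
  m <- match(id1, id2)
  if (anyNA(m)) {
    bad <- unique(w1$patient_id[is.na(m)])
    stop("missing well 2 observations for: ", paste(utils::head(bad), collapse = ", "),
         call. = FALSE)
  }
  w2 <- w2[m, ]
  in1 <- w1$mutant_uids >= min_mutant_families
  in2 <- w2$mutant_uids >= min_mutant_families
  keep <- in1 | in2  # single-well candidates are kept, flagged, never positive
  w1 <- w1[keep, ]; w2 <- w2[keep, ]
  both <- in1[keep] & in2[keep]
  if (nrow(w1) == 0) {
    return(data.frame(patient_id = character(0), assay = character(0),
                      key = character(0), gene = character(0),
                      avg_maf = numeric(0), diff_stat = numeric(0),
                      p1 = numeric(0), p2 = numeric(0), z1 = numeric(0),
                      z2 = numeric(0), stouffer_z = numeric(0),
                      present_in_both_wells = logical(0), stringsAsFactors = FALSE))
  }
  maf1 <- compute_maf(w1$mutant_uids, w1$total_uids)
  maf2 <- compute_maf(w2$mutant_uids, w2$total_uids)
  s1 <- normalized_score(maf1, w1$key, reference)
  s2 <- normalized_score(maf2, w2$key, reference)
  p1 <- empirical_pvalue(s1, reference)
  p2 <- empirical_pvalue(s2, reference)
  avg <- (maf1 + maf2) / 2
  data.frame(
    patient_id = w1$patient_id, assay = w1$assay, key = w1$key,
    gene = if ("gene" %in% names(w1)) w1$gene else NA_character_,
    avg_maf = avg,
    diff_stat = difference_stat(avg, w1$key, reference),
    p1 = p1, p2 = p2,
    z1 = stats::qnorm(1 - p1), z2 = stats::qnorm(1 - p2),
    stouffer_z = stouffer_combine(p1, p2, w1$total_uids, w2$total_uids),
    present_in_both_wells = both,
    stringsAsFactors = FALSE
  )
}

#' Calibrate the two decision thresholds from control panels
#'
#' The difference threshold `t_diff` is the highest MAF observed in any
#' control WBC observation, across all mutations and wells. The Stouffer-Z
#' threshold `t_z` is set on the healthy-control urines, scored end-to-end
#' with thresholds disabled: it equals the second-largest per-sample
#' maximum Z, with positivity defined as strictly greater — so exactly one
#' control urine exceeds it (the intended single allowed false positive
#' among the calibration urines).
#'
#' @param reference A [build_control_reference()] object.
#' @param wbc_obs Control WBC mutation well table.
#' @param urine_obs Healthy-control urine mutation well table (>= 2 samples).
#' @param min_mutant_families Candidate floor passed to the scorer.
#' @return The reference with `t_diff`, `t_z` and calibration metadata set.
#' @export
calibrate_thresholds <- function(reference, wbc_obs, urine_obs,
                                 min_mutant_families = 2L) {
  stopifnot(inherits(reference, "control_reference"))
  wbc_obs <- ensure_key(wbc_obs)
  reference$t_diff <- max(compute_maf(wbc_obs$mutant_uids, wbc_obs$total_uids))
  urine_ids <- unique(urine_obs$patient_id)
  if (length(urine_ids) < 2) {
    stop("cannot calibrate: need >= 2 control urine samples", call. = FALSE)
  }
  cand <- score_candidates(urine_obs, reference, min_mutant_families)
  cand <- cand[cand$present_in_both_wells, ]  # positivity requires both wells
  max_z <- rep(-Inf, length(urine_ids))
  names(max_z) <- urine_ids
  if (nrow(cand) > 0) {
    mz <- tapply(cand$stouffer_z, cand$patient_id, max)
    max_z[names(mz)] <- mz
  }
  ord <- sort(max_z, decreasing = TRUE)
  reference$t_z <- unname(ord[2])
  reference$calibration <- list(
    n_urines = length(urine_ids),
    max_z = max_z,
    n_exceeding = sum(max_z > reference$t_z)
  )
  reference
}

#' Call mutations for one or many samples
#'
#' Applies the calibrated two-criterion rule to every candidate mutation —
#' a mutation with at least `min_mutant_families` mutant UID families in
#' both of its two independent PCR wells. A candidate is positive when its
#' difference statistic exceeds `t_diff` or its UID-weighted Stouffer Z
#' exceeds `t_z` (both strict); a sample is mutation-positive when any of
#' its candidates is. Mutations seen in only one well are never positive.
#'
#' @param obs Mutation well table for one or more patients (two wells per
#'   patient per assay).
#' @param reference A calibrated [control_reference][calibrate_thresholds].
#' @param min_mutant_families Candidate floor (mutant UID families per well).
#' @return A list with `calls` — per-candidate results including `positive`
#'   and `triggering_criterion` in \{difference, stouffer, both, none\} —
#'   and `samples`: one row per (patient, assay) with the sample-level
#'   positivity flag and its best supporting mutation.
#' @export
call_mutations <- function(obs, reference, min_mutant_families = 2L) {
  stopifnot(inherits(reference, "control_reference"))
  if (is.na(reference$t_diff) || is.na(reference$t_z)) {
    stop("thresholds not calibrated; run calibrate_thresholds() first", call. = FALSE)
  }
  obs <- ensure_key(obs)
  check_wells(obs)
  cand <- score_candidates(obs, reference, min_mutant_families)
  diff_pos <- cand$diff_stat > reference$t_diff
  z_pos <- cand$stouffer_z > reference$t_z
  cand$positive <- cand$present_in_both_wells & (diff_pos | z_pos)
  cand$triggering_criterion <- ifelse(!cand$positive, "none",
                               ifelse(diff_pos & z_pos, "both",
                               ifelse(diff_pos, "difference", "stouffer")))
  all_pa <- unique(obs[, c("patient_id", "assay")])
  pa <- paste(cand$patient_id, cand$assay, sep = "\r")
  pos_tab <- tapply(cand$positive, pa, any)
  samples <- data.frame(
    patient_id = all_pa$patient_id, assay = all_pa$assay,
    positive = FALSE, top_key = NA_character_, top_avg_maf = NA_real_,
    stringsAsFactors = FALSE
  )
  idx <- match(paste(samples$patient_id, samples$assay, sep = "\r"), names(pos_tab))
  samples$positive[!is.na(idx)] <- as.logical(pos_tab[idx[!is.na(idx)]])
  pos <- cand[cand$positive, ]
  if (nrow(pos) > 0) {
    best <- pos[order(-pos$avg_maf), ]
    best <- best[!duplicated(paste(best$patient_id, best$assay, sep = "\r")), ]
    j <- match(paste(samples$patient_id, samples$assay, sep = "\r"),
               paste(best$patient_id, best$assay, sep = "\r"))
    samples$top_key[!is.na(j)] <- best$key[j[!is.na(j)]]
    samples$top_avg_maf[!is.na(j)] <- best$avg_maf[j[!is.na(j)]]
  }
  list(calls = cand, samples = samples)
}

# Every (patient, assay) must come as exactly two wells labelled 1 and 2.
check_wells <- function(obs) {
  tab <- table(obs$patient_id, obs$assay, obs$well)
  per <- tapply(obs$well, paste(obs$patient_id, obs$assay, sep = "\r"),
                function(w) length(unique(w)))
  if (any(per != 2)) {
    bad <- names(per)[per != 2][1]
    stop("expected exactly two wells per assay; offending patient/assay: ",
         gsub("\r", " / ", bad), call. = FALSE)
  }
  invisible(TRUE)
}

ensure_key <- function(obs) {
  if (!"key" %in% names(obs)) {
    obs$key <- mutation_key(obs$chrom, obs$pos, obs$ref, obs$alt)
  }
  obs
}

#' Genotype concordance over the identity-check SNP panel
#'
#' Compares two genotype vectors over the shared identity SNPs (31 common
#' SNPs on chromosomes 10 and 20 in the default panel) and flags pairs
#' whose concordance is too low to come from the same individual.
#'
#' @param genotypes_a,genotypes_b Named character vectors (names = SNP ids,
#'   values = genotypes such as `"AA"`; `NA` for missing calls).
#' @param min_fraction Concordance below this flags a mismatch.
#' @param min_compared Fewer informative SNPs than this also flags.
#' @return List with `fraction_matching`, `n_compared`, `mismatch`.
#' @export
identity_concordance <- function(genotypes_a, genotypes_b,
                                 min_fraction = 0.90, min_compared = 10L) {
  shared <- intersect(names(genotypes_a), names(genotypes_b))
  if (length(shared) == 0) stop("disjoint SNP sets", call. = FALSE)
  a <- genotypes_a[shared]; b <- genotypes_b[shared]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  frac <- if (n > 0) sum(a[ok] == b[ok]) / n else NA_real_
  list(fraction_matching = frac, n_compared = n,
       mismatch = isTRUE(frac < min_fraction) || n < min_compared)
}

#' Simulate identity-check genotypes
#'
#' Draws Hardy-Weinberg genotypes at the identity SNPs for `n` individuals
#' (one column per individual). Used to build planted-swap fixtures for
#' the identity check.
#'
#' @param n Number of individuals.
#' @param snp_panel A [default_snp_panel()]-shaped data.frame.
#' @param missing_rate Per-call missing probability.
#' @return Character matrix (SNPs x individuals) with SNP-id rownames.
#' @export
simulate_snp_genotypes <- function(n, snp_panel = default_snp_panel(),
                                   missing_rate = 0.02) {
  g <- vapply(seq_len(n), function(i) {
    dose <- stats::rbinom(nrow(snp_panel), 2, snp_panel$maf)
    geno <- ifelse(dose == 0, paste0(snp_panel$ref, snp_panel$ref),
            ifelse(dose == 1, paste0(snp_panel$ref, snp_panel$alt),
                   paste0(snp_panel$alt, snp_panel$alt)))
    geno[stats::runif(nrow(snp_panel)) < missing_rate] <- NA_character_
    geno
  }, character(nrow(snp_panel)))
  rownames(g) <- snp_panel$snp_id
  colnames(g) <- sprintf("ID%03d", seq_len(n))
  g
}
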