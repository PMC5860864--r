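# Synthetic-cohort generator: control panels, patient assay bundles, cohorts.
# All randomness flows from config$seed through derive_seed() so that a given
# configuration is bit-reproducible and independent draws use disjoint streams.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' reproduce the design of the source study: 188 healthy-control urines and
#' 188 control WBC panels (plus a 94-sample technical-specificity WBC set),
#' UID-family depths log-normal around a median of 10,000 per amplicon per
#' well, a per-position overdispersed background substitution process with
#' mean rate 1e-4, case mutant-allele fractions log-normal with median 8%
#' (multiplex) / 6% (TERT) truncated to [0.003, 0.8], and a down-scaled
#' 3,900-locus aneuploidy assay (100 loci per arm).
#'
#' @param seed Integer master seed; every stream is derived from it.
#' @param n_control_urines,n_control_wbc Control panel sizes.
#' @param n_control_wbc_technical Size of the separate technical-specificity
#'   WBC set (not used to build the reference by default).
#' @param uid_depth_meanlog,uid_depth_sdlog Log-normal parameters of the
#'   total UID-family count per amplicon per well.
#' @param background_error_rate Mean per-position substitution rate among
#'   UID families (set 0 for an error-free process).
#' @param position_rate_shape Gamma shape governing how much the mean error
#'   rate varies across panel positions (smaller = more heterogeneous).
#' @param error_dispersion Gamma shape of the per-observation rate mixing
#'   (smaller = heavier-than-Poisson tails in each well).
#' @param case_maf_meanlog_multiplex,case_maf_meanlog_tert,case_maf_sdlog
#'   Log-normal parameters of planted urine mutant fractions.
#' @param case_maf_range Truncation range of planted fractions.
#' @param tumor_mutation_probability Probability a case's tumor carries at
#'   least one queried mutation.
#' @param shed_probability Probability the urine contains assay-detectable
#'   tumor DNA given the tumor is mutated.
#' @param tert_mutation_probability Probability a mutated tumor carries a
#'   TERT-promoter hotspot mutation.
#' @param n_multiplex_mutations Integer vector of possible multiplex tumor
#'   mutation counts (sampled uniformly, conditional on the tumor being
#'   mutated; a tumor with zero multiplex draws and no TERT draw is given
#'   one multiplex mutation so "mutated" means mutated).
#' @param loci_per_arm Loci per chromosome arm in the aneuploidy assay.
#' @param locus_depth_meanlog,locus_depth_sdlog Log-normal parameters of a
#'   sample's total locus-count depth.
#' @param locus_weight_sdlog Log-sd of fixed per-locus amplification
#'   efficiencies (locus-to-locus imbalance shared by all samples).
#' @param recurrent_arms,recurrent_weight Recurrently altered arms and their
#'   sampling weight relative to other arms.
#' @param n_arm_events Integer vector of possible per-case arm-event counts.
#' @param tumor_aneuploid_probability Probability a case's tumor is
#'   aneuploid at all.
#' @param neoplastic_fraction_range Range of the urine neoplastic-cell
#'   fraction (drawn log-uniformly).
#' @param cytology_availability Probability a patient has a cytology result.
#' @param cytology_case_probs,cytology_control_probs Category probabilities
#'   (positive, atypical, negative) for cases and non-cases with cytology.
#' @param cohort_design Named list of `list(n = total, n_cases = cases)`
#'   per cohort; defaults to the three study cohorts.
#' @param panel,arm_map Panel and arm-map data.frames (see
#'   [default_panel()], [default_arm_map()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_control_urines = 188L,
                       n_control_wbc = 188L,
                       n_control_wbc_technical = 94L,
                       uid_depth_meanlog = log(1e4),
                       uid_depth_sdlog = 0.5,
                       background_error_rate = 1e-4,
                       position_rate_shape = 2,
                       error_dispersion = 20,
                       case_maf_meanlog_multiplex = log(0.08),
                       case_maf_meanlog_tert = log(0.06),
                       case_maf_sdlog = 1.0,
                       case_maf_range = c(0.003, 0.8),
                       tumor_mutation_probability = 0.95,
                       shed_probability = 0.91,
                       tert_mutation_probability = 0.6,
                       n_multiplex_mutations = 0:3,
                       loci_per_arm = 100L,
                       locus_depth_meanlog = log(4e7),
                       locus_depth_sdlog = 0.2,
                       locus_weight_sdlog = 0.1,
                       recurrent_arms = c("5q", "8q", "9p"),
                       recurrent_weight = 6,
                       n_arm_events = 1:5,
                       tumor_aneuploid_probability = 0.9,
                       neoplastic_fraction_range = c(0.002, 0.30),
                       cytology_availability = 0.61,
                       cytology_case_probs = c(positive = 0.43, atypical = 0.30, negative = 0.27),
                       cytology_control_probs = c(positive = 0, atypical = 0.25, negative = 0.75),
                       cohort_design = list(
                         early_detection = list(n = 570L, n_cases = 175L),
                         utuc = list(n = 56L, n_cases = 56L),
                         surveillance = list(n = 322L, n_cases = 187L)
                       ),
                       panel = default_panel(),
                       arm_map = default_arm_map(loci_per_arm)) {
  cfg <- as.list(environment())
  check_prob <- function(x, nm) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop("configuration error: `", nm, "` must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  check_prob(tumor_mutation_probability, "tumor_mutation_probability")
  check_prob(shed_probability, "shed_probability")
  check_prob(tert_mutation_probability, "tert_mutation_probability")
  check_prob(cytology_availability, "cytology_availability")
  check_prob(cytology_case_probs, "cytology_case_probs")
  check_prob(cytology_control_probs, "cytology_control_probs")
  if (background_error_rate < 0) {
    stop("configuration error: `background_error_rate` must be >= 0", call. = FALSE)
  }
  if (any(neoplastic_fraction_range <= 0) || any(neoplastic_fraction_range > 1)) {
    stop("configuration error: `neoplastic_fraction_range` must lie in (0, 1]",
         call. = FALSE)
  }
  if (uid_depth_sdlog < 0 || locus_depth_sdlog < 0) {
    stop("configuration error: `uid_depth_sdlog`/`locus_depth_sdlog` must be >= 0",
         call. = FALSE)
  }
  if (nrow(arm_map) %% length(unique(arm_map$arm)) != 0) {
    stop("configuration error: `arm_map` loci are not evenly divisible across arms",
         call. = FALSE)
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  seed:", x$seed, "\n")
  cat("  controls:", x$n_control_urines, "urines /", x$n_control_wbc, "WBC\n")
  cat("  panel:", nrow(x$panel), "queried positions;",
      nrow(x$arm_map), "aneuploidy loci over",
      length(unique(x$arm_map$arm)), "arms\n")
  cat("  background error rate:", x$background_error_rate, "\n")
  invisible(x)
}

# Deterministic sub-seed derivation (keeps values < 2^31 - 1).
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973 + 12345) %% 2147483647)
}

# Evaluate expr under a local RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Fixed per-position mean error rates, deterministic in config$seed and
# shared by every simulated sample so that positions keep their identity
# (this heterogeneity is why the caller normalizes per mutation).
panel_error_rates <- function(config) {
  n <- nrow(config$panel)
  if (config$background_error_rate == 0) {
    return(stats::setNames(rep(0, n), config$panel$key))
  }
  rates <- with_seed(derive_seed(config$seed, 101), {
    stats::rgamma(n, shape = config$position_rate_shape,
                  rate = config$position_rate_shape / config$background_error_rate)
  })
  stats::setNames(rates, config$panel$key)
}

# Fixed per-locus amplification weights for the aneuploidy assay.
locus_weights <- function(config) {
  n <- nrow(config$arm_map)
  w <- with_seed(derive_seed(config$seed, 102), {
    stats::rlnorm(n, meanlog = 0, sdlog = config$locus_weight_sdlog)
  })
  stats::setNames(w / sum(w), config$arm_map$locus_id)
}

# Vectorized background + planted UID-family draw for a block of wells.
# rows: one per (sample, well, key); planted_maf = 0 where nothing planted.
draw_mutant_counts <- function(total, rate, planted_maf, dispersion) {
  n <- length(total)
  bg <- integer(n)
  pos <- rate > 0
  if (any(pos)) {
    lambda <- stats::rgamma(sum(pos), shape = dispersion,
                            rate = dispersion / rate[pos])
    bg[pos] <- stats::rpois(sum(pos), total[pos] * lambda)
  }
  pl <- integer(n)
  has <- planted_maf > 0
  if (any(has)) {
    pl[has] <- stats::rbinom(sum(has), total[has], planted_maf[has])
  }
  pmin(bg + pl, total)
}

# One block of mutation wells for a set of samples over the full panel.
# planted: NULL or data.frame(sample_id, key, fraction).
simulate_mutation_wells <- function(sample_ids, config, planted = NULL) {
  panel <- config$panel
  rates <- panel_error_rates(config)
  n_s <- length(sample_ids); n_k <- nrow(panel)
  grid <- data.frame(
    patient_id = rep(sample_ids, each = 2L * n_k),
    well = rep(rep(1:2, each = n_k), times = n_s),
    key = rep(panel$key, times = 2L * n_s),
    stringsAsFactors = FALSE
  )
  idx <- match(grid$key, panel$key)
  grid$assay <- panel$assay[idx]
  grid$chrom <- panel$chrom[idx]
  grid$pos <- panel$pos[idx]
  grid$ref <- panel$ref[idx]
  grid$alt <- panel$alt[idx]
  grid$gene <- panel$gene[idx]
  grid$total_uids <- pmax(10L, as.integer(round(
    stats::rlnorm(nrow(grid), config$uid_depth_meanlog, config$uid_depth_sdlog))))
  planted_maf <- rep(0, nrow(grid))
  if (!is.null(planted) && nrow(planted) > 0) {
    if (any(planted$fraction <= 0 | planted$fraction > 1)) {
      stop("planted mutant fraction must lie in (0, 1]", call. = FALSE)
    }
    m <- match(paste(grid$patient_id, grid$key),
               paste(planted$sample_id, planted$key))
    hit <- !is.na(m)
    planted_maf[hit] <- planted$fraction[m[hit]]
  }
  grid$mutant_uids <- draw_mutant_counts(grid$total_uids, rates[grid$key],
                                         planted_maf, config$error_dispersion)
  grid$maf <- grid$mutant_uids / grid$total_uids
  grid[, c("patient_id", "assay", "well", "chrom", "pos", "ref", "alt",
           "gene", "mutant_uids", "total_uids", "maf", "key")]
}

#' Simulate healthy-control panels
#'
#' Generates the two control sets the calling pipeline is calibrated on:
#' white-blood-cell (WBC) DNA panels, which carry only the background error
#' process and define the mutation-specific null, and healthy-volunteer
#' urine panels, used to set the Stouffer-Z threshold. Each control sample
#' is assayed in two independent PCR wells per assay. A third, smaller WBC
#' set for technical-specificity checks is emitted alongside.
#'
#' @param config A [sim_config()].
#' @return A list with mutation well tables `wbc`, `urine`,
#'   `wbc_technical` (data.frames in the standard mutation-table layout)
#'   and `urine_loci`, a loci x samples count matrix of euploid
#'   aneuploidy-assay profiles for the control urines.
#' @export
simulate_control_panels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  wbc_ids <- sprintf("WBC%03d", seq_len(config$n_control_wbc))
  urine_ids <- sprintf("CTRL%03d", seq_len(config$n_control_urines))
  tech_ids <- sprintf("TWBC%03d", seq_len(config$n_control_wbc_technical))
  wbc <- with_seed(derive_seed(config$seed, 201),
                   simulate_mutation_wells(wbc_ids, config))
  urine <- with_seed(derive_seed(config$seed, 202),
                     simulate_mutation_wells(urine_ids, config))
  tech <- with_seed(derive_seed(config$seed, 203),
                    simulate_mutation_wells(tech_ids, config))
  loci <- with_seed(derive_seed(config$seed, 204),
                    simulate_euploid_profiles(length(urine_ids), config,
                                              sample_ids = urine_ids))
  list(wbc = wbc, urine = urine, wbc_technical = tech, urine_loci = loci)
}

#' Simulate an independent control urine panel
#'
#' Draws a fresh set of healthy-control urine mutation wells under the
#' same configuration — in particular the same fixed per-position error
#' landscape — but an independent noise seed. Used for held-out
#' specificity checks of thresholds calibrated on the primary panel.
#'
#' @param config A [sim_config()].
#' @param n Number of control urines.
#' @param seed Integer seed for the independent draw.
#' @return A mutation well table data.frame.
#' @export
simulate_urine_panel <- function(config, n = config$n_control_urines, seed) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sprintf("HELD%03d", seq_len(n))
  with_seed(seed, simulate_mutation_wells(ids, config))
}

#' Simulate euploid aneuploidy-assay profiles
#'
#' Draws locus-count profiles with no arm events: counts are multinomial
#' around the fixed per-locus amplification weights at a log-normally
#' distributed total depth. Uses the current RNG state (seed it yourself or
#' call through [simulate_control_panels()]).
#'
#' @param n Number of profiles.
#' @param config A [sim_config()].
#' @param sample_ids Optional column names.
#' @return A loci x samples integer matrix with locus_id rownames.
#' @export
simulate_euploid_profiles <- function(n, config, sample_ids = NULL) {
  w <- locus_weights(config)
  depth <- as.integer(round(stats::rlnorm(n, config$locus_depth_meanlog,
                                          config$locus_depth_sdlog)))
  m <- vapply(seq_len(n), function(i) {
    as.integer(stats::rmultinom(1, depth[i], w))
  }, integer(length(w)))
  rownames(m) <- names(w)
  colnames(m) <- if (is.null(sample_ids)) sprintf("EU%04d", seq_len(n)) else sample_ids
  m
}

# Locus profile for one sample given arm events at a neoplastic fraction.
# Single-copy events scale a diploid arm's expected representation by
# (1 + nf/2) for gains and (1 - nf/2) for losses.
simulate_locus_profile <- function(config, arm_events = NULL, neoplastic_fraction = 0) {
  w <- locus_weights(config)
  if (!is.null(arm_events) && nrow(arm_events) > 0 && neoplastic_fraction > 0) {
    fac <- stats::setNames(rep(1, length(w)), config$arm_map$arm)
    for (i in seq_len(nrow(arm_events))) {
      sgn <- if (arm_events$type[i] == "gain") 1 else -1
      hit <- config$arm_map$arm == arm_events$arm[i]
      fac[hit] <- 1 + sgn * neoplastic_fraction / 2
    }
    w <- w * fac
    w <- w / sum(w)
  }
  depth <- as.integer(round(stats::rlnorm(1, config$locus_depth_meanlog,
                                          config$locus_depth_sdlog)))
  stats::setNames(as.integer(stats::rmultinom(1, depth, w)), config$arm_map$locus_id)
}

#' Simulate one patient's assay bundle
#'
#' Produces the full per-patient measurement set: two multiplex wells, two
#' TERT wells (planted urine mutations appear in both wells, binomially
#' sampled per well and independent across wells, superimposed on the
#' background error process) and one aneuploidy locus-count profile in
#' which the patient's arm events scale arm representation by
#' (1 ± neoplastic_fraction / 2).
#'
#' @param truth A single-row truth record (see [simulate_cohort()]) or a
#'   list with elements `patient_id`, `planted` (data.frame `key`,
#'   `fraction`), `arm_events` (data.frame `arm`, `type`),
#'   `neoplastic_fraction`.
#' @param config A [sim_config()].
#' @param seed Optional integer; defaults to a stream derived from the
#'   config seed and the patient id.
#' @return A list with `mutations` (well table) and `loci` (named integer
#'   vector of locus counts).
#' @export
simulate_patient <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  planted <- truth$planted
  if (!is.null(planted) && nrow(planted) > 0) {
    if (any(planted$fraction <= 0 | planted$fraction > 1)) {
      stop("planted mutant fraction must lie in (0, 1]", call. = FALSE)
    }
    planted <- data.frame(sample_id = truth$patient_id, key = planted$key,
                          fraction = planted$fraction, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, 300 + sum(utf8ToInt(truth$patient_id)))
  }
  with_seed(seed, {
    muts <- simulate_mutation_wells(truth$patient_id, config, planted = planted)
    loci <- simulate_locus_profile(config, truth$arm_events,
                                   truth$neoplastic_fraction)
    list(mutations = muts, loci = loci)
  })
}

# Draw the tumor/urine truth for one case given the panel.
draw_case_truth <- function(config) {
  panel <- config$panel
  mutated <- stats::runif(1) < config$tumor_mutation_probability
  tumor_keys <- character(0)
  if (mutated) {
    n_mult <- sample(config$n_multiplex_mutations, 1)
    has_tert <- stats::runif(1) < config$tert_mutation_probability
    if (n_mult == 0 && !has_tert) n_mult <- 1
    mult_pool <- panel$key[panel$assay == "multiplex"]
    # weight multiplex picks by gene prevalence implied by panel density
    if (n_mult > 0) tumor_keys <- sample(mult_pool, n_mult)
    if (has_tert) {
      tert_pool <- panel$key[panel$assay == "tert"]
      tumor_keys <- c(tumor_keys, sample(tert_pool, 1,
                                         prob = c(0.79, 0.19, 0.02)))
    }
  }
  shed <- mutated && stats::runif(1) < config$shed_probability
  planted <- data.frame(key = character(0), fraction = numeric(0),
                        stringsAsFactors = FALSE)
  if (shed && length(tumor_keys) > 0) {
    assays <- panel$assay[match(tumor_keys, panel$key)]
    meanlog <- ifelse(assays == "tert", config$case_maf_meanlog_tert,
                      config$case_maf_meanlog_multiplex)
    f <- stats::rlnorm(length(tumor_keys), meanlog, config$case_maf_sdlog)
    f <- pmin(pmax(f, config$case_maf_range[1]), config$case_maf_range[2])
    planted <- data.frame(key = tumor_keys, fraction = f, stringsAsFactors = FALSE)
  }
  aneuploid <- stats::runif(1) < config$tumor_aneuploid_probability
  arm_events <- data.frame(arm = character(0), type = character(0),
                           stringsAsFactors = FALSE)
  nf <- 0
  if (aneuploid) {
    arms <- unique(config$arm_map$arm)
    wts <- ifelse(arms %in% config$recurrent_arms, config$recurrent_weight, 1)
    k <- sample(config$n_arm_events, 1)
    picked <- sample(arms, k, prob = wts)
    canonical <- c("5q" = "gain", "8q" = "gain", "9p" = "loss")
    type <- ifelse(picked %in% names(canonical), canonical[picked],
                   sample(c("gain", "loss"), length(picked), replace = TRUE))
    arm_events <- data.frame(arm = picked, type = unname(type),
                             stringsAsFactors = FALSE)
  }
  if (shed) {
    r <- config$neoplastic_fraction_range
    nf <- exp(stats::runif(1, log(r[1]), log(r[2])))
  }
  list(tumor_keys = tumor_keys, planted = planted, arm_events = arm_events,
       neoplastic_fraction = nf, shed = shed, tumor_mutated = mutated,
       tumor_aneuploid = aneuploid)
}

draw_cytology <- function(is_case, config) {
  if (stats::runif(1) >= config$cytology_availability) return("unavailable")
  probs <- if (is_case) config$cytology_case_probs else config$cytology_control_probs
  sample(c("positive", "atypical", "negative"), 1, prob = probs)
}

#' Simulate a full patient cohort
#'
#' Generates truth records, clinical sheet and assay data for one cohort.
#' Case counts match the design exactly: case status is assigned
#' deterministically and the order shuffled under the seed. Cases carry a
#' tumor mutation profile (multiplex and/or TERT), a urine-shedding
#' indicator, planted urine mutant fractions, arm events and a neoplastic
#' fraction; collection and diagnosis dates give cases a positive lead
#' time.
#'
#' @param config A [sim_config()].
#' @param cohort Name of the design entry in `config$cohort_design`, or a
#'   list `list(n =, n_cases =)`.
#' @return A list of class `uroseek_cohort`: `truth` (truth table),
#'   `clinical` (clinical sheet), `mutations` (well table for all
#'   patients), `loci` (loci x patients matrix), `tumor_mutations`
#'   (data.frame patient_id, key), `cohort`, `config`.
#' @export
simulate_cohort <- function(config, cohort = "early_detection") {
  stopifnot(inherits(config, "sim_config"))
  design <- if (is.list(cohort)) cohort else config$cohort_design[[cohort]]
  cohort_name <- if (is.list(cohort)) (cohort$name %||% "custom") else cohort
  if (is.null(design)) stop("unknown cohort design: ", cohort, call. = FALSE)
  n <- design$n; n_cases <- design$n_cases
  if (n_cases > n) stop("case count exceeds cohort size", call. = FALSE)
  ids <- sprintf("%s_P%04d", toupper(substr(cohort_name, 1, 3)), seq_len(n))

  seed0 <- derive_seed(config$seed, 400 + sum(utf8ToInt(cohort_name)))
  with_seed(seed0, {
    is_cancer <- sample(rep(c(TRUE, FALSE), c(n_cases, n - n_cases)))
    base_date <- as.Date("2015-01-01")
    collection <- base_date + sample.int(365L, n, replace = TRUE)
    truth_list <- vector("list", n)
    cytology <- character(n)
    diagnosis <- rep(as.Date(NA), n)
    for (i in seq_len(n)) {
      if (is_cancer[i]) {
        ct <- draw_case_truth(config)
        # days to clinical diagnosis: most cases within months, a tail > 1 yr
        delay <- stats::rgamma(1, shape = 0.55, scale = 130)
        diagnosis[i] <- collection[i] + round(delay)
      } else {
        ct <- list(tumor_keys = character(0),
                   planted = data.frame(key = character(0), fraction = numeric(0)),
                   arm_events = data.frame(arm = character(0), type = character(0)),
                   neoplastic_fraction = 0, shed = FALSE,
                   tumor_mutated = FALSE, tumor_aneuploid = FALSE)
      }
      cytology[i] <- draw_cytology(is_cancer[i], config)
      truth_list[[i]] <- ct
    }
    patient_seeds <- sample.int(2^31 - 2, n)
  })

  bundles <- lapply(seq_len(n), function(i) {
    simulate_patient(
      list(patient_id = ids[i], planted = truth_list[[i]]$planted,
           arm_events = truth_list[[i]]$arm_events,
           neoplastic_fraction = truth_list[[i]]$neoplastic_fraction),
      config, seed = patient_seeds[i])
  })
  mutations <- do.call(rbind, lapply(bundles, `[[`, "mutations"))
  loci <- vapply(bundles, `[[`, numeric(nrow(config$arm_map)), "loci")
  storage.mode(loci) <- "integer"
  rownames(loci) <- config$arm_map$locus_id
  colnames(loci) <- ids

  truth <- data.frame(
    patient_id = ids,
    cohort = cohort_name,
    is_cancer = is_cancer,
    tumor_mutated = vapply(truth_list, `[[`, logical(1), "tumor_mutated"),
    shed = vapply(truth_list, `[[`, logical(1), "shed"),
    tumor_aneuploid = vapply(truth_list, `[[`, logical(1), "tumor_aneuploid"),
    n_planted = vapply(truth_list, function(t) nrow(t$planted), integer(1)),
    neoplastic_fraction = vapply(truth_list, `[[`, numeric(1), "neoplastic_fraction"),
    cytology = cytology,
    collection_date = collection,
    diagnosis_date = diagnosis,
    stringsAsFactors = FALSE
  )
  tumor_mutations <- do.call(rbind, lapply(seq_len(n), function(i) {
    ks <- truth_list[[i]]$tumor_keys
    if (length(ks) == 0) return(NULL)
    data.frame(patient_id = ids[i], key = ks, stringsAsFactors = FALSE)
  }))
  planted_tbl <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- truth_list[[i]]$planted
    if (nrow(p) == 0) return(NULL)
    data.frame(patient_id = ids[i], key = p$key, fraction = p$fraction,
               stringsAsFactors = FALSE)
  }))
  clinical <- truth[, c("patient_id", "cohort", "is_cancer", "cytology",
                        "collection_date", "diagnosis_date")]
  structure(list(truth = truth, clinical = clinical, mutations = mutations,
                 loci = loci, tumor_mutations = tumor_mutations,
                 planted = planted_tbl, cohort = cohort_name, config = config),
            class = "uroseek_cohort")
}

#' @export
print.uroseek_cohort <- function(x, ...) {
  cat("Synthetic cohort '", x$cohort, "': ", nrow(x$truth), " patients (",
      sum(x$truth$is_cancer), " cancers)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
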