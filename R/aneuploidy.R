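# Arm-level aneuploidy detection from repeat-amplicon locus counts:
# share-based arm z-scores against a euploid reference, a synthetic
# low-fraction training set, an RBF-SVM genome-wide score in [0,1], and the
# strict (> 0.7 AND >= 1 arm call) decision rule.

#' Build the euploid arm reference
#'
#' Per-arm mean and standard deviation of arm representation (the sum of
#' locus shares on the arm) across a panel of euploid control profiles.
#'
#' @param profiles Loci x samples count matrix with locus_id rownames.
#' @param arm_map Data.frame mapping `locus_id` to `arm`.
#' @return List with `arms`, `mean`, `sd` (per-arm), `arm_map`.
#' @export
euploid_reference <- function(profiles, arm_map) {
  shares <- arm_share_matrix(profiles, arm_map)
  list(arms = rownames(shares),
       mean = rowMeans(shares),
       sd = pmax(apply(shares, 1, stats::sd), 1e-8),
       arm_map = arm_map)
}

# arms x samples matrix of arm shares (each column sums to 1).
arm_share_matrix <- function(profiles, arm_map) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, ncol = 1,
                                                 dimnames = list(names(profiles), "s1"))
  unknown <- setdiff(rownames(profiles), arm_map$locus_id)
  if (length(unknown) > 0) {
    stop("unknown loci not in arm map: ",
         paste(utils::head(unknown), collapse = ", "), call. = FALSE)
  }
  arm <- arm_map$arm[match(rownames(profiles), arm_map$locus_id)]
  totals <- colSums(profiles)
  if (any(totals <= 0)) stop("profile with zero total depth", call. = FALSE)
  agg <- rowsum(profiles, arm)
  sweep(agg, 2, totals, "/")
}

#' Arm-level z-scores for a locus-count profile
#'
#' Converts locus counts to shares (count / total depth), sums them per
#' chromosome arm, and standardizes each arm against the euploid reference:
#' `z = (share - ref_mean) / ref_sd`. Arms are called `gain` when
#' `z > arm_call_threshold`, `loss` when `z < -arm_call_threshold`, else
#' `neutral`.
#'
#' @param profile Named integer vector (or one-column matrix) of locus
#'   counts.
#' @param reference A [euploid_reference()] (or an `aneuploidy_model`,
#'   whose reference and threshold are used).
#' @param arm_call_threshold |z| cutoff; defaults to the model's, else 5.
#' @return data.frame with `arm`, `share`, `z`, `call`; attribute
#'   `total_depth`.
#' @export
arm_zscores <- function(profile, reference, arm_call_threshold = NULL) {
  if (inherits(reference, "aneuploidy_model")) {
    if (is.null(arm_call_threshold)) arm_call_threshold <- reference$arm_call_threshold
    reference <- reference$reference
  }
  if (is.null(arm_call_threshold)) arm_call_threshold <- 5
  shares <- arm_share_matrix(profile, reference$arm_map)[reference$arms, , drop = FALSE]
  z <- (shares[, 1] - reference$mean) / reference$sd
  call <- ifelse(z > arm_call_threshold, "gain",
                 ifelse(z < -arm_call_threshold, "loss", "neutral"))
  out <- data.frame(arm = reference$arms, share = shares[, 1], z = z,
                    call = call, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total_depth") <- sum(profile)
  out
}

# z feature matrix (samples x arms) for many profiles at once.
arm_z_features <- function(profiles, reference) {
  shares <- arm_share_matrix(profiles, reference$arm_map)[reference$arms, , drop = FALSE]
  t((shares - reference$mean) / reference$sd)
}

#' Build the synthetic aneuploid/euploid training set
#'
#' Mirrors the published training design: a large set of low
#' neoplastic-cell-fraction synthetic aneuploid samples (default 3,150)
#' plus euploid samples (default 677), all resampled from the euploid
#' control panel. Aneuploid samples carry 1-5 random single-copy arm
#' events injected at a neoplastic fraction drawn uniformly from
#' `fraction_range`. Each synthetic sample is a parametric resample of the
#' euploid panel: one multinomial draw around the pooled locus proportions
#' of the control profiles, at a depth drawn from the panel's realized
#' depths, so it carries the same single draw of measurement noise as a
#' real sample; aneuploid samples get their arm events injected into the
#' expected proportions before the draw. Features are the 39 arm z-scores
#' against the euploid reference.
#'
#' @param euploid_profiles Loci x samples count matrix (>= 50 columns).
#' @param arm_map Locus-to-arm map.
#' @param n_aneuploid,n_euploid Class sizes.
#' @param fraction_range Neoplastic-fraction range for injected events.
#' @param n_events_range Possible numbers of injected arm events.
#' @param seed Integer seed.
#' @return List with `features` (samples x arms), `labels` (factor
#'   aneuploid/euploid), `events` (per-row injected arms and fraction),
#'   `reference`.
#' @export
build_training_set <- function(euploid_profiles, arm_map,
                               n_aneuploid = 3150L, n_euploid = 677L,
                               fraction_range = c(0.005, 0.10),
                               n_events_range = 1:5, seed = 1L) {
  if (ncol(euploid_profiles) < 50) {
    stop("need >= 50 euploid control profiles to build a training set", call. = FALSE)
  }
  reference <- euploid_reference(euploid_profiles, arm_map)
  arms <- reference$arms
  locus_arm <- arm_map$arm[match(rownames(euploid_profiles), arm_map$locus_id)]
  pooled <- rowSums(euploid_profiles) / sum(euploid_profiles)
  depths <- colSums(euploid_profiles)

  resample_one <- function(events, fraction) {
    p <- pooled
    if (length(events$arm) > 0 && fraction > 0) {
      fac <- rep(1, length(p))
      for (j in seq_along(events$arm)) {
        sgn <- if (events$type[j] == "gain") 1 else -1
        fac[locus_arm == events$arm[j]] <- 1 + sgn * fraction / 2
      }
      p <- p * fac
      p <- p / sum(p)
    }
    depth <- depths[sample.int(length(depths), 1)]
    as.integer(stats::rmultinom(1, depth, p))
  }

  with_seed(seed, {
    n_total <- n_aneuploid + n_euploid
    mat <- matrix(0L, nrow = nrow(euploid_profiles), ncol = n_total)
    ev_arms <- character(n_total); ev_types <- character(n_total)
    ev_frac <- numeric(n_total)
    for (i in seq_len(n_aneuploid)) {
      k <- sample(n_events_range, 1)
      picked <- sample(arms, k)
      types <- sample(c("gain", "loss"), k, replace = TRUE)
      f <- stats::runif(1, fraction_range[1], fraction_range[2])
      mat[, i] <- resample_one(list(arm = picked, type = types), f)
      ev_arms[i] <- paste(picked, collapse = ",")
      ev_types[i] <- paste(types, collapse = ",")
      ev_frac[i] <- f
    }
    for (i in seq_len(n_euploid)) {
      mat[, n_aneuploid + i] <- resample_one(list(arm = character(0)), 0)
    }
    rownames(mat) <- rownames(euploid_profiles)
    features <- arm_z_features(mat, reference)
    labels <- factor(rep(c("aneuploid", "euploid"), c(n_aneuploid, n_euploid)),
                     levels = c("aneuploid", "euploid"))
    list(features = features, labels = labels,
         events = data.frame(arms = ev_arms, types = ev_types,
                             fraction = ev_frac, stringsAsFactors = FALSE),
         reference = reference)
  })
}

#' Train the genome-wide aneuploidy classifier
#'
#' Fits a radial-basis support vector machine on the 39 arm z-score
#' features and maps its decision values to a genome-wide aneuploidy score
#' in \[0, 1\] via the SVM's internal held-out (cross-validated) Platt
#' probability calibration. The per-arm call threshold is set so that at
#' most `euploid_arm_rate` of euploid training arms are called.
#'
#' @param training A [build_training_set()] result.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost SVM regularization constant.
#' @param score_threshold Genome-wide positivity cutoff (strict >).
#' @param euploid_arm_rate Target per-arm call rate among euploid training
#'   arms.
#' @param seed Seed for the internal probability cross-validation.
#' @return Object of class `aneuploidy_model`.
#' @importFrom e1071 svm
#' @export
train_aneuploidy_model <- function(training, kernel = c("radial", "linear"),
                                   cost = 1, score_threshold = 0.7,
                                   euploid_arm_rate = 0.01, seed = 1L) {
  kernel <- match.arg(kernel)
  if (nlevels(droplevels(training$labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  fit <- with_seed(seed, {
    e1071::svm(x = training$features, y = training$labels, kernel = kernel,
               cost = cost, probability = TRUE, scale = TRUE)
  })
  eu_z <- training$features[training$labels == "euploid", , drop = FALSE]
  arm_call_threshold <- as.numeric(stats::quantile(abs(eu_z), 1 - euploid_arm_rate))
  structure(list(
    svm = fit,
    reference = training$reference,
    arm_call_threshold = arm_call_threshold,
    score_threshold = score_threshold,
    metadata = list(version = "1.0", kernel = kernel, cost = cost, seed = seed,
                    n_aneuploid = sum(training$labels == "aneuploid"),
                    n_euploid = sum(training$labels == "euploid"),
                    fraction_range = range(training$events$fraction[
                      training$events$fraction > 0]))
  ), class = "aneuploidy_model")
}

#' @export
print.aneuploidy_model <- function(x, ...) {
  cat("Aneuploidy model (", x$metadata$kernel, " SVM): trained on ",
      x$metadata$n_aneuploid, " aneuploid + ", x$metadata$n_euploid,
      " euploid samples\n", sep = "")
  cat("  score threshold >", x$score_threshold,
      "; arm |z| threshold", signif(x$arm_call_threshold, 4), "\n")
  invisible(x)
}

#' The aneuploidy decision rule
#'
#' A sample is aneuploidy-positive when its genome-wide score strictly
#' exceeds the threshold AND at least one chromosome arm is called gained
#' or lost. A score of exactly the threshold is negative, as is any score
#' with zero arm calls.
#'
#' @param score Genome-wide aneuploidy score(s) in \[0, 1\].
#' @param n_arm_events Number of arms called gained or lost.
#' @param score_threshold Strict cutoff (default 0.7).
#' @return Logical vector.
#' @export
aneuploidy_decision <- function(score, n_arm_events, score_threshold = 0.7) {
  if (any(score < 0 | score > 1)) stop("score must lie in [0, 1]", call. = FALSE)
  score > score_threshold & n_arm_events >= 1
}

#' Score a sample for aneuploidy
#'
#' Computes the genome-wide aneuploidy score (calibrated SVM probability of
#' the aneuploid class, in \[0, 1\]) and the per-arm gain/loss calls, and
#' applies the decision rule: positive iff score strictly exceeds the score
#' threshold (default 0.7) AND at least one arm is called gained or lost.
#'
#' @param profile Named locus-count vector, or a loci x samples matrix to
#'   score several samples.
#' @param model An [train_aneuploidy_model()] object.
#' @return For a single profile, a list with `score`, `arm_calls`
#'   (data.frame from [arm_zscores()]), `n_arm_events`, `positive`. For a
#'   matrix, a data.frame with one row per sample.
#' @export
score_aneuploidy <- function(profile, model) {
  stopifnot(inherits(model, "aneuploidy_model"))
  single <- is.null(dim(profile))
  if (single) profile <- matrix(profile, ncol = 1,
                                dimnames = list(names(profile), "s1"))
  if (is.null(colnames(profile))) {
    colnames(profile) <- sprintf("s%04d", seq_len(ncol(profile)))
  }
  feats <- arm_z_features(profile, model$reference)
  pred <- stats::predict(model$svm, feats, probability = TRUE)
  score <- attr(pred, "probabilities")[, "aneuploid"]
  n_events <- colSums(abs(t(feats)) > model$arm_call_threshold)
  positive <- aneuploidy_decision(score, n_events, model$score_threshold)
  if (single) {
    list(score = unname(score[1]),
         arm_calls = arm_zscores(profile[, 1], model),
         n_arm_events = unname(n_events[1]),
         positive = unname(positive[1]))
  } else {
    data.frame(patient_id = colnames(profile), score = unname(score),
               n_arm_events = unname(n_events), positive = unname(positive),
               stringsAsFactors = FALSE)
  }
}

#' Detection-rate curve over neoplastic fractions
#'
#' For each neoplastic fraction, simulates `n_reps` samples carrying a
#' single random arm gain at that fraction and reports the fraction called
#' positive. Each sample is one multinomial draw around the pooled
#' locus proportions of the supplied euploid panel (pooling removes the
#' sampling noise of any single control, so a simulated sample carries the
#' same one draw of measurement noise as a real one). Used to locate the
#' reliable-detection limit of the assay.
#'
#' @param model An `aneuploidy_model`.
#' @param euploid_profiles Loci x samples matrix defining the euploid
#'   baseline and depths.
#' @param fractions Non-empty numeric vector of neoplastic fractions.
#' @param n_reps Replicates per fraction.
#' @param seed Integer seed.
#' @return data.frame with `fraction`, `detection_rate`, `n_reps`.
#' @export
detection_limit_curve <- function(model, euploid_profiles, fractions,
                                  n_reps = 100L, seed = 1L) {
  if (length(fractions) == 0) stop("empty fraction list", call. = FALSE)
  arm_map <- model$reference$arm_map
  locus_arm <- arm_map$arm[match(rownames(euploid_profiles), arm_map$locus_id)]
  pooled <- rowSums(euploid_profiles) / sum(euploid_profiles)
  depth <- as.integer(round(stats::median(colSums(euploid_profiles))))
  arms <- model$reference$arms
  rates <- with_seed(seed, {
    vapply(fractions, function(f) {
      mat <- vapply(seq_len(n_reps), function(i) {
        arm <- sample(arms, 1)
        p <- pooled
        if (f > 0) {
          p[locus_arm == arm] <- p[locus_arm == arm] * (1 + f / 2)
          p <- p / sum(p)
        }
        as.integer(stats::rmultinom(1, depth, p))
      }, integer(length(pooled)))
      rownames(mat) <- rownames(euploid_profiles)
      mean(score_aneuploidy(mat, model)$positive)
    }, numeric(1))
  })
  data.frame(fraction = fractions, detection_rate = rates, n_reps = n_reps)
}

#' Save / load an aneuploidy model
#'
#' Persists the model as a single versioned JSON archive: metadata,
#' euploid reference and thresholds as plain JSON arrays, and the fitted
#' SVM as a base64-encoded serialized payload.
#'
#' @param model An `aneuploidy_model`.
#' @param path File path.
#' @return `save_aneuploidy_model` returns `path` invisibly;
#'   `load_aneuploidy_model` returns the restored model.
#' @export
save_aneuploidy_model <- function(model, path) {
  stopifnot(inherits(model, "aneuploidy_model"))
  doc <- list(
    format = "uroseek_aneuploidy_model",
    version = model$metadata$version,
    metadata = model$metadata,
    arm_call_threshold = model$arm_call_threshold,
    score_threshold = model$score_threshold,
    reference = list(arms = model$reference$arms,
                     mean = unname(model$reference$mean),
                     sd = unname(model$reference$sd),
                     arm_map = model$reference$arm_map),
    svm_payload = jsonlite::base64_enc(serialize(model$svm, NULL))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_aneuploidy_model
#' @export
load_aneuploidy_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "uroseek_aneuploidy_model")) {
    stop("not an aneuploidy model archive: ", path, call. = FALSE)
  }
  reference <- list(arms = doc$reference$arms,
                    mean = stats::setNames(doc$reference$mean, doc$reference$arms),
                    sd = stats::setNames(doc$reference$sd, doc$reference$arms),
                    arm_map = as.data.frame(doc$reference$arm_map,
                                            stringsAsFactors = FALSE))
  structure(list(
    svm = unserialize(jsonlite::base64_dec(doc$svm_payload)),
    reference = reference,
    arm_call_threshold = doc$arm_call_threshold,
    score_threshold = doc$score_threshold,
    metadata = doc$metadata
  ), class = "aneuploidy_model")
}
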