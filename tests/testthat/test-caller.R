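# Mutation caller: MAF arithmetic, normalization, empirical p-values,
# Stouffer combination, threshold calibration, the two-criterion call and
# the identity check.

test_that("MAF is exact count arithmetic and rejects undefined input", {
  expect_equal(compute_maf(5, 100), 0.05)
  expect_equal(compute_maf(0, 10000), 0)
  expect_equal(compute_maf(8140, 100000), 0.0814)
  expect_error(compute_maf(1, 0), "total")
  expect_error(compute_maf(11, 10), "mutant")
})

test_that("control reference summarizes per-mutation distributions", {
  ref <- build_control_reference(test_controls$wbc)
  # pooled null: every control observation contributes once (both wells)
  expect_equal(length(ref$pooled_null),
               nrow(test_cfg$panel) * 188L * 2L)
  expect_false(is.unsorted(ref$pooled_null))
  expect_true(all(ref$keys$scale > 0))
  expect_error(build_control_reference(test_controls$wbc[0, ]), "empty")
})

test_that("all-zero control mutations get floored scale and non-positive scores", {
  tab <- make_patient_wells("C1", data.frame(
    key = "chr1:100:A:T", assay = "multiplex", m1 = 0, m2 = 0,
    t1 = 1000, t2 = 1000))
  tab <- rbind(tab, transform(tab, patient_id = "C2"))
  ref <- build_control_reference(tab)
  expect_equal(ref$keys$location, 0)
  expect_equal(ref$keys$scale, 0.2 / 4)  # floor 0.2 / n_obs dominates
  expect_true(all(ref$pooled_null <= 0))
  expect_equal(ref$keys$max_maf, 0)
})

test_that("per-mutation control maximum is the plain maximum", {
  mafs <- c(0, 1e-4, 3e-4)
  tab <- do.call(rbind, lapply(seq_along(mafs), function(i) {
    make_patient_wells(sprintf("C%d", i), data.frame(
      key = "chr2:5:G:A", assay = "multiplex",
      m1 = mafs[i] * 1e4, m2 = 0, t1 = 1e4, t2 = 1e4))
  }))
  ref <- build_control_reference(tab)
  expect_equal(ref$keys$max_maf, 3e-4)
})

test_that("normalized score is the centered, scaled MAF and is monotone", {
  ref <- test_reference
  k <- ref$keys$key[5]
  loc <- ref$keys$location[5]; sc <- ref$keys$scale[5]
  expect_equal(normalized_score(loc, k, ref), 0)
  expect_equal(normalized_score(loc + 2.5 * sc, k, ref), 2.5)
  mafs <- sort(runif(20))
  expect_false(is.unsorted(normalized_score(mafs, k, ref)))
  # explicit arithmetic: location 1e-4, scale 5e-5, maf 3.5e-4 -> 5
  expect_equal((3.5e-4 - 1e-4) / 5e-5, 5.0)
})

test_that("empirical p-values use add-one smoothing and match brute force", {
  null <- sort(rnorm(1000))
  expect_equal(empirical_pvalue(max(null) + 1, null), 1 / 1001)
  expect_equal(empirical_pvalue(min(null) - 1, null), 1)
  # tie handling and interior ranks against the brute-force oracle
  set.seed(8)
  nulls <- list(sort(rnorm(101)), sort(sample(0:5, 50, TRUE)), sort(rnorm(7)))
  for (nl in nulls) {
    scores <- c(nl[3], median(nl), max(nl), min(nl), rnorm(5))
    expect_equal(empirical_pvalue(scores, nl),
                 vapply(scores, brute_pvalue, 0, null = nl), tolerance = 1e-12)
  }
  # score at the median of an odd-length null has p ~ 0.5
  nl <- sort(rnorm(101))
  expect_equal(empirical_pvalue(median(nl), nl), brute_pvalue(median(nl), nl))
})

test_that("Stouffer combination obeys its closed-form identities", {
  p <- 0.03; u <- 5000
  expect_equal(stouffer_combine(p, p, u, u), sqrt(2) * qnorm(1 - p))
  # dominant first well: Z tends to z1
  expect_equal(stouffer_combine(0.01, 0.5, 1e10, 1), qnorm(0.99), tolerance = 1e-4)
  # worked arithmetic: p1=0.01, p2=0.10, uid1 = 4 uid2
  expect_equal(stouffer_combine(0.01, 0.10, 400, 100),
               (2 * qnorm(0.99) + qnorm(0.90)) / sqrt(5))
  expect_equal(round(stouffer_combine(0.01, 0.10, 400, 100), 3), 2.654)
  expect_error(stouffer_combine(0, 0.5, 10, 10), "p-values")
  expect_error(stouffer_combine(0.5, 0.5, 0, 10), "UID")
})

test_that("difference statistic is the signed excess over the control max", {
  ref <- test_reference
  k <- ref$keys$key[1]
  mx <- ref$keys$max_maf[1]
  expect_equal(difference_stat(mx, k, ref), 0)
  expect_equal(difference_stat(0.08, k, ref), 0.08 - mx)
  expect_lt(difference_stat(mx / 2, k, ref), 0)
})

test_that("threshold calibration allows exactly one positive control urine", {
  ref <- test_reference
  expect_equal(ref$t_diff, max(test_controls$wbc$maf))
  # the Stouffer threshold is the second-largest per-sample max Z
  mz <- sort(ref$calibration$max_z, decreasing = TRUE)
  expect_equal(ref$t_z, unname(mz[2]))
  expect_equal(sum(ref$calibration$max_z > ref$t_z), 1L)
  # re-scoring the calibration urines reproduces the single positive
  cm <- call_mutations(test_controls$urine, ref)
  n_pos <- sum(tapply(cm$samples$positive, cm$samples$patient_id, any))
  expect_equal(n_pos, 1L)
  expect_error(calibrate_thresholds(build_control_reference(test_controls$wbc),
                                    test_controls$wbc,
                                    test_controls$urine[test_controls$urine$patient_id == "CTRL001", ]),
               "2 control urine")
})

test_that("a mutation seen in only one well is never called positive", {
  ref <- test_reference
  k <- test_cfg$panel$key[test_cfg$panel$gene == "TP53"][1]
  tab <- make_patient_wells("P1", data.frame(
    key = k, assay = "multiplex", m1 = 2000, m2 = 0, t1 = 10000, t2 = 10000))
  # add the TERT wells so the sample is complete
  tert <- make_patient_wells("P1", data.frame(
    key = test_cfg$panel$key[test_cfg$panel$assay == "tert"][1],
    assay = "tert", m1 = 0, m2 = 0, t1 = 10000, t2 = 10000))
  out <- call_mutations(rbind(tab, tert), ref)
  row <- out$calls[out$calls$key == k, ]
  expect_false(row$present_in_both_wells)
  expect_false(row$positive)
  expect_false(any(out$samples$positive))
})

test_that("a planted 8% mutation is called, triggered by the difference criterion", {
  ref <- test_reference
  k <- test_cfg$panel$key[test_cfg$panel$gene == "TP53"][2]
  b <- simulate_patient(list(patient_id = "CASE1",
                             planted = data.frame(key = k, fraction = 0.08),
                             arm_events = NULL, neoplastic_fraction = 0),
                        test_cfg, seed = 202L)
  out <- call_mutations(b$mutations, ref)
  row <- out$calls[out$calls$key == k, ]
  expect_true(row$positive)
  expect_true(row$triggering_criterion %in% c("difference", "both"))
  expect_true(out$samples$positive[out$samples$assay == "multiplex"])
})

test_that("all-zero wells give an empty candidate list and a negative sample", {
  ref <- test_reference
  tab <- make_patient_wells("P0", data.frame(
    key = c("chr1:1:A:T", "chr5:1295228:G:A"), assay = c("multiplex", "tert"),
    m1 = 0, m2 = 0, t1 = 10000, t2 = 10000))
  out <- call_mutations(tab, ref)
  expect_equal(nrow(out$calls), 0L)
  expect_false(any(out$samples$positive))
})

test_that("a missing well is an error naming the patient", {
  ref <- test_reference
  tab <- make_patient_wells("PX", data.frame(
    key = "chr1:1:A:T", assay = "multiplex", m1 = 5, m2 = 5,
    t1 = 1000, t2 = 1000))
  expect_error(call_mutations(tab[tab$well == 1, ], ref), "two wells")
})

test_that("more mutant families never lower the statistics or flip a call off", {
  ref <- test_reference
  k <- test_cfg$panel$key[test_cfg$panel$gene == "FGFR3"][1]
  total <- 10000
  prev_z <- -Inf; prev_d <- -Inf; was_positive <- FALSE
  for (m in c(2, 5, 20, 100, 500, 2000, 8000)) {
    tab <- make_patient_wells("PM", data.frame(
      key = k, assay = "multiplex", m1 = m, m2 = m, t1 = total, t2 = total))
    tert <- make_patient_wells("PM", data.frame(
      key = "chr5:1295228:G:A", assay = "tert", m1 = 0, m2 = 0,
      t1 = total, t2 = total))
    out <- call_mutations(rbind(tab, tert), ref)
    row <- out$calls[out$calls$key == k, ]
    expect_gte(row$stouffer_z, prev_z)
    expect_gte(row$diff_stat, prev_d)
    if (was_positive) expect_true(row$positive)
    prev_z <- row$stouffer_z; prev_d <- row$diff_stat
    was_positive <- row$positive
  }
  expect_true(was_positive)
})

test_that("planted fractions at the 0.03% limit are detected at high depth", {
  cfg <- sim_config(seed = 57L, uid_depth_meanlog = log(1e5),
                    uid_depth_sdlog = 0.1)
  ctrl <- simulate_control_panels(cfg)
  ref <- calibrate_from_controls(ctrl)
  key <- cfg$panel$key[cfg$panel$gene == "TP53"][1]
  hits <- vapply(1:20, function(i) {
    b <- simulate_patient(list(patient_id = sprintf("S%02d", i),
                               planted = data.frame(key = key, fraction = 3e-4),
                               arm_events = NULL, neoplastic_fraction = 0),
                          cfg, seed = 7000 + i)
    out <- call_mutations(b$mutations, ref)
    any(out$calls$positive & out$calls$key == key)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("identity concordance flags planted sample swaps", {
  set.seed(31)
  g <- simulate_snp_genotypes(4)
  same <- identity_concordance(g[, 1], g[, 1])
  expect_equal(same$fraction_matching, 1)
  expect_false(same$mismatch)
  # a half-matching constructed pair is flagged
  a <- setNames(rep("AA", 30), sprintf("s%02d", 1:30))
  b <- a; b[1:15] <- "AB"
  half <- identity_concordance(a, b)
  expect_equal(half$fraction_matching, 0.5)
  expect_true(half$mismatch)
  expect_error(identity_concordance(setNames("AA", "x"), setNames("AA", "y")),
               "disjoint")
  # planted swap in a paired cohort: only the swapped pair mismatches
  urine <- g; tumor <- g
  tumor[, 2] <- g[, 3]  # swap
  flags <- vapply(1:4, function(i) {
    identity_concordance(urine[, i], tumor[, i])$mismatch
  }, logical(1))
  expect_equal(flags, c(FALSE, TRUE, FALSE, FALSE))
})
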