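# Synthetic-cohort generator: calibration of the error process, planted
# signal, arm events, cohort design and determinism.

test_that("zero background error rate gives exactly zero control MAFs", {
  cfg <- sim_config(seed = 3L, background_error_rate = 0,
                    n_control_urines = 5L, n_control_wbc = 5L,
                    n_control_wbc_technical = 2L)
  ctrl <- simulate_control_panels(cfg)
  expect_true(all(ctrl$wbc$mutant_uids == 0L))
  expect_true(all(ctrl$urine$maf == 0))
})

test_that("control panels match the study design and the error process mean", {
  expect_equal(length(unique(test_controls$urine$patient_id)), 188L)
  expect_equal(length(unique(test_controls$wbc$patient_id)), 188L)
  expect_equal(length(unique(test_controls$wbc_technical$patient_id)), 94L)
  # two wells per assay per control
  per <- with(test_controls$wbc, table(patient_id, assay, well))
  expect_true(all(per > 0))
  # empirical mean per-position MAF within 3 SE of the configured 1e-4;
  # observations at one position share its fixed rate, so the standard
  # error is taken across position means
  per_pos <- tapply(test_controls$wbc$maf, test_controls$wbc$key, mean)
  se <- sd(per_pos) / sqrt(length(per_pos))
  expect_lt(abs(mean(per_pos) - 1e-4), 3 * se)
})

test_that("planted mutations land in both wells at the planted fraction", {
  cfg <- sim_config(seed = 11L, uid_depth_sdlog = 0)  # depth fixed at 10,000
  key <- cfg$panel$key[cfg$panel$gene == "TP53"][1]
  lo <- qbinom(0.005, 10000, 0.08)
  hi <- qbinom(0.995, 10000, 0.08)
  for (i in 1:5) {
    b <- simulate_patient(list(patient_id = sprintf("P%d", i),
                               planted = data.frame(key = key, fraction = 0.08),
                               arm_events = NULL, neoplastic_fraction = 0),
                          cfg, seed = 100 + i)
    m <- b$mutations[b$mutations$key == key, ]
    expect_equal(nrow(m), 2L)
    # background adds at most a few families on top of the planted draw
    expect_true(all(m$mutant_uids >= lo & m$mutant_uids <= hi + 10))
  }
})

test_that("planted MAF is recovered unbiased over many wells", {
  cfg <- sim_config(seed = 13L)
  key <- cfg$panel$key[cfg$panel$gene == "KRAS"][1]
  f <- 0.05
  ids <- sprintf("M%04d", 1:300)
  planted <- data.frame(sample_id = ids, key = key, fraction = f)
  wells <- uroseek:::with_seed(991L,
    uroseek:::simulate_mutation_wells(ids, cfg, planted = planted))
  obs <- wells$maf[wells$key == key]   # 600 wells
  expect_gte(length(obs), 1000 * 0.5)  # 2 wells x 300 samples
  se <- sd(obs) / sqrt(length(obs))
  # unbiased up to the small additive background (~1e-4)
  expect_lt(abs(mean(obs) - f - 1e-4), 3 * se + 1e-4)
})

test_that("arm events scale arm representation by 1 +/- nf/2", {
  cfg <- sim_config(seed = 17L, locus_depth_meanlog = log(2e6),
                    locus_depth_sdlog = 0)
  arm_loci <- cfg$arm_map$locus_id[cfg$arm_map$arm == "8q"]
  ev <- data.frame(arm = "8q", type = "gain", stringsAsFactors = FALSE)
  share_gain <- replicate(20, {
    p <- uroseek:::with_seed(sample.int(1e6, 1), uroseek:::simulate_locus_profile(
      cfg, arm_events = ev, neoplastic_fraction = 0.10))
    sum(p[arm_loci]) / sum(p)
  })
  share_base <- replicate(20, {
    p <- uroseek:::with_seed(sample.int(1e6, 1), uroseek:::simulate_locus_profile(cfg))
    sum(p[arm_loci]) / sum(p)
  })
  # expected uplift ~5% (1 + 0.10/2), diluted only by renormalization
  ratio <- mean(share_gain) / mean(share_base)
  expect_gt(ratio, 1.035)
  expect_lt(ratio, 1.055)
})

test_that("gain share increases and loss share decreases with neoplastic fraction", {
  cfg <- sim_config(seed = 19L)
  mean_share <- function(arm, type, nf) {
    loci <- cfg$arm_map$locus_id[cfg$arm_map$arm == arm]
    ev <- data.frame(arm = arm, type = type, stringsAsFactors = FALSE)
    mean(replicate(10, {
      p <- uroseek:::simulate_locus_profile(cfg, ev, nf)
      sum(p[loci]) / sum(p)
    }))
  }
  set.seed(5)
  expect_gt(mean_share("5q", "gain", 0.25), mean_share("5q", "gain", 0.05))
  expect_lt(mean_share("9p", "loss", 0.25), mean_share("9p", "loss", 0.05))
})

test_that("locus profiles conserve their total depth across loci", {
  m <- test_controls$urine_loci
  expect_true(all(colSums(m) > 0))
  expect_equal(nrow(m), nrow(test_cfg$arm_map))
  # shares sum to one per sample by construction
  expect_equal(unname(colSums(sweep(m, 2, colSums(m), "/"))), rep(1, ncol(m)))
})

test_that("cohort design is honored exactly and degenerate designs flagged", {
  coh <- simulate_cohort(test_cfg, "early_detection")
  expect_equal(nrow(coh$truth), 570L)
  expect_equal(sum(coh$truth$is_cancer), 175L)
  allneg <- simulate_cohort(test_cfg, list(n = 10L, n_cases = 0L, name = "neg"))
  expect_equal(sum(allneg$truth$is_cancer), 0L)
  expect_error(simulate_cohort(test_cfg, list(n = 5L, n_cases = 6L)),
               "exceeds")
})

test_that("truth invariants hold: dates, shedding, planted within tumor", {
  coh <- simulate_cohort(test_cfg, "surveillance")
  tr <- coh$truth
  cases <- tr[tr$is_cancer, ]
  expect_true(all(cases$diagnosis_date >= cases$collection_date))
  expect_true(all(is.na(tr$diagnosis_date[!tr$is_cancer])))
  # every planted urine mutation is one of the patient's tumor mutations
  pl <- coh$planted
  tm <- paste(coh$tumor_mutations$patient_id, coh$tumor_mutations$key)
  expect_true(all(paste(pl$patient_id, pl$key) %in% tm))
})

test_that("identical seeds give byte-identical cohort files", {
  cfg <- sim_config(seed = 29L)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(simulate_cohort(cfg, list(n = 30L, n_cases = 10L, name = "rep")), d1)
  write_cohort(simulate_cohort(cfg, list(n = 30L, n_cases = 10L, name = "rep")), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid configuration names the offending field", {
  expect_error(sim_config(shed_probability = 1.5), "shed_probability")
  expect_error(sim_config(background_error_rate = -1), "background_error_rate")
  expect_error(sim_config(neoplastic_fraction_range = c(0, 0.3)),
               "neoplastic_fraction_range")
})

test_that("planted fractions outside (0, 1] are rejected", {
  cfg <- sim_config(seed = 1L)
  key <- cfg$panel$key[1]
  expect_error(simulate_patient(list(patient_id = "X",
    planted = data.frame(key = key, fraction = 1.2),
    arm_events = NULL, neoplastic_fraction = 0), cfg), "fraction")
})
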