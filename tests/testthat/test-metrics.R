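# Diagnostic evaluation: 2x2 tabulation, modified-Wald intervals, lead
# time, concordance, false-negative attribution and mutation spectra.

test_that("confusion tabulation matches hand counting", {
  n <- 20
  truth <- data.frame(patient_id = sprintf("p%02d", 1:n),
                      is_cancer = rep(c(TRUE, FALSE), each = 10))
  perfect <- data.frame(patient_id = truth$patient_id,
                        positive = truth$is_cancer)
  cc <- confusion_from_calls(perfect, truth)
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 10L, fp = 0L, tn = 10L, fn = 0L))
  allneg <- transform(perfect, positive = FALSE)
  m <- diagnostic_metrics(confusion_from_calls(allneg, truth))
  expect_equal(m$estimate[m$metric == "sensitivity"], 0)
  expect_equal(m$estimate[m$metric == "specificity"], 1)
  orphan <- data.frame(patient_id = "zzz", positive = TRUE)
  expect_error(confusion_from_calls(orphan, truth), "without truth")
})

test_that("diagnostic metrics reproduce the printed predictive values", {
  m <- diagnostic_metrics(confusion_counts(tp = 38, fp = 20, tn = 279, fn = 2))
  expect_equal(m$estimate[m$metric == "ppv"], 38 / 58)
  expect_equal(round(m$estimate[m$metric == "ppv"], 2), 0.66)
  expect_equal(m$estimate[m$metric == "npv"], 279 / 281)
  expect_equal(round(m$estimate[m$metric == "npv"], 3), 0.993)
  spec <- diagnostic_metrics(confusion_counts(0, 1, 187, 0))
  expect_equal(spec$estimate[spec$metric == "specificity"], 187 / 188)
  one <- diagnostic_metrics(confusion_counts(1, 0, 1, 0))
  expect_equal(one$estimate, rep(1, 4))
})

test_that("zero denominators are reported undefined, not zero", {
  m <- diagnostic_metrics(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(m$undefined[m$metric == "sensitivity"])
  expect_true(m$undefined[m$metric == "ppv"])
  expect_true(is.na(m$estimate[m$metric == "sensitivity"]))
  expect_false(m$undefined[m$metric == "specificity"])
})

test_that("modified Wald intervals match an independent re-derivation", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(5:500, 1); x <- sample(0:n, 1); z <- 1.96
    ci <- modified_wald_ci(x, n, z)
    pt <- (x + z^2 / 2) / (n + z^2)
    hw <- z * sqrt(pt * (1 - pt) / (n + z^2))
    expect_equal(unname(ci), c(max(0, pt - hw), min(1, pt + hw)),
                 tolerance = 1e-10)
  }
  # converges to the plain Wald interval for large n
  x <- 37000; n <- 1e5
  wald <- x / n + c(-1, 1) * 1.96 * sqrt((x / n) * (1 - x / n) / n)
  expect_lt(max(abs(modified_wald_ci(x, n) - wald)), 1e-3)
  expect_equal(unname(modified_wald_ci(0, 10)[1]), 0)
  expect_error(modified_wald_ci(11, 10), "x must")
  expect_error(modified_wald_ci(1, 0), "n must")
})

test_that("metrics agree with brute-force tabulation on random 2x2 tables", {
  set.seed(12)
  for (i in 1:1000) {
    cells <- as.integer(rmultinom(1, sample(4:200, 1), rep(0.25, 4)))
    cc <- confusion_counts(cells[1], cells[2], cells[3], cells[4])
    m <- diagnostic_metrics(cc)
    get <- function(name) m$estimate[m$metric == name]
    if (cells[1] + cells[4] > 0) expect_equal(get("sensitivity"), cells[1] / (cells[1] + cells[4]))
    if (cells[3] + cells[2] > 0) expect_equal(get("specificity"), cells[3] / (cells[3] + cells[2]))
    if (cells[1] + cells[2] > 0) expect_equal(get("ppv"), cells[1] / (cells[1] + cells[2]))
    if (cells[3] + cells[4] > 0) expect_equal(get("npv"), cells[3] / (cells[3] + cells[4]))
  }
})

test_that("PPV/NPV from counts equal the Bayes form at matching prevalence", {
  cc <- confusion_counts(tp = 38, fp = 20, tn = 279, fn = 2)
  m <- diagnostic_metrics(cc)
  sens <- m$estimate[m$metric == "sensitivity"]
  spec <- m$estimate[m$metric == "specificity"]
  prev <- (cc$tp + cc$fn) / attr(cc, "n")
  ppv_bayes <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
  npv_bayes <- spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)
  expect_equal(m$estimate[m$metric == "ppv"], ppv_bayes, tolerance = 1e-12)
  expect_equal(m$estimate[m$metric == "npv"], npv_bayes, tolerance = 1e-12)
})

test_that("lead time converts days to months and validates ordering", {
  d0 <- as.Date("2015-06-01")
  expect_equal(lead_time(d0, d0), 0)
  expect_equal(lead_time(d0, d0 + 365), 365 / 30.44, tolerance = 1e-12)
  expect_equal(round(lead_time(d0, d0 + 365), 2), 11.99)
  expect_error(lead_time(d0, d0 - 1), "precedes")
  # cohort mean equals the hand-computed mean over positive cases
  truth <- data.frame(patient_id = c("a", "b", "c"), is_cancer = c(TRUE, TRUE, FALSE),
                      collection_date = d0,
                      diagnosis_date = c(d0 + 61, d0 + 200, NA))
  res <- data.frame(patient_id = c("a", "b", "c"),
                    uroseek_positive = c(TRUE, TRUE, TRUE))
  lt <- lead_time_summary(res, truth)
  expect_equal(lt$mean_months, mean(c(61, 200) / 30.44))
  expect_equal(lt$n_over_12_months, 0L)
})

test_that("urine-tumor concordance counts shared mutation keys", {
  u <- data.frame(patient_id = c("a", "b"), key = c("k1", "k9"))
  t_ <- data.frame(patient_id = c("a", "b"), key = c("k1", "k2"))
  cc <- tumor_urine_concordance(u, t_)
  expect_equal(cc$per_patient$concordant, c(TRUE, FALSE))
  expect_equal(cc$fraction, 0.5)
  # patients without tumor data are excluded and counted
  u2 <- rbind(u, data.frame(patient_id = "c", key = "k3"))
  cc2 <- tumor_urine_concordance(u2, t_)
  expect_equal(cc2$n_no_tumor, 1L)
  expect_equal(cc2$n_evaluated, 2L)
})

test_that("false negatives split into the two failure modes", {
  tm <- data.frame(patient_id = c("a", "b"), key = c("k1", "k2"))
  attr <- false_negative_attribution(c("a", "b", "c", "d"), tm)
  expect_equal(attr$fraction_insufficient_cells, 0.5)
  expect_equal(attr$fraction_no_queried_mutation, 0.5)
  expect_equal(attr$fraction_insufficient_cells +
                 attr$fraction_no_queried_mutation, 1)
  expect_equal(attr$per_patient$cause,
               c("insufficient_cells", "insufficient_cells",
                 "no_queried_mutation", "no_queried_mutation"))
  empty <- false_negative_attribution(character(0), tm)
  expect_equal(empty$n_false_negative, 0L)
})

test_that("mutation spectra count the six classes and the A>T signature", {
  calls <- data.frame(
    gene = c(rep("TP53", 32), rep("HRAS", 2)),
    ref = c(rep("A", 18), rep("C", 14), "A", "T"),
    alt = c(rep("T", 18), rep("T", 14), "T", "A"),
    stringsAsFactors = FALSE)
  sp <- mutation_spectrum(calls)
  tp53 <- sp$per_gene[sp$per_gene$gene == "TP53", ]
  expect_equal(tp53$n, 32L)
  expect_equal(tp53$n_at_ta, 18L)
  expect_equal(tp53$fraction_at_ta, 0.5625)
  hras <- sp$per_gene[sp$per_gene$gene == "HRAS", ]
  expect_equal(hras$fraction_at_ta, 1)
  # classes partition the SNVs
  expect_equal(sum(sp$class_counts), nrow(calls))
  # empty input and non-SNV skipping
  expect_equal(sum(mutation_spectrum(calls[0, ])$class_counts), 0)
  calls$alt[1] <- "TT"
  expect_equal(mutation_spectrum(calls)$n_skipped, 1L)
})
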