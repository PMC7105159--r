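test_that("threshold rules count patients with the printed conventions", {
  # LDH-style inclusive cutoff
  tab <- contingency_from_threshold(values = c(280, 300, 100),
                                    labels = c("LMS", "LMS", "LM"),
                                    cutoff = 279, positive_direction = "ge")
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 0L, fn = 0L, tn = 1L))
  # boundary: 279 itself is test-positive under ">="
  t279 <- contingency_from_threshold(279, "LMS", 279, "ge")
  expect_equal(t279$tp, 1L)

  # age-style strict cutoff: exactly 49 is test-negative under ">"
  t49 <- contingency_from_threshold(49, "LMS", 49, "gt")
  expect_equal(t49$tp, 0L)
  expect_equal(t49$fn, 1L)

  # empty cohort: all-zero table, downstream metrics undefined
  t0 <- contingency_from_threshold(numeric(0), character(0), 279, "ge")
  m0 <- test_metrics(t0)
  expect_true(all(m0$undefined))
  expect_true(all(is.na(m0$estimates)))
})

test_that("diagnostic metrics match the LDH-rule and age-rule tables", {
  # LDH >= 279 U/L on 8 LMS / 9 LM
  ldh <- test_metrics(contingency_table(tp = 4, fp = 1, fn = 4, tn = 8))
  expect_equal(unname(ldh$estimates["sensitivity"]), 0.5)
  expect_equal(round(100 * ldh$estimates[["specificity"]]), 89)
  expect_equal(unname(ldh$estimates["ppv"]), 0.8)
  expect_equal(round(100 * ldh$estimates[["npv"]], 2), 66.67)

  # age > 49 years
  age <- test_metrics(contingency_table(tp = 5, fp = 4, fn = 3, tn = 5))
  expect_equal(unname(age$estimates["sensitivity"]), 0.625)
  expect_equal(round(100 * age$estimates[["specificity"]], 2), 55.56)
  expect_equal(round(100 * age$estimates[["ppv"]], 2), 55.56)
  expect_equal(unname(age$estimates["npv"]), 0.625)

  # degenerate: no diseased patients
  deg <- test_metrics(contingency_table(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_equal(unname(deg$estimates["specificity"]), 1)
  expect_true(deg$undefined[["sensitivity"]])
  expect_true(deg$undefined[["ppv"]])
})

test_that("metrics agree with brute-force per-patient counting", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    vals <- round(runif(n, 0, 400))
    labs <- sample(c("LM", "LMS"), n, TRUE)
    cut <- runif(1, 0, 400)
    dir <- sample(c("ge", "gt"), 1)
    tab <- contingency_from_threshold(vals, labs, cut, dir)
    pos <- if (dir == "ge") vals >= cut else vals > cut
    tp <- sum(pos & labs == "LMS"); fp <- sum(pos & labs == "LM")
    fn <- sum(!pos & labs == "LMS"); tn <- sum(!pos & labs == "LM")
    expect_identical(c(tab$tp, tab$fp, tab$fn, tab$tn), c(tp, fp, fn, tn))
    m <- test_metrics(tab)
    if (tp + fn > 0)
      expect_equal(unname(m$estimates["sensitivity"]), tp / (tp + fn))
    if (tn + fp > 0)
      expect_equal(unname(m$estimates["specificity"]), tn / (tn + fp))
  }
})

test_that("confidence intervals contain the estimate and stay in [0, 1]", {
  set.seed(13)
  for (i in 1:50) {
    tab <- contingency_table(sample(0:20, 1), sample(0:20, 1),
                             sample(0:20, 1), sample(0:20, 1))
    m <- test_metrics(tab)
    for (metric in names(m$estimates)) {
      if (m$undefined[[metric]] || is.na(m$ci[metric, 1])) next
      expect_gte(m$estimates[[metric]], m$ci[metric, 1] - 1e-12)
      expect_lte(m$estimates[[metric]], m$ci[metric, 2] + 1e-12)
      expect_gte(m$ci[metric, 1], 0)
      expect_lte(m$ci[metric, 2], 1)
    }
  }
})

test_that("Bayes predictive values follow the closed form and monotonicity", {
  pv <- bayes_predictive_values(0.95, 0.95, 0.0012)
  expect_equal(pv$ppv, 0.95 * 0.0012 / (0.95 * 0.0012 + 0.05 * 0.9988),
               tolerance = 1e-12)

  # perfect test
  p1 <- bayes_predictive_values(1, 1, 0.3)
  expect_equal(p1$ppv, 1)
  expect_equal(p1$npv, 1)

  # hand-evaluated at the upper prevalence bound 1.9%
  # ppv = .95*.019/(.95*.019 + .05*.981) = .01805/.06710 = .26900...
  p19 <- bayes_predictive_values(0.95, 0.95, 0.019)
  expect_equal(p19$ppv, 0.01805 / (0.01805 + 0.04905), tolerance = 1e-12)
  expect_equal(round(p19$ppv, 3), 0.269)

  # ppv increases and npv decreases with prevalence
  grid <- seq(0.001, 0.5, length.out = 40)
  ppvs <- vapply(grid, function(p)
    bayes_predictive_values(0.9, 0.8, p)$ppv, numeric(1))
  npvs <- vapply(grid, function(p)
    bayes_predictive_values(0.9, 0.8, p)$npv, numeric(1))
  expect_true(all(diff(ppvs) > 0))
  expect_true(all(diff(npvs) < 0))

  expect_error(bayes_predictive_values(1.2, 0.9, 0.1), "\\[0, 1\\]")
})

test_that("Welch t-test matches a hand-evaluated statistic", {
  # frozen two-group example; expectations computed from the explicit
  # Welch formula (means, variances, Welch-Satterthwaite df)
  a <- c(19.8, 21.2, 20.5, 23.1, 18.9)
  b <- c(24.6, 22.1, 25.3, 23.8)
  w <- welch_t(a, b)
  expect_equal(w$t, -3.284392492159, tolerance = 1e-9)
  expect_equal(w$df, 6.912479889450, tolerance = 1e-9)
  expect_equal(w$p_value, 0.013647724329, tolerance = 1e-9)

  # identical groups: t = 0, p = 1
  same <- c(1, 2, 3, 4)
  w0 <- welch_t(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "positive variance")
})

test_that("simulated cohorts separate LDH between groups plausibly", {
  co <- simulate_clinical_cohort(n_lm = 30, n_lms = 30, seed = 8)
  w <- welch_t(co$ldh[co$diagnosis == "LMS"], co$ldh[co$diagnosis == "LM"])
  expect_gt(w$t, 0)          # LMS group has higher LDH on average
  expect_lt(w$p_value, 0.05) # clearly separated at n = 30 per group
})

test_that("recurrence tallies count distinct patients per gene", {
  mut <- data.frame(
    patient_id = c("p1", "p1", "p2", "p3", "p3", "p4"),
    gene = c("MED12", "MED12", "MED12", "ACLY", "TP53", "ACLY"),
    deleterious = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  tal <- recurrent_gene_tally(mut, n_patients = 10, min_recurrence = 2)
  # MED12: p1 counted once despite two rows; TP53 non-deleterious;
  # ACLY in 2 patients
  expect_equal(tal$gene, c("ACLY", "MED12"))
  expect_equal(tal$n_patients_mutated, c(2L, 2L))
  expect_equal(tal$pct, c(20, 20))

  # a singleton gene is excluded at min_recurrence = 2
  one <- recurrent_gene_tally(
    data.frame(patient_id = "p1", gene = "RB1", deleterious = TRUE),
    n_patients = 10)
  expect_equal(nrow(one), 0)
})
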