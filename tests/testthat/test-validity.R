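test_that("strategy rules are inclusive conjunctions at the threshold", {
  one <- make_cohort(day1 = 35, random = 31, day2 = 30,
                     month2 = 40, month3 = 25)
  expect_true(apply_strategy("DAY1_RANDOM_DAY2", one))
  one$acr_random <- 29.9
  expect_false(apply_strategy("DAY1_RANDOM_DAY2", one))
  # gold standard needs all three monthly samples positive
  expect_false(apply_strategy("GOLD", make_cohort(day1 = 40, month2 = 40,
                                                  month3 = 25)))
  expect_error(apply_strategy("GOLD", one[, c("patient_id", "acr_day1")]),
               "acr_month2")
})

test_that("confusion tables enumerate the four outcome classes", {
  # one patient per outcome class for the RANDOM strategy
  ch <- make_cohort(day1 = c(50, 50, 50, 50),
                    random = c(50, 50, 10, 10),
                    month2 = c(50, 10, 10, 50),
                    month3 = c(50, 50, 50, 50))
  ct <- build_confusion(ch, "RANDOM")
  expect_equal(unlist(ct[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(ct$tp + ct$fp + ct$tn + ct$fn, nrow(ch))
  expect_error(build_confusion(ch[0, ], "DAY1"), "empty")
})

test_that("every strategy agrees with brute-force conjunction evaluation on
           all threshold-exceedance patterns", {
  samples <- c("acr_day1", "acr_random", "acr_day2", "acr_month2",
               "acr_month3")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(grid) <- samples
  acr <- as.data.frame(ifelse(as.matrix(grid), 45, 12))
  ch <- make_cohort(day1 = acr$acr_day1, random = acr$acr_random,
                    day2 = acr$acr_day2, month2 = acr$acr_month2,
                    month3 = acr$acr_month3)
  required <- list(DAY1 = "acr_day1", RANDOM = "acr_random",
                   DAY1_RANDOM = c("acr_day1", "acr_random"),
                   DAY1_DAY2 = c("acr_day1", "acr_day2"),
                   DAY1_RANDOM_DAY2 = c("acr_day1", "acr_random",
                                        "acr_day2"),
                   GOLD = c("acr_day1", "acr_month2", "acr_month3"))
  for (s in names(required)) {
    oracle <- apply(grid[required[[s]]], 1, all)
    expect_identical(unname(apply_strategy(s, ch)), unname(oracle))
  }
})

test_that("validity metrics reproduce the cohort study's percentages", {
  vm <- validity_metrics(confusion_table(tp = 82, fp = 23, tn = 52, fn = 0))
  expect_equal(100 * vm$sensitivity, 100.0)
  expect_equal(round_half_up(100 * vm$specificity), 69.3)
  expect_equal(round_half_up(100 * vm$ppv), 78.1)
  expect_equal(100 * vm$npv, 100.0)
  expect_equal(round_half_up(100 * vm$accuracy), 85.4)
  expect_equal(round_half_up(100 * vm$false_positive_rate), 30.7)
  expect_equal(vm$false_negative_rate, 0)

  vm <- validity_metrics(confusion_table(tp = 79, fp = 40, tn = 35, fn = 3))
  expect_equal(round_half_up(100 * vm$specificity), 46.7)
  expect_equal(round_half_up(100 * vm$accuracy), 72.6)
  expect_equal(round_half_up(100 * vm$sensitivity, 2), 96.34)
})

test_that("degenerate confusion tables give flagged, not NaN, metrics", {
  vm <- validity_metrics(confusion_table(tp = 1, fp = 0, tn = 1, fn = 0))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    expect_equal(vm[[m]], 1)
  # no gold-standard positives: sensitivity undefined, never NaN
  vm <- validity_metrics(confusion_table(tp = 0, fp = 2, tn = 8, fn = 0))
  expect_true(is.na(vm$sensitivity))
  expect_false(is.nan(vm$sensitivity))
  expect_false(is.nan(vm$specificity))
})

test_that("accuracy is the prevalence-weighted mean of sensitivity and
           specificity", {
  set.seed(42)
  for (i in 1:50) {
    counts <- rmultinom(1, 200, c(0.3, 0.2, 0.4, 0.1))
    ct <- confusion_table(tp = counts[1] + 1, fp = counts[2] + 1,
                          tn = counts[3] + 1, fn = counts[4] + 1)
    vm <- validity_metrics(ct)
    n <- ct$tp + ct$fp + ct$tn + ct$fn
    expect_equal(vm$accuracy,
                 vm$sensitivity * (ct$tp + ct$fn) / n +
                   vm$specificity * (ct$fp + ct$tn) / n)
    expect_equal(vm$sensitivity, 1 - vm$false_negative_rate)
    expect_equal(vm$specificity, 1 - vm$false_positive_rate)
  }
})

test_that("adding a required sample never increases strategy positives", {
  set.seed(8)
  ch <- generate_cohort(cohort_sim_params(n_patients = 500, seed = 8))
  n_day1 <- sum(apply_strategy("DAY1", ch))
  n_d1r <- sum(apply_strategy("DAY1_RANDOM", ch))
  n_d1d2 <- sum(apply_strategy("DAY1_DAY2", ch))
  n_all <- sum(apply_strategy("DAY1_RANDOM_DAY2", ch))
  expect_lte(n_d1r, n_day1)
  expect_lte(n_d1d2, n_day1)
  expect_lte(n_all, n_d1r)
  expect_lte(n_all, n_d1d2)
})

test_that("exact intervals match the study's printed bounds and an
           independent binomial oracle", {
  ci <- clopper_pearson(82, 82)
  expect_equal(round_half_up(100 * ci[["lower"]]), 95.6)
  expect_equal(100 * ci[["upper"]], 100.0)
  # the 82/82 lower bound has closed form (alpha/2)^(1/n)
  expect_equal(ci[["lower"]], 0.025^(1 / 82))

  ci <- clopper_pearson(52, 75)
  expect_equal(round_half_up(100 * ci[["lower"]]), 57.6)
  expect_equal(round_half_up(100 * ci[["upper"]]), 79.5)

  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)

  for (x in c(0, 1, 17, 35, 52, 74, 75)) {
    oracle <- stats::binom.test(x, 75)$conf.int
    ci <- clopper_pearson(x, 75)
    expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-10)
  }
  expect_error(clopper_pearson(5, 0), "n")
})

test_that("interval width shrinks with n and exact coverage is conservative", {
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    ci <- clopper_pearson(round(0.3 * n), n)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # exact coverage at n = 20: sum binomial mass over k whose CI contains p
  for (p in c(0.1, 0.5, 0.9)) {
    k <- 0:20
    ci <- clopper_pearson(k, 20)
    covered <- ci[, "lower"] <= p & p <= ci[, "upper"]
    expect_gte(sum(stats::dbinom(k, 20, p)[covered]), 0.95)
  }
})

test_that("the MDRD-based eGFR equation evaluates correctly", {
  expect_equal(compute_egfr(1.0, 1, female = FALSE), 175.0)
  direct <- 175 * 1.0407^-1.234 * 63.4^-0.179
  expect_equal(compute_egfr(1.0407, 63.4), direct)
  expect_equal(direct, 79.3, tolerance = 0.001)
  # umol/L overload divides by 88.4
  expect_equal(compute_egfr(92, 63.4, scr_unit = "umol_l"),
               compute_egfr(92 / 88.4, 63.4))
  expect_equal(compute_egfr(1.2, 60, female = TRUE),
               0.79 * compute_egfr(1.2, 60, female = FALSE))
  expect_error(compute_egfr(0, 60), "scr")
  expect_error(compute_egfr(1, -5), "age")
})
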