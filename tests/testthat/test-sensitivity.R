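test_that("samplers reproduce their central values and ranges", {
  set.seed(123)
  n <- 100000

  s <- parameterize_distribution(
    parameter_distribution("x", "fixed", 0.42))
  expect_equal(s(5), rep(0.42, 5))

  # lognormal from a 95% CI: the central value is the median
  s <- parameterize_distribution(
    parameter_distribution("rr_ckd_mortality", "lognormal", 1.63,
                           low = 1.5, high = 1.77))
  draws <- s(n)
  expect_lt(abs(stats::median(draws) - 1.63) / 1.63, 0.01)
  expect_lt(abs(stats::quantile(draws, 0.025) - 1.5) / 1.5, 0.05)
  expect_lt(abs(stats::quantile(draws, 0.975) - 1.77) / 1.77, 0.05)

  # gamma from a +/-25% range read as a 95% interval: mean matches
  s <- parameterize_distribution(
    parameter_distribution("ckd_annual_cost", "gamma", 34205,
                           half_width = 0.25))
  draws <- s(n)
  expect_lt(abs(mean(draws) - 34205) / 34205, 0.01)
  expect_lt(abs(stats::quantile(draws, 0.975) - 1.25 * 34205) /
              (1.25 * 34205), 0.05)

  # beta moment-matched to the utility's mean
  s <- parameterize_distribution(
    parameter_distribution("utility_ckd", "beta", 0.899,
                           half_width = 0.145))
  draws <- s(n)
  expect_lt(abs(mean(draws) - 0.899), 0.005)
  expect_true(all(draws > 0 & draws < 1))

  expect_error(parameter_distribution("u", "beta", 0.5, sd = 0.6),
               "infeasible")
})

test_that("tornado analysis responds only to influential parameters", {
  p <- model_parameters()
  vt <- study_validity()
  ranges <- list(
    ckd_annual_cost = c(0.75, 1.25) * p$ckd_annual_cost,
    # the cost of a strategy outside the compared pair cannot move results
    screening_cost_RANDOM = c(18, 30))
  tor <- one_way_tornado(p, vt, ranges,
                         pair = c("DAY1", "DAY1_RANDOM_DAY2"))
  swing <- stats::setNames(tor$swing, tor$parameter)
  expect_equal(swing[["screening_cost_RANDOM"]], 0)
  expect_gt(swing[["ckd_annual_cost"]], 0)
  # sorted by absolute swing: the zero-influence parameter comes last
  expect_equal(tor$parameter[nrow(tor)], "screening_cost_RANDOM")
})

test_that("tornado bounds reproduce direct model evaluations", {
  p <- model_parameters()
  vt <- study_validity()
  tor <- one_way_tornado(p, vt, list(rrr_treatment = c(0.08, 0.37)),
                         pair = c("DAY1", "DAY1_RANDOM_DAY2"))
  # independent re-runs at each bound
  direct <- function(rrr) {
    run2 <- function(s) {
      row <- vt[vt$strategy == s, ]
      run_markov(model_parameters(rrr_treatment = rrr),
                 list(sensitivity = row$sensitivity / 100,
                      specificity = row$specificity / 100), strategy = s)
    }
    a <- run2("DAY1"); b <- run2("DAY1_RANDOM_DAY2")
    c(b$total_cost - a$total_cost, b$total_qaly - a$total_qaly)
  }
  lo <- direct(0.08); hi <- direct(0.37)
  expect_equal(tor$incr_cost_low, lo[1])
  expect_equal(tor$incr_effect_low, lo[2])
  expect_equal(tor$incr_cost_high, hi[1])
  expect_equal(tor$incr_effect_high, hi[2])

  # a parameter evaluated at its base value reproduces the base case
  tor0 <- one_way_tornado(p, vt,
                          list(ckd_annual_cost = rep(p$ckd_annual_cost, 2)),
                          pair = c("DAY1", "DAY1_RANDOM_DAY2"))
  expect_equal(tor0$incr_cost_low, attr(tor0, "base_incr_cost"))
  expect_equal(tor0$incr_effect_high, attr(tor0, "base_incr_effect"))
})

test_that("discounting monotonicity shows up in one-way analysis", {
  p <- model_parameters()
  vt <- study_validity()
  for (s in c("DAY1", "RANDOM", "DAY1_RANDOM_DAY2")) {
    row <- vt[vt$strategy == s, ]
    v <- list(sensitivity = row$sensitivity / 100,
              specificity = row$specificity / 100)
    q0 <- run_markov(model_parameters(discount_rate = 0), v,
                     screening_cost = 24)$total_qaly
    q10 <- run_markov(model_parameters(discount_rate = 0.10), v,
                      screening_cost = 24)$total_qaly
    expect_gt(q0, q10)
  }
})

test_that("PSA is reproducible and degenerates correctly", {
  p <- model_parameters()
  vt <- study_validity()
  fixed <- list(parameter_distribution("ckd_annual_cost", "fixed",
                                       p$ckd_annual_cost))
  # all distributions fixed and validity unsampled: every draw equals the
  # deterministic base case
  psa <- run_psa(p, vt, 3, seed = 5, dists = fixed,
                 sample_validity = FALSE)
  base <- run_cea(p, vt)$results
  for (s in unique(psa$strategy)) {
    expect_equal(unique(psa$cost[psa$strategy == s]),
                 base$cost[base$strategy == s])
    expect_equal(unique(psa$effect[psa$strategy == s]),
                 base$effect[base$strategy == s])
  }
  a <- run_psa(p, vt, 50, seed = 11)
  b <- run_psa(p, vt, 50, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, run_psa(p, vt, 50, seed = 12)))
})

test_that("PSA means approach the deterministic base case", {
  p <- model_parameters()
  vt <- study_validity()
  psa <- run_psa(p, vt, 400, seed = 2, sample_validity = FALSE)
  base <- run_cea(p, vt)$results
  for (s in base$strategy) {
    expect_lt(abs(mean(psa$effect[psa$strategy == s]) -
                    base$effect[base$strategy == s]) /
                base$effect[base$strategy == s], 0.02)
    expect_lt(abs(mean(psa$cost[psa$strategy == s]) -
                    base$cost[base$strategy == s]) /
                base$cost[base$strategy == s], 0.10)
  }
})

test_that("acceptability curves are exhaustive-comparison fractions", {
  one <- data.frame(draw = 1:3, strategy = "A", cost = c(1, 2, 3),
                    effect = c(1, 1, 1))
  cc <- ceac(one, c(0, 1000))
  expect_equal(cc$A, c(1, 1))

  # one strategy dominant in every draw
  two <- data.frame(draw = rep(1:4, 2),
                    strategy = rep(c("A", "B"), each = 4),
                    cost = c(1:4, 11:14), effect = c(5:8, 1:4))
  cc <- ceac(two, c(0, 50000, 100000))
  expect_equal(cc$A, rep(1, 3))
  expect_equal(cc$B, rep(0, 3))

  # hand-built table vs exhaustive per-draw NMB comparison
  tab <- data.frame(draw = rep(1:4, 2),
                    strategy = rep(c("A", "B"), each = 4),
                    cost = c(100, 200, 300, 400, 150, 120, 500, 380),
                    effect = c(1.0, 2.0, 1.5, 2.5, 1.2, 1.8, 1.9, 2.6))
  w <- 200
  nmb_a <- w * tab$effect[1:4] - tab$cost[1:4]
  nmb_b <- w * tab$effect[5:8] - tab$cost[5:8]
  cc <- ceac(tab, w)
  expect_equal(cc$A, mean(nmb_a > nmb_b))
  expect_equal(cc$B, mean(nmb_b > nmb_a))
  expect_equal(cc$A + cc$B, 1)
  expect_error(ceac(tab, numeric(0)), "empty")
})
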