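test_that("overall rate is the width-weighted sum of interval rates", {
  p6 <- interval_partition(c(1, 2, 3, 14, -5), 38)
  ## published six-interval estimates (x 10^3) for the two minimum-lethality
  ## data sets; widths (1, 1, 1, 11, 19, 5)
  expect_equal(round(overall_rate(table6_rates(), p6), 4), 0.0821)
  u98 <- c(28.660, 0.272, 0.006, 0.018, 0.089, 1.443) * 1e-3
  expect_equal(round(overall_rate(u98, p6), 4), 0.0380)
  expect_identical(overall_rate(rep(0, 6), p6), 0)
  rv <- rate_vector(table6_rates(), p6)
  expect_equal(overall_rate(rv), overall_rate(table6_rates(), p6))
})

test_that("classical estimator reproduces published screen-wide rates", {
  expect_equal(round(classical_rate(2673, 271794), 4), 0.0098)
  expect_equal(round(classical_rate(30781, 271794), 4), 0.1133)
  expect_equal(round(classical_rate(10766, 271794), 4), 0.0396)
  expect_identical(classical_rate(0, 100), 0)
  expect_error(classical_rate(1, 0), "positive")
  expect_error(classical_rate(5, 4), "between")
})

test_that("hypothesis degrees of freedom are counted structurally", {
  expect_identical(hypothesis_spec("H1", 5)$df, 4L)
  expect_identical(hypothesis_spec("H2", 5)$df, 2L)
  for (h in c("H3", "H4", "H4b", "H5", "H6", "H7"))
    expect_identical(hypothesis_spec(h, 5)$df, 1L)
  expect_identical(hypothesis_spec("H1", 6)$df, 5L)
  expect_identical(hypothesis_spec("H8", 6)$df, 0L)
  ## custom equality classes: df = I - number of classes
  set.seed(9)
  for (rep in 1:20) {
    I <- sample(3:8, 1)
    cl <- sample(seq_len(sample(1:I, 1)), I, replace = TRUE)
    h <- hypothesis_classes(cl)
    expect_identical(h$df, I - length(unique(cl)))
  }
})

test_that("first-division ratio follows the published formula", {
  expect_equal(first_division_ratio(rep(0.01, 6)), 32 / 31)
  ## direct arithmetic on the printed all-lethality row gives 448.6
  expect_equal(round(first_division_ratio(table6_rates()), 1), 448.6)
  expect_identical(first_division_ratio(c(0, 1, 1, 1, 1) * 1e-3), 0)
  expect_identical(first_division_ratio(c(1e-3, 0, 0, 0, 0)), Inf)
})

test_that("male-to-female expected rate ratio matches the stated arithmetic", {
  expect_equal(round(male_female_ratio(100, 400, 30), 1), 3.9)
  expect_equal(round(male_female_ratio(500, 400, 30), 1), 1.7)
  expect_equal(male_female_ratio(1e9, 400, 30), 1, tolerance = 1e-6)
})

test_that("all-empty tallies give a zero rate vector with likelihood 0", {
  t0 <- pattern_tally(rep(5, 4), rep(list(integer(0)), 4))
  dyn <- mini_dynamics(6)
  coeffs <- tally_coefficients(t0, dyn, mini_partition(6), M = 50, seed = 1)
  fit <- fit_mle(t0, coeffs)
  expect_identical(fit$u, 0)
  expect_identical(fit$loglik, 0)
})

test_that("the MLE recovers generating rates from a truth tally", {
  ## moderate rates on a 5-interval partition; estimable with 1200 families
  part <- interval_partition(c(1, 2, 14, -5), 38)
  u_true <- c(0.05, 0.004, 0.0008, 0.001, 0.003)
  dyn <- germline_dynamics(38, 6, 8)
  cfg <- synth_config(n_families = 1200, lines = 20, u = u_true,
                      partition = part, dyn = dyn,
                      lethality = function(n) rep(1, n))
  exp1 <- generate_experiment(cfg, seed = 31)
  tt <- truth_tally(exp1, c(0.97, 1))
  coeffs <- tally_coefficients(tt, dyn, part, M = 1200, seed = 32)
  fit <- fit_mle(tt, coeffs)
  expect_true(fit$converged)
  expect_lt(abs(fit$u[1] / u_true[1] - 1), 0.2)
  ## interior intervals: looser tolerance, their information is much lower
  expect_lt(abs(fit$u[5] / u_true[5] - 1), 0.5)
  ## likelihood at the optimum at least matches the truth
  expect_gte(fit$loglik, tally_log_likelihood(tt, u_true, coeffs) - 1e-6)
})

test_that("likelihood-ratio test is calibrated near flat-rate null data", {
  part <- interval_partition(c(1, 2, 14, -5), 38)
  dyn <- germline_dynamics(38, 6, 8)
  cfg <- synth_config(n_families = 400, lines = 20, u = rep(2e-3, 5),
                      partition = part, dyn = dyn,
                      lethality = function(n) rep(1, n))
  exp1 <- generate_experiment(cfg, seed = 41)
  tt <- truth_tally(exp1, c(0.97, 1))
  coeffs <- tally_coefficients(tt, dyn, part, M = 800, seed = 42)
  lt <- lr_test(tt, coeffs, hypothesis_spec("H1", 5), n_starts = 6)
  expect_gte(lt$statistic, 0)
  expect_identical(lt$df, 4L)
  expect_gte(lt$p_value, 0)
  expect_lte(lt$p_value, 1)
  ## flat truth: no significant departure expected at this scale
  expect_gt(lt$p_value, 0.01)
})

test_that("dynamics scan marks feasibility and centres delta at the optimum", {
  part <- interval_partition(c(1, 2, 14, -5), 38)
  dyn <- germline_dynamics(38, 6, 8)
  cfg <- synth_config(n_families = 250, lines = 12, partition = part,
                      dyn = dyn, u = c(table6_rates()[1:4], 2e-3),
                      lethality = function(n) rep(1, n))
  exp1 <- generate_experiment(cfg, seed = 51)
  tt <- truth_tally(exp1, c(0.97, 1))
  sc <- scan_dynamics(tt, part, n5_groups = list(1:2, 5:6),
                      n8_groups = list(13:15, 7:9), M = 240, seed = 52,
                      n_starts = 2)
  expect_identical(nrow(sc), 4L)
  ## n5 in 1-2 with n8 in 13-15 is only partially feasible (n8 <= 16)
  r <- sc[sc$n5_group == "1-2" & sc$n8_group == "13-15", ]
  expect_true(r$feasible)
  expect_true(r$partial)
  expect_true(all(sc$delta >= 0, na.rm = TRUE))
  expect_identical(sum(sc$delta == 0, na.rm = TRUE), 1L)
})

test_that("adding non-mutant families shifts likelihoods but not delta ranks", {
  part <- interval_partition(c(1, 2, 14, -5), 38)
  dyn <- germline_dynamics(38, 6, 8)
  cfg <- synth_config(n_families = 120, lines = 8, partition = part,
                      dyn = dyn, u = c(table6_rates()[1:4], 2e-3),
                      lethality = function(n) rep(1, n))
  exp1 <- generate_experiment(cfg, seed = 61)
  tt <- truth_tally(exp1, c(0.97, 1))
  aug <- tt
  aug$families["8"] <- aug$families[["8"]] + 60L  # 60 extra non-mutant families
  grid5 <- list(3:4, 5:6)
  sc1 <- scan_dynamics(tt, part, grid5, list(7:9), M = 200, seed = 62,
                       n_starts = 2)
  sc2 <- scan_dynamics(aug, part, grid5, list(7:9), M = 200, seed = 62,
                       n_starts = 2)
  expect_identical(order(sc1$delta), order(sc2$delta))
  expect_true(all(sc2$loglik < sc1$loglik))
})
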