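test_that("confidence is the argmax probability with ties toward success", {
  cf <- confidence_of(c(0.7, 0.3, 0.5, 0, 1))
  expect_equal(cf$confidence, c(0.7, 0.7, 0.5, 1, 1))
  expect_equal(cf$pred_label, c(1L, 0L, 1L, 0L, 1L))
  expect_error(confidence_of(1.2), "\\[0, 1\\]")
  expect_error(confidence_of(-0.1), "\\[0, 1\\]")
})

test_that("selective risk counts kept errors and coverage correctly", {
  s <- scored_samples(c(0.9, 0.8, 0.3, 0.6), c(1, 1, 1, 1))
  # confidences 0.9, 0.8, 0.7, 0.6; third sample predicted 0 => wrong
  rp <- selective_risk(s, 0.75)
  expect_equal(rp$n_kept, 2L)
  expect_equal(rp$n_errors, 0L)
  expect_equal(rp$risk_hat, 0)
  expect_equal(rp$coverage, 0.5)
  rp <- selective_risk(s, 0.65)
  expect_equal(rp$n_kept, 3L)
  expect_equal(rp$n_errors, 1L)
  expect_equal(rp$risk_hat, 1 / 3)
  rp <- selective_risk(s, 0.95, beta = 0.1)
  expect_equal(rp$n_kept, 0L)
  expect_equal(rp$risk_ucb, 1)
  expect_error(selective_risk(s[0, ], 0.5), "nonempty")
})

test_that("binomial UCB matches closed form and the Beta-quantile oracle", {
  # zero-error closed form: (1-r)^n = beta  =>  r = 1 - beta^(1/n)
  for (n in 1:100)
    expect_equal(binom_ucb(0, n, 0.1), 1 - 0.1^(1 / n), tolerance = 1e-8)
  # k = n degenerate: any rate is consistent
  expect_equal(binom_ucb(c(5, 1), c(5, 1), 0.25), c(1, 1))
  expect_equal(binom_ucb(0, 0, 0.1), 1)
  expect_error(binom_ucb(2, 10, 0), "beta")
  expect_error(binom_ucb(2, 10, 1), "beta")
  expect_error(binom_ucb(3, 2, 0.1), "n_errors")
  # independent oracle: one-sided Clopper-Pearson via Beta quantile
  for (beta in c(0.01, 0.05, 0.1, 0.25)) {
    for (n in c(1, 2, 5, 13, 27, 50)) {
      k <- 0:n
      oracle <- ifelse(k == n, 1, stats::qbeta(1 - beta, k + 1, n - k))
      expect_equal(binom_ucb(k, n, beta), oracle, tolerance = 1e-6)
    }
  }
})

test_that("calibration: all-correct samples certify the smallest threshold", {
  set.seed(11)
  p <- runif(200, 0.5, 1)            # all predicted 1, all correct
  cal <- calibrate(scored_samples(p, rep(1L, 200)), alpha = 0.1, beta = 0.1)
  expect_true(cal$feasible)
  expect_equal(cal$lam_hat, min(cal$curve$lam))
  expect_equal(cal$lam_hat, 0)
  # full-coverage zero-error bound matches the closed form
  expect_equal(cal$curve$risk_ucb[1], 1 - 0.1^(1 / 200), tolerance = 1e-6)
})

test_that("calibration is infeasible when every sample is misclassified", {
  set.seed(12)
  p <- runif(100, 0.55, 0.95)
  cal <- calibrate(scored_samples(p, rep(0L, 100)), alpha = 0.2, beta = 0.1)
  expect_false(cal$feasible)
  expect_true(is.na(cal$lam_hat))
})

test_that("calibration matches a brute-force threshold scan", {
  set.seed(13)
  gen <- scored_sample_generator()
  for (rep in 1:5) {
    s <- gen(500)
    ss <- scored_samples(s$prob_success, s$true_label)
    cal <- calibrate(ss, alpha = 0.1, beta = 0.1)
    expect_equal(cal$lam_hat, brute_force_lam_hat(ss, 0.1, 0.1))
  }
})

test_that("calibration curve coverage is non-increasing and bounds valid", {
  set.seed(14)
  s <- scored_sample_generator()(400)
  cal <- calibrate(scored_samples(s$prob_success, s$true_label))
  expect_false(is.unsorted(rev(cal$curve$coverage)))
  expect_true(all(cal$curve$risk_ucb >= cal$curve$risk_hat - 1e-12))
  # suffix property at certifiable grid points
  if (cal$feasible) {
    suff <- cal$curve$lam >= cal$lam_hat & cal$curve$certifiable
    expect_true(all(cal$curve$risk_ucb[suff] <= cal$alpha))
  }
})

test_that("selective application keeps by confidence and abstains otherwise", {
  dec <- apply_selective(c(0.95, 0.55, 0.10), 0.8)
  expect_equal(dec$decision, c("1", "ABSTAIN", "0"))
  expect_equal(dec$kept, c(TRUE, FALSE, TRUE))
  expect_true(is.na(dec$pred_label[2]))
  expect_true(all(apply_selective(runif(50), 0)$kept))
  expect_true(all(!apply_selective(runif(50, 0.2, 0.8), 1)$kept))
  infeasible <- structure(list(feasible = FALSE), class = "trial_calibration")
  expect_warning(dec <- apply_selective(c(0.9, 0.2), infeasible), "abstain")
  expect_true(all(dec$decision == "ABSTAIN"))
})

test_that("a stricter failure rate never lowers the calibrated threshold", {
  set.seed(15)
  s <- scored_sample_generator()(600)
  ss <- scored_samples(s$prob_success, s$true_label)
  lo <- calibrate(ss, alpha = 0.1, beta = 0.5)
  hi <- calibrate(ss, alpha = 0.1, beta = 0.01)
  expect_true(lo$feasible)
  if (hi$feasible) expect_gte(hi$lam_hat, lo$lam_hat)
})

test_that("oracle sampler yields a perfect guarantee success fraction", {
  oracle <- function(n) {
    p <- runif(n, 0.6, 1)
    data.frame(prob_success = p, true_label = rep(1L, n))
  }
  mc <- guarantee_monte_carlo(oracle, n_cal = 100, n_test = 100,
                              n_rep = 20, seed = 5)
  expect_equal(mc$success_fraction, 1)
})
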