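test_that("PR-AUC and ROC-AUC match exhaustive oracles on random instances", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(pr_auc(scores, labels), pr_auc_oracle(scores, labels),
                 tolerance = 1e-9)
    expect_equal(roc_auc(scores, labels), roc_auc_oracle(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("ranking metrics hit their closed-form extremes and symmetries", {
  scores <- c(0.9, 0.8, 0.4, 0.2); labels <- c(1, 1, 0, 0)
  expect_equal(pr_auc(scores, labels), 1.0)
  expect_equal(roc_auc(scores, labels), 1.0)
  # permutation invariance
  set.seed(22)
  s <- runif(20); y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  perm <- sample(20)
  expect_equal(pr_auc(s[perm], y[perm]), pr_auc(s, y))
  # ROC-AUC invariance under label flip + score negation
  expect_equal(roc_auc(-s, 1 - y), roc_auc(s, y))
  expect_error(pr_auc(s, rep(1, 20)), "both classes")
  expect_error(roc_auc(s, rep(0, 20)), "both classes")
})

test_that("F1 and accuracy follow their definitions incl. degenerate cases", {
  expect_equal(f1_accuracy(c(1, 0, 1), c(1, 0, 1)), list(f1 = 1, accuracy = 1))
  r <- f1_accuracy(c(1, 1, 0, 0), c(1, 0, 1, 0))  # TP FP FN TN = 1 each
  expect_equal(r$f1, 0.5)
  expect_equal(r$accuracy, 0.5)
  # no positive predictions while positives exist: zero numerator, F1 = 0
  expect_equal(f1_accuracy(c(0, 0), c(1, 0))$f1, 0)
  # no positives anywhere: zero denominator, F1 = 0 with a warning
  expect_warning(r <- f1_accuracy(c(0, 0), c(0, 0)), "F1")
  expect_equal(r$f1, 0)
  expect_error(f1_accuracy(c(1, 0), c(1, 0, 1)), "length")
})

test_that("temporal split respects both date conditions and drops straddlers", {
  tr <- data.frame(
    trial_id = paste0("T", 1:6),
    start_date = c("2012-01-01", "2012-06-01", "2014-02-01",
                   "2012-03-01", "2014-06-01", "2013-01-01"),
    completion_date = c("2012-12-01", "2013-02-01", "2015-01-01",
                        "2013-06-30", "2015-06-01", "2014-05-01"))
  split <- "2013-08-08"
  expect_message(sp <- temporal_split(tr, split, validation_fraction = 0,
                                      seed = 1), "straddle")
  expect_setequal(sp$test$trial_id, c("T3", "T5"))
  expect_setequal(sp$train$trial_id, c("T1", "T2", "T4"))
  expect_equal(attr(sp, "n_dropped"), 1L)       # T6 straddles
  # seeded validation draw is reproducible
  tr2 <- tr[rep(1:4, 10), ]; tr2$trial_id <- paste0("X", 1:40)
  a <- suppressMessages(temporal_split(tr2, split, 0.25, seed = 9))
  b <- suppressMessages(temporal_split(tr2, split, 0.25, seed = 9))
  expect_identical(a$validation$trial_id, b$validation$trial_id)
  tr$start_date[1] <- NA
  expect_error(suppressMessages(temporal_split(tr, split)), "undated")
})

test_that("paired bootstrap p-value behaves at its boundaries and matches
           exhaustive enumeration on a tiny instance", {
  set.seed(23)
  y <- c(1, 0, 1, 0, 1)
  a <- c(0.1, 0.8, 0.2, 0.9, 0.15)   # anti-separating baseline
  # identical scores: no improvement, p = 1
  expect_equal(bootstrap_pvalue(a, a, y, "roc_auc", n_boot = 200, seed = 1), 1)
  # strict domination on every replicate: p at the add-one lower bound
  b <- c(0.9, 0.1, 0.95, 0.05, 0.9)   # perfectly separating
  p <- bootstrap_pvalue(a, b, y, "roc_auc", n_boot = 200, seed = 1)
  expect_lte(p, 1 / (200 + 1) + 1e-12)
  # exhaustive enumeration over all stratified resamples is deterministic
  # and must agree with a large sampled bootstrap within Monte-Carlo error
  pe <- bootstrap_pvalue(a, b, y, "accuracy", exhaustive = TRUE)
  expect_equal(pe, bootstrap_pvalue(a, b, y, "accuracy", exhaustive = TRUE))
  ps <- bootstrap_pvalue(a, b, y, "accuracy", n_boot = 4000, seed = 3)
  expect_lt(abs(pe - ps), 0.05)
  expect_error(bootstrap_pvalue(a[1:3], b, y, "roc_auc"), "paired")
})

test_that("lambda sweep is monotone in coverage and anchored at lambda = 0", {
  set.seed(24)
  s <- scored_sample_generator()(400)
  ss <- scored_samples(s$prob_success, s$true_label)
  sw <- lambda_sweep(ss)
  expect_false(is.unsorted(rev(sw$fraction_kept)))
  expect_equal(sw$fraction_kept[1], 1)
  expect_equal(sw$selective_accuracy[1],
               mean(ss$pred_label == ss$true_label))
  # confidence-correlated errors: accuracy at ~half coverage beats full
  half <- which.min(abs(sw$fraction_kept - 0.5))
  expect_gt(sw$selective_accuracy[half], sw$selective_accuracy[1])
})

test_that("metrics restricted to kept samples equal metrics on deleted rows", {
  set.seed(25)
  s <- scored_sample_generator()(300)
  kept <- s$prob_success > 0.3 & s$prob_success < 0.9
  a <- metrics_report(s$prob_success, s$true_label, kept = kept, n_boot = 0)
  b <- metrics_report(s$prob_success[kept], s$true_label[kept], n_boot = 0)
  expect_equal(a$pr_auc, b$pr_auc)
  expect_equal(a$roc_auc, b$roc_auc)
  expect_equal(a$f1, b$f1)
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$retain_rate, mean(kept))
})

test_that("relative improvement reproduces published improvement cells", {
  # phase-level PR-AUC improvements
  expect_equal(relative_improvement(0.5765, 0.7631), 32.37)
  expect_equal(relative_improvement(0.6093, 0.7399), 21.43)
  expect_equal(relative_improvement(0.7965, 0.9022), 13.27)
  expect_equal(relative_improvement(0.42, 0.42), 0)
  expect_error(relative_improvement(0, 0.5), "positive")
})
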