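# Selective classification with a distribution-free selective-accuracy
# guarantee.  A binary classifier emitting success probabilities is wrapped in
# a gate that abstains below a confidence threshold lambda-hat; the threshold
# is calibrated on held-out labelled samples so that, with probability at
# least 1 - beta over the calibration draw, the accuracy on non-abstained
# test points is at least 1 - alpha.  The calibration scans a one-sided
# binomial (Clopper-Pearson) upper confidence bound on the selective
# misclassification rate across candidate thresholds.

ABSTAIN <- "ABSTAIN"

#' Confidence and predicted label of a success probability
#'
#' For a binary classifier emitting the probability of the positive class,
#' the confidence is the probability of the predicted (argmax) class,
#' \code{max(p, 1 - p)}, always in \[0.5, 1\].  Ties at p = 0.5 are broken
#' toward label 1 so the map is deterministic.
#'
#' @param prob_success Numeric vector of success probabilities in \[0, 1\].
#' @return A data.frame with columns \code{confidence} and \code{pred_label}.
#' @examples
#' confidence_of(c(0.7, 0.3, 0.5))
#' @export
confidence_of <- function(prob_success) {
  stopifnot(is.numeric(prob_success))
  if (anyNA(prob_success) || any(prob_success < 0 | prob_success > 1))
    stop("prob_success must lie in [0, 1]")
  data.frame(
    confidence = pmax(prob_success, 1 - prob_success),
    pred_label = as.integer(prob_success >= 0.5)
  )
}

#' Assemble scored samples for calibration and evaluation
#'
#' @param prob_success Success probabilities in \[0, 1\].
#' @param true_label Optional 0/1 truth vector of the same length.
#' @return A data.frame with columns \code{prob_success}, \code{confidence},
#'   \code{pred_label} and (if given) \code{true_label}.
#' @export
scored_samples <- function(prob_success, true_label = NULL) {
  cf <- confidence_of(prob_success)
  out <- data.frame(prob_success = prob_success,
                    confidence = cf$confidence,
                    pred_label = cf$pred_label)
  if (!is.null(true_label)) {
    stopifnot(length(true_label) == length(prob_success),
              all(true_label %in% c(0L, 1L)))
    out$true_label <- as.integer(true_label)
  }
  out
}

#' Empirical selective risk at a confidence threshold
#'
#' Keeps the samples with confidence >= lam and counts misclassifications
#' among them.  When nothing is kept the point risk is undefined; it is
#' reported as 0 with the upper bound forced to 1, so a vacuous threshold can
#' never certify a guarantee.
#'
#' @param samples Data.frame with columns \code{confidence},
#'   \code{pred_label}, \code{true_label} (see [scored_samples()]).
#' @param lam Threshold in \[0, 1\].
#' @param beta Optional failure rate; when given, \code{risk_ucb} is the
#'   one-sided binomial upper bound of [binom_ucb()].
#' @return One-row data.frame: \code{lam}, \code{n_kept}, \code{n_errors},
#'   \code{risk_hat}, \code{coverage} and (with \code{beta}) \code{risk_ucb}.
#' @export
selective_risk <- function(samples, lam, beta = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("confidence", "pred_label", "true_label") %in% names(samples)))
  if (nrow(samples) == 0L) stop("samples must be nonempty")
  stopifnot(length(lam) == 1L, lam >= 0, lam <= 1)
  kept <- samples$confidence >= lam
  n_kept <- sum(kept)
  n_err <- sum(kept & (samples$pred_label != samples$true_label))
  out <- data.frame(
    lam = lam,
    n_kept = n_kept,
    n_errors = n_err,
    risk_hat = if (n_kept > 0L) n_err / n_kept else 0,
    coverage = n_kept / nrow(samples)
  )
  if (!is.null(beta))
    out$risk_ucb <- binom_ucb(n_err, n_kept, beta)
  out
}

#' One-sided binomial upper confidence bound on an error rate
#'
#' Given k errors observed among n kept samples, returns the largest error
#' rate r still consistent with the data at level beta:
#' \code{sup \{ r : pbinom(k, n, r) >= beta \}}, found by bisection to 1e-9.
#' This equals the one-sided Clopper-Pearson upper bound at confidence
#' 1 - beta.  With n = 0 the bound is 1 (conservative).
#'
#' @param n_errors Integer vector of error counts (k).
#' @param n_kept Integer vector of kept counts (n), recycled.
#' @param beta Failure rate in (0, 1).
#' @param tol Bisection tolerance on r.
#' @return Numeric vector of upper bounds in \[0, 1\].
#' @examples
#' binom_ucb(0, 20, 0.05)   # closed form: 1 - 0.05^(1/20)
#' @export
binom_ucb <- function(n_errors, n_kept, beta, tol = 1e-9) {
  stopifnot(length(beta) == 1L, is.finite(beta))
  if (beta <= 0 || beta >= 1) stop("beta must lie strictly in (0, 1)")
  n <- pmax(length(n_errors), length(n_kept))
  n_errors <- rep_len(as.numeric(n_errors), n)
  n_kept <- rep_len(as.numeric(n_kept), n)
  if (any(n_errors < 0 | n_errors > n_kept))
    stop("need 0 <= n_errors <= n_kept")
  vapply(seq_len(n), function(i) {
    k <- n_errors[i]; m <- n_kept[i]
    if (m == 0) return(1)
    if (k == m) return(1)          # pbinom(m, m, r) = 1 >= beta for all r
    if (k == 0) return(1 - beta^(1 / m))  # (1-r)^m = beta, closed form
    lo <- k / m; hi <- 1           # pbinom is nonincreasing in r
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (stats::pbinom(k, m, mid) >= beta) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Calibrate the abstention threshold for a selective-accuracy guarantee
#'
#' Evaluates the selective risk and its binomial upper bound on a grid of
#' candidate thresholds (the sorted unique calibration confidences plus the
#' sentinels 0 and 1 -- the empirical risk only changes at observed
#' confidences) and returns the smallest certifiable grid threshold whose
#' entire certifiable suffix keeps the upper bound at or below alpha.
#' Deploying that threshold guarantees selective accuracy >= 1 - alpha on
#' exchangeable test data with probability >= 1 - beta.
#'
#' A grid point keeping fewer than \code{n_min = ceiling(log(beta) /
#' log(1 - alpha))} samples can never be certified, even error-free (the
#' zero-error bound 1 - beta^(1/n) already exceeds alpha), so such points --
#' always present at the extreme top of a continuous-confidence grid -- are
#' excluded from both candidacy and the suffix requirement; which points
#' these are depends only on the confidences, never on the observed errors,
#' so the binomial bound at the certified points is unaffected.
#'
#' @param samples Calibration samples from [scored_samples()] with truth.
#' @param alpha Target selective error rate in (0, 1). Default 0.1.
#' @param beta Allowed failure rate of the guarantee in (0, 1). Default 0.1.
#' @param min_coverage Optional operational floor: thresholds keeping less
#'   than this fraction of the calibration samples are excluded from
#'   candidacy and from the suffix requirement (a decision aid that
#'   abstains on almost everything is not a useful operating point, and
#'   near-empty grid windows make the scan hinge on one or two samples).
#'   Like the certifiability floor, it depends only on the confidences,
#'   never the errors.  Default 0 (no floor).
#' @return An object of class \code{trial_calibration}: a list with
#'   \code{lam_hat}, \code{alpha}, \code{beta}, \code{n_min},
#'   \code{feasible} and \code{curve}, a data.frame of per-grid-point
#'   risk/coverage records with a \code{certifiable} flag.
#' @export
calibrate <- function(samples, alpha = 0.1, beta = 0.1, min_coverage = 0) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0L,
            "true_label" %in% names(samples))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (beta <= 0 || beta >= 1) stop("beta must lie strictly in (0, 1)")
  grid <- sort(unique(c(0, 1, samples$confidence)))
  curve <- do.call(rbind, lapply(grid, function(l)
    selective_risk(samples, l, beta = beta)))
  n_min <- ceiling(log(beta) / log(1 - alpha) - 1e-12)
  curve$certifiable <- curve$n_kept >= n_min &
    curve$coverage >= min_coverage
  ok <- curve$risk_ucb <= alpha
  # suffix condition over certifiable points: no certifiable point at or
  # above lam_hat may violate the bound
  bad <- curve$certifiable & !ok
  suffix_clean <- rev(cumsum(rev(bad))) == 0
  candidate <- curve$certifiable & suffix_clean
  feasible <- any(candidate)
  lam_hat <- if (feasible) grid[which(candidate)[1L]] else NA_real_
  structure(
    list(lam_hat = lam_hat, alpha = alpha, beta = beta, n_min = n_min,
         feasible = feasible, curve = curve),
    class = "trial_calibration"
  )
}

#' @export
print.trial_calibration <- function(x, ...) {
  cat("Selective-classification calibration\n")
  cat(sprintf("  target selective error alpha = %g, failure rate beta = %g\n",
              x$alpha, x$beta))
  if (x$feasible) {
    at <- x$curve[match(x$lam_hat, x$curve$lam), ]
    cat(sprintf("  lam_hat = %.6g (calibration coverage %.3f, risk %.4f, UCB %.4f)\n",
                x$lam_hat, at$coverage, at$risk_hat, at$risk_ucb))
  } else {
    cat("  infeasible: no threshold certifies the guarantee; abstain on all\n")
  }
  invisible(x)
}

#' Apply a calibrated threshold to new probabilities
#'
#' @param probs Success probabilities for fresh inputs.
#' @param lam_hat Threshold in \[0, 1\], or a \code{trial_calibration}.
#'   An infeasible calibration abstains on everything (with a warning).
#' @return Data.frame with \code{prob_success}, \code{confidence},
#'   \code{kept}, \code{pred_label} (NA when abstained) and \code{decision}
#'   (\code{"0"}, \code{"1"} or \code{"ABSTAIN"}).
#' @export
apply_selective <- function(probs, lam_hat) {
  if (inherits(lam_hat, "trial_calibration")) {
    if (!lam_hat$feasible) {
      warning("infeasible calibration: abstaining on all inputs")
      lam_hat <- Inf
    } else lam_hat <- lam_hat$lam_hat
  }
  stopifnot(length(lam_hat) == 1L, lam_hat >= 0)
  cf <- confidence_of(probs)
  kept <- cf$confidence >= lam_hat
  data.frame(
    prob_success = probs,
    confidence = cf$confidence,
    kept = kept,
    pred_label = ifelse(kept, cf$pred_label, NA_integer_),
    decision = ifelse(kept, as.character(cf$pred_label), ABSTAIN)
  )
}

#' Selective accuracy of decisions against truth
#'
#' Accuracy over the kept (non-abstained) decisions only; NA when everything
#' is abstained.
#'
#' @param decisions Output of [apply_selective()].
#' @param true_label 0/1 truth vector.
#' @return List with \code{selective_accuracy}, \code{retain_rate},
#'   \code{n_kept}.
#' @export
selective_accuracy <- function(decisions, true_label) {
  stopifnot(nrow(decisions) == length(true_label))
  kept <- decisions$kept
  list(
    selective_accuracy = if (any(kept))
      mean(decisions$pred_label[kept] == true_label[kept]) else NA_real_,
    retain_rate = mean(kept),
    n_kept = sum(kept)
  )
}

#' Monte-Carlo check of the selective-accuracy guarantee
#'
#' Repeatedly draws a calibration set and a test set from the same sampler,
#' calibrates the threshold, and measures whether the selective accuracy on
#' kept test points reaches 1 - alpha.  Replications where calibration is
#' infeasible, or where no test point is kept, vacuously satisfy the
#' guarantee (an abstain-all classifier misclassifies nothing it keeps).
#' The calibration theory promises a success fraction of at least 1 - beta.
#'
#' @param sampler Function(n) returning a data.frame with columns
#'   \code{prob_success} and \code{true_label} for n i.i.d. draws.
#' @param alpha,beta Guarantee parameters.
#' @param n_cal,n_test Calibration and test set sizes per replication.
#'   The guarantee is a statement about the population selective accuracy,
#'   so the default test draw is large enough that its sampling error is
#'   small against the guarantee margin.
#' @param n_rep Number of replications.
#' @param seed Integer seed for the whole experiment.
#' @return List with \code{success_fraction} and the per-replication
#'   data.frame \code{detail} (lam_hat, feasible, selective accuracy, kept).
#' @export
guarantee_monte_carlo <- function(sampler, alpha = 0.1, beta = 0.1,
                                  n_cal = 500, n_test = 2000,
                                  n_rep = 200, seed = 1) {
  stopifnot(is.function(sampler), n_rep >= 1)
  set.seed(seed)
  detail <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    cal <- sampler(n_cal)
    cal_s <- scored_samples(cal$prob_success, cal$true_label)
    cb <- calibrate(cal_s, alpha = alpha, beta = beta)
    te <- sampler(n_test)
    if (!cb$feasible) {
      return(data.frame(rep = r, lam_hat = NA_real_, feasible = FALSE,
                        sel_acc = NA_real_, n_kept = 0L, success = TRUE))
    }
    dec <- apply_selective(te$prob_success, cb$lam_hat)
    sa <- selective_accuracy(dec, te$true_label)
    data.frame(rep = r, lam_hat = cb$lam_hat, feasible = TRUE,
               sel_acc = sa$selective_accuracy, n_kept = sa$n_kept,
               success = sa$n_kept == 0L || sa$selective_accuracy >= 1 - alpha)
  }))
  list(success_fraction = mean(detail$success), detail = detail)
}
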