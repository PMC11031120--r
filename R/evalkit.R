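# Evaluation metrics, temporal splitting, paired-bootstrap significance and
# coverage-accuracy trade-off curves for trial approval predictors.

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) dialect: with thresholds at the unique
#' scores in decreasing order, the area is the sum over recall increments of
#' the precision attained at that threshold.  The precision envelope is not
#' interpolated.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 truth vector of the same length.
#' @return The area, in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || n_pos == length(labels))
    stop("pr_auc undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  # evaluate only at the last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the TPR/FPR curve, equivalently the Mann-Whitney
#' probability that a random positive outscores a random negative with ties
#' counted half.  Computed from mean ranks.
#'
#' @inheritParams pr_auc
#' @return The area, in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F1 score and accuracy of hard predictions
#'
#' F1 is the harmonic mean of precision and recall; a zero denominator
#' (no positive predictions or no positives) yields F1 = 0 with a warning.
#'
#' @param pred_labels 0/1 predictions.
#' @param labels 0/1 truth of the same length.
#' @return List with \code{f1} and \code{accuracy}.
#' @export
f1_accuracy <- function(pred_labels, labels) {
  if (length(pred_labels) != length(labels))
    stop("pred_labels and labels differ in length")
  stopifnot(all(pred_labels %in% c(0, 1)), all(labels %in% c(0, 1)))
  tp <- sum(pred_labels == 1 & labels == 1)
  fp <- sum(pred_labels == 1 & labels == 0)
  fn <- sum(pred_labels == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) {
    warning("F1 undefined (no positives predicted or present); reporting 0")
    0
  } else 2 * tp / (2 * tp + fp + fn)
  list(f1 = f1, accuracy = mean(pred_labels == labels))
}

#' Full metric report for scored predictions
#'
#' Computes PR-AUC, ROC-AUC, F1 and accuracy (hard labels at probability
#' 0.5), optionally restricted to kept samples of a selective classifier,
#' with bootstrap standard deviations over evaluation resamples.
#'
#' @param probs Success probabilities.
#' @param labels 0/1 truth.
#' @param kept Optional logical keep mask; metrics are computed on kept rows
#'   and \code{retain_rate} is its mean (1 when absent).
#' @param n_boot Bootstrap resamples for the standard deviations (0 = skip).
#' @param seed Seed for the bootstrap.
#' @return List of class \code{metrics_report}.
#' @export
metrics_report <- function(probs, labels, kept = NULL, n_boot = 200, seed = 1) {
  stopifnot(length(probs) == length(labels))
  retain <- if (is.null(kept)) 1 else mean(kept)
  if (!is.null(kept)) { probs <- probs[kept]; labels <- labels[kept] }
  one <- function(p, y) {
    # rank metrics are undefined on an empty or one-class evaluation set;
    # report NA rather than aborting a pipeline run
    rank_ok <- length(y) > 0 && length(unique(y)) == 2
    fa <- if (length(y) > 0) suppressWarnings(
      f1_accuracy(as.integer(p >= 0.5), y)) else list(f1 = NA_real_,
                                                      accuracy = NA_real_)
    c(pr_auc = if (rank_ok) pr_auc(p, y) else NA_real_,
      roc_auc = if (rank_ok) roc_auc(p, y) else NA_real_,
      f1 = fa$f1, accuracy = fa$accuracy)
  }
  pt <- one(probs, labels)
  sds <- rep(NA_real_, 4)
  if (anyNA(pt[c("pr_auc", "roc_auc")])) n_boot <- 0
  if (n_boot > 0) {
    set.seed(seed)
    bs <- replicate(n_boot, {
      i <- sample.int(length(probs), replace = TRUE)
      if (length(unique(labels[i])) < 2) rep(NA_real_, 4) else one(probs[i], labels[i])
    })
    sds <- apply(bs, 1, stats::sd, na.rm = TRUE)
  }
  structure(list(pr_auc = unname(pt[1]), roc_auc = unname(pt[2]),
                 f1 = unname(pt[3]), accuracy = unname(pt[4]),
                 retain_rate = retain, n_eval = length(labels),
                 boot_sd = stats::setNames(sds, names(pt))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Metrics on %d samples (retain rate %.4f)\n  PR-AUC %.4f  ROC-AUC %.4f  F1 %.4f  accuracy %.4f\n",
    x$n_eval, x$retain_rate, x$pr_auc, x$roc_auc, x$f1, x$accuracy))
  invisible(x)
}

#' Temporal train/validation/test split of a trial table
#'
#' Test trials start strictly after the split date; the training pool
#' completes strictly before it; trials straddling the split date satisfy
#' neither condition and are dropped (their count is attached as an
#' attribute and messaged).  A seeded random fraction of the training pool
#' becomes the validation set.
#'
#' @param trials Trial data.frame with \code{start_date} and
#'   \code{completion_date} columns (Date or ISO-8601 strings).
#' @param split_date Date (or string) defining the split.
#' @param validation_fraction Fraction of the training pool held out
#'   for validation. Default 0.15.
#' @param seed Seed for the validation draw.
#' @return List with \code{train}, \code{validation}, \code{test}
#'   data.frames; attribute \code{n_dropped} counts straddling trials.
#' @export
temporal_split <- function(trials, split_date, validation_fraction = 0.15,
                           seed = 1) {
  stopifnot(is.data.frame(trials),
            all(c("start_date", "completion_date") %in% names(trials)),
            validation_fraction >= 0, validation_fraction < 1)
  st <- as.Date(trials$start_date); en <- as.Date(trials$completion_date)
  if (anyNA(st) || anyNA(en)) {
    bad <- trials$trial_id[is.na(st) | is.na(en)]
    stop("undated trials: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  split_date <- as.Date(split_date)
  is_test <- st > split_date
  is_pool <- en < split_date
  dropped <- sum(!is_test & !is_pool)
  if (dropped > 0)
    message(dropped, " trial(s) straddle the split date and were dropped")
  pool <- trials[is_pool, , drop = FALSE]
  set.seed(seed)
  n_val <- floor(nrow(pool) * validation_fraction)
  vi <- sample.int(nrow(pool), n_val)
  out <- list(train = pool[setdiff(seq_len(nrow(pool)), vi), , drop = FALSE],
              validation = pool[vi, , drop = FALSE],
              test = trials[is_test, , drop = FALSE])
  if (nrow(out$test) == 0L) warning("temporal split produced an empty test set")
  attr(out, "n_dropped") <- dropped
  out
}

metric_fun <- function(metric) {
  switch(metric,
    pr_auc = function(p, y) pr_auc(p, y),
    roc_auc = function(p, y) roc_auc(p, y),
    f1 = function(p, y) f1_accuracy(as.integer(p >= 0.5), y)$f1,
    accuracy = function(p, y) f1_accuracy(as.integer(p >= 0.5), y)$accuracy,
    stop("unknown metric: ", metric))
}

#' Paired bootstrap p-value for a metric improvement
#'
#' Tests whether method b improves a metric over method a on the same
#' evaluation set: resamples evaluation indices with replacement --
#' stratified by class, so ranking metrics stay defined on every replicate
#' -- and reports the add-one-smoothed fraction of replicates where
#' metric(b) <= metric(a) (one-sided).  With \code{exhaustive = TRUE} all
#' stratified resamples are enumerated instead (only sensible for tiny n).
#'
#' @param scores_a,scores_b Paired prediction scores on identical samples.
#' @param labels 0/1 truth.
#' @param metric One of "pr_auc", "roc_auc", "f1", "accuracy".
#' @param n_boot Number of bootstrap resamples. Default 2000.
#' @param seed Seed.
#' @param exhaustive Enumerate all resamples instead of sampling.
#' @return The p-value.
#' @export
bootstrap_pvalue <- function(scores_a, scores_b, labels, metric = "roc_auc",
                             n_boot = 2000, seed = 1, exhaustive = FALSE) {
  n <- length(labels)
  if (length(scores_a) != n || length(scores_b) != n)
    stop("scores and labels must be paired (equal lengths)")
  f <- metric_fun(metric)
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present")
  stat <- function(i) {
    y <- labels[i]
    f(scores_b[i], y) <= f(scores_a[i], y)
  }
  if (exhaustive) {
    combos_pos <- expand.grid(rep(list(pos), length(pos)))
    combos_neg <- expand.grid(rep(list(neg), length(neg)))
    hits <- logical(0)
    for (r in seq_len(nrow(combos_pos)))
      for (s in seq_len(nrow(combos_neg)))
        hits <- c(hits, stat(c(as.integer(combos_pos[r, ]),
                               as.integer(combos_neg[s, ]))))
    return((1 + sum(hits)) / (1 + length(hits)))
  }
  set.seed(seed)
  hits <- vapply(seq_len(n_boot), function(b)
    stat(c(pos[sample.int(length(pos), replace = TRUE)],
           neg[sample.int(length(neg), replace = TRUE)])),
    logical(1))
  (1 + sum(hits)) / (n_boot + 1)
}

#' Coverage-accuracy trade-off sweep over thresholds
#'
#' For each grid threshold, keeps samples with confidence at or above it and
#' records the selective accuracy and the fraction kept -- the curve behind
#' coverage/accuracy trade-off plots.  The fraction kept is checked to be
#' non-increasing in the threshold.
#'
#' @param samples Scored samples with truth (see [scored_samples()]).
#' @param grid Optional threshold grid; default is the sorted unique
#'   confidences plus 0.
#' @return Data.frame with \code{lam}, \code{selective_accuracy},
#'   \code{fraction_kept}.
#' @export
lambda_sweep <- function(samples, grid = NULL) {
  stopifnot(is.data.frame(samples), "true_label" %in% names(samples))
  if (is.null(grid)) grid <- sort(unique(c(0, samples$confidence)))
  out <- do.call(rbind, lapply(grid, function(l) {
    kept <- samples$confidence >= l
    data.frame(
      lam = l,
      selective_accuracy = if (any(kept))
        mean(samples$pred_label[kept] == samples$true_label[kept]) else NA_real_,
      fraction_kept = mean(kept))
  }))
  stopifnot(!is.unsorted(rev(out$fraction_kept)))
  out
}

#' Relative improvement of a metric, in percent
#'
#' 100 * (improved - base) / base, reported to two decimals -- the
#' arithmetic behind published improvement columns.
#'
#' @param base Baseline metric value (> 0).
#' @param improved Improved metric value.
#' @return Percentage, rounded to two decimals.
#' @examples
#' relative_improvement(0.5765, 0.7631)  # 32.37
#' @export
relative_improvement <- function(base, improved) {
  if (any(base <= 0)) stop("base must be positive")
  round(100 * (improved - base) / base, 2)
}
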