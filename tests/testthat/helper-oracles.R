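# Independent brute-force oracles used across test files.  Each is written
# as plainly as possible (explicit loops, no shared code with the package)
# so it can serve as a reference implementation.

# step-wise average precision by enumerating every threshold
pr_auc_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Mann-Whitney pair counting, ties at half weight
roc_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# dense masked-GCN recursion with explicit index loops
gcn_oracle <- function(E0, J, A, B_list, W_list) {
  K <- nrow(E0); d <- ncol(E0)
  E <- E0
  for (n in seq_along(B_list)) {
    out <- matrix(0, K, d)
    for (i in seq_len(K)) for (c in seq_len(d)) {
      acc <- B_list[[n]][i, c]
      for (k in seq_len(K)) for (u in seq_len(d))
        acc <- acc + A[i, k] * J[i, k] * E[k, u] * W_list[[n]][u, c]
      out[i, c] <- max(acc, 0)
    }
    E <- out
  }
  E
}

# exhaustive threshold scan for the calibrated abstention threshold
brute_force_lam_hat <- function(samples, alpha, beta) {
  grid <- sort(unique(c(0, 1, samples$confidence)))
  n_min <- ceiling(log(beta) / log(1 - alpha) - 1e-12)
  stats <- t(vapply(grid, function(l) {
    kept <- samples$confidence >= l
    k <- sum(kept & samples$pred_label != samples$true_label)
    c(n = sum(kept), k = k)
  }, numeric(2)))
  ucb <- binom_ucb(stats[, "k"], stats[, "n"], beta)
  cert <- stats[, "n"] >= n_min
  for (i in seq_along(grid)) {
    if (!cert[i]) next
    later <- seq(i, length(grid))
    if (all(ucb[later][cert[later]] <= alpha)) return(grid[i])
  }
  NA_real_
}
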