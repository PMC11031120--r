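# The hierarchical interaction network: a fixed 13-node graph over drug,
# disease and protocol embeddings, ADMET and disease-risk knowledge heads,
# aggregation nodes, and a dynamic attentive GCN whose edge attention is
# computed from the initial node embeddings.  Trained end-to-end with
# binary cross-entropy after auxiliary-task warm starts.

# node order is fixed; row k of E0 always holds the k-th node here
NODE_NAMES <- c("delta", "tau", "pi", "A", "D", "M", "E", "T",
                "Psi", "PK", "IN", "AU", "PR")
ADMET_PROPS <- c("A", "D", "M", "E", "T")

#' Adjacency of the 13-node interaction graph
#'
#' Symmetrized union of the construction edges (drug node to each ADMET
#' head, disease to the risk head, ADMET heads to the PK aggregate, the
#' three inputs to the interaction node, risk + interaction to the
#' augmented node, PK + augmented to the prediction node) plus self-loops,
#' so each node keeps its own state under the masked GCN update.
#'
#' @return 13 x 13 binary matrix with dimnames = node names.
#' @export
hint_adjacency <- function() {
  K <- length(NODE_NAMES)
  J <- matrix(0, K, K, dimnames = list(NODE_NAMES, NODE_NAMES))
  edges <- rbind(
    cbind("tau", ADMET_PROPS),
    c("delta", "Psi"),
    cbind(ADMET_PROPS, "PK"),
    c("tau", "IN"), c("delta", "IN"), c("pi", "IN"),
    c("Psi", "AU"), c("IN", "AU"),
    c("PK", "PR"), c("AU", "PR"))
  for (r in seq_len(nrow(edges))) {
    J[edges[r, 1], edges[r, 2]] <- 1
    J[edges[r, 2], edges[r, 1]] <- 1
  }
  diag(J) <- 1
  J
}

#' Hyperparameters of the interaction network
#'
#' @param d Embedding dimension of every node. Default 64.
#' @param n_gcn GCN depth N. Default 2.
#' @param kernel_sizes Kernel sizes of the four sequential 1-D conv layers
#'   of the protocol encoder.
#' @param fp_bits Molecule fingerprint width; wider raw fingerprints are
#'   folded down to this many counts before the encoder.
#' @param epochs,lr,batch_size Fine-tuning schedule (Adam); \code{epochs}
#'   is a maximum when early stopping is active.
#' @param weight_decay Decoupled weight-decay rate applied at each Adam
#'   step; regularizes the over-parameterized encoders against
#'   memorizing the training trials.
#' @param early_stop_fraction Fraction of the training trials held out
#'   inside [train_hint()] to monitor held-out AUC per epoch and restore
#'   the best parameters; 0 disables early stopping.
#' @param patience Epochs without held-out improvement before fine-tuning
#'   stops.
#' @param pretrain_epochs_admet,pretrain_epochs_disease Warm-start epochs
#'   for the auxiliary heads.
#' @param seed Integer seed governing initialization and batching.
#' @return List of class \code{hint_config}.
#' @export
hint_config <- function(d = 64, n_gcn = 2, kernel_sizes = c(2, 3, 4, 5),
                        fp_bits = 256, epochs = 30, lr = 1e-3,
                        batch_size = 32, weight_decay = 1e-3,
                        early_stop_fraction = 0.15, patience = 5,
                        pretrain_epochs_admet = 30,
                        pretrain_epochs_disease = 100, seed = 1) {
  stopifnot(d >= 2, n_gcn >= 1, length(kernel_sizes) == 4,
            early_stop_fraction >= 0, early_stop_fraction < 0.5)
  structure(list(d = d, n_gcn = n_gcn, kernel_sizes = kernel_sizes,
                 fp_bits = fp_bits, epochs = epochs, lr = lr,
                 batch_size = batch_size, weight_decay = weight_decay,
                 early_stop_fraction = early_stop_fraction,
                 patience = patience,
                 pretrain_epochs_admet = pretrain_epochs_admet,
                 pretrain_epochs_disease = pretrain_epochs_disease,
                 seed = as.integer(seed)),
            class = "hint_config")
}

init_hint_params <- function(config, n_codes) {
  d <- config$d; K <- length(NODE_NAMES)
  p <- list(
    enc_W = glorot(d, config$fp_bits), enc_b = rep(0, d),
    gram_emb = matrix(stats::rnorm(n_codes * d, sd = 0.1), n_codes, d),
    gram_W = glorot(d, 2 * d), gram_b = rep(0, d), gram_v = glorot(d, 1)[, 1],
    prot_W = glorot(d, d), prot_b = rep(0, d),
    att_W = glorot(d, 2 * d), att_b = rep(0, d),
    att_v = glorot(d, 1)[, 1], att_c = 0,
    out_w = glorot(d, 1)[, 1], out_b = 0)
  for (k in 1:4) {
    ks <- config$kernel_sizes[k]
    p[[paste0("conv", k, "_W")]] <- glorot_conv(d, d, ks)
    p[[paste0("conv", k, "_b")]] <- rep(0, d)
  }
  for (pp in ADMET_PROPS) {
    hw <- init_highway(d)
    p[[paste0("adm_", pp, "_WT")]] <- hw$WT
    p[[paste0("adm_", pp, "_bT")]] <- hw$bT
    p[[paste0("adm_", pp, "_WH")]] <- hw$WH
    p[[paste0("adm_", pp, "_bH")]] <- hw$bH
    p[[paste0("adm_", pp, "_head_w")]] <- glorot(d, 1)[, 1]
    p[[paste0("adm_", pp, "_head_b")]] <- 0
  }
  for (nm in c("psi1", "psi2")) {
    hw <- init_highway(d)
    p[[paste0(nm, "_WT")]] <- hw$WT; p[[paste0(nm, "_bT")]] <- hw$bT
    p[[paste0(nm, "_WH")]] <- hw$WH; p[[paste0(nm, "_bH")]] <- hw$bH
  }
  p$psi_head_w <- glorot(d, 1)[, 1]; p$psi_head_b <- 0
  for (nd in list(c("pk", 5), c("in", 3), c("au", 2), c("pr", 2))) {
    nm <- nd[[1]]; m <- as.numeric(nd[[2]])
    p[[paste0(nm, "_W")]] <- glorot(d, m * d)
    p[[paste0(nm, "_b")]] <- rep(0, d)
    for (l in 1:2) {
      hw <- init_highway(d)
      p[[paste0(nm, l, "_WT")]] <- hw$WT; p[[paste0(nm, l, "_bT")]] <- hw$bT
      p[[paste0(nm, l, "_WH")]] <- hw$WH; p[[paste0(nm, l, "_bH")]] <- hw$bH
    }
  }
  for (n in seq_len(config$n_gcn)) {
    p[[paste0("gcn_B", n)]] <- matrix(0, K, d)
    p[[paste0("gcn_W", n)]] <- glorot(d, d)
  }
  p
}

hw_params <- function(params, prefix) {
  list(WT = params[[paste0(prefix, "_WT")]],
       bT = params[[paste0(prefix, "_bT")]],
       WH = params[[paste0(prefix, "_WH")]],
       bH = params[[paste0(prefix, "_bH")]])
}

# one aggregation node: linear m*d -> d, then two highway layers
agg_fwd <- function(cat_in, params, prefix) {
  a <- drop(params[[paste0(prefix, "_W")]] %*% cat_in) +
    params[[paste0(prefix, "_b")]]
  c1 <- highway_fwd(a, hw_params(params, paste0(prefix, 1)))
  c2 <- highway_fwd(c1$y, hw_params(params, paste0(prefix, 2)))
  list(y = c2$y, cat_in = cat_in, c1 = c1, c2 = c2)
}

agg_bwd <- function(dy, cache, params, gr, prefix) {
  dh <- highway_bwd(dy, cache$c2, hw_params(params, paste0(prefix, 2)),
                    gr, paste0(prefix, 2))
  da <- highway_bwd(dh, cache$c1, hw_params(params, paste0(prefix, 1)),
                    gr, paste0(prefix, 1))
  grad_add(gr, paste0(prefix, "_W"), tcrossprod(da, cache$cat_in))
  grad_add(gr, paste0(prefix, "_b"), da)
  drop(crossprod(params[[paste0(prefix, "_W")]], da))
}

#' Edge attention matrix from initial node embeddings
#'
#' Scores every ordered node pair (i, j) with a two-layer network (ReLU
#' hidden layer, sigmoid output) applied to the concatenation of the two
#' layer-0 embeddings.  All entries lie in (0, 1); the matrix need not be
#' symmetric since (i, j) and (j, i) concatenate in opposite order.
#'
#' @param E0 K x d matrix of initial node embeddings.
#' @param params Parameter list with \code{att_W}, \code{att_b},
#'   \code{att_v}, \code{att_c} (e.g. \code{model$params}).
#' @return K x K matrix of attention weights in (0, 1).
#' @export
attention_matrix <- function(E0, params) {
  stopifnot(is.matrix(E0), all(is.finite(E0)))
  K <- nrow(E0)
  pi_idx <- rep(seq_len(K), times = K)
  pj_idx <- rep(seq_len(K), each = K)
  Et <- t(E0)
  Z <- rbind(Et[, pi_idx, drop = FALSE], Et[, pj_idx, drop = FALSE])
  H <- pmax(params$att_W %*% Z + params$att_b, 0)
  s <- drop(crossprod(params$att_v, H)) + params$att_c
  matrix(sigmoid(s), K, K)
}

#' Masked attentive GCN forward pass
#'
#' Applies the update E_n = ReLU(B_n + (A * J) E_{n-1} W_n) for n = 1..N,
#' where * is the element-wise product masking attention to the graph's
#' edges, so messages flow only along edges of J.
#'
#' @param E0 K x d initial node embeddings.
#' @param J K x K binary adjacency.
#' @param A K x K attention matrix.
#' @param B_list,W_list Lists of per-layer bias (K x d) and weight (d x d)
#'   matrices; their common length is the depth N.
#' @return K x d matrix of final-layer embeddings (entries >= 0).
#' @export
gcn_forward <- function(E0, J, A, B_list, W_list) {
  stopifnot(length(B_list) == length(W_list), length(B_list) >= 1,
            all(dim(J) == c(nrow(E0), nrow(E0))), all(dim(A) == dim(J)))
  M <- unname(A * J)
  E <- unname(E0)
  for (n in seq_along(B_list))
    E <- pmax(B_list[[n]] + (M %*% E) %*% W_list[[n]], 0)
  E
}

# full forward pass on one preprocessed trial ---------------------------
# x: list(fp = n_drugs x fp_bits, anc = list of ancestor-index vectors,
#         S = d x L sentence matrix or NULL)
hint_forward <- function(params, x, config) {
  d <- config$d
  # drug encoder
  Zt <- params$enc_W %*% t(x$fp) + params$enc_b       # d x n_drugs
  Et <- pmax(Zt, 0)
  e_tau <- rowMeans(Et)
  # disease encoder (GRAM over ancestors)
  gcaches <- lapply(x$anc, gram_fwd, params = params)
  e_delta <- rowMeans(do.call(cbind, lapply(gcaches, `[[`, "G")))
  # protocol encoder: 4 sequential convs, mean pool, FC
  if (is.null(x$S)) {
    e_pi <- rep(0, d); ccaches <- NULL; pool <- NULL
  } else {
    ccaches <- vector("list", 4)
    X <- x$S
    for (k in 1:4) {
      ccaches[[k]] <- conv1d_fwd(X, params[[paste0("conv", k, "_W")]],
                                 params[[paste0("conv", k, "_b")]])
      X <- ccaches[[k]]$Y
    }
    pool <- rowMeans(X)
    e_pi <- drop(params$prot_W %*% pool) + params$prot_b
  }
  # knowledge tier
  acaches <- lapply(ADMET_PROPS, function(pp)
    highway_fwd(e_tau, hw_params(params, paste0("adm_", pp))))
  names(acaches) <- ADMET_PROPS
  p1 <- highway_fwd(e_delta, hw_params(params, "psi1"))
  p2 <- highway_fwd(p1$y, hw_params(params, "psi2"))
  e_psi <- p2$y
  # aggregation tier
  pk <- agg_fwd(unlist(lapply(acaches, `[[`, "y"), use.names = FALSE),
                params, "pk")
  inn <- agg_fwd(c(e_tau, e_delta, e_pi), params, "in")
  au <- agg_fwd(c(e_psi, inn$y), params, "au")
  pr <- agg_fwd(c(pk$y, au$y), params, "pr")
  E0 <- rbind(e_delta, e_tau, e_pi,
              do.call(rbind, lapply(acaches, `[[`, "y")),
              e_psi, pk$y, inn$y, au$y, pr$y)
  rownames(E0) <- NODE_NAMES
  # attentive GCN
  K <- nrow(E0)
  pi_idx <- rep(seq_len(K), times = K)
  pj_idx <- rep(seq_len(K), each = K)
  Etr <- t(E0)
  Z <- rbind(Etr[, pi_idx, drop = FALSE], Etr[, pj_idx, drop = FALSE])
  Ha <- pmax(params$att_W %*% Z + params$att_b, 0)
  sa <- drop(crossprod(params$att_v, Ha)) + params$att_c
  Avec <- sigmoid(sa)
  A <- matrix(Avec, K, K)
  M <- A * x$J
  Es <- vector("list", config$n_gcn + 1); Es[[1]] <- E0
  Ps <- Rs <- vector("list", config$n_gcn)
  for (n in seq_len(config$n_gcn)) {
    Rs[[n]] <- M %*% Es[[n]]
    Ps[[n]] <- params[[paste0("gcn_B", n)]] +
      Rs[[n]] %*% params[[paste0("gcn_W", n)]]
    Es[[n + 1]] <- pmax(Ps[[n]], 0)
  }
  u <- Es[[config$n_gcn + 1]][K, ]
  logit <- sum(params$out_w * u) + params$out_b
  list(prob = sigmoid(logit), logit = logit,
       E0 = E0, A = A, M = M, Es = Es, Ps = Ps, Rs = Rs,
       Z = Z, Ha = Ha, Avec = Avec, pi_idx = pi_idx, pj_idx = pj_idx,
       Zt = Zt, gcaches = gcaches, ccaches = ccaches, pool = pool,
       acaches = acaches, p1 = p1, p2 = p2,
       pk = pk, inn = inn, au = au, pr = pr, u = u)
}

hint_backward <- function(dlogit, fw, params, x, config, gr) {
  d <- config$d; K <- length(NODE_NAMES); N <- config$n_gcn
  grad_add(gr, "out_w", dlogit * fw$u)
  grad_add(gr, "out_b", dlogit)
  dE <- matrix(0, K, d)
  dE[K, ] <- dlogit * params$out_w
  dM <- matrix(0, K, K)
  for (n in rev(seq_len(N))) {
    dP <- dE * (fw$Ps[[n]] > 0)
    grad_add(gr, paste0("gcn_B", n), dP)
    grad_add(gr, paste0("gcn_W", n), crossprod(fw$Rs[[n]], dP))
    dR <- tcrossprod(dP, params[[paste0("gcn_W", n)]])
    dM <- dM + tcrossprod(dR, fw$Es[[n]])
    dE <- crossprod(fw$M, dR)
  }
  dE0 <- dE
  # attention backward
  dA <- dM * x$J
  dsa <- as.vector(dA) * fw$Avec * (1 - fw$Avec)
  grad_add(gr, "att_c", sum(dsa))
  grad_add(gr, "att_v", drop(fw$Ha %*% dsa))
  dZh <- tcrossprod(params$att_v, dsa) * (fw$Ha > 0)
  grad_add(gr, "att_W", tcrossprod(dZh, fw$Z))
  grad_add(gr, "att_b", rowSums(dZh))
  dZc <- crossprod(params$att_W, dZh)                 # 2d x K^2
  for (i in seq_len(K)) {
    sel_i <- fw$pi_idx == i
    sel_j <- fw$pj_idx == i
    dE0[i, ] <- dE0[i, ] +
      rowSums(dZc[seq_len(d), sel_i, drop = FALSE]) +
      rowSums(dZc[d + seq_len(d), sel_j, drop = FALSE])
  }
  # aggregation tier, reverse topological order
  dcat <- agg_bwd(dE0[13, ], fw$pr, params, gr, "pr")
  de_pk <- dE0[10, ] + dcat[seq_len(d)]
  de_au <- dE0[12, ] + dcat[d + seq_len(d)]
  dcat <- agg_bwd(de_au, fw$au, params, gr, "au")
  de_psi <- dE0[9, ] + dcat[seq_len(d)]
  de_in <- dE0[11, ] + dcat[d + seq_len(d)]
  dcat <- agg_bwd(de_in, fw$inn, params, gr, "in")
  de_tau <- dE0[2, ] + dcat[seq_len(d)]
  de_delta <- dE0[1, ] + dcat[d + seq_len(d)]
  de_pi <- dE0[3, ] + dcat[2 * d + seq_len(d)]
  dcat <- agg_bwd(de_pk, fw$pk, params, gr, "pk")
  # knowledge tier
  dh <- highway_bwd(de_psi, fw$p2, hw_params(params, "psi2"), gr, "psi2")
  de_delta <- de_delta +
    highway_bwd(dh, fw$p1, hw_params(params, "psi1"), gr, "psi1")
  for (k in seq_along(ADMET_PROPS)) {
    pp <- ADMET_PROPS[k]
    de_k <- dE0[3 + k, ] + dcat[(k - 1) * d + seq_len(d)]
    de_tau <- de_tau + highway_bwd(de_k, fw$acaches[[pp]],
                                   hw_params(params, paste0("adm_", pp)),
                                   gr, paste0("adm_", pp))
  }
  # protocol encoder backward
  if (!is.null(fw$ccaches)) {
    grad_add(gr, "prot_W", tcrossprod(de_pi, fw$pool))
    grad_add(gr, "prot_b", de_pi)
    dpool <- drop(crossprod(params$prot_W, de_pi))
    L <- ncol(fw$ccaches[[4]]$Y)
    dX <- matrix(dpool / L, d, L)
    for (k in 4:1)
      dX <- conv1d_bwd(dX, fw$ccaches[[k]],
                       params[[paste0("conv", k, "_W")]], gr,
                       paste0("conv", k))
  }
  # drug encoder backward
  nd <- ncol(fw$Zt)
  dZt <- matrix(de_tau / nd, d, nd) * (fw$Zt > 0)
  grad_add(gr, "enc_W", dZt %*% x$fp)
  grad_add(gr, "enc_b", rowSums(dZt))
  # disease encoder backward
  nc <- length(fw$gcaches)
  for (gc in fw$gcaches)
    gram_bwd(de_delta / nc, gc, params, gr)
  invisible(NULL)
}

# model construction and data preparation ------------------------------

#' Initialize an untrained interaction-network model
#'
#' Builds the parameter set, adjacency and ontology indices for a given
#' disease ontology.  Deterministic given \code{config$seed}.
#'
#' @param onto A \code{trial_ontology} covering every disease code the
#'   model will see.
#' @param config A [hint_config()].
#' @return Object of class \code{hint_model}.
#' @export
hint_init <- function(onto, config = hint_config()) {
  stopifnot(inherits(onto, "trial_ontology"), inherits(config, "hint_config"))
  set.seed(config$seed)
  codes <- onto$codes
  anc_idx <- lapply(codes, function(cd)
    match(ancestors(onto, cd), codes))
  names(anc_idx) <- codes
  structure(list(
    params = init_hint_params(config, length(codes)),
    config = config,
    nodes = NODE_NAMES,
    J = hint_adjacency(),
    codes = codes,
    anc_idx = anc_idx,
    history = list()), class = "hint_model")
}

#' @export
print.hint_model <- function(x, ...) {
  cat(sprintf(
    "Hierarchical interaction network: %d nodes, d = %d, GCN depth %d, %d disease codes%s\n",
    length(x$nodes), x$config$d, x$config$n_gcn, length(x$codes),
    if (length(x$history) > 0) " (trained)" else " (untrained)"))
  invisible(x)
}

parse_criteria <- function(json) {
  if (is.na(json) || !nzchar(json)) return(character(0))
  df <- jsonlite::fromJSON(json)
  if (length(df) == 0 || is.null(df$text)) return(character(0))
  as.character(df$text)
}

split_field <- function(x) strsplit(x, ";", fixed = TRUE)

# turn a trial table into per-trial model inputs
preprocess_trials <- function(trials, model) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  d <- model$config$d
  all_sm <- unique(unlist(split_field(trials$smiles)))
  fpm <- fp_features(all_sm, model$config$fp_bits)
  n_empty <- 0L
  xs <- lapply(seq_len(nrow(trials)), function(i) {
    sm <- split_field(trials$smiles[i])[[1]]
    if (length(sm) == 0) stop("trial ", trials$trial_id[i], ": no drugs")
    cds <- split_field(trials$icd_codes[i])[[1]]
    if (length(cds) == 0) stop("trial ", trials$trial_id[i], ": no diseases")
    unknown <- setdiff(cds, model$codes)
    if (length(unknown) > 0)
      stop("trial ", trials$trial_id[i], ": unknown ontology code: '",
           unknown[1], "'")
    sent <- parse_criteria(trials$criteria[i])
    S <- if (length(sent) == 0) NULL else t(sentence_embedding(sent, d))
    if (is.null(S)) n_empty <<- n_empty + 1L
    list(fp = fpm[sm, , drop = FALSE],
         anc = model$anc_idx[cds],
         S = S,
         J = model$J,
         trial_id = trials$trial_id[i],
         label = if ("label" %in% names(trials)) trials$label[i] else NA)
  })
  if (n_empty > 0)
    warning(n_empty, " trial(s) have an empty protocol; ",
            "their protocol embedding is the zero vector")
  xs
}

#' Per-disease historical success rates from labelled trials
#'
#' Empirical success fraction of the trials mentioning each code, shrunk
#' toward the global rate -- the supervision signal for the disease-risk
#' head.
#'
#' @param trials Labelled trial table.
#' @param shrink Pseudo-count of the shrinkage prior.
#' @return Data.frame (code, rate, n).
#' @export
disease_rates_from_trials <- function(trials, shrink = 5) {
  stopifnot("label" %in% names(trials))
  codes <- split_field(trials$icd_codes)
  long <- data.frame(code = unlist(codes),
                     label = rep(trials$label, lengths(codes)))
  gbar <- mean(trials$label)
  agg <- stats::aggregate(label ~ code, long, function(v)
    c(s = sum(v), n = length(v)))
  data.frame(code = agg$code,
             rate = (agg$label[, "s"] + shrink * gbar) /
               (agg$label[, "n"] + shrink),
             n = agg$label[, "n"])
}

# auxiliary-task gradients ----------------------------------------------

admet_sample_grad <- function(params, fp, y, prop, gr) {
  z <- drop(params$enc_W %*% fp) + params$enc_b
  e <- relu(z)
  hw <- highway_fwd(e, hw_params(params, paste0("adm_", prop)))
  logit <- sum(params[[paste0("adm_", prop, "_head_w")]] * hw$y) +
    params[[paste0("adm_", prop, "_head_b")]]
  p <- sigmoid(logit)
  dlogit <- p - y
  grad_add(gr, paste0("adm_", prop, "_head_w"), dlogit * hw$y)
  grad_add(gr, paste0("adm_", prop, "_head_b"), dlogit)
  dep <- dlogit * params[[paste0("adm_", prop, "_head_w")]]
  de <- highway_bwd(dep, hw, hw_params(params, paste0("adm_", prop)),
                    gr, paste0("adm_", prop))
  dz <- de * (z > 0)
  grad_add(gr, "enc_W", tcrossprod(dz, fp))
  grad_add(gr, "enc_b", dz)
  bce_loss(p, y)
}

disease_sample_grad <- function(params, anc, rate, gr) {
  gc <- gram_fwd(anc, params)
  p1 <- highway_fwd(gc$G, hw_params(params, "psi1"))
  p2 <- highway_fwd(p1$y, hw_params(params, "psi2"))
  logit <- sum(params$psi_head_w * p2$y) + params$psi_head_b
  p <- sigmoid(logit)
  dlogit <- p - rate
  grad_add(gr, "psi_head_w", dlogit * p2$y)
  grad_add(gr, "psi_head_b", dlogit)
  dep <- dlogit * params$psi_head_w
  dh <- highway_bwd(dep, p2, hw_params(params, "psi2"), gr, "psi2")
  dG <- highway_bwd(dh, p1, hw_params(params, "psi1"), gr, "psi1")
  gram_bwd(dG, gc, params, gr)
  bce_loss(p, rate)
}

run_epochs <- function(params, state, items, grad_fn, epochs, batch, lr,
                       weight_decay = 0) {
  losses <- numeric(epochs)
  n <- length(items)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (b0 in seq(1, n, by = batch)) {
      idx <- ord[b0:min(b0 + batch - 1, n)]
      gr <- grad_new()
      for (i in idx) tot <- tot + grad_fn(params, items[[i]], gr)
      st <- adam_step(params, grad_collect(gr, params, 1 / length(idx)),
                      state, lr = lr, weight_decay = weight_decay)
      params <- st$params; state <- st$state
    }
    losses[ep] <- tot / n
  }
  list(params = params, state = state, losses = losses)
}

#' Train the interaction network
#'
#' Three stages: (1) warm-start the molecule encoder and the five ADMET
#' heads on auxiliary molecule-property tables; (2) warm-start the disease
#' embedding and risk head on per-disease historical success rates; (3)
#' fine-tune everything end-to-end on the trial labels with binary
#' cross-entropy.  All stages use Adam and are deterministic given the
#' config seed.
#'
#' @param trials Labelled trial table (see [gen_trials()] for the dialect).
#' @param onto The disease ontology.
#' @param config A [hint_config()].
#' @param admet_tables Optional named list (A, D, M, E, T) of data.frames
#'   (smiles, label); omit to skip stage 1.
#' @param disease_rates Optional data.frame (code, rate); default computes
#'   [disease_rates_from_trials()] on the training trials.
#' @param verbose Print per-epoch losses.
#' @return A trained \code{hint_model} with a \code{history} of losses.
#' @export
train_hint <- function(trials, onto, config = hint_config(),
                       admet_tables = NULL, disease_rates = NULL,
                       verbose = FALSE) {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("empty training dataset")
  if (!"label" %in% names(trials) || anyNA(trials$label))
    stop("training trials must be labelled")
  if (length(unique(trials$label)) < 2)
    warning("all training labels are one class; proceeding anyway")
  model <- hint_init(onto, config)
  params <- model$params
  state <- adam_init(params)
  history <- list()

  if (!is.null(admet_tables) && config$pretrain_epochs_admet > 0) {
    stopifnot(all(ADMET_PROPS %in% names(admet_tables)))
    sm <- unique(unlist(lapply(admet_tables, `[[`, "smiles")))
    fpm <- fp_features(sm, config$fp_bits)
    items <- list()
    for (pp in ADMET_PROPS) {
      tb <- admet_tables[[pp]]
      for (r in seq_len(nrow(tb)))
        items[[length(items) + 1]] <- list(fp = fpm[tb$smiles[r], ],
                                           y = tb$label[r], prop = pp)
    }
    res <- run_epochs(params, state, items,
                      function(p, it, gr) admet_sample_grad(p, it$fp, it$y, it$prop, gr),
                      config$pretrain_epochs_admet, config$batch_size,
                      config$lr, config$weight_decay)
    params <- res$params; state <- res$state
    history$admet <- res$losses
    if (verbose) message("ADMET pretraining loss: ",
                         paste(round(res$losses, 4), collapse = " "))
  }

  if (config$pretrain_epochs_disease > 0) {
    if (is.null(disease_rates))
      disease_rates <- disease_rates_from_trials(trials)
    items <- lapply(seq_len(nrow(disease_rates)), function(r)
      list(anc = model$anc_idx[[disease_rates$code[r]]],
           rate = disease_rates$rate[r]))
    res <- run_epochs(params, state, items,
                      function(p, it, gr) disease_sample_grad(p, it$anc, it$rate, gr),
                      config$pretrain_epochs_disease, config$batch_size,
                      config$lr, config$weight_decay)
    params <- res$params; state <- res$state
    history$disease <- res$losses
    if (verbose) message("disease-risk pretraining final loss: ",
                         round(res$losses[length(res$losses)], 4))
  }

  model$params <- params
  xs <- preprocess_trials(trials, model)
  grad_fn <- function(p, x, gr) {
    fw <- hint_forward(p, x, config)
    hint_backward(fw$prob - x$label, fw, p, x, config, gr)
    bce_loss(fw$prob, x$label)
  }
  # optional internal monitor fold for early stopping
  es <- config$early_stop_fraction
  if (es > 0 && length(xs) >= 40) {
    vi <- sample.int(length(xs), floor(es * length(xs)))
    xs_val <- xs[vi]; xs_fit <- xs[-vi]
  } else {
    xs_val <- NULL; xs_fit <- xs
  }
  best <- list(params = params, score = -Inf, epoch = 0L)
  losses <- scores <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    res <- run_epochs(params, state, xs_fit, grad_fn, 1,
                      config$batch_size, config$lr, config$weight_decay)
    params <- res$params; state <- res$state
    losses <- c(losses, res$losses)
    if (is.null(xs_val)) next
    pv <- vapply(xs_val, function(x) hint_forward(params, x, config)$prob,
                 numeric(1))
    yv <- vapply(xs_val, `[[`, numeric(1), "label")
    score <- if (length(unique(yv)) == 2) roc_auc(pv, yv)
             else -bce_loss(pv, yv)
    scores <- c(scores, score)
    if (score > best$score)
      best <- list(params = params, score = score, epoch = ep)
    else if (ep - best$epoch >= config$patience) break
  }
  if (!is.null(xs_val)) params <- best$params
  model$params <- params
  history$finetune <- losses
  history$monitor_auc <- scores
  if (verbose) message("fine-tune loss: ",
                       paste(round(losses, 4), collapse = " "),
                       if (!is.null(xs_val))
                         paste0(" (best monitor AUC ",
                                round(best$score, 4), " at epoch ",
                                best$epoch, ")") else "")
  model$history <- history
  model
}

#' Predict approval probabilities for trials
#'
#' @param object A trained (or initialized) \code{hint_model}.
#' @param trials Trial table; labels not required.
#' @param ... Unused.
#' @return Data.frame (trial_id, prob_success).
#' @export
predict.hint_model <- function(object, trials, ...) {
  xs <- preprocess_trials(trials, object)
  probs <- vapply(xs, function(x)
    hint_forward(object$params, x, object$config)$prob, numeric(1))
  data.frame(trial_id = trials$trial_id, prob_success = probs,
             stringsAsFactors = FALSE)
}

#' Per-edge attention report for one trial
#'
#' Runs the forward pass and returns the attention weight of every edge of
#' the interaction graph (both directions plus self-loops), the quantity
#' used to read which trial components drive a prediction.
#'
#' @param model A \code{hint_model}.
#' @param trial One-row trial table.
#' @return List with \code{prob_success} and \code{edges}, a data.frame
#'   (src, dst, weight), weights in (0, 1).
#' @export
attention_report <- function(model, trial) {
  stopifnot(nrow(trial) == 1)
  x <- preprocess_trials(trial, model)[[1]]
  fw <- hint_forward(model$params, x, model$config)
  idx <- which(model$J == 1, arr.ind = TRUE)
  list(prob_success = fw$prob,
       edges = data.frame(src = NODE_NAMES[idx[, 1]],
                          dst = NODE_NAMES[idx[, 2]],
                          weight = fw$A[idx],
                          stringsAsFactors = FALSE))
}

# user-facing encoder/head surfaces -------------------------------------

#' Drug-set embedding: mean of per-molecule encoder outputs
#' @param model A \code{hint_model}.
#' @param smiles Nonempty character vector of SMILES.
#' @return Numeric d-vector.
#' @export
embed_drugs <- function(model, smiles) {
  stopifnot(length(smiles) >= 1)
  fp <- fp_features(smiles, model$config$fp_bits)
  rowMeans(pmax(model$params$enc_W %*% t(fp) + model$params$enc_b, 0))
}

#' Disease-set embedding: mean of GRAM ontology-attentive code embeddings
#' @param model A \code{hint_model}.
#' @param codes Nonempty character vector of ontology codes.
#' @return Numeric d-vector.
#' @export
embed_diseases <- function(model, codes) {
  stopifnot(length(codes) >= 1)
  unknown <- setdiff(codes, model$codes)
  if (length(unknown) > 0)
    stop("unknown ontology code: '", unknown[1], "'")
  G <- vapply(codes, function(cd)
    gram_fwd(model$anc_idx[[cd]], model$params)$G,
    numeric(model$config$d))
  rowMeans(matrix(G, nrow = model$config$d))
}

#' GRAM attention weights of a code over its ancestor set
#' @param model A \code{hint_model}.
#' @param code One ontology code.
#' @return Named numeric vector (sums to 1) over the code and its ancestors.
#' @export
gram_attention <- function(model, code) {
  if (!code %in% model$codes) stop("unknown ontology code: '", code, "'")
  anc <- model$anc_idx[[code]]
  stats::setNames(gram_fwd(anc, model$params)$alpha, model$codes[anc])
}

#' Protocol embedding from eligibility-criteria sentences
#'
#' Hashed bag-of-token sentence vectors pass through four sequential 1-D
#' convolutions of distinct kernel sizes, global mean pooling and a final
#' fully connected layer.  The result depends on sentence order (the convs
#' scan the sequence).  An empty protocol embeds to the zero vector with a
#' warning.
#'
#' @param model A \code{hint_model}.
#' @param sentences Character vector of criteria sentences.
#' @return Numeric d-vector.
#' @export
embed_protocol <- function(model, sentences) {
  p <- model$params; d <- model$config$d
  if (length(sentences) == 0) {
    warning("empty protocol; returning the zero embedding")
    return(rep(0, d))
  }
  X <- t(sentence_embedding(sentences, d))
  for (k in 1:4)
    X <- conv1d_fwd(X, p[[paste0("conv", k, "_W")]],
                    p[[paste0("conv", k, "_b")]])$Y
  drop(p$prot_W %*% rowMeans(X)) + p$prot_b
}

#' ADMET knowledge head
#'
#' Applies the property-specific highway transform to a drug embedding and
#' the sigmoid scoring head, yielding the knowledge-node embedding and the
#' probability that the property is present.
#'
#' @param model A \code{hint_model}.
#' @param e_tau Drug embedding (d-vector).
#' @param property One of "A", "D", "M", "E", "T".
#' @return List (embedding, prob).
#' @export
admet_head <- function(model, e_tau, property) {
  if (!property %in% ADMET_PROPS)
    stop("invalid ADMET property tag: '", property, "'")
  p <- model$params
  hw <- highway_fwd(e_tau, hw_params(p, paste0("adm_", property)))
  logit <- sum(p[[paste0("adm_", property, "_head_w")]] * hw$y) +
    p[[paste0("adm_", property, "_head_b")]]
  list(embedding = hw$y, prob = sigmoid(logit))
}

#' Disease-risk head: 2-layer highway transform plus sigmoid scorer
#' @param model A \code{hint_model}.
#' @param e_delta Disease embedding (d-vector).
#' @return List (embedding, prob).
#' @export
disease_risk_head <- function(model, e_delta) {
  p <- model$params
  h1 <- highway_fwd(e_delta, hw_params(p, "psi1"))
  h2 <- highway_fwd(h1$y, hw_params(p, "psi2"))
  logit <- sum(p$psi_head_w * h2$y) + p$psi_head_b
  list(embedding = h2$y, prob = sigmoid(logit))
}

#' Aggregation tier: PK, interaction, augmented and prediction nodes
#'
#' Each node concatenates its inputs, applies a linear map to dimension d
#' and a 2-layer highway network.
#'
#' @param model A \code{hint_model}.
#' @param e_tau,e_delta,e_pi Input-tier embeddings (d-vectors).
#' @param e_admet Named list/vector set of the five ADMET embeddings in
#'   order A, D, M, E, T.
#' @param e_psi Disease-risk embedding.
#' @return List (e_PK, e_IN, e_AU, e_PR), each a d-vector.
#' @export
aggregate_nodes <- function(model, e_tau, e_delta, e_pi, e_admet, e_psi) {
  p <- model$params
  d <- model$config$d
  va <- unlist(e_admet, use.names = FALSE)
  stopifnot(length(va) == 5 * d, length(e_tau) == d, length(e_delta) == d,
            length(e_pi) == d, length(e_psi) == d)
  pk <- agg_fwd(va, p, "pk")
  inn <- agg_fwd(c(e_tau, e_delta, e_pi), p, "in")
  au <- agg_fwd(c(e_psi, inn$y), p, "au")
  pr <- agg_fwd(c(pk$y, au$y), p, "pr")
  list(e_PK = pk$y, e_IN = inn$y, e_AU = au$y, e_PR = pr$y)
}
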