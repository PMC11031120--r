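# small fixtures shared across blocks
small_onto <- gen_ontology(depth = 2, branching = 2, seed = 1)
small_cfg <- hint_config(d = 8, fp_bits = 64, seed = 5)
small_model <- hint_init(small_onto, small_cfg)

test_that("the interaction graph is 13 nodes, symmetric, self-looped", {
  J <- hint_adjacency()
  expect_equal(dim(J), c(13L, 13L))
  expect_identical(rownames(J),
                   c("delta", "tau", "pi", "A", "D", "M", "E", "T",
                     "Psi", "PK", "IN", "AU", "PR"))
  expect_true(all(J == t(J)))
  expect_true(all(diag(J) == 1))
  # tier wiring: inputs reach IN, ADMET reach PK, PK/AU reach PR
  expect_equal(unname(J["tau", "IN"]), 1)
  expect_equal(unname(J["pi", "IN"]), 1)
  expect_equal(unname(J["A", "PK"]), 1)
  expect_equal(unname(J["PK", "PR"]), 1)
  expect_equal(unname(J["AU", "PR"]), 1)
  expect_equal(unname(J["pi", "PK"]), 0)
})

test_that("drug embedding is the mean of per-molecule encoder outputs", {
  m <- hint_init(small_onto, hint_config(d = 8, seed = 5))
  u <- embed_drugs(m, "CCO")
  v <- embed_drugs(m, "c1ccccc1")
  expect_length(u, 8)
  expect_equal(embed_drugs(m, c("CCO", "c1ccccc1")), (u + v) / 2)
  expect_equal(embed_drugs(m, c("CCO", "CCO")), u)
  expect_error(embed_drugs(m, "not(a(smiles"), "unparseable SMILES")
})

test_that("disease embedding attends over ancestors with weights summing to 1", {
  expect_error(embed_diseases(small_model, "NOPE"), "NOPE")
  for (cd in c("C01", "C01.2", "ROOT")) {
    w <- gram_attention(small_model, cd)
    expect_equal(sum(w), 1)
    expect_named(w, ancestors(small_onto, cd))
  }
  # root has no ancestors beyond itself: its embedding is its basis vector
  expect_equal(embed_diseases(small_model, "ROOT"),
               small_model$params$gram_emb[match("ROOT", small_model$codes), ])
  # two codes average their per-code embeddings
  a <- embed_diseases(small_model, "C01")
  b <- embed_diseases(small_model, "C02.1")
  expect_equal(embed_diseases(small_model, c("C01", "C02.1")), (a + b) / 2)
})

test_that("protocol embedding is deterministic, d-dimensional, order-sensitive", {
  sent <- c("inclusion adults aged 18 to 75",
            "exclusion pregnant participants",
            "randomized double blind design")
  e1 <- embed_protocol(small_model, sent)
  expect_length(e1, 8)
  expect_identical(e1, embed_protocol(small_model, sent))
  expect_length(embed_protocol(small_model, sent[1]), 8)
  expect_warning(e0 <- embed_protocol(small_model, character(0)), "empty")
  expect_equal(e0, rep(0, 8))
})

test_that("highway layer reduces to carry or transform in its gate limits", {
  set.seed(6)
  d <- 5
  x <- rnorm(d)
  p <- list(WT = matrix(rnorm(d * d), d), bT = rep(-50, d),
            WH = matrix(rnorm(d * d), d), bH = rnorm(d))
  expect_equal(highway_layer(x, p), x, tolerance = 1e-8)   # gate closed
  p$bT <- rep(50, d)                                        # gate open
  expect_equal(highway_layer(x, p), pmax(p$WH %*% x + p$bH, 0)[, 1],
               tolerance = 1e-8)
  # hand evaluation: T = sigmoid(WT x + bT), H = relu(WH x + bH)
  p$bT <- rep(0.3, d)
  tt <- 1 / (1 + exp(-(p$WT %*% x + 0.3)))
  hh <- pmax(p$WH %*% x + p$bH, 0)
  expect_equal(highway_layer(x, p), (tt * hh + (1 - tt) * x)[, 1])
})

test_that("knowledge heads emit probabilities strictly inside (0, 1)", {
  e_tau <- embed_drugs(small_model, "CCO")
  for (pp in c("A", "D", "M", "E", "T")) {
    h <- admet_head(small_model, e_tau, pp)
    expect_length(h$embedding, 8)
    expect_gt(h$prob, 0); expect_lt(h$prob, 1)
  }
  expect_error(admet_head(small_model, e_tau, "X"), "invalid ADMET")
  e_delta <- embed_diseases(small_model, "C01.1")
  r1 <- disease_risk_head(small_model, e_delta)
  r2 <- disease_risk_head(small_model, e_delta)
  expect_identical(r1$prob, r2$prob)
  expect_gt(r1$prob, 0); expect_lt(r1$prob, 1)
})

test_that("aggregation nodes reduce to the bias path when weights vanish", {
  m <- small_model
  d <- 8
  # zero every aggregation weight; plant a known bias at the PK linear map
  v <- seq_len(d) / 10
  for (nm in c("pk", "in", "au", "pr")) {
    m$params[[paste0(nm, "_W")]][] <- 0
    m$params[[paste0(nm, "_b")]][] <- 0
    for (l in 1:2) for (suf in c("_WT", "_WH", "_bH"))
      m$params[[paste0(nm, l, suf)]][] <- 0
    for (l in 1:2) m$params[[paste0(nm, l, "_bT")]][] <- 0
  }
  m$params$pk_b <- v
  ag <- aggregate_nodes(m, rnorm(d), rnorm(d), rnorm(d),
                        replicate(5, rnorm(d), simplify = FALSE), rnorm(d))
  # two zero-weight highways halve the carried input twice: v -> v/4
  expect_equal(ag$e_PK, v / 4)
  expect_equal(ag$e_IN, rep(0, d))
  expect_length(ag$e_PR, d)
})

test_that("attention weights live in (0, 1) and are symmetric for equal rows", {
  set.seed(7)
  E0 <- matrix(rnorm(13 * 8), 13, 8)
  E0[4, ] <- E0[9, ]                      # two identical node embeddings
  A <- attention_matrix(E0, small_model$params)
  expect_true(all(A > 0 & A < 1))
  expect_equal(A[4, 9], A[9, 4])
  expect_equal(A[4, 2], A[9, 2])
})

test_that("the masked GCN agrees with a brute-force dense oracle", {
  J <- hint_adjacency()
  for (seed in 1:20) {
    set.seed(seed)
    d <- 4
    E0 <- matrix(rnorm(13 * d), 13, d)
    A <- matrix(runif(13 * 13), 13, 13)
    B <- list(matrix(rnorm(13 * d), 13, d), matrix(rnorm(13 * d), 13, d))
    W <- list(matrix(rnorm(d * d), d, d), matrix(rnorm(d * d), d, d))
    expect_equal(gcn_forward(E0, J, A, B, W), gcn_oracle(E0, J, A, B, W),
                 tolerance = 1e-6)
  }
})

test_that("GCN limit cases: zero mask and edge ablation", {
  set.seed(8)
  d <- 4
  E0 <- matrix(rnorm(13 * d), 13, d)
  B <- list(matrix(rnorm(13 * d), 13, d), matrix(rnorm(13 * d), 13, d))
  W <- list(matrix(rnorm(d * d), d, d), matrix(rnorm(d * d), d, d))
  # A = 0 wipes all messages: output is ReLU of the final bias exactly
  Z <- gcn_forward(E0, hint_adjacency(), matrix(0, 13, 13), B, W)
  expect_identical(Z, pmax(B[[2]], 0))
  # masked propagation: with edge (i -> j) absent and attention recomputed,
  # node j's layer-1 output ignores arbitrary changes to row i
  for (seed in 1:20) {
    set.seed(seed)
    m <- hint_init(small_onto, hint_config(d = 6, seed = seed))
    J <- m$J
    i <- 3; j <- 10                      # pi -> PK is not an edge
    expect_equal(unname(J[j, i]), 0)
    E0a <- matrix(rnorm(13 * 6), 13, 6)
    E0b <- E0a; E0b[i, ] <- rnorm(6) * 10
    B1 <- list(m$params$gcn_B1); W1 <- list(m$params$gcn_W1)
    Ea <- gcn_forward(E0a, J, attention_matrix(E0a, m$params), B1, W1)
    Eb <- gcn_forward(E0b, J, attention_matrix(E0b, m$params), B1, W1)
    expect_equal(Ea[j, ], Eb[j, ], tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences through the network", {
  ns <- asNamespace("trialselect")
  set.seed(42)
  onto <- gen_ontology(depth = 2, branching = 2, seed = 3)
  cfg <- hint_config(d = 6, fp_bits = 32, seed = 7)
  model <- hint_init(onto, cfg)
  params <- model$params
  x <- list(fp = matrix(rbinom(2 * 32, 1, 0.3), 2, 32),
            anc = model$anc_idx[c("C01.1", "C02")],
            S = t(ns$sentence_embedding(
              c("phase ii study", "exclusion severe impairment",
                "inclusion adults"), 6)),
            J = model$J, label = 1)
  fw <- ns$hint_forward(params, x, cfg)
  gr <- ns$grad_new()
  ns$hint_backward(fw$prob - x$label, fw, params, x, cfg, gr)
  grads <- ns$grad_collect(gr, params)
  loss_at <- function(p) ns$bce_loss(ns$hint_forward(p, x, cfg)$prob, x$label)
  eps <- 1e-6
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 5e-3,
                   label = paste("grad", nm, "entry", i))
    }
  }
})

test_that("prediction is deterministic, in (0,1), and training reduces loss", {
  cfg <- synth_config(n_trials = 60, seed = 41)
  g <- gen_trials(cfg)
  mcfg <- hint_config(d = 8, epochs = 4, pretrain_epochs_admet = 3,
                      pretrain_epochs_disease = 5, seed = 6)
  ad <- gen_admet_tables(cfg, g$truth)
  m1 <- train_hint(g$trials, g$ontology, mcfg, admet_tables = ad)
  m2 <- train_hint(g$trials, g$ontology, mcfg, admet_tables = ad)
  expect_identical(m1$history$finetune, m2$history$finetune)
  expect_lt(m1$history$finetune[length(m1$history$finetune)],
            m1$history$finetune[1])
  p1 <- predict(m1, g$trials)
  expect_identical(p1, predict(m2, g$trials))
  expect_true(all(p1$prob_success > 0 & p1$prob_success < 1))
  expect_error(train_hint(g$trials[0, ], g$ontology, mcfg), "empty")
  one_class <- g$trials; one_class$label <- 1L
  expect_warning(
    train_hint(one_class[1:20, ], g$ontology,
               hint_config(d = 4, epochs = 1, pretrain_epochs_admet = 0,
                           pretrain_epochs_disease = 0, seed = 1)),
    "one class")
})

test_that("ADMET pretraining separates a noise-free property table", {
  cfg <- synth_config(n_trials = 30, seed = 43)
  g <- gen_trials(cfg)
  ad <- gen_admet_tables(cfg, g$truth, flip_noise = 0)
  # noise-free and separable: train the heads to convergence, no decay
  mcfg <- hint_config(d = 16, epochs = 0, pretrain_epochs_admet = 150,
                      weight_decay = 0, pretrain_epochs_disease = 0, seed = 2)
  m <- train_hint(g$trials, g$ontology, mcfg, admet_tables = ad)
  acc <- vapply(c("A", "D", "M", "E", "T"), function(pp) {
    tb <- ad[[pp]]
    probs <- vapply(tb$smiles, function(s)
      admet_head(m, embed_drugs(m, s), pp)$prob, numeric(1))
    mean(as.integer(probs >= 0.5) == tb$label)
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("disease-risk pretraining recovers the planted risk ranking", {
  cfg <- synth_config(n_trials = 30, seed = 44)
  g <- gen_trials(cfg)
  leaves <- ontology_leaves(g$ontology)
  rates <- data.frame(code = leaves,
                      rate = 1 - g$truth$disease_risk[leaves])
  mcfg <- hint_config(d = 16, epochs = 0, pretrain_epochs_admet = 0,
                      pretrain_epochs_disease = 400, seed = 2)
  m <- train_hint(g$trials, g$ontology, mcfg, disease_rates = rates)
  probs <- vapply(leaves, function(cd)
    disease_risk_head(m, embed_diseases(m, cd))$prob, numeric(1))
  rho <- cor(probs, rates$rate, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("attention reports cover every edge with weights in (0, 1)", {
  g <- gen_trials(synth_config(n_trials = 5, seed = 45))
  m <- hint_init(g$ontology, hint_config(d = 8, seed = 3))
  rep1 <- attention_report(m, g$trials[1, ])
  expect_equal(nrow(rep1$edges), sum(hint_adjacency() == 1))
  expect_true(all(rep1$edges$weight > 0 & rep1$edges$weight < 1))
  expect_gt(rep1$prob_success, 0); expect_lt(rep1$prob_success, 1)
})
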