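# Minimal neural-network primitives: parameter initialization, highway
# layers, 1-D convolutions and an Adam optimizer, all with analytic
# backward passes.  Everything operates on plain numeric vectors/matrices;
# gradients are accumulated into an environment keyed by parameter name.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

glorot_conv <- function(d_out, d_in, ks) {
  lim <- sqrt(6 / (d_in * ks + d_out))
  array(stats::runif(d_out * d_in * ks, -lim, lim), dim = c(d_out, d_in, ks))
}

# parameters of one highway layer: transform gate T = sigmoid(WT x + bT),
# transform H = relu(WH x + bH), output T*H + (1-T)*x.  Gate biases start
# at -1 so early training favours the identity carry path.
init_highway <- function(d) {
  list(WT = glorot(d, d), bT = rep(-1, d), WH = glorot(d, d), bH = rep(0, d))
}

highway_fwd <- function(x, p) {
  zT <- drop(p$WT %*% x) + p$bT
  tt <- sigmoid(zT)
  zH <- drop(p$WH %*% x) + p$bH
  h <- relu(zH)
  list(y = tt * h + (1 - tt) * x, x = x, tt = tt, h = h)
}

# returns dx; writes parameter grads (prefix_WT etc.) into gr
highway_bwd <- function(dy, cache, p, gr, prefix) {
  tt <- cache$tt; h <- cache$h; x <- cache$x
  dtt <- dy * (h - x)
  dh <- dy * tt
  dzT <- dtt * tt * (1 - tt)
  dzH <- dh * (h > 0)
  grad_add(gr, paste0(prefix, "_WT"), tcrossprod(dzT, x))
  grad_add(gr, paste0(prefix, "_bT"), dzT)
  grad_add(gr, paste0(prefix, "_WH"), tcrossprod(dzH, x))
  grad_add(gr, paste0(prefix, "_bH"), dzH)
  dy * (1 - tt) + drop(crossprod(p$WT, dzT)) + drop(crossprod(p$WH, dzH))
}

#' Gated highway layer
#'
#' Computes \code{T(x) * H(x) + (1 - T(x)) * x} with a sigmoid transform
#' gate T and a ReLU transform H, the gated-residual unit used throughout
#' the interaction network to ease gradient flow.
#'
#' @param x Numeric vector.
#' @param params List with matrices \code{WT}, \code{WH} (d x d) and biases
#'   \code{bT}, \code{bH} (length d), e.g. from the trained model.
#' @return Numeric vector of the same length.
#' @export
highway_layer <- function(x, params) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  highway_fwd(x, params)$y
}

# same-padded 1-D convolution stack over a (channels x positions) input
conv1d_fwd <- function(X, W, b) {
  ks <- dim(W)[3]; L <- ncol(X); d_out <- dim(W)[1]
  pl <- (ks - 1) %/% 2; pr <- ks - 1 - pl
  Xp <- cbind(matrix(0, nrow(X), pl), X, matrix(0, nrow(X), pr))
  Z <- matrix(b, d_out, L)
  for (u in seq_len(ks))
    Z <- Z + W[, , u] %*% Xp[, u:(u + L - 1), drop = FALSE]
  list(Y = pmax(Z, 0), Z = Z, Xp = Xp, pl = pl, L = L)
}

conv1d_bwd <- function(dY, cache, W, gr, prefix) {
  ks <- dim(W)[3]; L <- cache$L; pl <- cache$pl
  dZ <- dY * (cache$Z > 0)
  dW <- array(0, dim = dim(W))
  for (u in seq_len(ks))
    dW[, , u] <- dZ %*% t(cache$Xp[, u:(u + L - 1), drop = FALSE])
  grad_add(gr, paste0(prefix, "_W"), dW)
  grad_add(gr, paste0(prefix, "_b"), rowSums(dZ))
  dXp <- matrix(0, nrow(cache$Xp), ncol(cache$Xp))
  for (u in seq_len(ks))
    dXp[, u:(u + L - 1)] <- dXp[, u:(u + L - 1)] + crossprod(W[, , u], dZ)
  dXp[, (pl + 1):(pl + L), drop = FALSE]
}

# gradient store -------------------------------------------------------

grad_new <- function() new.env(parent = emptyenv())

grad_add <- function(gr, name, val) {
  cur <- gr[[name]]
  gr[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

grad_collect <- function(gr, params, scale = 1) {
  out <- lapply(names(params), function(nm) {
    g <- gr[[nm]]
    if (is.null(g)) NULL else g * scale
  })
  stats::setNames(out, names(params))
}

# Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0)
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
  }
  list(params = params, state = state)
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
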