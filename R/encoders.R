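# Input encoders: molecule fingerprints (via Open Babel path fingerprints),
# a hashed bag-of-token sentence embedding for eligibility criteria, and a
# GRAM-style ontology-attentive disease embedding.

.fp_cache <- new.env(parent = emptyenv())

#' Fixed-length molecule fingerprints from SMILES
#'
#' Parses each SMILES with the chemistry toolkit and returns 1024-bit hashed
#' path fingerprints (Open Babel FP2), the fixed substructure features that
#' feed the learned molecule perceptron.  Results are cached per SMILES
#' string.  An unparseable SMILES raises an error naming the offending
#' string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Numeric matrix, one row per input (rownames = SMILES), 1024 cols.
#' @export
molecule_fingerprints <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  uniq <- unique(smiles)
  have <- vapply(uniq, function(s) !is.null(.fp_cache[[s]]), logical(1))
  todo <- uniq[!have]
  if (length(todo) > 0) {
    names(todo) <- paste0("m", seq_along(todo))
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(todo)),
      error = function(e) {
        # batch failed: identify the offending molecule(s) one by one
        for (s in todo) {
          ok <- tryCatch({
            suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "m1")))
            TRUE
          }, error = function(e2) FALSE)
          if (!ok) stop("unparseable SMILES: '", s, "'", call. = FALSE)
        }
        stop("SMILES parsing failed: ", conditionMessage(e), call. = FALSE)
      })
    fpset <- ChemmineR::fingerprintOB(sdf, "FP2")
    m <- as.matrix(fpset@fpma)
    for (k in seq_along(todo)) .fp_cache[[todo[[k]]]] <- as.numeric(m[k, ])
  }
  out <- do.call(rbind, lapply(smiles, function(s) .fp_cache[[s]]))
  rownames(out) <- smiles
  out
}

#' Hashed bag-of-token sentence embedding
#'
#' Deterministic, dependency-free text features: tokens are lower-cased
#' alphanumeric runs, each hashed twice (polynomial rolling hash) to pick a
#' coordinate in 1..d and a sign; the sentence vector is the signed token
#' count divided by the token count.  No learned parameters.
#'
#' @param text Character vector of sentences.
#' @param d Embedding dimension.
#' @return Matrix, one row per sentence, d columns.
#' @export
sentence_embedding <- function(text, d) {
  stopifnot(d >= 1)
  out <- matrix(0, length(text), d)
  for (i in seq_along(text)) {
    toks <- strsplit(tolower(gsub("[^a-z0-9 ]", " ", tolower(text[i]))),
                     "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) next
    v <- numeric(d)
    for (tk in toks) {
      h <- 0
      for (b in utf8ToInt(tk)) h <- (h * 31 + b) %% 1048573
      idx <- (h %% d) + 1
      sgn <- if ((h %/% d) %% 2 == 0) 1 else -1
      v[idx] <- v[idx] + sgn
    }
    out[i, ] <- v / length(toks)
  }
  out
}

# molecules differ widely in their number of active fingerprint bits;
# row-normalizing equalizes their scale at the encoder input
fp_normalize <- function(fp) {
  nrm <- sqrt(rowSums(fp * fp))
  fp / pmax(nrm, 1)
}

# fold a fingerprint matrix to a smaller bit width (standard fingerprint
# folding: OR of the halves, here additive so counts are kept)
fp_fold <- function(fp, bits) {
  if (ncol(fp) <= bits) return(fp)
  idx <- (seq_len(ncol(fp)) - 1) %% bits + 1
  out <- matrix(0, nrow(fp), bits, dimnames = list(rownames(fp), NULL))
  for (j in seq_len(ncol(fp)))
    out[, idx[j]] <- out[, idx[j]] + fp[, j]
  out
}

# encoder-ready molecule features: fingerprints folded to the model width
# and row-normalized
fp_features <- function(smiles, bits) {
  fp_normalize(fp_fold(molecule_fingerprints(smiles), bits))
}

# GRAM-style ontology-attentive disease embedding ----------------------
#
# Each code c attends over its ancestor set A(c) (itself included): the
# attention weight of ancestor a is a softmax over A(c) of a two-layer
# scorer applied to the concatenated basis vectors of (c, a); the code
# embedding is the attention-weighted sum of ancestor basis vectors.

gram_fwd <- function(anc_idx, params) {
  emb <- params$gram_emb
  a <- length(anc_idx)
  embA <- emb[anc_idx, , drop = FALSE]              # a x d
  d <- ncol(embA)
  ec <- embA[1L, ]                                   # the code itself
  U <- rbind(matrix(ec, d, a), t(embA))              # 2d x a
  H <- pmax(params$gram_W %*% U + params$gram_b, 0)  # d x a
  s <- drop(crossprod(params$gram_v, H))
  s <- s - max(s)
  alpha <- exp(s) / sum(exp(s))
  G <- drop(crossprod(embA, alpha))                  # d
  list(G = G, alpha = alpha, H = H, U = U, embA = embA, anc_idx = anc_idx)
}

gram_bwd <- function(dG, cache, params, gr) {
  embA <- cache$embA; alpha <- cache$alpha
  a <- nrow(embA); d <- ncol(embA)
  dalpha <- drop(embA %*% dG)
  dembA <- tcrossprod(alpha, dG)                     # a x d
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  grad_add(gr, "gram_v", drop(cache$H %*% ds))
  dH <- tcrossprod(params$gram_v, ds)                # d x a
  dZ <- dH * (cache$H > 0)
  grad_add(gr, "gram_W", tcrossprod(dZ, cache$U))
  grad_add(gr, "gram_b", rowSums(dZ))
  dU <- crossprod(params$gram_W, dZ)                 # 2d x a
  dembA[1L, ] <- dembA[1L, ] + rowSums(dU[seq_len(d), , drop = FALSE])
  dembA <- dembA + t(dU[d + seq_len(d), , drop = FALSE])
  demb <- matrix(0, nrow(params$gram_emb), d)
  for (k in seq_len(a))
    demb[cache$anc_idx[k], ] <- demb[cache$anc_idx[k], ] + dembA[k, ]
  grad_add(gr, "gram_emb", demb)
  invisible(NULL)
}
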