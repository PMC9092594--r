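# Forward and backward passes of the sequence network.
#
# Internal representation: a batch is packed to its real (unmasked)
# positions only — an m x d matrix where m = sum(lengths), rows ordered
# sequence-major (all positions of sequence 1, then sequence 2, ...).
# Padded positions are never materialized, so they cannot influence any
# output: padding invariance holds by construction, and no compute is spent
# on pad rows. The public layer wrappers in model.R scatter results back to
# the padded n x L x d arrays of the user-facing feature type.

add_row_vec <- function(M, v) {
  M + rep(v, each = nrow(M))
}

mul_col_vec <- function(M, v) {
  # multiply column j of M by v[j]
  M * rep(v, each = nrow(M))
}

# Packing metadata for a tokenized batch: row r of the packed matrix is
# position pos_of[r] of sequence seq_of[r].
pack_meta <- function(lengths) {
  n <- length(lengths)
  list(n = n, lengths = lengths, m = sum(lengths),
       seq_of = rep(seq_len(n), lengths),
       pos_of = sequence(lengths),
       Lrow = rep(lengths, lengths),
       row_start = cumsum(c(0L, lengths[-n])))
}

# Rows for which a shift by `o` positions stays inside the same sequence.
shift_valid <- function(meta, o) {
  which(meta$pos_of + o >= 1L & meta$pos_of + o <= meta$Lrow)
}

# out[r] = X[r + o] where position pos_of[r] + o exists, zero otherwise.
# Consecutive positions of a sequence occupy consecutive packed rows, so the
# source row is simply r + o.
shift_packed <- function(X, idx, o) {
  Y <- matrix(0, nrow(X), ncol(X))
  Y[idx, ] <- X[idx + o, ]
  Y
}

dropout_mask <- function(nr, nc, p) {
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# ---- layer norm ----------------------------------------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(Y = add_row_vec(mul_col_vec(xhat, g), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- mul_col_vec(dY, g)
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# ---- multi-kernel convolution -------------------------------------------

conv_fwd <- function(X, meta, cfg, params, shift_idx) {
  ks <- cfg$kernel_sizes
  d <- cfg$d_model
  outs <- vector("list", length(ks))
  shifts <- vector("list", length(ks))
  for (kk in seq_along(ks)) {
    k <- ks[kk]
    h <- (k - 1L) %/% 2L
    W <- params[[paste0("conv", k, "_W")]]
    Yk <- 0
    sh <- vector("list", k)
    for (j in seq_len(k)) {
      o <- j - h - 1L
      Xs <- if (o == 0L) X else shift_packed(X, shift_idx[[as.character(o)]], o)
      sh[[j]] <- Xs
      Yk <- Yk + Xs %*% matrix(W[j, , ], d, d)
    }
    outs[[kk]] <- add_row_vec(Yk, params[[paste0("conv", k, "_b")]])
    shifts[[kk]] <- sh
  }
  C <- do.call(cbind, outs)
  P <- add_row_vec(C %*% params$proj_W, params$proj_b)
  list(P = P, C = C, shifts = shifts)
}

conv_bwd <- function(dP, cache, meta, cfg, params, shift_idx, grads) {
  ks <- cfg$kernel_sizes
  d <- cfg$d_model
  grads$proj_W <- crossprod(cache$C, dP)
  grads$proj_b <- colSums(dP)
  dC <- tcrossprod(dP, params$proj_W)
  dX <- 0
  for (kk in seq_along(ks)) {
    k <- ks[kk]
    h <- (k - 1L) %/% 2L
    W <- params[[paste0("conv", k, "_W")]]
    dYk <- dC[, ((kk - 1L) * d + 1L):(kk * d), drop = FALSE]
    dW <- array(0, dim = c(k, d, d))
    for (j in seq_len(k)) {
      o <- j - h - 1L
      Wj <- matrix(W[j, , ], d, d)
      dW[j, , ] <- crossprod(cache$shifts[[kk]][[j]], dYk)
      dYW <- tcrossprod(dYk, Wj)
      dX <- dX + if (o == 0L) dYW else {
        shift_packed(dYW, shift_idx[[as.character(-o)]], -o)
      }
    }
    grads[[paste0("conv", k, "_W")]] <- dW
    grads[[paste0("conv", k, "_b")]] <- colSums(dYk)
  }
  list(dX = dX, grads = grads)
}

# ---- multi-head self-attention ------------------------------------------

mha_fwd <- function(X, meta, nh, params, prefix, collect_attention = FALSE) {
  d <- ncol(X)
  dk <- d %/% nh
  Q <- add_row_vec(X %*% params[[paste0(prefix, "_Wq")]], params[[paste0(prefix, "_bq")]])
  K <- add_row_vec(X %*% params[[paste0(prefix, "_Wk")]], params[[paste0(prefix, "_bk")]])
  V <- add_row_vec(X %*% params[[paste0(prefix, "_Wv")]], params[[paste0(prefix, "_bv")]])
  Y0 <- matrix(0, meta$m, d)
  A_list <- vector("list", meta$n)
  scale <- 1 / sqrt(dk)
  for (i in seq_len(meta$n)) {
    Li <- meta$lengths[i]
    rows <- (meta$row_start[i] + 1L):(meta$row_start[i] + Li)
    Ai <- array(0, dim = c(Li, Li, nh))
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * scale
      A <- softmax_rows(S)
      Ai[, , hh] <- A
      Y0[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
    A_list[[i]] <- Ai
  }
  Y <- add_row_vec(Y0 %*% params[[paste0(prefix, "_Wo")]], params[[paste0(prefix, "_bo")]])
  list(Y = Y, Q = Q, K = K, V = V, Y0 = Y0, A_list = A_list)
}

mha_bwd <- function(dY, cache, X, meta, nh, params, prefix, grads) {
  d <- ncol(X)
  dk <- d %/% nh
  scale <- 1 / sqrt(dk)
  grads[[paste0(prefix, "_Wo")]] <- crossprod(cache$Y0, dY)
  grads[[paste0(prefix, "_bo")]] <- colSums(dY)
  dY0 <- tcrossprod(dY, params[[paste0(prefix, "_Wo")]])
  dQ <- matrix(0, meta$m, d)
  dK <- matrix(0, meta$m, d)
  dV <- matrix(0, meta$m, d)
  for (i in seq_len(meta$n)) {
    Li <- meta$lengths[i]
    rows <- (meta$row_start[i] + 1L):(meta$row_start[i] + Li)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      A <- matrix(cache$A_list[[i]][, , hh], Li, Li)
      dO <- dY0[rows, cols, drop = FALSE]
      dA <- tcrossprod(dO, cache$V[rows, cols, drop = FALSE])
      dV[rows, cols] <- crossprod(A, dO)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * scale
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) * scale
    }
  }
  grads[[paste0(prefix, "_Wq")]] <- crossprod(X, dQ)
  grads[[paste0(prefix, "_bq")]] <- colSums(dQ)
  grads[[paste0(prefix, "_Wk")]] <- crossprod(X, dK)
  grads[[paste0(prefix, "_bk")]] <- colSums(dK)
  grads[[paste0(prefix, "_Wv")]] <- crossprod(X, dV)
  grads[[paste0(prefix, "_bv")]] <- colSums(dV)
  dX <- tcrossprod(dQ, params[[paste0(prefix, "_Wq")]]) +
    tcrossprod(dK, params[[paste0(prefix, "_Wk")]]) +
    tcrossprod(dV, params[[paste0(prefix, "_Wv")]])
  list(dX = dX, grads = grads)
}

# ---- full forward pass ---------------------------------------------------

forward_pass <- function(params, cfg, batch, training = FALSE,
                         keep_cache = FALSE, collect_attention = FALSE) {
  lengths <- batch$lengths
  if (any(lengths < 1L)) {
    stop("forward: degenerate input, a sequence has no unmasked positions")
  }
  d <- cfg$d_model
  meta <- pack_meta(lengths)
  tv_all <- as.vector(t(batch$tokens))
  tv <- tv_all[as.vector(t(batch$mask))]
  if (any(tv < 1L) || any(tv > 20L)) {
    stop("forward: token outside vocabulary range 1..20 at an unmasked position")
  }
  drop_p <- if (training) cfg$dropout else 0

  # shift index sets for the convolution offsets
  shift_idx <- list()
  if (length(cfg$kernel_sizes) > 0L) {
    hmax <- (max(cfg$kernel_sizes) - 1L) %/% 2L
    for (o in setdiff(seq(-hmax, hmax), 0L)) {
      shift_idx[[as.character(o)]] <- shift_valid(meta, o)
    }
  }

  cache <- list(meta = meta, tv = tv, shift_idx = shift_idx)

  # embedding: token t -> row t+1 of the 21 x d table (row 1 = pad = zeros)
  X0 <- params$emb[tv + 1L, , drop = FALSE]
  cache$X0 <- X0

  if (length(cfg$kernel_sizes) > 0L) {
    cv <- conv_fwd(X0, meta, cfg, params, shift_idx)
    P <- cv$P
    cache$conv <- cv
  } else {
    P <- X0
  }

  pe <- positional_encoding(max(lengths), d)
  Z <- P + pe[meta$pos_of, , drop = FALSE]
  if (drop_p > 0) {
    M0 <- dropout_mask(meta$m, d, drop_p)
    Z <- Z * M0
    cache$M0 <- M0
  }

  attn_keep <- if (collect_attention) vector("list", cfg$n_blocks) else NULL
  blocks <- if (keep_cache) vector("list", cfg$n_blocks) else NULL
  for (b in seq_len(cfg$n_blocks)) {
    prefix <- paste0("blk", b)
    bc <- list(Zin = Z)
    at <- mha_fwd(Z, meta, cfg$n_heads, params, prefix)
    if (collect_attention) attn_keep[[b]] <- at$A_list
    attn_out <- at$Y
    if (drop_p > 0) {
      bc$Mattn <- dropout_mask(meta$m, d, drop_p)
      attn_out <- attn_out * bc$Mattn
    }
    ln1 <- layernorm_fwd(Z + attn_out,
                         params[[paste0(prefix, "_ln1_g")]],
                         params[[paste0(prefix, "_ln1_b")]])
    Z1 <- ln1$Y
    T1 <- add_row_vec(Z1 %*% params[[paste0(prefix, "_W1")]],
                      params[[paste0(prefix, "_b1")]])
    pos1 <- T1 > 0
    H <- T1 * pos1
    Fout <- add_row_vec(H %*% params[[paste0(prefix, "_W2")]],
                        params[[paste0(prefix, "_b2")]])
    if (drop_p > 0) {
      bc$Mffn <- dropout_mask(meta$m, d, drop_p)
      Fout <- Fout * bc$Mffn
    }
    ln2 <- layernorm_fwd(Z1 + Fout,
                         params[[paste0(prefix, "_ln2_g")]],
                         params[[paste0(prefix, "_ln2_b")]])
    if (keep_cache) {
      bc$attn <- at
      bc$ln1 <- ln1
      bc$Z1 <- Z1
      bc$pos1 <- pos1
      bc$H <- H
      bc$ln2 <- ln2
      blocks[[b]] <- bc
    }
    Z <- ln2$Y
  }
  cache$blocks <- blocks

  # pooling over the (real) positions of each sequence
  if (cfg$pooling == "mean") {
    pooled <- rowsum(Z, meta$seq_of) / lengths
    dimnames(pooled) <- NULL
  } else if (cfg$pooling == "max") {
    pooled <- matrix(0, meta$n, d)
    argm <- matrix(0L, meta$n, d)
    for (i in seq_len(meta$n)) {
      rows <- (meta$row_start[i] + 1L):(meta$row_start[i] + lengths[i])
      block <- Z[rows, , drop = FALSE]
      am <- max.col(t(block), ties.method = "first")
      argm[i, ] <- rows[am]
      pooled[i, ] <- block[cbind(am, seq_len(d))]
    }
    cache$argmax <- argm
  } else {
    pooled <- Z[meta$row_start + 1L, , drop = FALSE]
  }
  cache$pooled <- pooled

  T1h <- add_row_vec(pooled %*% params$head_W1, params$head_b1)
  posh <- T1h > 0
  A1 <- T1h * posh
  penult <- if (cfg$head_residual) A1 + pooled else A1
  logits <- add_row_vec(penult %*% params$head_W2, params$head_b2)
  probs <- softmax_rows(logits)
  cache$posh <- posh
  cache$penult <- penult

  list(probs = probs, penult = penult, logits = logits,
       cache = if (keep_cache) cache else NULL,
       attention = attn_keep)
}

# ---- full backward pass --------------------------------------------------

backward_pass <- function(params, cfg, cache, dlogits) {
  meta <- cache$meta
  d <- cfg$d_model
  lengths <- meta$lengths
  grads <- list()

  grads$head_W2 <- crossprod(cache$penult, dlogits)
  grads$head_b2 <- colSums(dlogits)
  dpenult <- tcrossprod(dlogits, params$head_W2)
  dT1h <- dpenult * cache$posh
  grads$head_W1 <- crossprod(cache$pooled, dT1h)
  grads$head_b1 <- colSums(dT1h)
  dpooled <- tcrossprod(dT1h, params$head_W1)
  if (cfg$head_residual) dpooled <- dpooled + dpenult

  if (cfg$pooling == "mean") {
    dZ <- (dpooled / lengths)[meta$seq_of, , drop = FALSE]
  } else if (cfg$pooling == "max") {
    dZ <- matrix(0, meta$m, d)
    for (i in seq_len(meta$n)) {
      dZ[cbind(cache$argmax[i, ], seq_len(d))] <-
        dZ[cbind(cache$argmax[i, ], seq_len(d))] + dpooled[i, ]
    }
  } else {
    dZ <- matrix(0, meta$m, d)
    dZ[meta$row_start + 1L, ] <- dpooled
  }

  for (b in rev(seq_len(cfg$n_blocks))) {
    prefix <- paste0("blk", b)
    bc <- cache$blocks[[b]]
    l2 <- layernorm_bwd(dZ, bc$ln2, params[[paste0(prefix, "_ln2_g")]])
    grads[[paste0(prefix, "_ln2_g")]] <- l2$dg
    grads[[paste0(prefix, "_ln2_b")]] <- l2$db
    dsum2 <- l2$dX
    dF <- if (!is.null(bc$Mffn)) dsum2 * bc$Mffn else dsum2
    grads[[paste0(prefix, "_W2")]] <- crossprod(bc$H, dF)
    grads[[paste0(prefix, "_b2")]] <- colSums(dF)
    dH <- tcrossprod(dF, params[[paste0(prefix, "_W2")]])
    dT1 <- dH * bc$pos1
    grads[[paste0(prefix, "_W1")]] <- crossprod(bc$Z1, dT1)
    grads[[paste0(prefix, "_b1")]] <- colSums(dT1)
    dZ1 <- dsum2 + tcrossprod(dT1, params[[paste0(prefix, "_W1")]])
    l1 <- layernorm_bwd(dZ1, bc$ln1, params[[paste0(prefix, "_ln1_g")]])
    grads[[paste0(prefix, "_ln1_g")]] <- l1$dg
    grads[[paste0(prefix, "_ln1_b")]] <- l1$db
    dsum1 <- l1$dX
    dattn <- if (!is.null(bc$Mattn)) dsum1 * bc$Mattn else dsum1
    mb <- mha_bwd(dattn, bc$attn, bc$Zin, meta, cfg$n_heads, params, prefix, grads)
    grads <- mb$grads
    dZ <- dsum1 + mb$dX
  }

  if (!is.null(cache$M0)) dZ <- dZ * cache$M0
  # positional encoding is a constant: gradient passes straight through
  if (length(cfg$kernel_sizes) > 0L) {
    cb <- conv_bwd(dZ, cache$conv, meta, cfg, params, cache$shift_idx, grads)
    grads <- cb$grads
    dX0 <- cb$dX
  } else {
    dX0 <- dZ
  }

  g <- rowsum(dX0, cache$tv)
  dE <- matrix(0, 21L, d)
  dE[as.integer(rownames(g)) + 1L, ] <- g
  grads$emb <- dE

  grads
}
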