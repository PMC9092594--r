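# Architecture contracts: embedding, convolution, attention, forward pass.

test_that("embedding maps equal tokens to equal rows and pads to zero", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 1)
  b <- encode_batch(list(peptide_record("a", "CAC", 1),
                         peptide_record("b", "WCW", 0)), max_len = 4)
  emb <- embed_tokens(m, b)
  expect_equal(dim(emb$values), c(2L, 4L, cfg$d_model))
  # token C appears at (1,1), (1,3), (2,2): identical embedding rows
  expect_equal(emb$values[1, 1, ], emb$values[1, 3, ])
  expect_equal(emb$values[1, 1, ], emb$values[2, 2, ])
  # padded cells carry the zero vector
  expect_equal(emb$values[1, 4, ], rep(0, cfg$d_model))
  # a fully padded row embeds to all zeros
  allpad <- list(tokens = matrix(0L, 1, 4),
                 mask = matrix(FALSE, 1, 4), lengths = 0L)
  expect_equal(embed_tokens(m, allpad)$values[1, , ],
               matrix(0, 4, cfg$d_model))
})

test_that("shape is preserved through every stage at n=8, L=50, d=64", {
  cfg <- model_config()  # d_model 64, kernels {1,3,5}, 4 heads, 2 blocks
  m <- init_model(cfg, seed = 2)
  b <- encode_batch(tiny_records(4, 4, seed = 8, len_range = c(10, 50),
                                 motif = "KWKWK"), max_len = 50)
  emb <- embed_tokens(m, b)
  expect_equal(dim(emb$values), c(8L, 50L, 64L))
  cv <- multi_kernel_conv(m, emb)
  expect_equal(dim(cv$values), c(8L, 50L, 64L))
  pe <- positional_encoding(50, 64)
  cv$values <- cv$values + rep(pe, each = 8)  # broadcast over sequences
  e1 <- encoder_block(m, cv, block = 1)
  expect_equal(dim(e1$values), c(8L, 50L, 64L))
  e2 <- encoder_block(m, e1, block = 2)
  expect_equal(dim(e2$values), c(8L, 50L, 64L))
  expect_true(all(is.finite(e2$values)))
})

test_that("a width-1 kernel with identity weights is the identity map", {
  cfg <- tiny_config(kernel_sizes = 1L)
  m <- init_model(cfg, seed = 3)
  d <- cfg$d_model
  m$params$conv1_W[1, , ] <- diag(d)
  m$params$conv1_b <- numeric(d)
  m$params$proj_W <- diag(d)
  m$params$proj_b <- numeric(d)
  b <- encode_batch(tiny_records(3, 3, seed = 4), max_len = 20)
  emb <- embed_tokens(m, b)
  out <- multi_kernel_conv(m, emb)
  expect_equal(out$values, emb$values, tolerance = 1e-12)
})

test_that("kernel set {3,5} concatenates two maps before the fused projection", {
  cfg <- tiny_config(kernel_sizes = c(3L, 5L))
  m <- init_model(cfg, seed = 5)
  expect_equal(dim(m$params$proj_W), c(2L * cfg$d_model, cfg$d_model))
  expect_error(model_config(kernel_sizes = c(2L, 3L)), "odd")
})

test_that("same-length convolution matches a direct sliding-window oracle", {
  # constant-in-position input: all interior outputs must be equal, and every
  # position must equal the direct convolution sum with zero boundary padding
  cfg <- tiny_config(kernel_sizes = 3L, d_model = 2L, n_heads = 1L)
  m <- init_model(cfg, seed = 6)
  b <- encode_batch(list(peptide_record("a", "AAAAAA", 1)), max_len = 6)
  emb <- embed_tokens(m, b)
  out <- multi_kernel_conv(m, emb)
  x <- emb$values[1, , ]   # 6 x 2, identical rows
  W <- m$params$conv3_W
  bias <- m$params$conv3_b
  conv_oracle <- matrix(0, 6, 2)
  for (l in 1:6) {
    acc <- bias
    for (j in 1:3) {
      src <- l + j - 2  # offsets -1, 0, +1
      if (src >= 1 && src <= 6) acc <- acc + as.vector(x[src, ] %*% W[j, , ])
    }
    conv_oracle[l, ] <- acc
  }
  proj_oracle <- sweep(conv_oracle %*% m$params$proj_W, 2,
                       m$params$proj_b, "+")
  expect_equal(out$values[1, , ], proj_oracle, tolerance = 1e-12)
  # interior rows (full receptive field) are identical for constant input
  expect_equal(proj_oracle[2, ], proj_oracle[5, ], tolerance = 1e-12)
})

test_that("attention rows over unmasked keys sum to one; length-1 weight is 1", {
  cfg <- tiny_config(n_blocks = 1L)
  m <- init_model(cfg, seed = 7)
  b <- encode_batch(list(peptide_record("a", "ACDEFGHIK", 1),
                         peptide_record("b", "W", 0),
                         peptide_record("c", "KLAK", 1)), max_len = 12)
  emb <- embed_tokens(m, b)
  out <- encoder_block(m, emb, block = 1, return_attention = TRUE)
  for (i in 1:3) {
    A <- out$attention[[i]]
    expect_equal(dim(A)[1], b$lengths[i])
    for (h in seq_len(cfg$n_heads)) {
      expect_equal(rowSums(matrix(A[, , h], dim(A)[1])),
                   rep(1, dim(A)[1]), tolerance = 1e-6)
    }
  }
  expect_equal(as.vector(out$attention[[2]]), rep(1, cfg$n_heads))
})

test_that("scaled dot-product attention matches hand arithmetic on a 2-position toy", {
  cfg <- model_config(d_model = 2L, kernel_sizes = integer(0), n_heads = 1L,
                      n_blocks = 1L, ffn_dim = 4L, dropout = 0, max_len = 2L)
  m <- init_model(cfg, seed = 8)
  X <- matrix(c(1, -1, 0.5, 2), 2, 2, byrow = TRUE)
  Wq <- matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2)
  Wk <- matrix(c(-0.5, 0.2, 0.3, 0.1), 2, 2)
  Wv <- matrix(c(0.2, 0.6, -0.1, 0.3), 2, 2)
  m$params$blk1_Wq <- Wq; m$params$blk1_bq <- c(0, 0)
  m$params$blk1_Wk <- Wk; m$params$blk1_bk <- c(0, 0)
  m$params$blk1_Wv <- Wv; m$params$blk1_bv <- c(0, 0)
  meta <- acpmka:::pack_meta(2L)
  got <- acpmka:::mha_fwd(X, meta, 1L, m$params, "blk1")
  # scalar oracle
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  oracle <- matrix(0, 2, 2)
  for (q in 1:2) {
    s <- c(sum(Q[q, ] * K[1, ]), sum(Q[q, ] * K[2, ])) / sqrt(2)
    w <- exp(s) / sum(exp(s))
    oracle[q, ] <- w[1] * V[1, ] + w[2] * V[2, ]
  }
  expect_equal(got$Y0, oracle, tolerance = 1e-12)
})

test_that("full forward on a frozen-weight toy matches a scalar reimplementation", {
  cfg <- model_config(d_model = 2L, kernel_sizes = 1L, n_heads = 1L,
                      n_blocks = 1L, ffn_dim = 4L, dropout = 0, max_len = 3L,
                      head_residual = FALSE)
  m <- init_model(cfg, seed = 9)
  p <- m$params
  recs <- list(peptide_record("a", "ACD", 1), peptide_record("b", "KW", 0))
  b <- encode_batch(recs, max_len = 3)
  got <- predict(m, b)

  # independent scalar path, explicit loops throughout
  pe_row <- function(pos) c(sin(pos), cos(pos))  # d=2: i=0 pair only
  ln <- function(v, g, beta) {
    mu <- mean(v); s <- sqrt(mean((v - mu)^2) + 1e-5)
    g * (v - mu) / s + beta
  }
  for (si in 1:2) {
    seqc <- strsplit(recs[[si]]$sequence, "")[[1]]
    L <- length(seqc)
    X <- matrix(0, L, 2)
    for (l in 1:L) {
      tok <- match(seqc[l], aa_alphabet())
      X[l, ] <- p$emb[tok + 1, ]                       # embedding
      X[l, ] <- as.vector(X[l, ] %*% p$conv1_W[1, , ]) + p$conv1_b
      X[l, ] <- as.vector(X[l, ] %*% p$proj_W) + p$proj_b
      X[l, ] <- X[l, ] + pe_row(l - 1)                 # positional code
    }
    Q <- K <- V <- matrix(0, L, 2)
    for (l in 1:L) {
      Q[l, ] <- as.vector(X[l, ] %*% p$blk1_Wq) + p$blk1_bq
      K[l, ] <- as.vector(X[l, ] %*% p$blk1_Wk) + p$blk1_bk
      V[l, ] <- as.vector(X[l, ] %*% p$blk1_Wv) + p$blk1_bv
    }
    Z1 <- matrix(0, L, 2)
    for (q in 1:L) {
      s <- numeric(L)
      for (k in 1:L) s[k] <- sum(Q[q, ] * K[k, ]) / sqrt(2)
      w <- exp(s - max(s)) / sum(exp(s - max(s)))
      att <- numeric(2)
      for (k in 1:L) att <- att + w[k] * V[k, ]
      att <- as.vector(att %*% p$blk1_Wo) + p$blk1_bo
      Z1[q, ] <- ln(X[q, ] + att, p$blk1_ln1_g, p$blk1_ln1_b)
    }
    Z2 <- matrix(0, L, 2)
    for (l in 1:L) {
      h <- pmax(as.vector(Z1[l, ] %*% p$blk1_W1) + p$blk1_b1, 0)
      f <- as.vector(h %*% p$blk1_W2) + p$blk1_b2
      Z2[l, ] <- ln(Z1[l, ] + f, p$blk1_ln2_g, p$blk1_ln2_b)
    }
    pooled <- colMeans(Z2)
    pen <- pmax(as.vector(pooled %*% p$head_W1) + p$head_b1, 0)
    z <- as.vector(pen %*% p$head_W2) + p$head_b2
    prob <- exp(z - max(z)) / sum(exp(z - max(z)))
    expect_equal(got$probabilities[si, ], prob, tolerance = 1e-6)
    expect_equal(got$penultimate[si, ], pen, tolerance = 1e-6)
  }
})

test_that("probability rows sum to one and batch order permutes outputs", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 10)
  recs <- tiny_records(4, 4, seed = 11)
  b <- encode_batch(recs, max_len = 20)
  pr <- predict(m, b)
  expect_equal(rowSums(pr$probabilities), rep(1, 8), tolerance = 1e-6)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  pr2 <- predict(m, encode_batch(recs[perm], max_len = 20))
  expect_equal(pr2$probabilities, pr$probabilities[perm, ], tolerance = 1e-12)
})

test_that("appending extra pad columns never changes predictions", {
  cfg <- model_config(dropout = 0)
  m <- init_model(cfg, seed = 12)
  recs <- tiny_records(3, 3, seed = 13, len_range = c(10, 30))
  p50 <- predict(m, encode_batch(recs, max_len = 50))
  p64 <- predict(m, encode_batch(recs, max_len = 64))
  expect_equal(p50$probabilities, p64$probabilities, tolerance = 1e-5)
})

test_that("with no encoder blocks the head sees exactly the pooled conv features", {
  cfg <- tiny_config(n_blocks = 0L, head_residual = FALSE)
  m <- init_model(cfg, seed = 14)
  recs <- tiny_records(3, 2, seed = 15)
  b <- encode_batch(recs, max_len = 20)
  pr <- predict(m, b)
  # ablation-path oracle: pool the public conv output + positional code
  emb <- embed_tokens(m, b)
  cv <- multi_kernel_conv(m, emb)
  pe <- positional_encoding(20, cfg$d_model)
  pooled <- t(vapply(seq_along(recs), function(i) {
    L <- b$lengths[i]
    colMeans(cv$values[i, 1:L, , drop = TRUE] + pe[1:L, ])
  }, numeric(cfg$d_model)))
  pen <- pmax(sweep(pooled %*% m$params$head_W1, 2, m$params$head_b1, "+"), 0)
  z <- sweep(pen %*% m$params$head_W2, 2, m$params$head_b2, "+")
  expect_equal(pr$probabilities, exp(z) / rowSums(exp(z)), tolerance = 1e-8)
})

test_that("analytic gradients match finite differences on every parameter group", {
  cfg <- model_config(d_model = 4L, kernel_sizes = c(1L, 3L), n_heads = 2L,
                      n_blocks = 1L, ffn_dim = 8L, dropout = 0, max_len = 8L)
  m <- init_model(cfg, seed = 16)
  recs <- list(peptide_record("a", "ACDKW", 1), peptide_record("b", "GYACDKWP", 0),
               peptide_record("c", "KLAKLA", 1), peptide_record("d", "WWYEE", 0))
  b <- encode_batch(recs, max_len = 8)
  fpar <- focal_params()
  labels <- b$labels
  fp <- acpmka:::forward_pass(m$params, cfg, b, keep_cache = TRUE)
  dl <- acpmka:::focal_loss_grad_logits(fp$probs, labels, fpar)
  grads <- acpmka:::backward_pass(m$params, cfg, fp$cache, dl)
  lossfn <- function(params) {
    f <- acpmka:::forward_pass(params, cfg, b)
    focal_loss(f$probs[cbind(1:4, labels + 1L)], fpar, labels = labels)
  }
  h <- 1e-5
  set.seed(17)
  for (nm in names(m$params)) {
    p0 <- m$params[[nm]]
    for (ii in sample(length(p0), min(4, length(p0)))) {
      pp <- m$params
      pp[[nm]][ii] <- p0[ii] + h
      lp <- lossfn(pp)
      pp[[nm]][ii] <- p0[ii] - h
      lm <- lossfn(pp)
      num <- (lp - lm) / (2 * h)
      ana <- grads[[nm]][ii]
      if (abs(num) < 1e-10 && abs(ana) < 1e-10) next
      expect_equal(ana, num, tolerance = 1e-4,
                   label = paste("gradient of", nm, "entry", ii))
    }
  }
})

test_that("degenerate and invalid inputs raise informative errors", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 18)
  allpad <- structure(list(tokens = matrix(0L, 1, 4),
                           mask = matrix(FALSE, 1, 4),
                           lengths = 0L, labels = 0L, ids = "x", max_len = 4L),
                      class = "tokenized_batch")
  expect_error(predict(m, allpad), "degenerate")
  expect_error(model_config(d_model = 9), "even")
  expect_error(model_config(d_model = 10, n_heads = 4), "divisible")
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("checkpoints round-trip through save_model/load_model", {
  m <- init_model(tiny_config(), seed = 19)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
})
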