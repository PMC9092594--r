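# Model construction and the public layer-level operations.

init_param_list <- function(cfg) {
  d <- cfg$d_model
  params <- list()
  # residue embedding: 21 rows (pad + 20 residues); pad row pinned at zero
  emb <- matrix(stats::rnorm(21L * d, sd = 1 / sqrt(d)), 21L, d)
  emb[1L, ] <- 0
  params$emb <- emb
  ks <- cfg$kernel_sizes
  if (length(ks) > 0L) {
    for (k in ks) {
      W <- array(0, dim = c(k, d, d))
      for (j in seq_len(k)) W[j, , ] <- glorot_uniform(k * d, d, d, d)
      params[[paste0("conv", k, "_W")]] <- W
      params[[paste0("conv", k, "_b")]] <- numeric(d)
    }
    params$proj_W <- glorot_uniform(length(ks) * d, d)
    params$proj_b <- numeric(d)
  }
  for (b in seq_len(cfg$n_blocks)) {
    prefix <- paste0("blk", b)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      params[[paste0(prefix, "_", w)]] <- glorot_uniform(d, d)
    }
    for (w in c("bq", "bk", "bv", "bo")) {
      params[[paste0(prefix, "_", w)]] <- numeric(d)
    }
    params[[paste0(prefix, "_ln1_g")]] <- rep(1, d)
    params[[paste0(prefix, "_ln1_b")]] <- numeric(d)
    params[[paste0(prefix, "_W1")]] <- glorot_uniform(d, cfg$ffn_dim)
    params[[paste0(prefix, "_b1")]] <- numeric(cfg$ffn_dim)
    params[[paste0(prefix, "_W2")]] <- glorot_uniform(cfg$ffn_dim, d)
    params[[paste0(prefix, "_b2")]] <- numeric(d)
    params[[paste0(prefix, "_ln2_g")]] <- rep(1, d)
    params[[paste0(prefix, "_ln2_b")]] <- numeric(d)
  }
  params$head_W1 <- glorot_uniform(d, cfg$d_penult)
  params$head_b1 <- numeric(cfg$d_penult)
  params$head_W2 <- glorot_uniform(cfg$d_penult, cfg$n_classes)
  params$head_b2 <- numeric(cfg$n_classes)
  params
}

#' Initialize a sequence classification model
#'
#' Builds the full network — residue embedding, multi-kernel convolution,
#' positional encoding, stacked self-attention encoder blocks and the
#' classification head — with Glorot-uniform weight initialization.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An `acp_model`: list with `config` and a flat named `params` list.
#' @export
#' @examples
#' m <- init_model(model_config(d_model = 8, n_heads = 2), seed = 1)
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  params <- with_seed_local(seed, init_param_list(config))
  structure(list(config = config, params = params, init_seed = as.integer(seed)),
            class = "acp_model")
}

#' @export
print.acp_model <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf(paste0(
    "<acp_model> d_model=%d kernels={%s} heads=%d blocks=%d ffn=%d ",
    "max_len=%d (%d parameters)\n"),
    cfg$d_model, paste(cfg$kernel_sizes, collapse = ","), cfg$n_heads,
    cfg$n_blocks, cfg$ffn_dim, cfg$max_len, npar))
  invisible(x)
}

# Scatter a packed m x d matrix (real positions only, sequence-major) into
# the public padded n x L x d array; pad cells are zero.
packed_to_array <- function(X, meta, L) {
  A <- array(0, dim = c(meta$n, L, ncol(X)))
  idx <- cbind(rep(meta$seq_of, ncol(X)),
               rep(meta$pos_of, ncol(X)),
               rep(seq_len(ncol(X)), each = meta$m))
  A[idx] <- as.vector(X)
  A
}

# Gather the real positions of a padded n x L x d array into packed form.
array_to_packed <- function(A, meta) {
  idx <- cbind(rep(meta$seq_of, dim(A)[3L]),
               rep(meta$pos_of, dim(A)[3L]),
               rep(seq_len(dim(A)[3L]), each = meta$m))
  matrix(A[idx], meta$m, dim(A)[3L])
}

features_meta <- function(features) {
  lengths <- features$lengths %||% rowSums(features$mask)
  if (any(lengths < 1L)) {
    stop("degenerate input: a sequence has no unmasked positions")
  }
  pack_meta(lengths)
}

#' Embed a tokenized batch into dense residue features
#'
#' Each residue token maps to a learned `d_model`-vector; the same residue
#' maps to the same vector at every position, and the padding token maps to
#' the zero vector.
#'
#' @param model An [init_model()] result.
#' @param batch A [encode_batch()] result.
#' @return A `sequence_features` list: `values` (n x L x d_model array) and
#'   `mask` (n x L logical).
#' @export
embed_tokens <- function(model, batch) {
  tv <- as.vector(t(batch$tokens))
  if (any(tv < 0L) || any(tv > 20L)) {
    stop("embed_tokens: token outside vocabulary range 0..20")
  }
  # pad token 0 maps to the zero row of the embedding table
  X <- model$params$emb[tv + 1L, , drop = FALSE]
  n <- nrow(batch$tokens)
  L <- ncol(batch$tokens)
  A <- aperm(array(X, dim = c(L, n, ncol(X))), c(2L, 1L, 3L))
  structure(list(values = A, mask = batch$mask, lengths = batch$lengths),
            class = "sequence_features")
}

#' Apply the multi-kernel convolution block
#'
#' For each configured odd kernel width k, a same-length convolution along
#' the sequence axis maps the L x d_model features to L x d_model; the
#' per-kernel maps are concatenated on the feature axis and linearly
#' projected back to d_model. With an empty kernel set the input is returned
#' unchanged (the embedding-only ablation variant).
#'
#' @param model An [init_model()] result.
#' @param features A `sequence_features` list (see [embed_tokens()]).
#' @return A `sequence_features` list of the same shape.
#' @export
multi_kernel_conv <- function(model, features) {
  cfg <- model$config
  if (length(cfg$kernel_sizes) == 0L) return(features)
  meta <- features_meta(features)
  X <- array_to_packed(features$values, meta)
  hmax <- (max(cfg$kernel_sizes) - 1L) %/% 2L
  shift_idx <- list()
  for (o in setdiff(seq(-hmax, hmax), 0L)) {
    shift_idx[[as.character(o)]] <- shift_valid(meta, o)
  }
  P <- conv_fwd(X, meta, cfg, model$params, shift_idx)$P
  structure(list(values = packed_to_array(P, meta, dim(features$values)[2L]),
                 mask = features$mask, lengths = meta$lengths),
            class = "sequence_features")
}

#' Apply one self-attention encoder block
#'
#' Multi-head scaled dot-product self-attention (padded key positions
#' excluded), residual connection and normalization, position-wise
#' feed-forward network, second residual connection and normalization.
#' Output shape equals input shape.
#'
#' @param model An [init_model()] result.
#' @param features A `sequence_features` list.
#' @param block Which encoder block's weights to use (default 1).
#' @param return_attention If TRUE, also return the per-sequence attention
#'   weight arrays (length-n list of L_i x L_i x n_heads arrays).
#' @return A `sequence_features` list; with `return_attention`, an
#'   `attention` element is attached.
#' @export
encoder_block <- function(model, features, block = 1L, return_attention = FALSE) {
  cfg <- model$config
  stopifnot(block >= 1L, block <= cfg$n_blocks)
  meta <- features_meta(features)
  X <- array_to_packed(features$values, meta)
  prefix <- paste0("blk", block)
  params <- model$params
  at <- mha_fwd(X, meta, cfg$n_heads, params, prefix)
  ln1 <- layernorm_fwd(X + at$Y, params[[paste0(prefix, "_ln1_g")]],
                       params[[paste0(prefix, "_ln1_b")]])
  T1 <- add_row_vec(ln1$Y %*% params[[paste0(prefix, "_W1")]],
                    params[[paste0(prefix, "_b1")]])
  Fout <- add_row_vec(relu(T1) %*% params[[paste0(prefix, "_W2")]],
                      params[[paste0(prefix, "_b2")]])
  ln2 <- layernorm_fwd(ln1$Y + Fout, params[[paste0(prefix, "_ln2_g")]],
                       params[[paste0(prefix, "_ln2_b")]])
  out <- structure(list(values = packed_to_array(ln2$Y, meta,
                                                 dim(features$values)[2L]),
                        mask = features$mask, lengths = meta$lengths),
                   class = "sequence_features")
  if (return_attention) out$attention <- at$A_list
  out
}

#' Predict class probabilities for a tokenized batch
#'
#' Runs the full forward pass: embedding, multi-kernel convolution, addition
#' of the sinusoidal positional encoding, the stacked encoder blocks, masked
#' pooling over real positions, and the classification head. Dropout is
#' disabled (inference mode).
#'
#' @param object An `acp_model`.
#' @param batch A `tokenized_batch` (or list of `peptide_record`s, which is
#'   encoded with the model's `max_len`).
#' @param ... Unused.
#' @return A `prediction_output`: list with `probabilities` (n x 2 matrix,
#'   columns = classes 0 and 1, rows summing to 1) and `penultimate`
#'   (n x d_penult feature matrix for visualization).
#' @export
predict.acp_model <- function(object, batch, ...) {
  if (!inherits(batch, "tokenized_batch")) {
    batch <- encode_batch(batch, max_len = object$config$max_len)
  }
  fp <- forward_pass(object$params, object$config, batch, training = FALSE)
  structure(list(probabilities = fp$probs, penultimate = fp$penult,
                 labels = batch$labels, ids = batch$ids),
            class = "prediction_output")
}

#' Save / load a model with its configuration embedded
#'
#' @param model An `acp_model`.
#' @param path File path (RDS).
#' @return `path` invisibly; `load_model` returns the `acp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "acp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "acp_model")) stop("load_model: not an acp_model checkpoint")
  m
}
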