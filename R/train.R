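# Focal-loss training with Adam, plus dataset-level evaluation.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
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
  }
  list(params = params, state = state)
}

# Take penultimate features of a dataset with the current weights.
take_snapshot <- function(params, cfg, batch, epoch, split_tag) {
  fp <- forward_pass(params, cfg, batch, training = FALSE)
  structure(list(epoch = epoch, features = fp$penult,
                 labels = batch$labels, split_tag = split_tag),
            class = "feature_snapshot")
}

#' Train the model with focal loss
#'
#' Minibatch Adam optimization of the focal loss for a fixed number of
#' epochs. Deterministic under a fixed `train_config` seed. Optionally
#' records penultimate-layer feature snapshots (for visualization) at
#' requested epochs; epoch 0 means "before any update".
#'
#' @param model An [init_model()] result (returned updated).
#' @param dataset List of [peptide_record()]s, or a `tokenized_batch`. Must
#'   contain both classes.
#' @param config A [train_config()].
#' @param snapshot_epochs Integer vector of epochs at which to snapshot
#'   penultimate features (0 = at initialization), or NULL.
#' @param snapshot_data Optional second dataset (e.g. the test split) to
#'   snapshot alongside the training data.
#' @param verbose Print per-epoch loss lines to stderr.
#' @return List: `model` (trained), `history` (data.frame epoch/loss),
#'   `snapshots` (list of `feature_snapshot`s).
#' @export
train_model <- function(model, dataset, config = train_config(),
                        snapshot_epochs = NULL, snapshot_data = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "acp_model"), inherits(config, "train_config"))
  cfg <- model$config
  batch_all <- if (inherits(dataset, "tokenized_batch")) dataset else {
    encode_batch(dataset, max_len = cfg$max_len)
  }
  labels <- batch_all$labels
  if (length(unique(labels)) < 2L) {
    stop("train_model: dataset must contain both classes")
  }
  snap_batch2 <- if (!is.null(snapshot_data)) {
    if (inherits(snapshot_data, "tokenized_batch")) snapshot_data else {
      encode_batch(snapshot_data, max_len = cfg$max_len)
    }
  } else NULL

  n <- nrow(batch_all$tokens)
  params <- model$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  snapshots <- list()
  grab <- function(epoch, params) {
    out <- list(take_snapshot(params, cfg, batch_all, epoch, "train"))
    if (!is.null(snap_batch2)) {
      out <- c(out, list(take_snapshot(params, cfg, snap_batch2, epoch, "test")))
    }
    out
  }
  if (0L %in% snapshot_epochs) snapshots <- c(snapshots, grab(0L, params))

  with_seed_local(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        mb <- list(tokens = batch_all$tokens[idx, , drop = FALSE],
                   mask = batch_all$mask[idx, , drop = FALSE],
                   lengths = batch_all$lengths[idx],
                   labels = labels[idx])
        fp <- forward_pass(params, cfg, mb, training = TRUE, keep_cache = TRUE)
        pt <- fp$probs[cbind(seq_along(idx), mb$labels + 1L)]
        loss <- focal_loss(pt, config$focal, labels = mb$labels)
        if (!is.finite(loss)) {
          stop("train_model: non-finite loss at epoch ", epoch,
               " (divergence); lower the learning rate")
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        dlogits <- focal_loss_grad_logits(fp$probs, mb$labels, config$focal)
        grads <- backward_pass(params, cfg, fp$cache, dlogits)
        st <- adam_step(params, grads, state, config$learning_rate)
        params <- st$params
        state <- st$state
      }
      epoch_loss <- epoch_loss / n
      history[nrow(history) + 1L, ] <- list(epoch, epoch_loss)
      if (verbose) {
        message(sprintf("epoch %3d/%d  focal loss %.5f",
                        epoch, config$epochs, epoch_loss))
      }
      if (epoch %in% snapshot_epochs) snapshots <- c(snapshots, grab(epoch, params))
    }
  })

  model$params <- params
  list(model = model, history = history, snapshots = snapshots)
}

#' Evaluate a trained model on a dataset
#'
#' @param model An `acp_model`.
#' @param dataset List of `peptide_record`s or a `tokenized_batch` with labels.
#' @param threshold Decision threshold for the threshold metrics.
#' @return List: `report` (a `metric_report` incl. AUCs), `scores`
#'   (probability of the positive class), `labels`.
#' @export
evaluate_model <- function(model, dataset, threshold = 0.5) {
  pred <- stats::predict(model, dataset)
  scores <- pred$probabilities[, 2L]
  list(report = evaluate_scores(scores, pred$labels, threshold),
       scores = scores, labels = pred$labels)
}
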