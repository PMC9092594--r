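# Stratified k-fold cross-validation.

#' Stratified k-fold split
#'
#' Shuffles each class independently (seeded) and deals its members to the
#' folds round-robin, so every fold's class ratio matches the dataset's
#' within one sample and the k test sets partition the index set.
#'
#' @param labels Binary label vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return List of `fold_split`s: each has `fold_id`, `train_indices`,
#'   `test_indices`.
#' @export
kfold_split <- function(labels, k = 10L, seed = 1L) {
  stopifnot(is_count(k, min = 2L))
  if (!all(labels %in% c(0, 1))) stop("kfold_split: labels must be 0/1")
  for (cl in c(0, 1)) {
    if (sum(labels == cl) < k) {
      stop("kfold_split: class ", cl, " has fewer than k = ", k, " members")
    }
  }
  idx_all <- seq_along(labels)
  fold_of <- integer(length(labels))
  with_seed_local(seed, {
    for (cl in c(0, 1)) {
      members <- sample(idx_all[labels == cl])
      fold_of[members] <- rep_len(seq_len(k), length(members))
    }
  })
  lapply(seq_len(k), function(f) {
    structure(list(fold_id = f,
                   train_indices = idx_all[fold_of != f],
                   test_indices = idx_all[fold_of == f]),
              class = "fold_split")
  })
}

subset_batch <- function(batch, idx) {
  structure(list(tokens = batch$tokens[idx, , drop = FALSE],
                 mask = batch$mask[idx, , drop = FALSE],
                 lengths = batch$lengths[idx],
                 labels = batch$labels[idx],
                 ids = batch$ids[idx],
                 max_len = batch$max_len),
            class = "tokenized_batch")
}

#' Stratified k-fold cross-validation of the full model
#'
#' Re-initializes and trains one model per fold on the in-fold data and
#' scores the held-out fold. Reports per-fold metrics, their macro average,
#' and a pooled report computed from the concatenated out-of-fold
#' predictions.
#'
#' @param dataset List of `peptide_record`s.
#' @param k Number of folds (default 10).
#' @param model_config A [model_config()].
#' @param config A [train_config()]; its seed drives the fold split, each
#'   fold's initialization and its shuffling.
#' @param verbose Print fold progress.
#' @return List: `folds` (list of `metric_report`s), `per_fold`
#'   (data.frame), `macro` (named means over folds), `pooled`
#'   (`metric_report` on concatenated predictions), `scores`, `labels`,
#'   `fold_id` (out-of-fold prediction vectors).
#' @export
kfold_cv <- function(dataset, k = 10L, model_config = acpmka::model_config(),
                     config = train_config(), verbose = FALSE) {
  batch_all <- encode_batch(dataset, max_len = model_config$max_len)
  labels <- batch_all$labels
  splits <- kfold_split(labels, k = k, seed = config$seed)
  n <- length(labels)
  oof_scores <- rep(NA_real_, n)
  oof_fold <- rep(NA_integer_, n)
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    sp <- splits[[f]]
    fold_seed <- derive_seed(config$seed, f)
    model <- init_model(model_config, seed = fold_seed)
    fold_cfg <- config
    fold_cfg$seed <- fold_seed
    tr <- train_model(model, subset_batch(batch_all, sp$train_indices), fold_cfg)
    ev <- evaluate_model(tr$model, subset_batch(batch_all, sp$test_indices))
    fold_reports[[f]] <- ev$report
    oof_scores[sp$test_indices] <- ev$scores
    oof_fold[sp$test_indices] <- f
    if (verbose) {
      message(sprintf("fold %2d/%d  acc %.3f  auc %.3f",
                      f, k, ev$report$accuracy, ev$report$auc_roc))
    }
  }
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    data.frame(fold = f, as.data.frame(unclass(fold_reports[[f]])))
  }))
  macro <- colMeans(per_fold[, -1L])
  pooled <- evaluate_scores(oof_scores, labels)
  list(folds = fold_reports, per_fold = per_fold, macro = macro,
       pooled = pooled, scores = oof_scores, labels = labels,
       fold_id = oof_fold, splits = splits)
}
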