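# Parameter-sweep and ablation harnesses: train one model per grid point or
# architecture variant on a fixed train/test pair with a shared seed and
# tabulate accuracy, precision, recall, F1 and AUC.

sweep_row <- function(report) {
  data.frame(accuracy = report$accuracy, precision = report$precision,
             recall = report$sensitivity, f1 = report$f1,
             auc = report$auc_roc)
}

train_and_score <- function(mcfg, tcfg, train_set, test_set) {
  model <- init_model(mcfg, seed = tcfg$seed)
  tr <- train_model(model, train_set, tcfg)
  ev <- evaluate_model(tr$model, test_set)
  list(report = ev$report, scores = ev$scores, labels = ev$labels,
       model = tr$model)
}

#' Sweep one hyperparameter over a grid
#'
#' Trains and evaluates one model per grid point on a fixed train/test pair
#' with a shared seed, and flags the best row per metric.
#'
#' @param parameter `"learning_rate"` or `"kernel_sizes"`.
#' @param grid For `learning_rate`, a numeric vector; for `kernel_sizes`, a
#'   list of integer vectors (e.g. `list(1, 3, c(1, 3), c(1, 3, 5))`).
#' @param train_set,test_set Lists of `peptide_record`s.
#' @param model_config,config Base [model_config()] / [train_config()];
#'   the swept field is overridden per grid point.
#' @param verbose Print progress.
#' @return data.frame with one row per grid point: the grid value,
#'   accuracy, precision, recall, f1, auc, and logical `best_*` columns
#'   flagging the argmax per metric.
#' @export
sweep_param <- function(parameter = c("learning_rate", "kernel_sizes"),
                        grid, train_set, test_set,
                        model_config = acpmka::model_config(),
                        config = train_config(), verbose = FALSE) {
  parameter <- match.arg(parameter)
  if (length(grid) == 0L) stop("sweep_param: empty grid")
  if (parameter == "kernel_sizes" && !is.list(grid)) grid <- as.list(grid)
  rows <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    mcfg <- model_config
    tcfg <- config
    if (parameter == "learning_rate") {
      lr <- grid[[g]]
      if (!is.numeric(lr) || lr <= 0) stop("sweep_param: invalid learning rate")
      tcfg$learning_rate <- lr
      label <- format(lr)
    } else {
      ks <- as.integer(grid[[g]])
      mcfg <- model_config_update(mcfg, kernel_sizes = ks)
      label <- paste(ks, collapse = "+")
    }
    res <- train_and_score(mcfg, tcfg, train_set, test_set)
    rows[[g]] <- cbind(data.frame(value = label), sweep_row(res$report))
    if (verbose) message(sprintf("%s = %s  acc %.3f  auc %.3f", parameter,
                                 label, res$report$accuracy, res$report$auc_roc))
  }
  tab <- do.call(rbind, rows)
  for (m in c("accuracy", "precision", "recall", "f1", "auc")) {
    tab[[paste0("best_", m)]] <- seq_len(nrow(tab)) == which.max(tab[[m]])
  }
  tab
}

# Rebuild a model_config with some fields replaced (revalidates).
model_config_update <- function(cfg, ...) {
  fields <- utils::modifyList(
    list(d_model = cfg$d_model, kernel_sizes = cfg$kernel_sizes,
         n_heads = cfg$n_heads, n_blocks = cfg$n_blocks,
         ffn_dim = cfg$ffn_dim, dropout = cfg$dropout,
         max_len = cfg$max_len, d_penult = cfg$d_penult,
         pooling = cfg$pooling, head_residual = cfg$head_residual),
    list(...))
  do.call(model_config, fields)
}

ablation_kernels <- list(
  "embedding-only" = integer(0),  # conv block bypassed
  "single-cnn" = 3L,
  "multi-cnn" = c(1L, 3L, 5L)
)

#' Architecture ablation
#'
#' Compares three variants that differ only in the convolution block:
#' `embedding-only` (no convolution; positional encoding added to the raw
#' embedding), `single-cnn` (one kernel of width 3) and `multi-cnn`
#' (kernels 1, 3, 5). All variants share the train/test pair and the seed.
#'
#' @param train_set,test_set Lists of `peptide_record`s.
#' @param variants Character vector of variant names (default all three).
#' @param model_config,config Base configs; `kernel_sizes` is overridden
#'   per variant.
#' @param verbose Print progress.
#' @return List: `table` (one row per variant: accuracy, precision, recall,
#'   f1, auc) and `curves` (per-variant scores and labels for ROC/PR
#'   plotting).
#' @export
ablate <- function(train_set, test_set,
                   variants = names(ablation_kernels),
                   model_config = acpmka::model_config(),
                   config = train_config(), verbose = FALSE) {
  unknown <- setdiff(variants, names(ablation_kernels))
  if (length(unknown) > 0L) {
    stop("ablate: unknown variant(s): ", paste(unknown, collapse = ", "))
  }
  rows <- list()
  curves <- list()
  for (v in variants) {
    mcfg <- model_config_update(model_config,
                                kernel_sizes = ablation_kernels[[v]])
    res <- train_and_score(mcfg, config, train_set, test_set)
    rows[[v]] <- cbind(data.frame(variant = v), sweep_row(res$report))
    curves[[v]] <- list(scores = res$scores, labels = res$labels)
    if (verbose) message(sprintf("%-14s acc %.3f  auc %.3f", v,
                                 res$report$accuracy, res$report$auc_roc))
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       curves = curves)
}
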