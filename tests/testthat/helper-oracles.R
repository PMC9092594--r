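# Independent scalar oracles used across tests. These deliberately avoid the
# package's vectorized implementations: plain arithmetic, explicit loops.

# Direct evaluation of the confusion-table metric formulas.
metrics_oracle <- function(tp, fp, tn, fn) {
  se <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  acc <- (tp + tn) / (tp + fp + tn + fn)
  den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  f1 <- if (prec + se > 0) 2 * prec * se / (prec + se) else 0
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  list(sensitivity = se, specificity = sp, precision = prec, accuracy = acc,
       mcc = mcc, f1 = f1, tpr = se, fpr = fpr,
       correct_index = (se + 1 - fpr) / 2)
}

# All-pairs Mann-Whitney AUC: mean over positive/negative pairs of
# [s+ > s-] + 0.5 [s+ = s-].
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Scalar positional-encoding formula.
pe_oracle <- function(p, i, d_model) {
  c(sin(p / 10000^(2 * i / d_model)), cos(p / 10000^(2 * i / d_model)))
}

# Scalar focal loss for one sample.
focal_oracle <- function(p, alpha, gamma) {
  -alpha * (1 - p)^gamma * log(p)
}

# Per-sample brute-force confusion tally.
confusion_oracle <- function(scores, labels, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    if (pred && labels[i] == 0) fp <- fp + 1L
    if (!pred && labels[i] == 0) tn <- tn + 1L
    if (!pred && labels[i] == 1) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# A small architecture that trains in a couple of seconds.
tiny_config <- function(...) {
  defaults <- list(d_model = 8L, kernel_sizes = c(1L, 3L), n_heads = 2L,
                   n_blocks = 1L, ffn_dim = 16L, dropout = 0, max_len = 20L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_records <- function(n_pos = 10, n_neg = 10, seed = 5, motif_prob = 1,
                         len_range = c(8L, 18L), motif = "KWKWK") {
  generate_dataset(fixture_spec(n_pos, n_neg, len_range = len_range,
                                motif = motif, motif_prob = motif_prob,
                                seed = seed))
}
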