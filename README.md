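# acpmka

Sequence-based classification of anticancer peptides (ACPs) with a
multi-kernel convolutional + self-attention network, in pure R.

Anticancer peptides are short (10–50 residue) peptides with confirmed
activity against tumour cells. Ranking candidate sequences computationally
before synthesis is a standard step in peptide drug discovery, and the
discriminative signal is thought to live in short clusters of adjacent
residues and their arrangement along the chain. `acpmka` is for
bioinformaticians who want such a classifier whose every moving part —
network, gradients, loss, metrics, cross-validation, visualization — is
inspectable, tested R code.

## The model

A peptide is tokenized over the 20-letter amino-acid alphabet and passed
through:

1. a learned residue **embedding** (width *d*<sub>model</sub> = 64; same
   residue ⇒ same vector at every position, padding ⇒ zero vector);
2. a **multi-kernel convolution**: same-length convolutions of odd widths
   {1, 3, 5} run in parallel, their maps are concatenated on the feature
   axis and linearly fused back to *d*<sub>model</sub>;
3. a sinusoidal **positional encoding**,
   PE(p, 2i) = sin(p / 10000^(2i/d)), PE(p, 2i+1) = cos(p / 10000^(2i/d)),
   added elementwise;
4. stacked transformer **encoder blocks** (default 2): multi-head scaled
   dot-product self-attention softmax(QKᵀ/√d_k)V with padded keys excluded,
   position-wise feed-forward, residual connections and layer
   normalization;
5. a **task head**: masked mean pooling, linear → ReLU (the penultimate
   features, exposed for visualization) → linear → softmax.

Training minimizes the **focal loss**
FL(p_t) = −α_t (1−p_t)^γ log(p_t) (defaults α_t = 0.3, γ = 2) with Adam at
learning rate 2·10⁻⁴ for 50 epochs. All gradients are analytic and are
tested against finite differences.

The evaluation harness computes sensitivity, specificity, precision,
accuracy, MCC, F1, the correct index (TPR + 1 − FPR)/2, AUC-ROC
(Mann–Whitney, ties = ½) and AUC-PR, and provides stratified k-fold
cross-validation, learning-rate / kernel-combination sweeps, architecture
ablations (embedding-only / single-kernel / multi-kernel) and PCA/t-SNE
projection of penultimate features across training epochs.

Because the curated ACP benchmark sets are external downloads, the package
ships a synthetic generator (`fixture_spec()` / `generate_dataset()`) that
plants a contiguous sequence motif into positives with tunable probability
— fully informative at `motif_prob = 1`, pure negative control at
`motif_prob = 0` — so the whole pipeline is testable offline.

## A worked example

```r
library(acpmka)

spec  <- fixture_spec(n_pos = 60, n_neg = 60, motif = "KLAKLAK", seed = 7)
train <- generate_dataset(spec)
test  <- generate_dataset(fixture_spec(40, 40, motif = "KLAKLAK", seed = 8))

cfg <- model_config(d_model = 32, n_blocks = 1, ffn_dim = 64)
fit <- train_model(init_model(cfg, seed = 1), train,
                   train_config(learning_rate = 1e-3, epochs = 10, seed = 1))
evaluate_model(fit$model, test)$report
#> <metric_report>
#>   sensitivity   specificity     precision      accuracy           mcc
#>        1.0000        0.8000        0.8333        0.9000        0.8165
#>            f1           tpr           fpr correct_index       auc_roc
#>        0.9091        1.0000        0.2000        0.9000        0.9781
#>        auc_pr
#>        0.9784
```

After ten epochs on 120 synthetic peptides the model finds every planted
motif (sensitivity 1.0) at the cost of eight false positives among the 40
motif-free negatives (specificity 0.80); the ranking itself is nearly
perfect (AUC 0.978). More epochs, or the default 64-wide two-block
architecture, push held-out accuracy above 0.95 (that stronger claim is
what the test suite asserts at the 500-train/164-test scale).

A thin command-line interface over the same functions lives at
`inst/scripts/acpmka-cli.R` (subcommands `simulate`, `train`, `evaluate`,
`cv`, `sweep`, `ablate`, `visualize`).

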