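# 2-D projection of penultimate-layer features (PCA / exact t-SNE), a
# quantitative cluster-separation score, and ROC/PR curve rendering.

# Exact (non-Barnes-Hut) t-SNE. Adequate for the few hundred points typical
# of feature-snapshot visualization. Perplexity is calibrated per point by
# binary search on the Gaussian bandwidth; the embedding is optimized by
# gradient descent with momentum and early exaggeration.
tsne_exact <- function(X, perplexity = 30, n_iter = 400, eta = 100,
                       exaggeration = 4, exaggerate_iter = 100) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  if (perplexity < 1) perplexity <- 1
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    bmin <- -Inf
    bmax <- Inf
    di <- D2[i, -i]
    for (it in seq_len(50L)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(di), length(di)) else p <- p / sp
      H <- -sum(p * log(pmax(p, 1e-300)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {  # entropy too high -> narrow the kernel
        bmin <- beta
        beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2
      } else {
        bmax <- beta
        beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(n_iter)) {
    Pit <- if (iter <= exaggerate_iter) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (iter < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Project a feature snapshot to 2-D
#'
#' PCA projects onto the top-2 principal components of the centered feature
#' matrix; t-SNE computes a standard exact embedding under a fixed seed
#' (perplexity clipped to `(n - 1) / 3` for small inputs).
#'
#' @param snapshot A `feature_snapshot` (see [train_model()]), or any list
#'   with a numeric `features` matrix.
#' @param method `"pca"` or `"tsne"`.
#' @param seed Integer seed (t-SNE initialization; PCA is deterministic).
#' @param perplexity t-SNE perplexity (default 30).
#' @return n x 2 coordinate matrix.
#' @export
project <- function(snapshot, method = c("pca", "tsne"), seed = 1L,
                    perplexity = 30) {
  method <- match.arg(method)
  X <- snapshot$features
  stopifnot(is.matrix(X), nrow(X) >= 3L, ncol(X) >= 2L)
  if (method == "pca") {
    sds <- apply(X, 2L, stats::sd)
    if (all(sds < 1e-12)) {
      warning("project: constant feature matrix, PCA components are degenerate")
      return(matrix(0, nrow(X), 2L))
    }
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    out <- matrix(0, nrow(X), 2L)
    out[, seq_len(k)] <- pc$x[, seq_len(k)]
    out
  } else {
    with_seed_local(seed, tsne_exact(X, perplexity = perplexity))
  }
}

#' Class-separation score of a 2-D projection
#'
#' Leave-one-out 1-nearest-neighbour label agreement: 1 means perfectly
#' separated class clusters, about 0.5 means fully mixed labels, 0 means
#' every point's nearest neighbour carries the opposite label.
#'
#' @param coordinates n x 2 coordinate matrix.
#' @param labels Binary labels, one per row.
#' @return Score in \[0, 1\].
#' @export
separation_score <- function(coordinates, labels) {
  stopifnot(nrow(coordinates) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("separation_score: both classes must be present")
  }
  D <- as.matrix(stats::dist(coordinates))
  diag(D) <- Inf
  nn <- apply(D, 1L, which.min)
  mean(labels[nn] == labels)
}

#' Plot ROC and PR curves for one or more models
#'
#' Renders a two-panel figure (ROC left, PR right) with one curve per model
#' and the AUC annotated in the legend, and writes the underlying curve
#' points as CSV.
#'
#' @param models Named list; each element a list with `scores` and `labels`
#'   (e.g. the `curves` element of [ablate()]).
#' @param prefix Output path prefix; writes `<prefix>_curves.pdf`,
#'   `<prefix>_curves.png` and `<prefix>_curves.csv`. NULL skips files.
#' @return List: `plot` (ggplot object), `data` (curve points data.frame),
#'   invisibly.
#' @export
plot_curves <- function(models, prefix = NULL) {
  if (length(models) == 0L) stop("plot_curves: no model scores supplied")
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  pieces <- lapply(names(models), function(nm) {
    sc <- models[[nm]]$scores
    lb <- models[[nm]]$labels
    roc <- roc_points(sc, lb)
    pr <- pr_points(sc, lb)
    lab_roc <- sprintf("%s (AUC %.3f)", nm, auc_roc(sc, lb))
    lab_pr <- sprintf("%s (AP %.3f)", nm, auc_pr(sc, lb))
    rbind(data.frame(model = nm, curve = "ROC", x = roc$fpr, y = roc$tpr,
                     threshold = roc$threshold, legend = lab_roc),
          data.frame(model = nm, curve = "PR", x = pr$recall, y = pr$precision,
                     threshold = pr$threshold, legend = lab_pr))
  })
  df <- do.call(rbind, pieces)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = legend)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(x = "FPR / Recall", y = "TPR / Precision", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom", legend.direction = "vertical")
  if (!is.null(prefix)) {
    ggplot2::ggsave(paste0(prefix, "_curves.pdf"), p, width = 8, height = 4.5)
    ggplot2::ggsave(paste0(prefix, "_curves.png"), p, width = 8, height = 4.5,
                    dpi = 150)
    utils::write.csv(df, paste0(prefix, "_curves.csv"), row.names = FALSE)
  }
  invisible(list(plot = p, data = df))
}

#' Write 2-D projections of feature snapshots across epochs
#'
#' Projects each snapshot with [project()] and returns (and optionally
#' writes) tidy coordinates with columns id, split_tag, label, x, y, epoch,
#' method — one row per sample per snapshot.
#'
#' @param snapshots List of `feature_snapshot`s (see [train_model()]).
#' @param methods Projection methods to apply.
#' @param seed Seed passed to [project()].
#' @param path Optional CSV output path.
#' @return data.frame of coordinates, invisibly if `path` is given.
#' @export
project_snapshots <- function(snapshots, methods = c("pca", "tsne"),
                              seed = 1L, path = NULL) {
  rows <- list()
  for (sn in snapshots) {
    for (m in methods) {
      xy <- project(sn, method = m, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        id = seq_len(nrow(xy)), split_tag = sn$split_tag,
        label = sn$labels, x = xy[, 1L], y = xy[, 2L],
        epoch = sn$epoch, method = m)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
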