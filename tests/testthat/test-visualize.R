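# PCA / t-SNE projection, separation score, curve rendering.

test_that("PCA of centered data with diagonal covariance returns the inputs", {
  set.seed(1)
  X <- cbind(rnorm(40, sd = 3), rnorm(40, sd = 1))
  X <- sweep(X, 2, colMeans(X))
  X[, 2] <- X[, 2] - sum(X[, 1] * X[, 2]) / sum(X[, 1]^2) * X[, 1]  # orthogonalize
  co <- project(list(features = X), method = "pca")
  # same point set up to per-axis sign
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(co[, j], X[, j], tolerance = 1e-6)) ||
                  isTRUE(all.equal(co[, j], -X[, j], tolerance = 1e-6)))
  }
})

test_that("PCA of collinear points has zero variance on the second axis", {
  t <- seq(-2, 2, length.out = 30)
  X <- outer(t, runif(10))  # rank-1: points on a line in 10-D
  co <- project(list(features = X), method = "pca")
  expect_lt(stats::sd(co[, 2]), 1e-10)
})

test_that("PCA explained variance matches an independent eigendecomposition", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  co <- project(list(features = X), method = "pca")
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(apply(co, 2, stats::var), ev[1:2], tolerance = 1e-10)
})

test_that("PCA is invariant to adding a constant vector to all features", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  a <- project(list(features = X), method = "pca")
  b <- project(list(features = sweep(X, 2, c(5, -2, 11), "+")), method = "pca")
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(a[, j], b[, j], tolerance = 1e-8)) ||
                  isTRUE(all.equal(a[, j], -b[, j], tolerance = 1e-8)))
  }
})

test_that("a constant feature matrix triggers the degenerate-PCA warning", {
  X <- matrix(1, 10, 4)
  expect_warning(project(list(features = X), method = "pca"), "degenerate")
})

test_that("t-SNE is deterministic under a fixed seed and emits 2 columns", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  a <- project(list(features = X), method = "tsne", seed = 7)
  b <- project(list(features = X), method = "tsne", seed = 7)
  c <- project(list(features = X), method = "tsne", seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_equal(ncol(a), 2L)
  # well-separated blobs stay separated in the embedding
  expect_equal(separation_score(a, rep(c(0, 1), each = 20)), 1)
})

test_that("separation score is 1 for distant clusters, ~0.5 for shuffled labels, 0 for twins", {
  far <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2), matrix(rnorm(60, 50, 0.1), 30, 2))
  expect_equal(separation_score(far, rep(c(0, 1), each = 30)), 1)

  set.seed(5)
  blob <- matrix(rnorm(400), 200, 2)
  labs <- sample(rep(c(0, 1), 100))
  expect_equal(separation_score(blob, labs), 0.5, tolerance = 0.1)

  pts <- matrix(rnorm(20), 10, 2)
  twins <- rbind(pts, pts + 1e-9)
  expect_equal(separation_score(twins, rep(c(0, 1), each = 10)), 0)
  expect_error(separation_score(blob, rep(1, 200)), "both classes")
})

test_that("plot_curves writes figure files and CSV rows per threshold", {
  set.seed(6)
  scores <- c(runif(30, 0.4, 1), runif(30, 0, 0.6))
  labels <- rep(c(1, 0), each = 30)
  prefix <- file.path(withr::local_tempdir(), "curves")
  out <- plot_curves(list(toy = list(scores = scores, labels = labels)),
                     prefix = prefix)
  expect_true(file.exists(paste0(prefix, "_curves.pdf")))
  expect_true(file.exists(paste0(prefix, "_curves.png")))
  csv <- utils::read.csv(paste0(prefix, "_curves.csv"))
  n_thr <- length(unique(scores))
  expect_equal(sum(csv$curve == "ROC"), n_thr + 1L)  # thresholds + (0,0) endpoint
  expect_equal(sum(csv$curve == "PR"), n_thr)
  expect_error(plot_curves(list()), "no model scores")
  # perfect scores hug the (0,1) corner with AUC 1 in the legend
  perf <- plot_curves(list(m = list(scores = labels, labels = labels)))
  expect_match(unique(perf$data$legend[perf$data$curve == "ROC"]), "1.000")
})

test_that("project_snapshots emits tidy coordinates for every snapshot/method", {
  set.seed(7)
  sn <- list(
    structure(list(epoch = 0L, features = matrix(rnorm(60), 20, 3),
                   labels = rep(c(0, 1), 10), split_tag = "train"),
              class = "feature_snapshot"),
    structure(list(epoch = 5L, features = matrix(rnorm(60), 20, 3),
                   labels = rep(c(0, 1), 10), split_tag = "test"),
              class = "feature_snapshot"))
  df <- project_snapshots(sn, methods = c("pca", "tsne"), seed = 9)
  expect_equal(nrow(df), 20L * 2L * 2L)
  expect_setequal(names(df), c("id", "split_tag", "label", "x", "y",
                               "epoch", "method"))
  expect_setequal(unique(df$method), c("pca", "tsne"))
})
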