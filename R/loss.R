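# Focal loss for binary classification.
#
# FL(p_t) = -alpha_t * (1 - p_t)^gamma * log(p_t), averaged over the batch,
# where p_t is the predicted probability of the ground-truth class. The
# modulating factor (1 - p_t)^gamma down-weights easy examples; alpha_t
# balances the classes. gamma = 0 with alpha = 1 is plain cross-entropy.

FOCAL_EPS <- 1e-7

focal_alpha_t <- function(params, labels = NULL, n = NULL) {
  a <- params$alpha
  if (length(a) == 1L) return(rep(a, n %||% length(labels)))
  if (is.null(labels)) stop("per-class alpha requires labels")
  ifelse(labels == 1L, a[2L], a[1L])
}

#' Focal loss
#'
#' Mean over samples of `-alpha_t * (1 - p_t)^gamma * log(p_t)`, with `p_t`
#' floored at 1e-7 before the logarithm.
#'
#' @param p_true Vector of predicted probabilities of the ground-truth class,
#'   one per sample, each in \[0, 1\].
#' @param params A [focal_params()].
#' @param labels Optional binary labels, required only when `params$alpha`
#'   is a per-class pair.
#' @param reduce `"mean"` (default) or `"none"` (per-sample losses).
#' @return Non-negative scalar (or vector when `reduce = "none"`).
#' @export
#' @examples
#' focal_loss(0.5, focal_params(alpha = 0.3, gamma = 2))  # 0.3 * 0.25 * log 2
focal_loss <- function(p_true, params = focal_params(), labels = NULL,
                       reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(params, "focal_params"))
  if (length(p_true) == 0L) stop("focal_loss: empty input")
  if (any(!is.finite(p_true)) || any(p_true < 0) || any(p_true > 1)) {
    stop("focal_loss: p_true must lie in [0, 1]")
  }
  p <- pmax(p_true, FOCAL_EPS)
  at <- focal_alpha_t(params, labels, n = length(p))
  loss <- -at * (1 - p)^params$gamma * log(p)
  if (reduce == "mean") mean(loss) else loss
}

# d(mean focal loss)/d(logits) for a softmax head.
# probs: n x 2 softmax output; labels in {0,1}. Derivative of
# f(p_t) = -a (1-p_t)^g log p_t is
#   f'(p_t) = a [ g (1-p_t)^(g-1) log p_t - (1-p_t)^g / p_t ]
# and dp_t/dz_j = p_t (1[j = t] - p_j), giving
#   dL/dz_j = f'(p_t) p_t (1[j=t] - p_j) / n.
# Below the numerical floor on p_t the loss is constant, so the gradient is 0.
focal_loss_grad_logits <- function(probs, labels, params) {
  n <- nrow(probs)
  tcol <- labels + 1L
  pt_raw <- probs[cbind(seq_len(n), tcol)]
  pt <- pmax(pt_raw, FOCAL_EPS)
  at <- focal_alpha_t(params, labels, n = n)
  g <- params$gamma
  term1 <- if (g == 0) 0 else g * (1 - pt)^(g - 1) * log(pt)
  # limit of (1-p)^(g-1) log p as p -> 1 is 0 for every g > 0
  if (g > 0) term1[pt == 1] <- 0
  fprime <- at * (term1 - (1 - pt)^g / pt)
  fprime[pt_raw < FOCAL_EPS] <- 0
  ind <- matrix(0, n, ncol(probs))
  ind[cbind(seq_len(n), tcol)] <- 1
  (fprime * pt / n) * (ind - probs)
}
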