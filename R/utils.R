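# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic entry points go through this so
# that a single seed argument fully determines their output.
with_seed_local <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministically derive a child seed from a master seed and an integer tag,
# kept within the 32-bit signed range.
derive_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 7919 + as.double(tag) * 104729) %% 2147483647L)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax with max-subtraction for stability.
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

glorot_uniform <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -l, l), nrow, ncol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
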