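# Sinusoidal positional encoding.

#' Sinusoidal positional encoding matrix
#'
#' Deterministic position features added to the convolutional output so that
#' self-attention can use residue order. For position `p` (0-based) and
#' channel pair `i` (0-based, `i < d_model/2`):
#' \deqn{PE(p, 2i) = \sin(p / 10000^{2i/d_{model}})}
#' \deqn{PE(p, 2i+1) = \cos(p / 10000^{2i/d_{model}})}
#' Row `p + 1` of the returned matrix is the encoding of position `p`.
#'
#' @param max_len Number of positions (rows).
#' @param d_model Even channel count (columns).
#' @return `max_len x d_model` numeric matrix with entries in \[-1, 1\].
#' @export
#' @examples
#' pe <- positional_encoding(50, 64)
#' pe[1, 1:4]  # position 0: sin 0 = 0, cos 0 = 1, ...
positional_encoding <- function(max_len, d_model) {
  stopifnot(is_count(max_len), is_count(d_model))
  if (d_model %% 2L != 0L) {
    stop("positional_encoding: d_model must be even (paired sin/cos channels)")
  }
  p <- seq_len(max_len) - 1
  i <- seq_len(d_model %/% 2L) - 1
  # angle[p+1, i+1] = p / 10000^(2i/d_model)
  ang <- outer(p, 10000^(-2 * i / d_model))
  pe <- matrix(0, max_len, d_model)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}
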