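# Synthetic labelled peptide datasets with a plantable, tunable class signal.
#
# Negatives are drawn i.i.d. from a background residue distribution; positives
# are drawn from the same background and then, with probability `motif_prob`,
# a contiguous motif is planted at a uniformly random admissible offset. With
# motif_prob = 0 the two class distributions are identical, which provides a
# negative control: no classifier can beat chance in expectation.

#' Specify a synthetic peptide dataset
#'
#' @param n_pos,n_neg Number of positive / negative records (>= 0).
#' @param len_range Inclusive integer interval of sequence lengths, default
#'   `c(10, 50)` (typical anticancer-peptide lengths).
#' @param motif Residue string planted into positives. Default "KLAKLAK", a
#'   short lytic-peptide-like repeat; any string over the 20-letter alphabet
#'   no longer than `min(len_range)` is allowed.
#' @param motif_prob Probability that a positive carries the motif, in
#'   \[0, 1\]. Default 1 (fully informative signal).
#' @param background Length-20 vector of residue frequencies (alphabetical
#'   order) summing to 1. Default uniform 1/20.
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_pos, n_neg, len_range = c(10L, 50L),
                         motif = "KLAKLAK", motif_prob = 1,
                         background = rep(1 / 20, 20), seed = 1L) {
  stopifnot(is_count(n_pos, min = 0L), is_count(n_neg, min = 0L),
            length(len_range) == 2L)
  len_range <- as.integer(len_range)
  if (len_range[1L] < 1L || len_range[2L] < len_range[1L]) {
    stop("fixture_spec: len_range must be an increasing interval within [1, Inf)")
  }
  motif <- toupper(motif)
  mchars <- strsplit(motif, "")[[1L]]
  bad <- setdiff(unique(mchars), aa_alphabet())
  if (length(bad) > 0L) {
    stop("fixture_spec: motif contains non-alphabet residue(s): ",
         paste(bad, collapse = ", "))
  }
  if (nchar(motif) > len_range[1L]) {
    stop("fixture_spec: motif length ", nchar(motif),
         " exceeds minimum sequence length ", len_range[1L])
  }
  if (!is.numeric(motif_prob) || motif_prob < 0 || motif_prob > 1) {
    stop("fixture_spec: motif_prob must be in [0, 1]")
  }
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("fixture_spec: background must be 20 non-negative frequencies summing to 1")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 len_range = len_range, motif = motif,
                 motif_prob = motif_prob, background = as.numeric(background),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic labelled peptide dataset
#'
#' @param spec A [fixture_spec()].
#' @return List of [peptide_record()]s: `n_pos` positives followed by
#'   `n_neg` negatives.
#' @export
#' @examples
#' recs <- generate_dataset(fixture_spec(5, 5, seed = 7))
#' table(vapply(recs, function(r) r$label, integer(1)))
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  alpha <- aa_alphabet()
  mchars <- strsplit(spec$motif, "")[[1L]]
  mlen <- length(mchars)
  with_seed_local(spec$seed, {
    draw_background <- function(L) {
      sample(alpha, L, replace = TRUE, prob = spec$background)
    }
    recs <- vector("list", spec$n_pos + spec$n_neg)
    for (i in seq_len(spec$n_pos)) {
      L <- sample(spec$len_range[1L]:spec$len_range[2L], 1L)
      chars <- draw_background(L)
      if (stats::runif(1L) < spec$motif_prob) {
        off <- sample(seq_len(L - mlen + 1L), 1L)
        chars[off:(off + mlen - 1L)] <- mchars
      }
      recs[[i]] <- peptide_record(sprintf("pos_%04d", i),
                                  paste(chars, collapse = ""), 1L)
    }
    for (i in seq_len(spec$n_neg)) {
      L <- sample(spec$len_range[1L]:spec$len_range[2L], 1L)
      recs[[spec$n_pos + i]] <- peptide_record(
        sprintf("neg_%04d", i),
        paste(draw_background(L), collapse = ""), 0L)
    }
    recs
  })
}

#' Write a synthetic dataset as FASTA pairs plus a JSON provenance sidecar
#'
#' Emits `<prefix>_pos.fasta`, `<prefix>_neg.fasta` and `<prefix>_spec.json`
#' (the generating spec, for provenance).
#'
#' @param records Output of [generate_dataset()].
#' @param spec The generating [fixture_spec()].
#' @param prefix Output path prefix (directory must exist).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fixture <- function(records, spec, prefix) {
  labs <- vapply(records, function(r) r$label, integer(1L))
  paths <- c(pos = paste0(prefix, "_pos.fasta"),
             neg = paste0(prefix, "_neg.fasta"),
             spec = paste0(prefix, "_spec.json"))
  write_fasta(records[labs == 1L], paths[["pos"]])
  write_fasta(records[labs == 0L], paths[["neg"]])
  jsonlite::write_json(unclass(spec), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
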