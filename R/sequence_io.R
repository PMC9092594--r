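# Reading, validating, tokenizing and batching peptide sequences.
#
# The vocabulary covers the 20 canonical amino acids in alphabetical order,
# indices 1..20; index 0 is reserved for padding. Labels travel out-of-band
# (one FASTA file per class), never parsed from headers.

#' The canonical amino-acid alphabet
#'
#' The 20 one-letter residue codes in alphabetical order. Token index of a
#' residue is its position in this vector; 0 is the padding token.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Residue-to-token lookup
#'
#' @return Named integer vector mapping each residue letter to its token
#'   index (A = 1, ..., Y = 20).
#' @export
aa_vocab <- function() {
  stats::setNames(seq_along(aa_alphabet()), aa_alphabet())
}

#' Construct a labelled peptide record
#'
#' @param id Identifier string.
#' @param sequence Amino-acid sequence over the 20-letter alphabet
#'   (case-insensitive; stored uppercased).
#' @param label Binary class: 1 = positive (e.g. anticancer peptide),
#'   0 = negative.
#' @return A `peptide_record`: a list with fields `id`, `sequence`, `label`.
#' @export
#' @examples
#' peptide_record("p1", "GATCDCPLR", 1)
peptide_record <- function(id, sequence, label) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("peptide_record: sequence must be non-empty (id: ", id, ")")
  }
  if (!label %in% c(0L, 1L)) {
    stop("peptide_record: label must be 0 or 1, got ", label)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1L]]), aa_alphabet())
  if (length(bad) > 0L) {
    stop("peptide_record: invalid residue(s) ", paste(bad, collapse = ", "),
         " in sequence of '", id, "'")
  }
  structure(list(id = id, sequence = sequence, label = as.integer(label)),
            class = "peptide_record")
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(sprintf("<peptide_record> %s [label %d] %s\n", x$id, x$label, x$sequence))
  invisible(x)
}

#' Validate (or repair) a peptide record against the canonical alphabet
#'
#' Under `policy = "reject"` any residue outside the 20-letter alphabet is an
#' error naming the residue and its position. Under `policy = "drop-residue"`
#' offending characters are removed and the event reported via [message()].
#'
#' @param record A `peptide_record`, or a list with `id`, `sequence`, `label`
#'   fields (sequence may still contain non-canonical residues).
#' @param policy `"reject"` (default) or `"drop-residue"`.
#' @return A validated `peptide_record`.
#' @export
#' @examples
#' r <- list(id = "x", sequence = "ACXDE", label = 0)
#' validate_record(r, policy = "drop-residue")  # -> sequence "ACDE"
validate_record <- function(record, policy = c("reject", "drop-residue")) {
  policy <- match.arg(policy)
  seq <- toupper(record$sequence)
  chars <- strsplit(seq, "")[[1L]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad) > 0L) {
    if (policy == "reject") {
      stop(sprintf(
        "validate_record: invalid residue '%s' at position %d in '%s'",
        chars[bad[1L]], bad[1L], record$id))
    }
    message(sprintf("validate_record: dropped %d non-canonical residue(s) (%s) from '%s'",
                    length(bad), paste(unique(chars[bad]), collapse = ","), record$id))
    chars <- chars[-bad]
    if (length(chars) == 0L) {
      stop("validate_record: sequence of '", record$id,
           "' is empty after dropping non-canonical residues")
    }
    seq <- paste(chars, collapse = "")
  }
  peptide_record(record$id, seq, record$label)
}

# Light structural pre-scan of a FASTA file so parse errors carry line numbers.
check_fasta_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("read_fasta: '", path, "' contains no FASTA entries (empty input)")
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("read_fasta: malformed FASTA in '", path, "' at line ", first,
         ": expected a '>' header before sequence data")
  }
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in headers) {
    nxt <- nonblank[nonblank > h]
    if (length(nxt) == 0L || startsWith(trimws(lines[nxt[1L]]), ">")) {
      stop("read_fasta: malformed FASTA in '", path, "' at line ", h,
           ": header '", trimws(lines[h]), "' has no sequence lines")
    }
  }
  invisible(length(headers))
}

#' Read labelled peptides from a FASTA file
#'
#' Parses a (plain, possibly multi-line) FASTA file with Biostrings and
#' attaches the supplied binary label to every entry. Sequences are
#' uppercased; entry order is preserved. Header text up to the first
#' whitespace becomes the record id.
#'
#' @param path Path to a FASTA file.
#' @param label Binary label (0/1) attached to every record in the file.
#' @param policy Residue policy passed to [validate_record()].
#' @return List of [peptide_record()]s.
#' @export
read_fasta <- function(path, label, policy = c("reject", "drop-residue")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  check_fasta_structure(path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    stop("read_fasta: '", path, "' contains no FASTA entries (empty input)")
  }
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1L), 1L)
  seqs <- unname(toupper(as.character(ss)))
  lapply(seq_along(ss), function(i) {
    validate_record(list(id = ids[i], sequence = seqs[i], label = label),
                    policy = policy)
  })
}

#' Write peptide records to a FASTA file
#'
#' @param records List of `peptide_record`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, function(r) r$sequence, character(1L))
  ids <- vapply(records, function(r) r$id, character(1L))
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Tokenize and pad a set of peptide records
#'
#' Maps residues through the alphabetical vocabulary (A = 1, ..., Y = 20),
#' right-pads with token 0 to `max_len`, and builds the padding mask. By
#' default sequences longer than `max_len` are an error: silent truncation
#' would change the biology.
#'
#' @param records List of `peptide_record`s.
#' @param max_len Padded length (default 50, the upper end of typical ACP
#'   lengths).
#' @param on_long `"error"` (default) or `"truncate"`.
#' @return A `tokenized_batch`: list with `tokens` (n x max_len integer
#'   matrix), `mask` (logical matrix, TRUE at real residues), `lengths`,
#'   `labels`, `ids`, `max_len`.
#' @export
#' @examples
#' b <- encode_batch(list(peptide_record("a", "ACD", 1)), max_len = 5)
#' b$tokens  # 1 2 3 0 0
encode_batch <- function(records, max_len = 50L, on_long = c("error", "truncate")) {
  on_long <- match.arg(on_long)
  stopifnot(is_count(max_len))
  if (length(records) == 0L) stop("encode_batch: no records supplied")
  n <- length(records)
  vocab <- aa_vocab()
  tokens <- matrix(0L, n, max_len)
  lengths <- integer(n)
  for (i in seq_len(n)) {
    chars <- strsplit(records[[i]]$sequence, "")[[1L]]
    if (length(chars) > max_len) {
      if (on_long == "error") {
        stop("encode_batch: sequence '", records[[i]]$id, "' has length ",
             length(chars), " > max_len ", max_len)
      }
      chars <- chars[seq_len(max_len)]
    }
    L <- length(chars)
    tokens[i, seq_len(L)] <- vocab[chars]
    lengths[i] <- L
  }
  mask <- matrix(rep(seq_len(max_len), each = n) <= lengths, n, max_len)
  structure(list(
    tokens = tokens, mask = mask, lengths = lengths,
    labels = vapply(records, function(r) r$label, integer(1L)),
    ids = vapply(records, function(r) r$id, character(1L)),
    max_len = as.integer(max_len)
  ), class = "tokenized_batch")
}

#' Decode a tokenized batch back to sequences
#'
#' @param batch A `tokenized_batch`.
#' @return Character vector of sequences (padding stripped).
#' @export
decode_batch <- function(batch) {
  alpha <- aa_alphabet()
  vapply(seq_len(nrow(batch$tokens)), function(i) {
    toks <- batch$tokens[i, seq_len(batch$lengths[i])]
    paste(alpha[toks], collapse = "")
  }, character(1L))
}

#' @export
print.tokenized_batch <- function(x, ...) {
  cat(sprintf("<tokenized_batch> %d sequences, max_len %d, lengths %d-%d\n",
              nrow(x$tokens), x$max_len, min(x$lengths), max(x$lengths)))
  invisible(x)
}
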