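#' One-hot encode a peptide sequence
#'
#' Converts a validated amino-acid sequence into the fixed-size network
#' input: a 20 x 120 binary matrix whose rows follow the alphabet order
#' and whose columns are residue positions. Column `j` carries a single 1
#' at the row of residue `j`; sequences longer than 120 residues are
#' truncated after the 120th amino acid and shorter ones are padded on the
#' C-terminal side with all-zero columns.
#'
#' @param sequence Canonical amino-acid string (see [validate_and_filter()]).
#' @param alphabet An [aa_alphabet()].
#' @param max_len Number of columns of the encoding (120).
#' @return An `encoded_peptide`: the 20 x 120 integer matrix with
#'   attribute `true_length = min(nchar(sequence), max_len)`.
#' @examples
#' m <- encode_peptide("ACDW")
#' which(m[, 1] == 1) # row 1: A
#' @export
encode_peptide <- function(sequence, alphabet = aa_alphabet(),
                           max_len = 120L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  rows <- alphabet$index_of[res]
  if (anyNA(rows)) {
    pos <- which(is.na(rows))[1]
    stop("cannot encode symbol '", res[pos], "' at position ", pos,
         ": not in alphabet ", alphabet_string(alphabet))
  }
  tl <- min(length(res), max_len)
  m <- matrix(0L, nrow = length(alphabet$symbols), ncol = max_len,
              dimnames = list(alphabet$symbols, NULL))
  m[cbind(rows[seq_len(tl)], seq_len(tl))] <- 1L
  structure(m, true_length = tl, class = c("encoded_peptide", class(m)))
}

#' Decode a one-hot peptide matrix back to its sequence
#'
#' Inverse of [encode_peptide()] up to truncation: for sequences of at
#' most 120 residues the round trip is exact; longer sequences decode to
#' their first 120 residues. Malformed encodings (a column within the true
#' length whose entries do not sum to exactly one) are an error.
#'
#' @param encoded An `encoded_peptide` from [encode_peptide()].
#' @param alphabet An [aa_alphabet()].
#' @return The amino-acid string.
#' @export
decode_peptide <- function(encoded, alphabet = aa_alphabet()) {
  tl <- attr(encoded, "true_length")
  stopifnot(is.matrix(encoded), !is.null(tl))
  if (tl == 0L) return("")
  block <- encoded[, seq_len(tl), drop = FALSE]
  ones <- colSums(block)
  if (any(ones != 1L)) {
    stop("malformed encoding: column ", which(ones != 1L)[1],
         " has ", ones[which(ones != 1L)[1]], " ones (expected 1)")
  }
  rows <- apply(block, 2L, which.max)
  paste(alphabet$symbols[rows], collapse = "")
}

#' Encode a peptide set as a batch
#'
#' Encodes every record of a validated [peptide_set()] and returns the
#' batch in the layout consumed by the networks: an `n x 120 x 20` numeric
#' array (sample x position x alphabet channel) plus the aligned label
#' vector. The per-record matrices equal [encode_peptide()] transposed
#' into that layout; order is preserved.
#'
#' @param set A validated [peptide_set()], non-empty.
#' @param alphabet An [aa_alphabet()].
#' @param for_prediction If `FALSE` (training), every record must carry a
#'   0/1 label; if `TRUE`, labels may be absent.
#' @param max_len Number of encoded positions (120).
#' @return An `encoded_batch`: list with `x` (the array), `labels`
#'   (integer vector or `NULL`), `ids`, `lengths` (true, pre-truncation
#'   residue counts) and `alphabet`.
#' @export
encode_batch <- function(set, alphabet = aa_alphabet(),
                         for_prediction = FALSE, max_len = 120L) {
  stopifnot(inherits(set, "peptide_set"))
  if (nrow(set) == 0L) stop("cannot encode an empty peptide set")
  labels <- set$label
  if (!for_prediction) {
    if (anyNA(labels)) stop("training batch contains unlabeled records; ",
                            "label every record or set for_prediction = TRUE")
    labels <- as.integer(labels)
  } else if (all(is.na(labels))) {
    labels <- NULL
  } else if (anyNA(labels)) {
    stop("batch mixes labeled and unlabeled records")
  }
  n <- nrow(set)
  nsym <- length(alphabet$symbols)
  x <- array(0, dim = c(n, max_len, nsym))
  for (i in seq_len(n)) {
    res <- strsplit(set$sequence[i], "")[[1]]
    rows <- alphabet$index_of[res]
    if (anyNA(rows)) {
      pos <- which(is.na(rows))[1]
      stop("record '", set$id[i], "': cannot encode symbol '", res[pos],
           "' at position ", pos)
    }
    tl <- min(length(res), max_len)
    x[cbind(i, seq_len(tl), rows[seq_len(tl)])] <- 1
  }
  structure(
    list(x = x, labels = labels, ids = set$id,
         lengths = nchar(set$sequence), alphabet = alphabet),
    class = "encoded_batch"
  )
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat(sprintf("encoded_batch: %d peptide(s), %d x %d one-hot, %s\n",
              dim(x$x)[1], dim(x$x)[3], dim(x$x)[2],
              if (is.null(x$labels)) "unlabeled" else "labeled"))
  invisible(x)
}

# subset an encoded batch by sample index
batch_subset <- function(batch, idx) {
  structure(
    list(x = batch$x[idx, , , drop = FALSE],
         labels = if (is.null(batch$labels)) NULL else batch$labels[idx],
         ids = batch$ids[idx], lengths = batch$lengths[idx],
         alphabet = batch$alphabet),
    class = "encoded_batch"
  )
}

# stack two encoded batches (same alphabet) along the sample dimension
batch_bind <- function(a, b) {
  stopifnot(identical(a$alphabet$symbols, b$alphabet$symbols))
  na <- dim(a$x)[1]; nb <- dim(b$x)[1]
  x <- array(0, dim = c(na + nb, dim(a$x)[2], dim(a$x)[3]))
  x[seq_len(na), , ] <- a$x
  x[na + seq_len(nb), , ] <- b$x
  labels <- if (is.null(a$labels) || is.null(b$labels)) NULL else
    c(a$labels, b$labels)
  structure(
    list(x = x, labels = labels, ids = c(a$ids, b$ids),
         lengths = c(a$lengths, b$lengths), alphabet = a$alphabet),
    class = "encoded_batch"
  )
}
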