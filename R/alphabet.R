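#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in the fixed order used for
#' the rows of every encoded peptide matrix. The order is alphabetical
#' (`ACDEFGHIKLMNPQRSTVWY`), is serialized into every saved model's
#' metadata, and must match between training and classification.
#'
#' @param symbols Character scalar giving the alphabet as a single string.
#'   Defaults to the canonical alphabetical order; a custom order is only
#'   useful when loading a model trained with one.
#' @return An object of class `aa_alphabet`: a list with `symbols`
#'   (character vector of length 20) and `index_of` (named integer vector
#'   mapping symbol to row index).
#' @examples
#' ab <- aa_alphabet()
#' ab$index_of[["C"]]
#' @export
aa_alphabet <- function(symbols = "ACDEFGHIKLMNPQRSTVWY") {
  stopifnot(is.character(symbols), length(symbols) == 1L)
  sym <- strsplit(symbols, "")[[1]]
  if (length(sym) != 20L || anyDuplicated(sym)) {
    stop("alphabet must contain exactly 20 distinct one-letter codes")
  }
  structure(
    list(symbols = sym, index_of = setNames(seq_along(sym), sym)),
    class = "aa_alphabet"
  )
}

#' @export
format.aa_alphabet <- function(x, ...) {
  paste0("<aa_alphabet: ", paste(x$symbols, collapse = ""), ">")
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

alphabet_string <- function(alphabet) paste(alphabet$symbols, collapse = "")

# regex character class of the canonical residues
canonical_pattern <- function(alphabet = aa_alphabet()) {
  paste0("^[", alphabet_string(alphabet), "]+$")
}
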