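#' Construct a peptide set
#'
#' A peptide set is the package's container for a collection of identified
#' amino-acid sequences with optional binary labels (1 = precursor peptide,
#' 0 = non-precursor) and optional externally supplied HMM-hit flags. It is
#' a data frame with columns `id`, `sequence`, `label`, `hit_flag` plus
#' `name` and `provenance` attributes, so all the usual data-frame verbs
#' apply.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param sequence Character vector of upper-case amino-acid sequences.
#' @param label Optional integer vector of 0/1 class labels (recycled if
#'   scalar), or `NULL` for unlabeled sets.
#' @param hit_flag Optional logical vector of HMM-hit annotations.
#' @param name Short name for the set.
#' @param provenance Free-text note on where the sequences came from.
#' @return A `peptide_set` (data frame).
#' @examples
#' peptide_set(c("a", "b"), c("MKTAY", "MGGLL"), label = 1)
#' @export
peptide_set <- function(id, sequence, label = NULL, hit_flag = NULL,
                        name = "peptides", provenance = "") {
  id <- as.character(id)
  sequence <- as.character(sequence)
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  n <- length(id)
  if (is.null(label)) {
    label <- rep(NA_integer_, n)
  } else {
    label <- as.integer(rep(label, length.out = n))
    bad <- !is.na(label) & !label %in% c(0L, 1L)
    if (any(bad)) stop("labels must be 0 or 1")
  }
  if (is.null(hit_flag)) {
    hit_flag <- rep(NA, n)
  } else {
    hit_flag <- as.logical(rep(hit_flag, length.out = n))
  }
  out <- data.frame(
    id = id, sequence = sequence, label = label, hit_flag = hit_flag,
    stringsAsFactors = FALSE
  )
  attr(out, "name") <- name
  attr(out, "provenance") <- provenance
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf(
    "peptide_set '%s': %d sequence(s)%s\n",
    attr(x, "name") %||% "peptides", nrow(x),
    if (all(is.na(x$label))) "" else
      sprintf(" (%d positive, %d negative)",
              sum(x$label == 1L, na.rm = TRUE),
              sum(x$label == 0L, na.rm = TRUE))
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count labeled classes in a peptide set
#'
#' @param set A [peptide_set()].
#' @return Named integer vector with elements `positive`, `negative`,
#'   `unlabeled`.
#' @export
class_counts <- function(set) {
  c(positive = sum(set$label == 1L, na.rm = TRUE),
    negative = sum(set$label == 0L, na.rm = TRUE),
    unlabeled = sum(is.na(set$label)))
}

#' Read peptide sequences from a FASTA file
#'
#' Reads one record per FASTA entry, in file order. Sequences are
#' upper-cased and a trailing stop character (`*`), as emitted by ORF
#' callers, is stripped. The first whitespace-delimited token of each
#' header is the record id; duplicate ids are an error because downstream
#' predictions are keyed by id. No residue validation happens here — see
#' [validate_and_filter()].
#'
#' @param path Path to an amino-acid FASTA file.
#' @param label Optional 0/1 label applied to every record.
#' @param name Set name; defaults to the file name.
#' @return A [peptide_set()].
#' @export
read_fasta <- function(path, label = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(seqs) == 0L) stop("no FASTA records found in ", path)
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, "", 1L)
  raw <- toupper(as.character(seqs))
  raw <- sub("\\*+$", "", raw)
  if (any(!nzchar(raw))) stop("empty sequence for record(s): ",
                              paste(ids[!nzchar(raw)], collapse = ", "))
  peptide_set(ids, unname(raw), label = label, name = name,
              provenance = paste0("read from ", path))
}

#' Write a peptide set to FASTA
#'
#' @param set A [peptide_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  x <- Biostrings::BStringSet(setNames(set$sequence, set$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Validate residues and length-filter a peptide set
#'
#' Removes records containing any non-canonical residue (e.g. `X`, `B`,
#' `Z`, `J`, `U`, `O`): the one-hot encoding has no 21st symbol, so such
#' records are excluded rather than altered, mirroring how candidate
#' sequences with unknown amino acids are dropped before classification.
#' Records outside the `[min_len, max_len]` length window (bounds
#' inclusive) are removed unless `allow_out_of_range`; sequences longer
#' than 120 residues that are kept this way are truncated later, at
#' encoding time.
#'
#' @param set A [peptide_set()], non-empty.
#' @param min_len,max_len Inclusive length bounds in residues.
#' @param allow_out_of_range Keep records outside the length window.
#' @param alphabet An [aa_alphabet()].
#' @return A list with `set` (the filtered [peptide_set()]) and `report`,
#'   a named integer vector: `input`, `removed_unknown_residue`,
#'   `removed_too_short`, `removed_too_long`, `kept`.
#' @export
validate_and_filter <- function(set, min_len = 20L, max_len = 120L,
                                allow_out_of_range = FALSE,
                                alphabet = aa_alphabet()) {
  stopifnot(inherits(set, "peptide_set"))
  if (nrow(set) == 0L) stop("empty peptide set")
  ok_residues <- grepl(canonical_pattern(alphabet), set$sequence)
  len <- nchar(set$sequence)
  too_short <- ok_residues & len < min_len
  too_long <- ok_residues & len > max_len
  keep <- ok_residues
  if (!allow_out_of_range) keep <- keep & !too_short & !too_long
  report <- c(
    input = nrow(set),
    removed_unknown_residue = sum(!ok_residues),
    removed_too_short = if (allow_out_of_range) 0L else sum(too_short),
    removed_too_long = if (allow_out_of_range) 0L else sum(too_long),
    kept = sum(keep)
  )
  out <- set[keep, , drop = FALSE]
  attr(out, "name") <- attr(set, "name")
  attr(out, "provenance") <- attr(set, "provenance")
  class(out) <- class(set)
  if (nrow(out) == 0L) {
    stop("no records left after validation (",
         report[["removed_unknown_residue"]], " unknown-residue, ",
         report[["removed_too_short"]] + report[["removed_too_long"]],
         " out-of-range removals)")
  }
  list(set = out, report = report)
}

#' Drop duplicate sequences, keeping first occurrences
#'
#' Training corpora collated from several sources contain overlapping
#' sequences; dereplication keeps the first occurrence of each distinct
#' sequence string (case-sensitive, id-blind) and preserves order
#' otherwise. Idempotent.
#'
#' @param set A [peptide_set()].
#' @return The dereplicated [peptide_set()].
#' @export
dereplicate <- function(set) {
  stopifnot(inherits(set, "peptide_set"))
  keep <- !duplicated(set$sequence)
  out <- set[keep, , drop = FALSE]
  attr(out, "name") <- attr(set, "name")
  attr(out, "provenance") <- attr(set, "provenance")
  class(out) <- class(set)
  out
}

#' Write a prediction table to TSV
#'
#' Writes one row per prediction with columns `id`, `length`,
#' `score_negative`, `score_positive`, `call`, scores printed with six
#' decimal places, input order preserved.
#'
#' @param results A prediction data frame as returned by
#'   [classify_fasta()] or [predict_peptides()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  need <- c("id", "length", "score_negative", "score_positive", "call")
  if (!all(need %in% names(results))) {
    stop("prediction table must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    id = results$id,
    length = as.integer(results$length),
    score_negative = sprintf("%.6f", results$score_negative),
    score_positive = sprintf("%.6f", results$score_positive),
    call = results$call,
    stringsAsFactors = FALSE
  )
  con <- suppressWarnings(tryCatch(file(path, "w"), error = function(e)
    stop("cannot write predictions to ", path, ": ", conditionMessage(e))))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path TSV path.
#' @return A data frame with the five prediction columns.
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$length <- as.integer(df$length)
  df$score_negative <- as.numeric(df$score_negative)
  df$score_positive <- as.numeric(df$score_positive)
  df
}
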