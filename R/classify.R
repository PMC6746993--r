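# positive call iff the score strictly exceeds the threshold; exact ties
# resolve to the negative class
call_from_score <- function(score_positive, threshold = 0.5) {
  ifelse(score_positive > threshold, "precursor", "non-precursor")
}

#' Classify a validated peptide set
#'
#' Scores each record with a trained model and calls it `"precursor"`
#' when the positive-class probability strictly exceeds `threshold`
#' (exact ties resolve to `"non-precursor"` — the conservative choice for
#' a discovery filter). At the default threshold 0.5 this equals the
#' argmax call on the normalized 2-vector, ties aside.
#'
#' @param model A `rippnet_model`.
#' @param set A validated [peptide_set()].
#' @param threshold Positive-call threshold in \[0, 1\].
#' @return Data frame with columns `id`, `length`, `score_negative`,
#'   `score_positive`, `call`, in input order.
#' @export
classify_peptides <- function(model, set, threshold = 0.5) {
  stopifnot(inherits(set, "peptide_set"))
  batch <- encode_batch(set, model$alphabet, for_prediction = TRUE,
                        max_len = model$spec$input_length)
  probs <- predict_peptides(model, batch)
  data.frame(
    id = set$id,
    length = nchar(set$sequence),
    score_negative = probs[, "score_negative"],
    score_positive = probs[, "score_positive"],
    call = call_from_score(probs[, "score_positive"], threshold),
    stringsAsFactors = FALSE
  )
}

#' Classify candidate sequences from a FASTA file
#'
#' Reads candidates, silently skips (but counts) records that fail
#' validation — non-canonical residues such as `X`, or lengths outside
#' the 20-120 window unless `allow_out_of_range` — and scores the rest.
#'
#' @param path Candidate FASTA file.
#' @param model A `rippnet_model`, or a directory accepted by
#'   [load_model()].
#' @param threshold Positive-call threshold.
#' @param allow_out_of_range Keep candidates outside the length window
#'   (they are truncated to 120 residues at encoding).
#' @param min_len,max_len Length window.
#' @return List with `predictions` (see [classify_peptides()]) and
#'   `summary`: counts of input, classified, skipped (with the
#'   per-reason validation report) and positive calls.
#' @export
classify_fasta <- function(path, model, threshold = 0.5,
                           allow_out_of_range = FALSE,
                           min_len = 20L, max_len = 120L) {
  if (is.character(model)) model <- load_model(model)
  candidates <- read_fasta(path)
  vf <- validate_and_filter(candidates, min_len = min_len,
                            max_len = max_len,
                            allow_out_of_range = allow_out_of_range,
                            alphabet = model$alphabet)
  predictions <- classify_peptides(model, vf$set, threshold = threshold)
  list(
    predictions = predictions,
    summary = list(
      n_input = nrow(candidates),
      n_classified = nrow(predictions),
      n_skipped = nrow(candidates) - nrow(predictions),
      validation_report = vf$report,
      n_positive_calls = sum(predictions$call == "precursor"),
      threshold = threshold
    )
  )
}

#' HMM-hit enrichment of predicted precursors
#'
#' Given per-sequence predictions and externally supplied binary HMM-hit
#' flags, reports the hit rate in the whole candidate set, among
#' sequences called precursor, and among the rest, plus the fold
#' enrichment: (hit rate among predicted positives) / (overall hit
#' rate). When the overall hit rate is zero the fold enrichment is
#' undefined and reported as `NA`, never as infinity. If every sequence
#' is called positive the enrichment is exactly 1.
#'
#' @param predictions Prediction data frame (needs `id` and `call`).
#' @param hit_flags Named logical/0-1 vector keyed by id, or a two-column
#'   data frame (id, hit). Every prediction id must be present.
#' @return An `enrichment_summary` list: `n`, `n_predicted_positive`,
#'   `hit_rate_overall`, `hit_rate_positive`, `hit_rate_negative`,
#'   `fold_enrichment`.
#' @export
enrichment_report <- function(predictions, hit_flags) {
  stopifnot(is.data.frame(predictions),
            all(c("id", "call") %in% names(predictions)))
  if (is.data.frame(hit_flags)) {
    if (ncol(hit_flags) < 2L) stop("hit table needs columns (id, hit)")
    hit_flags <- setNames(as.logical(as.numeric(hit_flags[[2]])),
                          as.character(hit_flags[[1]]))
  }
  missing <- setdiff(predictions$id, names(hit_flags))
  if (length(missing)) {
    stop("prediction id(s) missing from the hit table: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)",
                                            length(missing) - 10L))
  }
  hits <- as.logical(hit_flags[predictions$id])
  pos <- predictions$call == "precursor"
  rate <- function(x) if (length(x)) mean(x) else NA_real_
  overall <- rate(hits)
  rate_pos <- rate(hits[pos])
  fold <- if (!is.na(rate_pos) && overall > 0) rate_pos / overall else NA_real_
  structure(
    list(
      n = length(hits),
      n_predicted_positive = sum(pos),
      hit_rate_overall = overall,
      hit_rate_positive = rate_pos,
      hit_rate_negative = rate(hits[!pos]),
      fold_enrichment = fold
    ),
    class = "enrichment_summary"
  )
}

#' @export
print.enrichment_summary <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf(
    paste0("enrichment over %d sequence(s): %d called precursor\n",
           "  hit rate overall %s, among positives %s, among negatives %s\n",
           "  fold enrichment: %s\n"),
    x$n, x$n_predicted_positive, pct(x$hit_rate_overall),
    pct(x$hit_rate_positive), pct(x$hit_rate_negative),
    if (is.na(x$fold_enrichment)) "undefined"
    else sprintf("%.2f", x$fold_enrichment)))
  invisible(x)
}

#' Read a two-column id/hit TSV
#'
#' Accepts a header line (`id<TAB>hit`) or none; the second column must
#' be 0/1.
#'
#' @param path TSV path.
#' @return Named logical vector keyed by id.
#' @export
read_hit_flags <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t")[[1]][2])))
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("hit table needs two tab-separated columns")
  vals <- as.numeric(df[[2]])
  if (any(is.na(vals)) || !all(vals %in% c(0, 1))) {
    stop("hit flags must be 0 or 1")
  }
  setNames(as.logical(vals), as.character(df[[1]]))
}
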