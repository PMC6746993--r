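# Shipped example data. All fixtures regenerate byte-identically from
# recorded seeds via the synthetic generator; a checksum manifest guards
# against silent drift.

FIXTURE_SEED_TRAIN <- 42L
FIXTURE_SEED_CANDIDATES <- 43L

.fixture_sets <- function() {
  train <- generate_peptides(synthetic_spec(60L, 120L,
                                            seed = FIXTURE_SEED_TRAIN))
  cand <- generate_peptides(synthetic_spec(15L, 25L,
                                           seed = FIXTURE_SEED_CANDIDATES))
  n_cand <- nrow(cand$positives) + nrow(cand$negatives)
  candidates <- peptide_set(
    sprintf("cand_%04d", seq_len(n_cand + 2L)),
    c(cand$positives$sequence, cand$negatives$sequence,
      # two deliberately invalid candidates: an unknown residue and a
      # too-short sequence, exercising the skip-and-count path
      "MKTXAYLLVVAGGTTSSDDEE", "MKTAY"),
    name = "example_candidates",
    provenance = "synthetic candidates; last two records fail validation"
  )
  hits <- data.frame(
    id = candidates$id,
    hit = as.integer(seq_len(n_cand + 2L) <= nrow(cand$positives)),
    stringsAsFactors = FALSE
  )
  list(train = train, candidates = candidates, hits = hits)
}

.fixture_files <- c("example_positives.fasta", "example_negatives.fasta",
                    "example_candidates.fasta", "example_hits.tsv")

#' Regenerate the shipped example fixtures
#'
#' Rebuilds the example FASTA/TSV files from their recorded seeds and
#' writes a checksum manifest (`MANIFEST.txt`). Intended for package
#' maintenance and for verifying that shipped fixtures match their
#' generators ([verify_fixtures()]).
#'
#' @param dir Output directory.
#' @return Invisibly, the manifest as a named character vector of MD5s.
#' @export
regenerate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- .fixture_sets()
  write_fasta(sets$train$positives, file.path(dir, "example_positives.fasta"))
  write_fasta(sets$train$negatives, file.path(dir, "example_negatives.fasta"))
  write_fasta(sets$candidates, file.path(dir, "example_candidates.fasta"))
  write.table(sets$hits, file.path(dir, "example_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sums <- tools::md5sum(file.path(dir, .fixture_files))
  names(sums) <- .fixture_files
  writeLines(sprintf("%s  %s", sums, names(sums)),
             file.path(dir, "MANIFEST.txt"))
  invisible(sums)
}

#' Verify shipped fixtures against their manifest
#'
#' Recomputes each fixture's MD5 and compares it with `MANIFEST.txt`,
#' failing with the name of the first drifted fixture.
#'
#' @param dir Fixture directory; defaults to the installed copies.
#' @return `TRUE`, invisibly, if everything matches.
#' @export
verify_fixtures <- function(dir = system.file("extdata", package = "rippnet")) {
  manifest_path <- file.path(dir, "MANIFEST.txt")
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- read.table(manifest_path, header = FALSE,
                         col.names = c("md5", "file"),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) stop("fixture missing: ", manifest$file[i])
    actual <- unname(tools::md5sum(f))
    if (!identical(actual, manifest$md5[i])) {
      stop("fixture checksum mismatch: ", manifest$file[i])
    }
  }
  invisible(TRUE)
}
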