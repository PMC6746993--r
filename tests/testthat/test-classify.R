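extdata <- function(...) system.file("extdata", ..., package = "rippnet")

# one small trained model on the shipped example corpus, reused below
example_model_dir <- function() {
  memo("example_model_dir", function() {
    out <- file.path(tempdir(), "example_run")
    cli_train(c("--positives", extdata("example_positives.fasta"),
                "--negatives", extdata("example_negatives.fasta"),
                "--arch", "cnn_linear", "--out", out,
                "--seed", "3", "--max-rounds", "6", "--patience", "6",
                "--subsample-fraction", "0.5", "--batch-size", "8",
                "--quiet"))
    file.path(out, "model")
  })
}

test_that("cli_train writes model, history log and config echo", {
  dir <- dirname(example_model_dir())
  expect_true(file.exists(file.path(dir, "model", "metadata.json")))
  expect_true(file.exists(file.path(dir, "model", "weights.rds")))
  expect_true(file.exists(file.path(dir, "history.log")))
  expect_true(file.exists(file.path(dir, "config.json")))
  log <- readLines(file.path(dir, "history.log"))
  expect_true(any(grepl("^# seed: 3$", log)))
  expect_true(any(grepl("^round\t", log)))
})

test_that("two train runs with the same inputs and seed are byte-identical", {
  run <- function(out) {
    cli_train(c("--positives", extdata("example_positives.fasta"),
                "--negatives", extdata("example_negatives.fasta"),
                "--arch", "cnn_linear", "--out", out,
                "--seed", "5", "--max-rounds", "3", "--patience", "3",
                "--subsample-fraction", "0.5", "--batch-size", "8",
                "--quiet"))
    file.path(out, "history.log")
  }
  log1 <- run(tempfile("runA_"))
  log2 <- run(tempfile("runB_"))
  expect_identical(readBin(log1, "raw", file.size(log1)),
                   readBin(log2, "raw", file.size(log2)))
})

test_that("training on an empty-after-filtering set fails cleanly", {
  bad_neg <- write_raw_fasta(list(n1 = "MKXT", n2 = "MMX"))
  out <- tempfile("fail_")
  expect_error(
    cli_train(c("--positives", extdata("example_positives.fasta"),
                "--negatives", bad_neg, "--out", out, "--quiet")),
    "no records left")
  expect_false(dir.exists(out))
})

test_that("classification skips invalid candidates and counts them", {
  res <- classify_fasta(extdata("example_candidates.fasta"),
                        example_model_dir())
  expect_identical(res$summary$n_input, 42L)
  expect_identical(res$summary$n_skipped, 2L)
  expect_identical(nrow(res$predictions), 40L)
  expect_identical(
    unname(res$summary$validation_report[["removed_unknown_residue"]]), 1L)
  expect_identical(
    unname(res$summary$validation_report[["removed_too_short"]]), 1L)
  expect_true(all(abs(res$predictions$score_negative +
                        res$predictions$score_positive - 1) < 1e-6))
})

test_that("extreme thresholds and the argmax rule behave as specified", {
  res1 <- classify_fasta(extdata("example_candidates.fasta"),
                         example_model_dir(), threshold = 1.0)
  expect_identical(res1$summary$n_positive_calls, 0L)

  res <- classify_fasta(extdata("example_candidates.fasta"),
                        example_model_dir())
  argmax <- ifelse(res$predictions$score_positive >
                     res$predictions$score_negative,
                   "precursor", "non-precursor")
  ties <- res$predictions$score_positive == res$predictions$score_negative
  expect_identical(res$predictions$call[!ties], argmax[!ties])
})

test_that("cli_classify writes the prediction TSV and cli_enrich the report", {
  out_tsv <- tempfile(fileext = ".tsv")
  cli_classify(c("--input", extdata("example_candidates.fasta"),
                 "--model", example_model_dir(),
                 "--out", out_tsv, "--quiet"))
  preds <- read_predictions(out_tsv)
  expect_identical(nrow(preds), 40L)

  out_txt <- tempfile(fileext = ".txt")
  summ <- cli_enrich(c("--predictions", out_tsv,
                       "--hits", extdata("example_hits.tsv"),
                       "--out", out_txt, "--quiet"))
  lines <- readLines(out_txt)
  expect_true(any(grepl("^fold_enrichment\t", lines)))
  expect_identical(summ$n, 40L)
})

test_that("fold enrichment equals the brute-force ratio of hit rates", {
  withr::with_seed(50, {
    preds <- data.frame(
      id = sprintf("c%03d", 1:100),
      call = sample(c("precursor", "non-precursor"), 100, replace = TRUE,
                    prob = c(0.3, 0.7)),
      stringsAsFactors = FALSE
    )
    hits <- setNames(runif(100) < ifelse(preds$call == "precursor",
                                         0.4, 0.05), preds$id)
  })
  summ <- enrichment_report(preds, hits)
  pos <- preds$call == "precursor"
  expect_equal(summ$hit_rate_overall, mean(hits))
  expect_equal(summ$hit_rate_positive, mean(hits[pos]))
  expect_equal(summ$fold_enrichment, mean(hits[pos]) / mean(hits))
})

test_that("enrichment handles the degenerate cases", {
  preds <- data.frame(id = c("a", "b", "c"),
                      call = c("precursor", "precursor", "precursor"),
                      stringsAsFactors = FALSE)
  hits <- c(a = TRUE, b = FALSE, c = TRUE)
  # every sequence called positive: enrichment is exactly 1
  expect_identical(enrichment_report(preds, hits)$fold_enrichment, 1)

  none <- c(a = FALSE, b = FALSE, c = FALSE)
  summ <- enrichment_report(preds, none)
  expect_identical(summ$hit_rate_overall, 0)
  expect_true(is.na(summ$fold_enrichment))

  expect_error(enrichment_report(preds, c(a = TRUE)), "missing.*b")
})

test_that("cli_synth writes a reproducible FASTA pair", {
  prefix <- tempfile("synth_")
  cli_synth(c("--out-prefix", prefix, "--n-pos", "10", "--ratio", "3",
              "--seed", "12", "--quiet"))
  pos <- read_fasta(paste0(prefix, "_positives.fasta"))
  neg <- read_fasta(paste0(prefix, "_negatives.fasta"))
  expect_identical(nrow(pos), 10L)
  expect_identical(nrow(neg), 30L)
  sets <- generate_imbalanced(synthetic_spec(10, 10, seed = 12L), ratio = 3L)
  expect_identical(pos$sequence, sets$positives$sequence)
})

test_that("unknown subcommands are rejected", {
  expect_error(cli_main("frobnicate"), "unknown subcommand")
})
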