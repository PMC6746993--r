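# Shared fixtures built in code. Heavy objects are memoized for the
# lifetime of the test run so several test files can share one training
# run instead of repeating it.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# write a FASTA from raw header/sequence pairs (exercises the reader on
# hand-built input, independent of write_fasta)
write_raw_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(h) {
    c(paste0(">", h), entries[[h]])
  })), path)
  path
}

random_peptides <- function(n, lengths, seed = 1) {
  withr::with_seed(seed, {
    vapply(sample(lengths, n, replace = TRUE), function(len) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                   replace = TRUE), collapse = "")
    }, "")
  })
}

# small, perfectly separable dataset (noise-free motif) shared by the
# capacity and normalization tests
toy_separable_sets <- function() {
  memo("toy_separable", function() {
    generate_peptides(synthetic_spec(25L, 25L, substitution_prob = 0,
                                     seed = 3L))
  })
}

# one quick trained model per architecture (a single optimization round
# on the toy set) for "trained model" checks
quick_trained_model <- function(arch) {
  memo(paste0("quick_", arch), function() {
    sets <- toy_separable_sets()
    cfg <- training_config(max_rounds = 1L, patience = 1L, seed = 2L,
                           negative_subsample_fraction = 0.99,
                           train_fraction = 0.8)
    train_model(build_model(model_spec(arch), seed = 2L),
                sets$positives, sets$negatives, cfg)$model
  })
}

# the full-scale synthetic study: 300 positives at 7:1 imbalance,
# parallel CNN, reduced round budget; shared by the training-contract
# and learnability checks
study_training_run <- function() {
  memo("study_run", function() {
    sets <- generate_imbalanced(synthetic_spec(300L, 300L, seed = 11L),
                                ratio = 7L)
    cfg <- training_config(max_rounds = 40L, patience = 20L, seed = 11L)
    model <- build_model(model_spec("cnn_parallel"), seed = 11L)
    list(sets = sets,
         result = train_model(model, sets$positives, sets$negatives, cfg),
         config = cfg)
  })
}
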