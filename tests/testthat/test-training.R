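test_that("training_config enforces its invariants", {
  expect_error(training_config(negative_subsample_fraction = 1), "fractions")
  expect_error(training_config(train_fraction = 0), "fractions")
  expect_error(training_config(patience = 300, max_rounds = 200),
               "patience")
  expect_error(training_config(optimizer_name = "sgd"), "adam")
  cfg <- training_config()
  expect_identical(cfg$resample_interval, 5L)
  expect_identical(cfg$patience, 50L)
  expect_identical(cfg$max_rounds, 200L)
})

test_that("negative subsampling takes floor(fraction * n) without replacement", {
  neg <- peptide_set(sprintf("n%02d", 1:10), random_peptides(10, 20:40))
  sub <- subsample_negatives(neg, 0.35, seed = 1L)
  expect_identical(nrow(sub), 3L)
  expect_true(all(sub$id %in% neg$id))
  expect_false(anyDuplicated(sub$id) > 0)

  expect_error(subsample_negatives(neg, 0.05), "empty")
  expect_error(subsample_negatives(neg, 1.2), "fraction")
})

test_that("subsampling is deterministic per seed and varies across seeds", {
  neg <- peptide_set(sprintf("n%03d", 1:200), random_peptides(200, 20:40))
  draws <- lapply(1:20, function(s) {
    subsample_negatives(neg, 0.35, seed = s)$id
  })
  again <- lapply(1:20, function(s) {
    subsample_negatives(neg, 0.35, seed = s)$id
  })
  expect_identical(draws, again)
  expect_gt(length(unique(vapply(draws, paste, "", collapse = ","))), 15)
})

test_that("a 35% negative subsample reproduces the reference cycle size", {
  neg <- peptide_set(sprintf("n%05d", 1:19224),
                     rep(strrep("A", 25), 19224) , label = 0L)
  sub <- subsample_negatives(neg, 0.35, seed = 1L)
  expect_identical(nrow(sub), 6728L)
  expect_identical(nrow(sub) + 2726L, 9454L)
})

test_that("the train/held-out split is stratified, disjoint and exhaustive", {
  seqs <- random_peptides(100, 20:60, seed = 41)
  set <- peptide_set(sprintf("s%03d", 1:100), seqs,
                     label = rep(c(1L, 0L), c(20, 80)))
  batch <- encode_batch(set)
  sp <- split_train_heldout(batch, 0.85, seed = 1L)
  expect_identical(sum(sp$train$labels == 1L), 17L)
  expect_identical(length(sp$train$labels), 85L)
  expect_identical(length(sp$heldout$labels), 15L)
  expect_length(intersect(sp$train$ids, sp$heldout$ids), 0)
  expect_setequal(c(sp$train$ids, sp$heldout$ids), set$id)

  unlab <- encode_batch(peptide_set("a", strrep("M", 30)),
                        for_prediction = TRUE)
  expect_error(split_train_heldout(unlab), "unlabeled")
  onecls <- encode_batch(peptide_set(c("a", "b"),
                                     c(strrep("M", 30), strrep("A", 30)),
                                     label = 1L))
  expect_error(split_train_heldout(onecls), "both classes")
})

test_that("per-class train counts equal the floor of the fraction everywhere", {
  withr::with_seed(77, {
    for (rep in 1:50) {
      n_pos <- sample(5:40, 1)
      n_neg <- sample(5:40, 1)
      frac <- runif(1, 0.5, 0.9)
      set <- peptide_set(sprintf("s%03d", seq_len(n_pos + n_neg)),
                         random_peptides(n_pos + n_neg, 20:40, seed = rep),
                         label = rep(c(1L, 0L), c(n_pos, n_neg)))
      sp <- tryCatch(split_train_heldout(encode_batch(set), frac),
                     error = function(e) NULL)
      if (is.null(sp)) next
      expect_identical(sum(sp$train$labels == 1L),
                       as.integer(floor(frac * n_pos)))
      expect_identical(sum(sp$train$labels == 0L),
                       as.integer(floor(frac * n_neg)))
      expect_identical(length(sp$train$labels) + length(sp$heldout$labels),
                       n_pos + n_neg)
    }
  })
})

test_that("majority baseline is the larger class fraction", {
  expect_equal(majority_baseline(2726, 19224), 19224 / 21950)
  expect_identical(round(100 * majority_baseline(2726, 19224), 1), 87.6)
  expect_equal(majority_baseline(5, 5), 0.5)
  expect_equal(majority_baseline(0, 7), 1)
  expect_error(majority_baseline(0, 0), "non-empty")
})

test_that("evaluate_model matches a brute-force counting oracle", {
  set <- peptide_set(sprintf("s%02d", 1:30),
                     random_peptides(30, 20:120, seed = 43),
                     label = rep(c(1L, 0L), 15))
  batch <- encode_batch(set)
  for (arch in c("lstm", "cnn_linear")) {
    model <- build_model(model_spec(arch), seed = 5L)
    rep_ <- evaluate_model(model, batch)
    probs <- predict_peptides(model, batch)
    calls <- as.integer(probs[, "score_positive"] > 0.5)
    correct <- calls == set$label
    expect_equal(rep_$positive_accuracy, mean(correct[set$label == 1L]))
    expect_equal(rep_$negative_accuracy, mean(correct[set$label == 0L]))
    expect_equal(rep_$total_accuracy, mean(correct))
    expect_identical(sum(rep_$counts[c("correct_positive",
                                       "correct_negative")]),
                     sum(correct))
  }
  unlab <- encode_batch(peptide_set("a", strrep("M", 30)),
                        for_prediction = TRUE)
  expect_error(evaluate_model(build_model(model_spec("lstm"), seed = 1),
                              unlab), "unlabeled")
})

test_that("a perfect classifier scores 1.0 on all three accuracies", {
  sets <- toy_separable_sets()
  model <- quick_trained_model("cnn_linear")
  comb <- peptide_set(c(sets$positives$id, sets$negatives$id),
                      c(sets$positives$sequence, sets$negatives$sequence),
                      label = c(sets$positives$label, sets$negatives$label))
  rep_ <- evaluate_model(model, encode_batch(comb))
  if (rep_$total_accuracy == 1) {
    expect_equal(rep_$positive_accuracy, 1)
    expect_equal(rep_$negative_accuracy, 1)
  }
  # the identity always holds, perfect or not
  expect_equal(rep_$total_accuracy,
               (rep_$counts[["correct_positive"]] +
                  rep_$counts[["correct_negative"]]) /
                 sum(rep_$counts[c("n_positive", "n_negative")]))
})

test_that("resampling happens at round 1 and every interval thereafter", {
  sets <- toy_separable_sets()
  cfg <- training_config(max_rounds = 11L, patience = 11L, seed = 6L,
                         resample_interval = 5L,
                         negative_subsample_fraction = 0.5,
                         train_fraction = 0.8)
  res <- train_model(build_model(model_spec("cnn_linear"), seed = 6L),
                     sets$positives, sets$negatives, cfg)
  expect_identical(which(res$history$resampled), c(1L, 6L, 11L))
})

test_that("checkpoints are strictly increasing and best weights are returned", {
  run <- study_training_run()
  hist <- run$result$history
  ck <- hist$heldout_accuracy[hist$checkpointed]
  expect_true(all(diff(ck) > 0))
  expect_equal(max(hist$heldout_accuracy), run$result$best_accuracy)
  expect_identical(hist$round[which.max(hist$heldout_accuracy)],
                   run$result$best_round)
  # returned weights reproduce the checkpointed accuracy on the recorded
  # held-out partition
  re_eval <- evaluate_model(run$result$model, run$result$best_heldout)
  expect_equal(re_eval$total_accuracy, run$result$best_accuracy)
})

test_that("patience stops the loop one round after a perfect first round", {
  sets <- toy_separable_sets()
  cfg <- training_config(max_rounds = 30L, patience = 1L, seed = 2L,
                         batch_size = 8L, learning_rate = 3e-3,
                         negative_subsample_fraction = 0.99,
                         train_fraction = 0.8)
  res <- train_model(build_model(model_spec("cnn_linear"), seed = 2L),
                     sets$positives, sets$negatives, cfg)
  expect_identical(res$stop_reason, "patience")
  expect_identical(nrow(res$history), res$best_round + 1L)
  if (res$history$heldout_accuracy[1] == 1) {
    expect_identical(nrow(res$history), 2L)
  }
})

test_that("training aborts with the round index on non-finite loss", {
  sets <- toy_separable_sets()
  model <- build_model(model_spec("cnn_linear"), seed = 2L)
  # overflow the classification layer so the logits go infinite and the
  # loss turns NaN on the very first minibatch
  model$params[["classify.W"]][] <- 1e308
  cfg <- training_config(max_rounds = 2L, patience = 2L, seed = 2L,
                         negative_subsample_fraction = 0.99,
                         train_fraction = 0.8)
  expect_error(train_model(model, sets$positives, sets$negatives, cfg),
               "non-finite training loss in round 1")
})

test_that("identical data, config and seed reproduce the history exactly", {
  sets <- toy_separable_sets()
  cfg <- training_config(max_rounds = 3L, patience = 3L, seed = 13L,
                         negative_subsample_fraction = 0.5,
                         train_fraction = 0.8)
  r1 <- train_model(build_model(model_spec("cnn_linear"), seed = 13L),
                    sets$positives, sets$negatives, cfg)
  r2 <- train_model(build_model(model_spec("cnn_linear"), seed = 13L),
                    sets$positives, sets$negatives, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})
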