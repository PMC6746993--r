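#' Training-loop configuration
#'
#' Bundles every constant of the training procedure: the negative class is
#' subsampled to 35% each cycle to counter the roughly 7:1 imbalance of
#' genome-mining corpora, 85% of each cycle's set trains the network
#' (sparse cross-entropy loss, Adam) and the remaining 15% measures total
#' accuracy, the negative subsample is redrawn every 5 rounds, and
#' optimization halts after 50 rounds without improvement or 200 rounds
#' overall.
#'
#' @param negative_subsample_fraction Fraction of the negative set drawn
#'   each cycle.
#' @param train_fraction Fraction of each cycle's set used for weight
#'   optimization; the rest is the held-out accuracy set.
#' @param resample_interval Rounds between redraws of the negative
#'   subsample (the first round always draws one).
#' @param patience Rounds without held-out improvement before stopping.
#' @param max_rounds Hard cap on optimization rounds.
#' @param seed Integer seed controlling subsampling, splitting, shuffling
#'   and dropout; recorded in every run log.
#' @param batch_size Minibatch size of one optimization pass.
#' @param learning_rate Adam step size.
#' @param optimizer_name,loss_name Recorded in the config echo; only
#'   `"adam"` and `"sparse_cross_entropy"` are implemented.
#' @return A `training_config` list.
#' @export
training_config <- function(negative_subsample_fraction = 0.35,
                            train_fraction = 0.85,
                            resample_interval = 5L,
                            patience = 50L,
                            max_rounds = 200L,
                            seed = 1L,
                            batch_size = 32L,
                            learning_rate = 1e-3,
                            optimizer_name = "adam",
                            loss_name = "sparse_cross_entropy") {
  cfg <- list(
    negative_subsample_fraction = as.numeric(negative_subsample_fraction),
    train_fraction = as.numeric(train_fraction),
    resample_interval = as.integer(resample_interval),
    patience = as.integer(patience),
    max_rounds = as.integer(max_rounds),
    seed = as.integer(seed),
    batch_size = as.integer(batch_size),
    learning_rate = as.numeric(learning_rate),
    optimizer_name = optimizer_name,
    loss_name = loss_name
  )
  if (cfg$negative_subsample_fraction <= 0 ||
      cfg$negative_subsample_fraction >= 1 ||
      cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    stop("fractions must lie strictly between 0 and 1")
  }
  if (cfg$patience > cfg$max_rounds) stop("patience must not exceed max_rounds")
  if (cfg$resample_interval < 1L || cfg$max_rounds < 1L ||
      cfg$batch_size < 1L) {
    stop("resample_interval, max_rounds and batch_size must be positive")
  }
  if (!identical(optimizer_name, "adam")) {
    stop("only the 'adam' optimizer is implemented")
  }
  structure(cfg, class = "training_config")
}

#' Draw a random subsample of the negative set
#'
#' Uniform sampling without replacement of `floor(fraction * n)` records.
#' With 19224 negatives at the default 0.35 this yields 6728 sequences,
#' which together with a full positive set of 2726 gives the 9454-sequence
#' training cycle of the reference corpus.
#'
#' @param negatives A [peptide_set()] of negative records.
#' @param fraction Subsample fraction in (0, 1).
#' @param seed Optional integer; when given the draw is made from a
#'   private RNG stream, otherwise from the current global stream.
#' @return A [peptide_set()] with the sampled records (input order).
#' @export
subsample_negatives <- function(negatives, fraction = 0.35, seed = NULL) {
  stopifnot(inherits(negatives, "peptide_set"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(negatives)
  size <- floor(fraction * n)
  if (size < 1L) stop("subsample of ", n, " records at fraction ", fraction,
                      " would be empty")
  idx <- sort(local_seed(seed, sample.int(n, size)))
  out <- negatives[idx, , drop = FALSE]
  attr(out, "name") <- attr(negatives, "name")
  attr(out, "provenance") <- attr(negatives, "provenance")
  class(out) <- class(negatives)
  out
}

#' Stratified train/held-out split of a labeled batch
#'
#' Splits an encoded, labeled batch so that `train_fraction` of each class
#' (floor per class) lands in the training partition; the partitions are
#' disjoint, exhaustive, and preserve the class ratio to within one record
#' per class.
#'
#' @param batch A labeled `encoded_batch`.
#' @param train_fraction Fraction per class assigned to training.
#' @param seed Optional integer for a private RNG stream.
#' @return List with elements `train` and `heldout` (both `encoded_batch`).
#' @export
split_train_heldout <- function(batch, train_fraction = 0.85, seed = NULL) {
  stopifnot(inherits(batch, "encoded_batch"))
  if (is.null(batch$labels)) stop("batch is unlabeled")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (!all(c(0L, 1L) %in% batch$labels)) {
    stop("both classes must be present to stratify the split")
  }
  train_idx <- local_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      members <- which(batch$labels == cl)
      take <- floor(train_fraction * length(members))
      if (take < 1L || take >= length(members)) {
        stop("class ", cl, " too small to split at fraction ", train_fraction)
      }
      sample(members, take)
    }))
  })
  train_idx <- sort(train_idx)
  heldout_idx <- setdiff(seq_along(batch$labels), train_idx)
  list(train = batch_subset(batch, train_idx),
       heldout = batch_subset(batch, heldout_idx))
}

# one epoch of minibatch Adam over a labeled batch; returns mean loss
run_epoch <- function(model, batch, adam, learning_rate, batch_size, round) {
  n <- dim(batch$x)[1]
  order <- sample.int(n)
  total_loss <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- order[start:min(start + batch_size - 1L, n)]
    xb <- batch$x[idx, , , drop = FALSE]
    yb <- batch$labels[idx]
    fwd <- net_forward(model$layers, model$params, xb, train = TRUE)
    lo <- softmax_xent(fwd$y, yb)
    if (!is.finite(lo$loss)) {
      stop("non-finite training loss in round ", round,
           " (minibatch starting at ", start, ")")
    }
    bwd <- net_backward(model$layers, model$params, fwd$caches, lo$dlogits)
    upd <- adam_step(model$params, bwd$grads, adam, lr = learning_rate)
    model$params <- upd$params
    adam <- upd$state
    total_loss <- total_loss + lo$loss * length(idx)
  }
  list(model = model, adam = adam, loss = total_loss / n)
}

# held-out total accuracy at the 0.5 threshold (ties -> negative)
heldout_accuracy <- function(model, batch) {
  probs <- predict_peptides(model, batch)
  calls <- as.integer(probs[, "score_positive"] > 0.5)
  mean(calls == batch$labels)
}

#' Train a classifier with negative resampling and checkpointing
#'
#' Runs the round-based optimization loop: at round 1 and every
#' `resample_interval` rounds thereafter, a fresh random subsample of the
#' negative set is drawn, combined with the full positive set, and
#' re-split 85/15; each round then performs one epoch of minibatch Adam
#' over the training partition and evaluates total accuracy on the
#' held-out partition. Weights are checkpointed whenever held-out accuracy
#' strictly improves on the running best, and the loop stops after
#' `patience` rounds without improvement or at `max_rounds`. The returned
#' model carries the checkpointed (best) weights, not the final-round
#' weights.
#'
#' The whole loop is driven by `config$seed`, so identical inputs and
#' configuration reproduce the history exactly.
#'
#' @param model An untrained (or pre-seeded) `rippnet_model` from
#'   [build_model()].
#' @param positives,negatives Validated [peptide_set()]s; the full
#'   positive set is used every cycle.
#' @param config A [training_config()].
#' @param log_path Optional path; when given, a tab-separated
#'   line-per-round run log is written there.
#' @param quiet Suppress per-round progress on the diagnostic stream.
#' @return A list of class `training_result`: `model` (best weights),
#'   `history` (data frame: round, loss, heldout_accuracy, checkpointed,
#'   resampled), `best_accuracy`, `best_round`, `stop_reason`
#'   (`"patience"` or `"max_rounds"`), and `best_heldout` (the held-out
#'   partition in force when the best checkpoint was taken).
#' @export
train_model <- function(model, positives, negatives, config = training_config(),
                        log_path = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "rippnet_model"),
            inherits(config, "training_config"))
  if (nrow(positives) == 0L || nrow(negatives) == 0L) {
    stop("positive and negative sets must both be non-empty")
  }
  pos_batch <- encode_batch(peptide_set(positives$id, positives$sequence,
                                        label = 1L),
                            model$alphabet, max_len = model$spec$input_length)
  neg_all <- encode_batch(peptide_set(negatives$id, negatives$sequence,
                                      label = 0L),
                          model$alphabet, max_len = model$spec$input_length)
  local_seed(config$seed, {
    adam <- adam_init(model$params)
    best_params <- NULL
    best_acc <- -Inf
    best_round <- 0L
    best_heldout <- NULL
    history <- vector("list", config$max_rounds)
    stop_reason <- "max_rounds"
    split <- NULL
    n_neg <- length(neg_all$labels)
    sub_size <- floor(config$negative_subsample_fraction * n_neg)
    if (sub_size < 1L) stop("negative subsample would be empty")
    for (r in seq_len(config$max_rounds)) {
      resampled <- (r - 1L) %% config$resample_interval == 0L
      if (resampled) {
        idx <- sort(sample.int(n_neg, sub_size))
        cycle <- batch_bind(pos_batch, batch_subset(neg_all, idx))
        split <- split_train_heldout(cycle, config$train_fraction)
      }
      ep <- run_epoch(model, split$train, adam, config$learning_rate,
                      config$batch_size, r)
      model <- ep$model
      adam <- ep$adam
      acc <- heldout_accuracy(model, split$heldout)
      checkpointed <- acc > best_acc
      if (checkpointed) {
        best_acc <- acc
        best_round <- r
        best_params <- model$params
        best_heldout <- split$heldout
      }
      history[[r]] <- data.frame(
        round = r, loss = ep$loss, heldout_accuracy = acc,
        checkpointed = checkpointed, resampled = resampled
      )
      if (!quiet) {
        message(sprintf(
          "round %3d  loss %.6f  heldout acc %.4f%s%s",
          r, ep$loss, acc, if (checkpointed) "  *" else "",
          if (resampled) "  [resampled]" else ""))
      }
      if (r - best_round >= config$patience) {
        stop_reason <- "patience"
        history <- history[seq_len(r)]
        break
      }
    }
    history <- do.call(rbind, history[!vapply(history, is.null, TRUE)])
    model$params <- best_params
    model$metadata$training_run <- list(
      seed = config$seed, rounds_run = nrow(history),
      best_round = best_round, best_accuracy = best_acc,
      stop_reason = stop_reason
    )
    if (!is.null(log_path)) {
      write_history_log(history, config, log_path)
    }
    structure(
      list(model = model, history = history, best_accuracy = best_acc,
           best_round = best_round, stop_reason = stop_reason,
           best_heldout = best_heldout),
      class = "training_result"
    )
  })
}

#' @export
print.training_result <- function(x, ...) {
  cat(sprintf(
    "training_result: %d round(s), best held-out accuracy %.4f at round %d (stopped: %s)\n",
    nrow(x$history), x$best_accuracy, x$best_round, x$stop_reason))
  invisible(x)
}

# deterministic text log: config echo then one line per round
write_history_log <- function(history, config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(config)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(config[[nm]], digits = 15),
                             collapse = ",")), con)
  }
  writeLines("round\tloss\theldout_accuracy\tcheckpointed\tresampled", con)
  writeLines(sprintf("%d\t%.6f\t%.6f\t%d\t%d",
                     history$round, history$loss, history$heldout_accuracy,
                     as.integer(history$checkpointed),
                     as.integer(history$resampled)), con)
  invisible(path)
}

#' Per-class and total accuracy of a classifier
#'
#' Because candidate corpora are heavily imbalanced, total accuracy alone
#' is misleading (see [majority_baseline()]); this reports positive-set,
#' negative-set and total accuracy with their underlying counts.
#'
#' @param model A `rippnet_model`.
#' @param batch A labeled `encoded_batch`.
#' @return An `accuracy_report` list: `positive_accuracy`,
#'   `negative_accuracy`, `total_accuracy`, and `counts` (named integer
#'   vector: n_positive, n_negative, correct_positive, correct_negative).
#' @export
evaluate_model <- function(model, batch) {
  stopifnot(inherits(batch, "encoded_batch"))
  if (is.null(batch$labels)) stop("cannot evaluate an unlabeled batch")
  probs <- predict_peptides(model, batch)
  calls <- as.integer(probs[, "score_positive"] > 0.5)
  pos <- batch$labels == 1L
  counts <- c(
    n_positive = sum(pos), n_negative = sum(!pos),
    correct_positive = sum(calls[pos] == 1L),
    correct_negative = sum(calls[!pos] == 0L)
  )
  structure(
    list(
      positive_accuracy = if (counts[["n_positive"]] > 0)
        counts[["correct_positive"]] / counts[["n_positive"]] else NA_real_,
      negative_accuracy = if (counts[["n_negative"]] > 0)
        counts[["correct_negative"]] / counts[["n_negative"]] else NA_real_,
      total_accuracy = (counts[["correct_positive"]] +
                          counts[["correct_negative"]]) / sum(pos | !pos),
      counts = counts
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "accuracy: positive %.4f (%d/%d)  negative %.4f (%d/%d)  total %.4f\n",
    x$positive_accuracy, x$counts[["correct_positive"]],
    x$counts[["n_positive"]], x$negative_accuracy,
    x$counts[["correct_negative"]], x$counts[["n_negative"]],
    x$total_accuracy))
  invisible(x)
}

#' Majority-class accuracy baseline
#'
#' The total accuracy achieved by labeling every sequence with the larger
#' class — e.g. 87.6% on a corpus of 2726 positives and 19224 negatives.
#' Any useful classifier must beat this on an imbalanced set.
#'
#' @param positive_count,negative_count Non-negative class sizes (not both
#'   zero).
#' @return The baseline accuracy as a fraction.
#' @export
majority_baseline <- function(positive_count, negative_count) {
  stopifnot(positive_count >= 0, negative_count >= 0)
  total <- positive_count + negative_count
  if (total == 0) stop("at least one class must be non-empty")
  max(positive_count, negative_count) / total
}
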