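ARCHITECTURES <- c("lstm", "cnn_linear", "cnn_parallel",
                   "cnn_linear_lstm", "cnn_parallel_lstm")

MODEL_FORMAT_VERSION <- "1.0"

#' Declare a classifier architecture
#'
#' Resolves an architecture name and its hyperparameters into a validated
#' specification. Five architectures are available:
#'
#' * `lstm` — a single bidirectional LSTM (60 cells, 0.15 recurrent
#'   dropout), then a 60-unit dense layer.
#' * `cnn_linear` — three successive convolutions, max-pooled in groups
#'   of 2, then a 40-unit dense layer.
#' * `cnn_parallel` — three parallel branches (kernel sizes 3/6/9), each
#'   two stacked convolutions with a max-pool between them, concatenated
#'   and merged by a 150-filter kernel-3 convolution, max-pooled in
#'   groups of 3, then a 60-unit dense layer.
#' * `cnn_linear_lstm` / `cnn_parallel_lstm` — the corresponding CNN with
#'   a 60-cell LSTM inserted before its dense layer.
#'
#' Every variant ends in a 0.5-rate dropout layer and a 2-unit softmax
#' classification layer whose output sums to 1 and is read as
#' (P(non-precursor), P(precursor)). The linear CNN's filter/kernel sizes
#' and the parallel branches' kernel sizes are artifact defaults (they are
#' configurable and serialized with the weights).
#'
#' @param architecture One of `"lstm"`, `"cnn_linear"`, `"cnn_parallel"`,
#'   `"cnn_linear_lstm"`, `"cnn_parallel_lstm"`.
#' @param lstm_units LSTM cells per direction.
#' @param lstm_recurrent_dropout Recurrent (variational) dropout fraction
#'   of the bidirectional LSTM in the `lstm` architecture.
#' @param head_dropout Dropout fraction before the classification layer.
#' @param dense_units Width of the penultimate dense layer; defaults to
#'   40 for the linear-CNN family and 60 otherwise.
#' @param cnn_linear_filters,cnn_linear_kernels Integer vectors of length
#'   3: filters and kernel sizes of the linear CNN stack.
#' @param parallel_branch_kernels Kernel size of each parallel branch.
#' @param parallel_branch_filters Filters per branch convolution.
#' @param merge_conv_filters,merge_conv_kernel The post-concatenation
#'   convolution of the parallel CNN.
#' @param branch_pool Pool width between the two convolutions of a branch.
#' @param final_pool Pool width after the last convolution; defaults to 2
#'   for the linear family and 3 for the parallel family.
#' @param input_length Encoded positions per peptide (120).
#' @return A `model_spec` list.
#' @export
model_spec <- function(architecture,
                       lstm_units = 60L,
                       lstm_recurrent_dropout = 0.15,
                       head_dropout = 0.5,
                       dense_units = NULL,
                       cnn_linear_filters = c(64L, 128L, 64L),
                       cnn_linear_kernels = c(7L, 5L, 3L),
                       parallel_branch_kernels = c(3L, 6L, 9L),
                       parallel_branch_filters = 64L,
                       merge_conv_filters = 150L,
                       merge_conv_kernel = 3L,
                       branch_pool = 2L,
                       final_pool = NULL,
                       input_length = 120L) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  if (is.null(dense_units)) {
    dense_units <- if (architecture %in% c("cnn_linear", "cnn_linear_lstm"))
      40L else 60L
  }
  if (is.null(final_pool)) {
    final_pool <- if (architecture %in% c("cnn_parallel", "cnn_parallel_lstm"))
      3L else 2L
  }
  spec <- list(
    architecture = architecture,
    lstm_units = as.integer(lstm_units),
    lstm_recurrent_dropout = as.numeric(lstm_recurrent_dropout),
    head_dropout = as.numeric(head_dropout),
    dense_units = as.integer(dense_units),
    cnn_linear_filters = as.integer(cnn_linear_filters),
    cnn_linear_kernels = as.integer(cnn_linear_kernels),
    parallel_branch_kernels = as.integer(parallel_branch_kernels),
    parallel_branch_filters = as.integer(parallel_branch_filters),
    merge_conv_filters = as.integer(merge_conv_filters),
    merge_conv_kernel = as.integer(merge_conv_kernel),
    branch_pool = as.integer(branch_pool),
    final_pool = as.integer(final_pool),
    input_length = as.integer(input_length)
  )
  frac <- c(spec$lstm_recurrent_dropout, spec$head_dropout)
  if (any(frac < 0 | frac >= 1)) stop("dropout fractions must lie in [0, 1)")
  counts <- c(spec$lstm_units, spec$dense_units, spec$cnn_linear_filters,
              spec$cnn_linear_kernels, spec$parallel_branch_kernels,
              spec$parallel_branch_filters, spec$merge_conv_filters,
              spec$merge_conv_kernel, spec$branch_pool, spec$final_pool,
              spec$input_length)
  if (any(counts < 1L)) stop("unit/filter/kernel/pool counts must be positive")
  if (length(spec$cnn_linear_filters) != 3L ||
      length(spec$cnn_linear_kernels) != 3L ||
      length(spec$parallel_branch_kernels) != 3L) {
    stop("cnn_linear_filters, cnn_linear_kernels and parallel_branch_kernels ",
         "must each have length 3")
  }
  structure(spec, class = "model_spec")
}

# layer descriptor list for one architecture
build_topology <- function(spec) {
  head_layers <- function(units) list(
    list(type = "dense", name = "dense", units = units, act = "relu"),
    list(type = "dropout", name = "head_drop", rate = spec$head_dropout),
    list(type = "dense", name = "classify", units = 2L, act = "linear")
  )
  linear_stack <- function() lapply(1:3, function(i) {
    list(type = "conv1d", name = paste0("conv", i),
         filters = spec$cnn_linear_filters[i],
         kernel = spec$cnn_linear_kernels[i])
  })
  parallel_block <- function() {
    branches <- lapply(seq_along(spec$parallel_branch_kernels), function(i) {
      k <- spec$parallel_branch_kernels[i]
      list(
        list(type = "conv1d", name = sprintf("br%d_conv1", i),
             filters = spec$parallel_branch_filters, kernel = k),
        list(type = "maxpool", name = sprintf("br%d_pool", i),
             width = spec$branch_pool),
        list(type = "conv1d", name = sprintf("br%d_conv2", i),
             filters = spec$parallel_branch_filters, kernel = k)
      )
    })
    list(
      list(type = "parallel", name = "branches", branches = branches),
      list(type = "conv1d", name = "merge_conv",
           filters = spec$merge_conv_filters, kernel = spec$merge_conv_kernel),
      list(type = "maxpool", name = "final_pool", width = spec$final_pool)
    )
  }
  switch(spec$architecture,
    lstm = c(
      list(list(type = "lstm", name = "bilstm", units = spec$lstm_units,
                bidirectional = TRUE,
                rec_dropout = spec$lstm_recurrent_dropout)),
      head_layers(spec$dense_units)
    ),
    cnn_linear = c(
      linear_stack(),
      list(list(type = "maxpool", name = "final_pool",
                width = spec$final_pool),
           list(type = "flatten", name = "flatten")),
      head_layers(spec$dense_units)
    ),
    cnn_parallel = c(
      parallel_block(),
      list(list(type = "flatten", name = "flatten")),
      head_layers(spec$dense_units)
    ),
    cnn_linear_lstm = c(
      linear_stack(),
      list(list(type = "maxpool", name = "final_pool",
                width = spec$final_pool),
           list(type = "lstm", name = "lstm", units = spec$lstm_units,
                bidirectional = FALSE, rec_dropout = 0)),
      head_layers(spec$dense_units)
    ),
    cnn_parallel_lstm = c(
      parallel_block(),
      list(list(type = "lstm", name = "lstm", units = spec$lstm_units,
                bidirectional = FALSE, rec_dropout = 0)),
      head_layers(spec$dense_units)
    )
  )
}

#' Build an (untrained) classifier
#'
#' Instantiates the network topology of a [model_spec()] with
#' Glorot-uniform initial weights (LSTM forget-gate biases start at 1).
#'
#' @param spec A [model_spec()].
#' @param alphabet An [aa_alphabet()]; fixed for the life of the model and
#'   serialized with its weights.
#' @param seed Optional integer; when given, initialization is drawn from
#'   a private RNG stream seeded with it, leaving the global RNG alone.
#' @return A `rippnet_model` handle with components `spec`, `alphabet`,
#'   `layers`, `params` and `metadata`.
#' @export
build_model <- function(spec, alphabet = aa_alphabet(), seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  in_shape <- list(kind = "seq", L = spec$input_length,
                   C = length(alphabet$symbols))
  net <- local_seed(seed, net_init(build_topology(spec), in_shape))
  structure(
    list(spec = spec, alphabet = alphabet, layers = net$layers,
         params = net$params,
         metadata = list(format_version = MODEL_FORMAT_VERSION,
                         created = format(Sys.time(), tz = "UTC"),
                         training_run = NULL)),
    class = "rippnet_model"
  )
}

#' @export
print.rippnet_model <- function(x, ...) {
  cat(sprintf("rippnet_model '%s': %s parameters, alphabet %s%s\n",
              x$spec$architecture,
              format(n_params(x$params), big.mark = ","),
              alphabet_string(x$alphabet),
              if (is.null(x$metadata$training_run)) " (untrained)" else ""))
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' @param model A `rippnet_model`.
#' @return Integer count.
#' @export
count_params <- function(model) n_params(model$params)

#' Score encoded peptides
#'
#' Runs the network in inference mode (dropout disabled) and returns the
#' normalized class probabilities. Predictions are computed in chunks so
#' memory stays flat for large candidate sets.
#'
#' @param model A `rippnet_model`.
#' @param batch An `encoded_batch` from [encode_batch()], or a single
#'   `encoded_peptide` from [encode_peptide()].
#' @param chunk_size Samples per forward pass.
#' @return An `n x 2` matrix with columns `score_negative`,
#'   `score_positive`; each row sums to 1.
#' @export
predict_peptides <- function(model, batch, chunk_size = 256L) {
  stopifnot(inherits(model, "rippnet_model"))
  if (inherits(batch, "encoded_peptide")) {
    x <- array(0, dim = c(1L, ncol(batch), nrow(batch)))
    x[1L, , ] <- t(unclass(batch))
  } else if (inherits(batch, "encoded_batch")) {
    if (!identical(batch$alphabet$symbols, model$alphabet$symbols)) {
      stop("batch alphabet does not match the model's alphabet")
    }
    x <- batch$x
  } else {
    stop("batch must be an encoded_batch or encoded_peptide")
  }
  d <- dim(x)
  if (d[2] != model$spec$input_length ||
      d[3] != length(model$alphabet$symbols)) {
    stop("input shape ", d[2], " x ", d[3], " does not match expected ",
         model$spec$input_length, " x ", length(model$alphabet$symbols))
  }
  n <- d[1]
  out <- matrix(0, n, 2L,
                dimnames = list(NULL, c("score_negative", "score_positive")))
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    logits <- net_forward(model$layers, model$params,
                          x[idx, , , drop = FALSE], train = FALSE)$y
    out[idx, ] <- softmax_rows(logits)
  }
  out
}

#' Save a trained model
#'
#' Writes the weights as an opaque blob (`weights.rds`) next to a
#' plain-text JSON sidecar (`metadata.json`) carrying the architecture
#' name, every [model_spec()] field, the alphabet string and the format
#' version. The two files travel together.
#'
#' @param model A `rippnet_model`.
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rippnet_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format_version = model$metadata$format_version,
    architecture = model$spec$architecture,
    spec = unclass(model$spec),
    alphabet = alphabet_string(model$alphabet),
    created = model$metadata$created,
    training_run = model$metadata$training_run,
    n_params = n_params(model$params)
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model$params, file.path(path, "weights.rds"))
  invisible(path)
}

#' Load a saved model
#'
#' Rebuilds the network from the JSON sidecar and restores its weights,
#' validating that the metadata names a format version, an alphabet and an
#' architecture, and that every weight tensor matches the topology.
#'
#' @param path Directory written by [save_model()].
#' @param architecture Optional expected architecture name; loading fails
#'   if the saved model is of a different architecture.
#' @return A `rippnet_model`.
#' @export
load_model <- function(path, architecture = NULL) {
  meta_path <- file.path(path, "metadata.json")
  wts_path <- file.path(path, "weights.rds")
  if (!file.exists(meta_path)) stop("model metadata not found: ", meta_path)
  if (!file.exists(wts_path)) stop("model weights not found: ", wts_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("format_version", "alphabet", "architecture")) {
    if (is.null(meta[[field]]) || !nzchar(as.character(meta[[field]])[1])) {
      stop("model metadata is missing required field '", field, "'")
    }
  }
  if (!is.null(architecture) &&
      !identical(meta$architecture, architecture)) {
    stop("saved model is architecture '", meta$architecture,
         "', not '", architecture, "'")
  }
  spec_fields <- meta$spec
  spec_fields$architecture <- NULL
  spec <- do.call(model_spec, c(list(architecture = meta$architecture),
                                spec_fields))
  alphabet <- aa_alphabet(meta$alphabet)
  model <- build_model(spec, alphabet, seed = 0L)
  params <- readRDS(wts_path)
  if (!setequal(names(params), names(model$params))) {
    missing <- setdiff(names(model$params), names(params))
    extra <- setdiff(names(params), names(model$params))
    stop("saved weights do not match the '", meta$architecture,
         "' topology (missing: ", paste(missing, collapse = ", "),
         "; unexpected: ", paste(extra, collapse = ", "), ")")
  }
  for (nm in names(model$params)) {
    if (!identical(dim(params[[nm]]) %||% length(params[[nm]]),
                   dim(model$params[[nm]]) %||% length(model$params[[nm]]))) {
      stop("weight tensor '", nm, "' has the wrong shape")
    }
  }
  model$params <- params[names(model$params)]
  model$metadata$format_version <- meta$format_version
  model$metadata$created <- meta$created
  model$metadata$training_run <- meta$training_run
  model
}
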