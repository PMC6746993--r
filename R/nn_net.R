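# Network assembly: a network is an ordered list of layer descriptors
# (plain lists with a $type, a unique $name and hyperparameters). A
# "parallel" descriptor holds several sub-networks whose sequence outputs
# are concatenated along the channel dimension. Parameters live in one
# flat named list keyed "<layer name>.<tensor>"; gradients mirror it.

net_init <- function(layers, in_shape) {
  params <- list()
  shape <- in_shape
  out_layers <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "parallel") {
      branch_shapes <- list()
      for (bi in seq_along(ly$branches)) {
        sub <- net_init(ly$branches[[bi]], shape)
        ly$branches[[bi]] <- sub$layers
        params <- c(params, sub$params)
        branch_shapes[[bi]] <- sub$out_shape
      }
      Ls <- vapply(branch_shapes, function(s) s$L, 0)
      if (length(unique(Ls)) != 1L) {
        stop("parallel branches disagree on output length: ",
             paste(Ls, collapse = ", "))
      }
      ly$branch_C <- vapply(branch_shapes, function(s) s$C, 0)
      shape <- list(kind = "seq", L = Ls[1],
                    C = sum(ly$branch_C))
    } else {
      ini <- switch(ly$type,
        conv1d = conv1d_init(ly, shape),
        maxpool = maxpool_init(ly, shape),
        lstm = lstm_init(ly, shape),
        dense = dense_init(ly, shape),
        flatten = flatten_init(ly, shape),
        dropout = list(params = list(), out_shape = shape),
        stop("unknown layer type: ", ly$type)
      )
      if (length(ini$params)) {
        names(ini$params) <- paste0(ly$name, ".", names(ini$params))
        params <- c(params, ini$params)
      }
      shape <- ini$out_shape
    }
    out_layers[[i]] <- ly
  }
  list(layers = out_layers, params = params, out_shape = shape)
}

net_forward <- function(layers, params, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "parallel") {
      outs <- vector("list", length(ly$branches))
      bc <- vector("list", length(ly$branches))
      for (bi in seq_along(ly$branches)) {
        sub <- net_forward(ly$branches[[bi]], params, x, train)
        outs[[bi]] <- sub$y
        bc[[bi]] <- sub$caches
      }
      n <- dim(outs[[1]])[1]; L <- dim(outs[[1]])[2]
      y <- array(0, dim = c(n, L, sum(ly$branch_C)))
      off <- 0L
      for (bi in seq_along(outs)) {
        Cb <- ly$branch_C[bi]
        y[, , off + seq_len(Cb)] <- outs[[bi]]
        off <- off + Cb
      }
      x <- y
      caches[[i]] <- if (train) bc else NULL
    } else {
      res <- switch(ly$type,
        conv1d = conv1d_forward(ly, params[[paste0(ly$name, ".W")]],
                                params[[paste0(ly$name, ".b")]], x, train),
        maxpool = maxpool_forward(ly, x, train),
        lstm = lstm_forward(ly, params, ly$name, x, train),
        dense = dense_forward(ly, params[[paste0(ly$name, ".W")]],
                              params[[paste0(ly$name, ".b")]], x, train),
        flatten = flatten_forward(ly, x, train),
        dropout = dropout_forward(ly, x, train)
      )
      x <- res$y
      caches[[i]] <- res$cache
    }
  }
  list(y = x, caches = caches)
}

net_backward <- function(layers, params, caches, dy, need_dx = FALSE) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    first <- (i == 1L)
    want_dx <- need_dx || !first
    if (ly$type == "parallel") {
      off <- 0L
      dxa <- NULL
      for (bi in seq_along(ly$branches)) {
        Cb <- ly$branch_C[bi]
        dyb <- dy[, , off + seq_len(Cb), drop = FALSE]
        off <- off + Cb
        sub <- net_backward(ly$branches[[bi]], params, caches[[i]][[bi]],
                            dyb, need_dx = want_dx)
        grads <- c(grads, sub$grads)
        if (want_dx) dxa <- if (is.null(dxa)) sub$dx else dxa + sub$dx
      }
      dy <- dxa
    } else {
      res <- switch(ly$type,
        conv1d = conv1d_backward(ly, params[[paste0(ly$name, ".W")]],
                                 caches[[i]], dy, want_dx),
        maxpool = maxpool_backward(ly, caches[[i]], dy),
        lstm = lstm_backward(ly, params, ly$name, caches[[i]], dy, want_dx),
        dense = dense_backward(ly, params[[paste0(ly$name, ".W")]],
                               caches[[i]], dy, want_dx),
        flatten = flatten_backward(ly, caches[[i]], dy),
        dropout = dropout_backward(ly, caches[[i]], dy)
      )
      if (length(res$grads)) {
        names(res$grads) <- paste0(ly$name, ".", names(res$grads))
        grads <- c(grads, res$grads)
      }
      dy <- res$dx
    }
  }
  list(dx = dy, grads = grads)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

n_params <- function(params) sum(vapply(params, length, 0L))
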