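# Neural-network primitives: initialization, forward and backward passes.
#
# All layers operate on batches. Sequence layers take a numeric array of
# dim (n, L, C) = (samples, positions, channels); dense layers take an
# (n, d) matrix. Backward passes are hand-derived and vectorized over the
# batch so every heavy operation is a BLAS matrix product. Parameters are
# kept in a flat named list ("<layer>.<tensor>"), which keeps the Adam
# update and (de)serialization trivial.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -limit, limit), nrow, ncol)
}

# slice position t of an (n, L, C) array as an (n, C) matrix
.slice_t <- function(x, t) {
  d <- dim(x)
  matrix(x[, t, , drop = FALSE], d[1], d[3])
}

## ---- conv1d (stride 1, "same" zero padding) --------------------------------

conv1d_init <- function(layer, in_shape) {
  k <- layer$kernel; C <- in_shape$C; F_ <- layer$filters
  params <- list(
    W = glorot_uniform(k * C, F_, fan_in = k * C, fan_out = k * F_),
    b = numeric(F_)
  )
  list(params = params, out_shape = list(kind = "seq", L = in_shape$L, C = F_))
}

# im2col: (n, L, C) -> (n*L, k*C), rows ordered sample-fastest within position
.im2col <- function(x, k, pad_l) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  M <- matrix(0, n * L, k * C)
  for (o in seq_len(k) - 1L) {
    dlt <- o - pad_l
    p1 <- max(1L, 1L - dlt); p2 <- min(L, L - dlt)
    if (p1 > p2) next
    rows <- ((p1 - 1L) * n + 1L):(p2 * n)
    M[rows, (o * C + 1L):((o + 1L) * C)] <-
      matrix(x[, (p1 + dlt):(p2 + dlt), , drop = FALSE],
             nrow = n * (p2 - p1 + 1L))
  }
  M
}

conv1d_forward <- function(layer, W, b, x, train) {
  d <- dim(x); n <- d[1]; L <- d[2]
  k <- layer$kernel
  pad_l <- (k - 1L) %/% 2L
  M <- .im2col(x, k, pad_l)
  Z <- M %*% W
  Z <- Z + rep(b, each = n * L)
  act <- Z > 0
  Y <- Z * act
  list(y = array(Y, dim = c(n, L, layer$filters)),
       cache = if (train) list(M = M, act = act, n = n, L = L,
                               C = d[3], pad_l = pad_l) else NULL)
}

conv1d_backward <- function(layer, W, cache, dy, need_dx) {
  n <- cache$n; L <- cache$L; C <- cache$C
  k <- layer$kernel; pad_l <- cache$pad_l
  dZ <- matrix(dy, n * L, layer$filters) * cache$act
  grads <- list(W = crossprod(cache$M, dZ), b = colSums(dZ))
  dx <- NULL
  if (need_dx) {
    dM <- tcrossprod(dZ, W)
    dx <- array(0, dim = c(n, L, C))
    for (o in seq_len(k) - 1L) {
      dlt <- o - pad_l
      p1 <- max(1L, 1L - dlt); p2 <- min(L, L - dlt)
      if (p1 > p2) next
      rows <- ((p1 - 1L) * n + 1L):(p2 * n)
      np <- p2 - p1 + 1L
      dx[, (p1 + dlt):(p2 + dlt), ] <-
        dx[, (p1 + dlt):(p2 + dlt), , drop = FALSE] +
        array(dM[rows, (o * C + 1L):((o + 1L) * C), drop = FALSE],
              dim = c(n, np, C))
    }
  }
  list(dx = dx, grads = grads)
}

## ---- max pooling (non-overlapping groups, trailing remainder dropped) ------

maxpool_init <- function(layer, in_shape) {
  list(params = list(),
       out_shape = list(kind = "seq", L = in_shape$L %/% layer$width,
                        C = in_shape$C))
}

maxpool_forward <- function(layer, x, train) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  w <- layer$width; Lp <- L %/% w
  x4 <- array(x[, seq_len(Lp * w), , drop = FALSE], dim = c(n, w, Lp, C))
  best <- array(x4[, 1, , , drop = FALSE], dim = c(n, Lp, C))
  arg <- array(1L, dim = c(n, Lp, C))
  if (w > 1L) for (j in 2:w) {
    cand <- array(x4[, j, , , drop = FALSE], dim = c(n, Lp, C))
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(y = best,
       cache = if (train) list(arg = arg, n = n, L = L, C = C, Lp = Lp)
               else NULL)
}

maxpool_backward <- function(layer, cache, dy) {
  n <- cache$n; L <- cache$L; C <- cache$C; Lp <- cache$Lp
  w <- layer$width
  dx4 <- array(0, dim = c(n, w, Lp, C))
  for (j in seq_len(w)) {
    sel <- cache$arg == j
    tmp <- array(0, dim = c(n, Lp, C))
    tmp[sel] <- dy[sel]
    dx4[, j, , ] <- tmp
  }
  dx <- array(0, dim = c(n, L, C))
  dx[, seq_len(Lp * w), ] <- array(dx4, dim = c(n, Lp * w, C))
  list(dx = dx, grads = list())
}

## ---- LSTM (returns the final hidden state) ---------------------------------

lstm_init <- function(layer, in_shape) {
  C <- in_shape$C; H <- layer$units
  one_dir <- function() {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias starts open
    list(Wx = glorot_uniform(C, 4 * H), Wh = glorot_uniform(H, 4 * H), b = b)
  }
  if (isTRUE(layer$bidirectional)) {
    f <- one_dir(); r <- one_dir()
    params <- list(Wx_f = f$Wx, Wh_f = f$Wh, b_f = f$b,
                   Wx_b = r$Wx, Wh_b = r$Wh, b_b = r$b)
    out <- 2L * H
  } else {
    f <- one_dir()
    params <- list(Wx_f = f$Wx, Wh_f = f$Wh, b_f = f$b)
    out <- H
  }
  list(params = params, out_shape = list(kind = "flat", d = out))
}

# one direction over positions `steps`; returns last hidden state
.lstm_dir_forward <- function(x, steps, Wx, Wh, b, rmask, train) {
  d <- dim(x); n <- d[1]; H <- ncol(Wh)
  H <- H / 4
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  L <- length(steps)
  cache <- NULL
  if (train) {
    cache <- list(
      I = array(0, c(n, L, H)), Fg = array(0, c(n, L, H)),
      G = array(0, c(n, L, H)), O = array(0, c(n, L, H)),
      TC = array(0, c(n, L, H)), CS = array(0, c(n, L, H)),
      HS = array(0, c(n, L, H))
    )
  }
  brow <- rep(b, each = n)
  for (s in seq_len(L)) {
    xt <- .slice_t(x, steps[s])
    A <- xt %*% Wx + (h * rmask) %*% Wh
    A <- A + brow
    i <- sigmoid(A[, 1:H, drop = FALSE])
    f <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (train) {
      cache$I[, s, ] <- i; cache$Fg[, s, ] <- f; cache$G[, s, ] <- g
      cache$O[, s, ] <- o; cache$TC[, s, ] <- tc
      cache$CS[, s, ] <- cc; cache$HS[, s, ] <- h
    }
  }
  list(h = h, cache = cache)
}

.lstm_dir_backward <- function(x, steps, Wx, Wh, rmask, cache, dh_last,
                               need_dx) {
  d <- dim(x); n <- d[1]; C <- d[3]
  H <- ncol(Wh) / 4
  L <- length(steps)
  dWx <- matrix(0, C, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dx <- if (need_dx) array(0, dim = d) else NULL
  dh <- dh_last; dc <- matrix(0, n, H)
  sl <- function(a, s) matrix(a[, s, , drop = FALSE], n, H)
  for (s in L:1) {
    i <- sl(cache$I, s); f <- sl(cache$Fg, s); g <- sl(cache$G, s)
    o <- sl(cache$O, s); tc <- sl(cache$TC, s)
    cprev <- if (s > 1) sl(cache$CS, s - 1) else matrix(0, n, H)
    hprev <- if (s > 1) sl(cache$HS, s - 1) else matrix(0, n, H)
    da_o <- (dh * tc) * o * (1 - o)
    dc <- dc + dh * o * (1 - tc^2)
    da_i <- (dc * g) * i * (1 - i)
    da_f <- (dc * cprev) * f * (1 - f)
    da_g <- (dc * i) * (1 - g^2)
    da <- cbind(da_i, da_f, da_g, da_o)
    xt <- .slice_t(x, steps[s])
    dWx <- dWx + crossprod(xt, da)
    dWh <- dWh + crossprod(hprev * rmask, da)
    db <- db + colSums(da)
    dh <- (da %*% t(Wh)) * rmask
    dc <- dc * f
    if (need_dx) dx[, steps[s], ] <- da %*% t(Wx)
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

lstm_forward <- function(layer, params, prefix, x, train) {
  d <- dim(x); n <- d[1]; L <- d[2]
  H <- layer$units
  p <- layer$rec_dropout %||% 0
  mk_mask <- function() {
    if (train && p > 0) {
      matrix((runif(n * H) >= p) / (1 - p), n, H)
    } else {
      matrix(1, n, H)
    }
  }
  g <- function(nm) params[[paste0(prefix, ".", nm)]]
  rmask_f <- mk_mask()
  fwd <- .lstm_dir_forward(x, seq_len(L), g("Wx_f"), g("Wh_f"), g("b_f"),
                           rmask_f, train)
  if (isTRUE(layer$bidirectional)) {
    rmask_b <- mk_mask()
    bwd <- .lstm_dir_forward(x, L:1, g("Wx_b"), g("Wh_b"), g("b_b"),
                             rmask_b, train)
    y <- cbind(fwd$h, bwd$h)
    cache <- if (train) list(x = x, f = fwd$cache, b = bwd$cache,
                             rmask_f = rmask_f, rmask_b = rmask_b) else NULL
  } else {
    y <- fwd$h
    cache <- if (train) list(x = x, f = fwd$cache, rmask_f = rmask_f)
             else NULL
  }
  list(y = y, cache = cache)
}

lstm_backward <- function(layer, params, prefix, cache, dy, need_dx) {
  x <- cache$x
  L <- dim(x)[2]; H <- layer$units
  g <- function(nm) params[[paste0(prefix, ".", nm)]]
  res_f <- .lstm_dir_backward(x, seq_len(L), g("Wx_f"), g("Wh_f"),
                              cache$rmask_f, cache$f,
                              dy[, seq_len(H), drop = FALSE], need_dx)
  grads <- list(Wx_f = res_f$dWx, Wh_f = res_f$dWh, b_f = res_f$db)
  dx <- res_f$dx
  if (isTRUE(layer$bidirectional)) {
    res_b <- .lstm_dir_backward(x, L:1, g("Wx_b"), g("Wh_b"),
                                cache$rmask_b, cache$b,
                                dy[, H + seq_len(H), drop = FALSE], need_dx)
    grads$Wx_b <- res_b$dWx; grads$Wh_b <- res_b$dWh; grads$b_b <- res_b$db
    if (need_dx) dx <- dx + res_b$dx
  }
  list(dx = dx, grads = grads)
}

## ---- dense, flatten, dropout ----------------------------------------------

dense_init <- function(layer, in_shape) {
  d <- in_shape$d
  list(params = list(W = glorot_uniform(d, layer$units), b = numeric(layer$units)),
       out_shape = list(kind = "flat", d = layer$units))
}

dense_forward <- function(layer, W, b, x, train) {
  Z <- x %*% W
  Z <- Z + rep(b, each = nrow(x))
  if (identical(layer$act, "relu")) {
    act <- Z > 0
    list(y = Z * act, cache = if (train) list(x = x, act = act) else NULL)
  } else {
    list(y = Z, cache = if (train) list(x = x, act = NULL) else NULL)
  }
}

dense_backward <- function(layer, W, cache, dy, need_dx) {
  dZ <- if (is.null(cache$act)) dy else dy * cache$act
  list(dx = if (need_dx) tcrossprod(dZ, W) else NULL,
       grads = list(W = crossprod(cache$x, dZ), b = colSums(dZ)))
}

flatten_init <- function(layer, in_shape) {
  list(params = list(),
       out_shape = list(kind = "flat", d = in_shape$L * in_shape$C))
}

flatten_forward <- function(layer, x, train) {
  d <- dim(x)
  list(y = matrix(x, d[1], d[2] * d[3]),
       cache = if (train) list(d = d) else NULL)
}

flatten_backward <- function(layer, cache, dy) {
  list(dx = array(dy, dim = cache$d), grads = list())
}

dropout_forward <- function(layer, x, train) {
  if (!train || layer$rate <= 0) return(list(y = x, cache = NULL))
  mask <- matrix((runif(length(x)) >= layer$rate) / (1 - layer$rate),
                 nrow(x), ncol(x))
  list(y = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, cache, dy) {
  list(dx = if (is.null(cache)) dy else dy * cache$mask, grads = list())
}

## ---- softmax head / loss ---------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean sparse cross-entropy over integer labels in {0,1}; returns loss and
# the gradient w.r.t. the logits
softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dZ <- p
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dlogits = dZ / n, probs = p)
}
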