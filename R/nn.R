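# Minimal neural-network engine: dense, LSTM (uni/bidirectional),
# conv1d (same padding), maxpool1d (stride 1), dropout, batchnorm,
# flatten and repeat-vector layers with analytic backprop and Adam.
# Sequence tensors are B x T x C arrays, flat tensors B x D matrices.
# BLAS matrix products carry the load; layer gradients are verified
# against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(x) pmax(x, 0),
                     # derivative expressed through the output value
                     dfo = function(y) (y > 0) * 1),
         tanh = list(f = tanh, dfo = function(y) 1 - y^2),
         linear = list(f = identity, dfo = function(y) 1),
         stop("unknown activation: ", name))
}

glorot_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

orthogonal_init <- function(n, m) {
  a <- matrix(stats::rnorm(max(n, m)^2), max(n, m))
  q <- qr.Q(qr(a))
  q[seq_len(n), seq_len(m), drop = FALSE]
}

## ---- layer weight construction -------------------------------------

init_lstm_weights <- function(input_dim, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1  # unit forget-gate bias
  list(W = glorot_uniform(input_dim, 4 * units),
       R = orthogonal_init(units, 4 * units),
       b = b)
}

nn_init_layer <- function(layer, in_shape) {
  w <- switch(layer$kind,
    lstm = init_lstm_weights(in_shape$dim, layer$units),
    `bidirectional-lstm` = list(
      fwd = init_lstm_weights(in_shape$dim, layer$units),
      bwd = init_lstm_weights(in_shape$dim, layer$units)),
    conv1d = list(W = glorot_uniform(layer$kernel * in_shape$dim,
                                     layer$filters),
                  b = numeric(layer$filters)),
    `time-distributed-affine` = list(
      W = glorot_uniform(in_shape$dim, layer$units),
      b = numeric(layer$units)),
    batchnorm = list(gamma = rep(1, in_shape$dim),
                     beta = numeric(in_shape$dim)),
    NULL)
  state <- if (layer$kind == "batchnorm") {
    list(moving_mean = numeric(in_shape$dim),
         moving_var = rep(1, in_shape$dim))
  } else NULL
  list(weights = w, state = state)
}

## ---- forward passes -------------------------------------------------

lstm_cell_forward <- function(xs, w, activation, return_sequences) {
  T <- length(xs); B <- nrow(xs[[1]]); U <- length(w$b) / 4
  act <- act_fun(activation)
  h <- matrix(0, B, U); cc <- matrix(0, B, U)
  cache <- vector("list", T)
  hs <- if (return_sequences) vector("list", T) else NULL
  iU <- 1:U; fU <- U + iU; gU <- 2 * U + iU; oU <- 3 * U + iU
  for (t in seq_len(T)) {
    z <- xs[[t]] %*% w$W + h %*% w$R +
      matrix(w$b, B, 4 * U, byrow = TRUE)
    gi <- sigmoid(z[, iU, drop = FALSE])
    gf <- sigmoid(z[, fU, drop = FALSE])
    gg <- act$f(z[, gU, drop = FALSE])
    go <- sigmoid(z[, oU, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    a <- act$f(cc)
    h_prev <- h
    h <- go * a
    cache[[t]] <- list(x = xs[[t]], gi = gi, gf = gf, gg = gg, go = go,
                       c_prev = c_prev, cc = cc, a = a, h_prev = h_prev)
    if (return_sequences) hs[[t]] <- h
  }
  list(out = if (return_sequences) hs else h,
       cache = list(steps = cache, act = activation, U = U))
}

lstm_cell_backward <- function(dout, cache, w, return_sequences) {
  steps <- cache$steps; T <- length(steps); U <- cache$U
  act <- act_fun(cache$act)
  B <- nrow(steps[[1]]$x)
  dW <- array(0, dim = dim(w$W)); dR <- array(0, dim = dim(w$R))
  db <- numeric(length(w$b))
  dh_next <- matrix(0, B, U); dc <- matrix(0, B, U)
  dxs <- vector("list", T)
  for (t in rev(seq_len(T))) {
    s <- steps[[t]]
    dh <- dh_next + (if (return_sequences) dout[[t]]
                     else if (t == T) dout else matrix(0, B, U))
    dgo <- dh * s$a
    dc <- dc + dh * s$go * act$dfo(s$a)
    dgi <- dc * s$gg
    dgf <- dc * s$c_prev
    dgg <- dc * s$gi
    dz <- cbind(dgi * s$gi * (1 - s$gi),
                dgf * s$gf * (1 - s$gf),
                dgg * act$dfo(s$gg),
                dgo * s$go * (1 - s$go))
    dW <- dW + crossprod(s$x, dz)
    dR <- dR + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- tcrossprod(dz, w$W)
    dh_next <- tcrossprod(dz, w$R)
    dc <- dc * s$gf
  }
  list(dx = dxs, grads = list(W = dW, R = dR, b = db))
}

# split B x T x C array into list of B x C matrices
seq_to_list <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[2]), function(t) matrix(x[, t, ], d[1], d[3]))
}

list_to_seq <- function(xs) {
  B <- nrow(xs[[1]]); T <- length(xs); C <- ncol(xs[[1]])
  out <- array(0, dim = c(B, T, C))
  for (t in seq_len(T)) out[, t, ] <- xs[[t]]
  out
}

conv1d_forward <- function(x, w, kernel, activation = "relu") {
  d <- dim(x); B <- d[1]; T <- d[2]; C <- d[3]
  pad_l <- (kernel - 1) %/% 2
  act <- act_fun(activation)
  # im2col: rows = (B, t_out), cols = (tap, channel)
  M <- matrix(0, B * T, kernel * C)
  for (k in seq_len(kernel)) {
    src <- seq_len(T) - pad_l + (k - 1)
    ok <- src >= 1 & src <= T
    cols <- ((k - 1) * C + 1):(k * C)
    for (t in which(ok)) {
      M[((t - 1) * B + 1):(t * B), cols] <- matrix(x[, src[t], ], B, C)
    }
  }
  Ymat <- M %*% w$W + matrix(w$b, B * T, length(w$b), byrow = TRUE)
  Y <- act$f(Ymat)
  out <- array(0, dim = c(B, T, length(w$b)))
  for (t in seq_len(T)) {
    out[, t, ] <- Y[((t - 1) * B + 1):(t * B), , drop = FALSE]
  }
  list(out = out, cache = list(M = M, Y = Y, dims = d, kernel = kernel,
                               activation = activation))
}

conv1d_backward <- function(dout, cache, w) {
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]
  kernel <- cache$kernel
  act <- act_fun(cache$activation)
  nf <- length(w$b)
  dY <- matrix(0, B * T, nf)
  for (t in seq_len(T)) {
    dY[((t - 1) * B + 1):(t * B), ] <- matrix(dout[, t, ], B, nf)
  }
  dY <- dY * act$dfo(cache$Y)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, w$W)
  pad_l <- (kernel - 1) %/% 2
  dx <- array(0, dim = d)
  for (k in seq_len(kernel)) {
    src <- seq_len(T) - pad_l + (k - 1)
    ok <- src >= 1 & src <= T
    cols <- ((k - 1) * C + 1):(k * C)
    for (t in which(ok)) {
      dx[, src[t], ] <- dx[, src[t], ] +
        matrix(dM[((t - 1) * B + 1):(t * B), cols], B, C)
    }
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool1d_forward <- function(x, width) {
  d <- dim(x); B <- d[1]; T <- d[2]; C <- d[3]
  T_out <- T - width + 1L
  out <- array(0, dim = c(B, T_out, C))
  argmax <- array(0L, dim = c(B, T_out, C))
  for (t in seq_len(T_out)) {
    best <- matrix(x[, t, ], B, C); arg <- array(t, dim = c(B, C))
    for (k in seq_len(width - 1L)) {
      cand <- matrix(x[, t + k, ], B, C)
      better <- cand > best
      best[better] <- cand[better]
      arg[better] <- t + k
    }
    out[, t, ] <- best
    argmax[, t, ] <- arg
  }
  list(out = out, cache = list(argmax = argmax, dims = d, width = width))
}

maxpool1d_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, dim = d)
  T_out <- d[2] - cache$width + 1L
  for (t in seq_len(T_out)) {
    for (b in seq_len(d[1])) {
      src <- cache$argmax[b, t, ]
      for (cch in seq_len(d[3])) {
        dx[b, src[cch], cch] <- dx[b, src[cch], cch] + dout[b, t, cch]
      }
    }
  }
  list(dx = dx, grads = NULL)
}

batchnorm_forward <- function(x, w, state, training, momentum = 0.99,
                              eps = 1e-3) {
  d <- dim(x); B <- d[1]; T <- d[2]; C <- d[3]
  xm <- matrix(0, B * T, C)
  for (t in seq_len(T)) xm[((t - 1) * B + 1):(t * B), ] <-
    matrix(x[, t, ], B, C)
  if (training) {
    mu <- colMeans(xm)
    vv <- colMeans(sweep(xm, 2, mu)^2)
    state$moving_mean <- momentum * state$moving_mean + (1 - momentum) * mu
    state$moving_var <- momentum * state$moving_var + (1 - momentum) * vv
  } else {
    mu <- state$moving_mean; vv <- state$moving_var
  }
  inv_sd <- 1 / sqrt(vv + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, "*")
  ym <- sweep(sweep(xhat, 2, w$gamma, "*"), 2, w$beta, "+")
  out <- array(0, dim = d)
  for (t in seq_len(T)) out[, t, ] <-
    ym[((t - 1) * B + 1):(t * B), , drop = FALSE]
  list(out = out, state = state,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d))
}

batchnorm_backward <- function(dout, cache, w) {
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]
  n <- B * T
  dym <- matrix(0, n, C)
  for (t in seq_len(T)) dym[((t - 1) * B + 1):(t * B), ] <-
    matrix(dout[, t, ], B, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, w$gamma, "*")
  dxm <- sweep(dxhat - matrix(colMeans(dxhat), n, C, byrow = TRUE) -
                 cache$xhat * matrix(colMeans(dxhat * cache$xhat), n, C,
                                     byrow = TRUE),
               2, cache$inv_sd, "*")
  dx <- array(0, dim = d)
  for (t in seq_len(T)) dx[, t, ] <-
    dxm[((t - 1) * B + 1):(t * B), , drop = FALSE]
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- model-level forward/backward ----------------------------------

nn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  cur <- X  # B x T x C array
  caches <- vector("list", length(spec$layers))
  for (li in seq_along(spec$layers)) {
    layer <- spec$layers[[li]]
    w <- model$layers[[li]]$weights
    res <- switch(layer$kind,
      lstm = {
        r <- lstm_cell_forward(seq_to_list(cur), w, layer$activation,
                               layer$return_sequences)
        out <- if (layer$return_sequences) list_to_seq(r$out) else r$out
        list(out = out, cache = r$cache)
      },
      `bidirectional-lstm` = {
        xs <- seq_to_list(cur)
        rf <- lstm_cell_forward(xs, w$fwd, layer$activation,
                                layer$return_sequences)
        rb <- lstm_cell_forward(rev(xs), w$bwd, layer$activation,
                                layer$return_sequences)
        out <- if (layer$return_sequences) {
          f <- rf$out; b <- rev(rb$out)
          list_to_seq(Map(cbind, f, b))
        } else cbind(rf$out, rb$out)
        list(out = out, cache = list(fwd = rf$cache, bwd = rb$cache))
      },
      conv1d = conv1d_forward(cur, w, layer$kernel, layer$activation),
      maxpool1d = maxpool1d_forward(cur, layer$width),
      dropout = {
        if (training && layer$rate > 0) {
          mask <- array(stats::rbinom(length(cur), 1, 1 - layer$rate),
                        dim = dim(cur)) / (1 - layer$rate)
          list(out = cur * mask, cache = list(mask = mask))
        } else list(out = cur, cache = list(mask = NULL))
      },
      batchnorm = {
        r <- batchnorm_forward(cur, w, model$layers[[li]]$state, training)
        if (training) model$layers[[li]]$state <- r$state
        list(out = r$out, cache = r$cache)
      },
      flatten = {
        d <- dim(cur)
        out <- matrix(0, d[1], d[2] * d[3])
        for (t in seq_len(d[2])) {
          out[, ((t - 1) * d[3] + 1):(t * d[3])] <- matrix(cur[, t, ],
                                                           d[1], d[3])
        }
        list(out = out, cache = list(dims = d))
      },
      `repeat-vector` = {
        out <- array(cur, dim = c(nrow(cur), 1L, ncol(cur)))
        list(out = out, cache = NULL)
      },
      `time-distributed-affine` = {
        x2 <- if (length(dim(cur)) == 3L) {
          matrix(cur, dim(cur)[1], dim(cur)[3])  # T = 1 sequences
        } else cur
        out <- x2 %*% w$W + matrix(w$b, nrow(x2), length(w$b),
                                   byrow = TRUE)
        list(out = out, cache = list(x = x2, seq_in = length(dim(cur)) == 3L))
      },
      stop("nn_forward: unknown layer kind ", layer$kind))
    cur <- res$out
    caches[[li]] <- res$cache
  }
  list(out = cur, caches = caches, model = model)
}

nn_backward <- function(model, caches, dout) {
  spec <- model$spec
  grads <- vector("list", length(spec$layers))
  dcur <- dout
  for (li in rev(seq_along(spec$layers))) {
    layer <- spec$layers[[li]]
    w <- model$layers[[li]]$weights
    cache <- caches[[li]]
    res <- switch(layer$kind,
      lstm = {
        din <- if (layer$return_sequences) seq_to_list(dcur) else dcur
        r <- lstm_cell_backward(din, cache, w, layer$return_sequences)
        list(dx = list_to_seq(r$dx), grads = r$grads)
      },
      `bidirectional-lstm` = {
        U <- layer$units
        if (layer$return_sequences) {
          ds <- seq_to_list(dcur)
          df <- lapply(ds, function(m) m[, 1:U, drop = FALSE])
          db <- lapply(ds, function(m) m[, U + 1:U, drop = FALSE])
          rf <- lstm_cell_backward(df, cache$fwd, w$fwd, TRUE)
          rb <- lstm_cell_backward(rev(db), cache$bwd, w$bwd, TRUE)
          dx <- Map(`+`, rf$dx, rev(rb$dx))
          list(dx = list_to_seq(dx), grads = list(fwd = rf$grads,
                                                  bwd = rb$grads))
        } else {
          rf <- lstm_cell_backward(dcur[, 1:U, drop = FALSE],
                                   cache$fwd, w$fwd, FALSE)
          rb <- lstm_cell_backward(dcur[, U + 1:U, drop = FALSE],
                                   cache$bwd, w$bwd, FALSE)
          dx <- Map(`+`, rf$dx, rev(rb$dx))
          list(dx = list_to_seq(dx), grads = list(fwd = rf$grads,
                                                  bwd = rb$grads))
        }
      },
      conv1d = conv1d_backward(dcur, cache, w),
      maxpool1d = maxpool1d_backward(dcur, cache),
      dropout = {
        dx <- if (is.null(cache$mask)) dcur else dcur * cache$mask
        list(dx = dx, grads = NULL)
      },
      batchnorm = batchnorm_backward(dcur, cache, w),
      flatten = {
        d <- cache$dims
        dx <- array(0, dim = d)
        for (t in seq_len(d[2])) {
          dx[, t, ] <- matrix(dcur[, ((t - 1) * d[3] + 1):(t * d[3])],
                              d[1], d[3])
        }
        list(dx = dx, grads = NULL)
      },
      `repeat-vector` = {
        list(dx = matrix(dcur, dim(dcur)[1], dim(dcur)[3]), grads = NULL)
      },
      `time-distributed-affine` = {
        dW <- crossprod(cache$x, dcur)
        db <- colSums(dcur)
        dx <- tcrossprod(dcur, w$W)
        if (cache$seq_in) dx <- array(dx, dim = c(nrow(dx), 1L, ncol(dx)))
        list(dx = dx, grads = list(W = dW, b = db))
      },
      stop("nn_backward: unknown layer kind ", layer$kind))
    dcur <- res$dx
    grads[li] <- list(res$grads)  # keep NULL slots for weightless layers
  }
  list(grads = grads, dx = dcur)
}

## ---- Adam optimiser -------------------------------------------------

# recursively walk weight/grad lists in parallel
adam_step <- function(w, g, m, v, lr, b1, b2, eps, t) {
  if (is.null(g)) return(list(w = w, m = m, v = v))
  if (is.list(w)) {
    for (nm in names(w)) {
      r <- adam_step(w[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, b1, b2,
                     eps, t)
      w[[nm]] <- r$w; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(w = w, m = m, v = v))
  }
  if (is.null(m)) { m <- w * 0; v <- w * 0 }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  w <- w - lr * mhat / (sqrt(vhat) + eps)
  list(w = w, m = m, v = v)
}

## ---- build / fit / predict ------------------------------------------

nn_build <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "forecaster_spec"))
  shapes <- chain_shapes(spec)
  layers <- with_seed(seed, {
    lapply(seq_along(spec$layers), function(li) {
      nn_init_layer(spec$layers[[li]], shapes$in_shapes[[li]])
    })
  })
  structure(list(spec = spec, layers = layers),
            class = "nn_model")
}

# total number of weight elements actually allocated (backend
# introspection; the analytic count_parameters must agree with this)
nn_num_params <- function(model) {
  count <- function(w) {
    if (is.null(w)) return(0)
    if (is.list(w)) return(sum(vapply(w, count, numeric(1))))
    length(w)
  }
  trainable <- sum(vapply(model$layers, function(l) count(l$weights),
                          numeric(1)))
  non_trainable <- sum(vapply(model$layers, function(l) count(l$state),
                              numeric(1)))
  list(trainable = trainable, non_trainable = non_trainable,
       total = trainable + non_trainable)
}

nn_fit <- function(model, X, y, epochs = 100, batch_size = 32,
                   lr = 1e-3, seed = 0L, verbose = FALSE) {
  n <- dim(X)[1]
  stopifnot(nrow(y) == n)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  mstate <- vector("list", length(model$layers))
  vstate <- vector("list", length(model$layers))
  step <- 0L
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        Xb <- X[bi, , , drop = FALSE]
        yb <- y[bi, , drop = FALSE]
        fwd <- nn_forward(model, Xb, training = TRUE)
        model <- fwd$model  # batchnorm moving stats
        pred <- fwd$out
        resid <- pred - yb
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop(sprintf("nn_fit: non-finite loss at epoch %d", ep))
        }
        ep_loss <- ep_loss + loss; nb <- nb + 1L
        dout <- 2 * resid / length(resid)
        bwd <- nn_backward(model, fwd$caches, dout)
        step <- step + 1L
        for (li in seq_along(model$layers)) {
          if (is.null(bwd$grads[[li]])) next
          r <- adam_step(model$layers[[li]]$weights, bwd$grads[[li]],
                         mstate[[li]], vstate[[li]], lr, b1, b2, eps,
                         step)
          model$layers[[li]]$weights <- r$w
          mstate[[li]] <- r$m; vstate[[li]] <- r$v
        }
      }
      losses[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d  loss %.6g", ep, losses[ep]))
    }
  })
  model$loss_history <- losses
  model
}

nn_predict <- function(model, X, batch_size = 256) {
  n <- dim(X)[1]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    pred <- nn_forward(model, X[bi, , , drop = FALSE],
                       training = FALSE)$out
    out <- rbind(out, pred)
  }
  out
}
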