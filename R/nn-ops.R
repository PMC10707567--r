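# Low-level neural-network primitives: 1D convolution via im2col, batch
# normalization, max pooling, dropout, dense layers, softmax cross-entropy
# and SGD-with-momentum updates. Everything is plain matrix algebra with
# hand-derived backward passes; gradient correctness is checked against
# finite differences in the test suite.
#
# Feature maps are rank-3 arrays [N, C, L]: batch x channels x length.

nn_init_mat <- function(nrow, ncol) {
  # Glorot-uniform
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), 1L, ncol(x)))
  stopifnot(length(dim(x)) == 3L)
  x
}

## ---- 1D convolution (same padding, odd kernel) ----

conv1d_init <- function(in_ch, out_ch, k) {
  stopifnot(k %% 2L == 1L)
  list(W = nn_init_mat(in_ch * k, out_ch), b = numeric(out_ch),
       k = as.integer(k), in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

im2col1d <- function(x, k) {
  d <- dim(x); n <- d[1]; ch <- d[2]; len <- d[3]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(n, ch, len + 2L * pad))
  xp[, , (pad + 1L):(pad + len)] <- x
  cols <- matrix(0, n * len, ch * k)
  for (c in seq_len(ch)) {
    for (j in seq_len(k)) {
      cols[, (c - 1L) * k + j] <- as.vector(xp[, c, j:(j + len - 1L), drop = FALSE])
    }
  }
  cols
}

conv1d_forward <- function(x, p) {
  d <- dim(x); n <- d[1]; len <- d[3]
  stopifnot(d[2] == p$in_ch)
  cols <- im2col1d(x, p$k)
  outm <- sweep(cols %*% p$W, 2L, p$b, `+`)
  out <- aperm(array(outm, c(n, len, p$out_ch)), c(1L, 3L, 2L))
  list(out = out, cache = list(cols = cols, dims = d))
}

conv1d_backward <- function(dout, p, cache) {
  d <- cache$dims; n <- d[1]; ch <- d[2]; len <- d[3]; k <- p$k
  doutm <- matrix(aperm(dout, c(1L, 3L, 2L)), n * len, p$out_ch)
  dW <- crossprod(cache$cols, doutm)
  db <- colSums(doutm)
  dcols <- doutm %*% t(p$W)
  pad <- (k - 1L) %/% 2L
  dxp <- array(0, c(n, ch, len + 2L * pad))
  for (c in seq_len(ch)) {
    for (j in seq_len(k)) {
      idx <- j:(j + len - 1L)
      dxp[, c, idx] <- dxp[, c, idx] + matrix(dcols[, (c - 1L) * k + j], n, len)
    }
  }
  dx <- dxp[, , (pad + 1L):(pad + len), drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

## ---- batch normalization (per channel over batch x length) ----

bn_init <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch),
       running_mean = rep(0, ch), running_var = rep(1, ch),
       momentum = 0.1, eps = 1e-5)
}

bn_forward <- function(x, p, training) {
  d <- dim(x); ch <- d[2]
  m <- d[1] * d[3]
  if (training) {
    mu <- apply(x, 2L, mean)
    v <- apply(x, 2L, function(z) mean((z - mean(z))^2))
  } else {
    mu <- p$running_mean
    v <- p$running_var
  }
  invstd <- 1 / sqrt(v + p$eps)
  xc <- sweep(x, 2L, mu, `-`)
  xhat <- sweep(xc, 2L, invstd, `*`)
  out <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
  state <- NULL
  if (training) {
    state <- list(
      running_mean = (1 - p$momentum) * p$running_mean + p$momentum * mu,
      running_var = (1 - p$momentum) * p$running_var + p$momentum * v * m / max(1, m - 1)
    )
  }
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, m = m, training = training),
       state = state)
}

bn_backward <- function(dout, p, cache) {
  ch <- dim(dout)[2]
  dgamma <- numeric(ch); dbeta <- numeric(ch)
  dx <- dout
  for (c in seq_len(ch)) {
    dv <- dout[, c, , drop = FALSE]
    xh <- cache$xhat[, c, , drop = FALSE]
    dbeta[c] <- sum(dv)
    dgamma[c] <- sum(dv * xh)
    if (cache$training) {
      m <- cache$m
      dxhat <- dv * p$gamma[c]
      dx[, c, ] <- (cache$invstd[c] / m) *
        (m * dxhat - sum(dxhat) - xh * sum(dxhat * xh))
    } else {
      dx[, c, ] <- dv * p$gamma[c] * cache$invstd[c]
    }
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- max pooling by integer factor (floor division of length) ----

maxpool1d_forward <- function(x, pool) {
  d <- dim(x); n <- d[1]; ch <- d[2]; len <- d[3]
  lo <- len %/% pool
  if (lo < 1L) stop_maacnn(sprintf("input length %d shorter than pool factor %d", len, pool))
  out <- array(-Inf, c(n, ch, lo))
  arg <- array(1L, c(n, ch, lo))
  for (j in seq_len(pool)) {
    slice <- x[, , seq.int(j, by = pool, length.out = lo), drop = FALSE]
    upd <- slice > out
    out[upd] <- slice[upd]
    arg[upd] <- j
  }
  list(out = out, cache = list(arg = arg, pool = pool, dims = d, lo = lo))
}

maxpool1d_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  lo <- cache$lo; pool <- cache$pool
  for (j in seq_len(pool)) {
    idx <- seq.int(j, by = pool, length.out = lo)
    mask <- (cache$arg == j) * dout
    dx[, , idx] <- dx[, , idx] + mask
  }
  dx
}

## ---- dropout (inverted scaling; identity in eval mode) ----

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

## ---- dense layer ----

dense_init <- function(d_in, d_out) {
  list(W = nn_init_mat(d_in, d_out), b = numeric(d_out))
}

dense_forward <- function(x, p) {
  list(out = sweep(x %*% p$W, 2L, p$b, `+`), cache = list(x = x))
}

dense_backward <- function(dout, p, cache) {
  list(dx = dout %*% t(p$W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

## ---- softmax + cross-entropy ----

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class labels in 0..(K-1); returns mean cross-entropy and the
# gradient of the mean loss w.r.t. the logits.
softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  probs <- softmax_rows(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}

## ---- SGD with momentum ----

# params/grads/velocity are parallel (possibly nested, possibly unnamed)
# lists of numeric arrays; NULL gradient entries are left untouched.
sgd_update <- function(params, grads, velocity, lr, momentum) {
  if (length(velocity) == 0L) {
    velocity <- vector("list", length(grads))
    names(velocity) <- names(grads)
  }
  keys <- if (is.null(names(grads))) seq_along(grads) else names(grads)
  for (nm in keys) {
    if (is.null(grads[[nm]])) next
    if (is.list(grads[[nm]])) {
      upd <- sgd_update(params[[nm]], grads[[nm]],
                        velocity[[nm]] %||% list(), lr, momentum)
      params[[nm]] <- upd$params
      velocity[[nm]] <- upd$velocity
    } else {
      v <- velocity[[nm]]
      if (is.null(v)) v <- 0 * grads[[nm]]
      v <- momentum * v - lr * grads[[nm]]
      params[[nm]] <- params[[nm]] + v
      velocity[[nm]] <- v
    }
  }
  list(params = params, velocity = velocity)
}
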