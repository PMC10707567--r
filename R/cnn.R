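# The 1D convolutional classifier: conv blocks (convolution -> rectifier
# -> batch normalization -> max pooling -> dropout), an additive skip
# connection with a 1x1 projection, flatten, a rectified dense layer, and
# a softmax head over (HC, ASD). L2 weight decay applies to convolution
# and dense weights only.

#' CNN configuration
#'
#' Defaults follow the design used throughout the package: three conv
#' blocks with channels (16, 32, 64), kernel 5, pooling 2, dropout 0.3,
#' dense width 128, L2 coefficient 1e-4, and one skip connection spanning
#' blocks 1-2. All of it is overridable; reduced settings are used for
#' desk-scale synthetic runs.
#'
#' @param n_blocks Number of conv blocks.
#' @param channels Integer vector of output channels, one per block.
#' @param kernel_size Odd convolution kernel width.
#' @param pool_factor Max-pooling factor applied in every block.
#' @param dropout_rate Dropout probability in `[0, 1)` (training only).
#' @param l2_coefficient Nonnegative L2 weight-decay coefficient.
#' @param dense_width Width of the rectified dense layer before softmax.
#' @param skip List of length-2 integer vectors; each `c(s, e)` adds a
#'   shortcut from the input of block `s` to the output of block `e`.
#' @param learning_rate,momentum,epochs,batch_size SGD settings.
#' @return A `"cnn_config"` list.
#' @export
cnn_config <- function(n_blocks = 3L, channels = c(16L, 32L, 64L),
                       kernel_size = 5L, pool_factor = 2L,
                       dropout_rate = 0.3, l2_coefficient = 1e-4,
                       dense_width = 128L, skip = list(c(1L, 2L)),
                       learning_rate = 1e-4, momentum = 0.9,
                       epochs = 200L, batch_size = 32L) {
  n_blocks <- as.integer(n_blocks)
  channels <- as.integer(channels)
  if (length(channels) != n_blocks) {
    stop_maacnn("channels must have one entry per block")
  }
  if (kernel_size %% 2L != 1L || kernel_size < 1L) {
    stop_maacnn("kernel_size must be a positive odd integer")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop_maacnn("dropout_rate must be in [0, 1)")
  if (l2_coefficient < 0) stop_maacnn("l2_coefficient must be nonnegative")
  if (missing(skip)) {
    # the default span only applies to networks deep enough to hold it
    skip <- Filter(function(sp) sp[2] <= n_blocks, skip)
  }
  for (sp in skip) {
    if (length(sp) != 2L || sp[1] > sp[2] || sp[1] < 1L || sp[2] > n_blocks) {
      stop_maacnn("each skip must be c(start, end) with 1 <= start <= end <= n_blocks")
    }
  }
  structure(list(n_blocks = n_blocks, channels = channels,
                 kernel_size = as.integer(kernel_size),
                 pool_factor = as.integer(pool_factor),
                 dropout_rate = dropout_rate, l2_coefficient = l2_coefficient,
                 dense_width = as.integer(dense_width), skip = skip,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size)),
            class = "cnn_config")
}

#' Initialize CNN parameters
#'
#' @param cfg A [cnn_config()].
#' @param input_len Input sequence length (the fused feature width F).
#' @param in_ch Input channel count (1 for fused feature vectors).
#' @param n_classes Number of output classes (2: HC, ASD).
#' @param seed Optional integer seed.
#' @return A `"cnn_model"` holding all parameters and the architecture.
#' @export
cnn_init <- function(cfg, input_len, in_ch = 1L, n_classes = 2L, seed = NULL) {
  stopifnot(inherits(cfg, "cnn_config"))
  input_len <- as.integer(input_len)
  len <- input_len
  for (b in seq_len(cfg$n_blocks)) {
    if (len < cfg$pool_factor) {
      stop_maacnn(sprintf(
        "block %d: length %d shorter than pool factor %d for input length %d",
        b, len, cfg$pool_factor, input_len))
    }
    len <- len %/% cfg$pool_factor
  }
  if (len < 1L) stop_maacnn("no spatial positions left after pooling")
  with_seed(seed, {
    blocks <- vector("list", cfg$n_blocks)
    ch_in <- in_ch
    for (b in seq_len(cfg$n_blocks)) {
      blocks[[b]] <- list(conv = conv1d_init(ch_in, cfg$channels[b], cfg$kernel_size),
                          bn = bn_init(cfg$channels[b]))
      ch_in <- cfg$channels[b]
    }
    # 1x1 projection per skip span; identity when shapes already match
    projs <- lapply(cfg$skip, function(sp) {
      from_ch <- if (sp[1] == 1L) in_ch else cfg$channels[sp[1] - 1L]
      to_ch <- cfg$channels[sp[2]]
      if (from_ch == to_ch) NULL else conv1d_init(from_ch, to_ch, 1L)
    })
    flat <- len * cfg$channels[cfg$n_blocks]
    structure(list(config = cfg, input_len = input_len, in_ch = in_ch,
                   blocks = blocks, projs = projs,
                   dense1 = dense_init(flat, cfg$dense_width),
                   dense2 = dense_init(cfg$dense_width, n_classes),
                   flat_len = len),
              class = "cnn_model")
  })
}

#' One convolutional block
#'
#' Applies, in order: same-padded 1D convolution, rectifier, batch
#' normalization, max pooling by the pool factor, and dropout (active only
#' when `training = TRUE`). Output length is `floor(input length / pool)`.
#'
#' @param x Feature map array `[N, C, L]` (a plain `N x L` matrix is
#'   treated as single-channel).
#' @param block List with `conv` and `bn` parameters (as built by
#'   [cnn_init()]).
#' @param pool_factor Max-pooling factor.
#' @param dropout_rate Dropout probability.
#' @param training Logical; enables batch statistics and dropout.
#' @return List with `out` (the block output), `cache` (for backprop) and
#'   `state` (updated batch-norm running statistics, when training).
#' @export
conv_block <- function(x, block, pool_factor, dropout_rate, training = FALSE) {
  x <- as_feature_map(x)
  cv <- conv1d_forward(x, block$conv)
  a <- relu(cv$out)
  bn <- bn_forward(a, block$bn, training)
  if (dim(bn$out)[3] < pool_factor) {
    stop_maacnn(sprintf("block input length %d shorter than pool factor %d",
                        dim(x)[3], pool_factor))
  }
  mp <- maxpool1d_forward(bn$out, pool_factor)
  dp <- dropout_forward(mp$out, dropout_rate, training)
  list(out = dp$out,
       cache = list(conv = cv$cache, act = cv$out, bn = bn$cache,
                    mp = mp$cache, dp = dp$cache),
       state = bn$state)
}

conv_block_backward <- function(dout, block, cache) {
  d1 <- dropout_backward(dout, cache$dp)
  d2 <- maxpool1d_backward(d1, cache$mp)
  d3 <- bn_backward(d2, block$bn, cache$bn)
  d4 <- d3$dx * (cache$act > 0)
  cv <- conv1d_backward(d4, block$conv, cache$conv)
  list(dx = cv$dx,
       grads = list(conv = list(W = cv$dW, b = cv$db),
                    bn = list(gamma = d3$dgamma, beta = d3$dbeta)))
}

#' Additive skip connection with 1x1 projection
#'
#' Implements `output = Conv(x) + G(x)`: the shortcut `Conv(x)` is a 1x1
#' convolution adjusting the channel count of the span input `x` to match
#' the main path `G(x)`, followed by max pooling with the span's total
#' pooling factor so lengths align. When input and output shapes already
#' match, the projection defaults to the identity.
#'
#' @param x Feature map at the start of the spanned blocks.
#' @param main Feature map produced by the spanned blocks.
#' @param proj 1x1 convolution parameters, or `NULL` for identity.
#' @param pool_total Product of the pool factors applied along the main
#'   path (1 if none).
#' @return List with `out` (the elementwise sum) and `cache`.
#' @export
skip_connect <- function(x, main, proj = NULL, pool_total = 1L) {
  x <- as_feature_map(x)
  main <- as_feature_map(main)
  cache <- list(proj = NULL, mp = NULL)
  sc <- x
  if (!is.null(proj)) {
    pf <- conv1d_forward(sc, proj)
    sc <- pf$out
    cache$proj <- pf$cache
  }
  if (pool_total > 1L) {
    mp <- maxpool1d_forward(sc, pool_total)
    sc <- mp$out
    cache$mp <- mp$cache
  }
  if (!all(dim(sc) == dim(main))) {
    stop_maacnn(sprintf(
      "skip connection shapes irreconcilable: shortcut [%s] vs main path [%s]",
      paste(dim(sc), collapse = "x"), paste(dim(main), collapse = "x")))
  }
  list(out = main + sc, cache = cache)
}

skip_connect_backward <- function(dout, proj, cache) {
  dsc <- dout
  if (!is.null(cache$mp)) dsc <- maxpool1d_backward(dsc, cache$mp)
  grads <- NULL
  if (!is.null(cache$proj)) {
    cv <- conv1d_backward(dsc, proj, cache$proj)
    dsc <- cv$dx
    grads <- list(W = cv$dW, b = cv$db)
  }
  list(dmain = dout, dx = dsc, grads = grads)
}

#' Forward pass of the CNN classifier
#'
#' Treats each row of the `N x F` input as a single-channel length-F
#' sequence and produces class probabilities. Probability columns are
#' ordered (HC, ASD); each row sums to 1 by construction.
#'
#' @param model A `"cnn_model"` from [cnn_init()].
#' @param x `N x F` matrix or `[N, C, F]` array.
#' @param training Logical; batch statistics and dropout are active only
#'   when `TRUE`.
#' @return List with `probs` (`N x 2`), `logits`, `cache` (when training
#'   is of interest for backprop) and `state` (batch-norm updates).
#' @export
cnn_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  x <- as_feature_map(x)
  if (dim(x)[3] != model$input_len || dim(x)[2] != model$in_ch) {
    stop_maacnn(sprintf("input [%s] does not match model (%d channels, length %d)",
                        paste(dim(x), collapse = "x"), model$in_ch, model$input_len))
  }
  skip_start <- vapply(cfg$skip, `[`, integer(1), 1L)
  caches <- vector("list", cfg$n_blocks)
  skip_in <- vector("list", length(cfg$skip))
  skip_caches <- vector("list", length(cfg$skip))
  states <- vector("list", cfg$n_blocks)
  h <- x
  for (b in seq_len(cfg$n_blocks)) {
    for (si in which(skip_start == b)) skip_in[[si]] <- h
    blk <- conv_block(h, model$blocks[[b]], cfg$pool_factor,
                      cfg$dropout_rate, training)
    caches[[b]] <- blk$cache
    states[[b]] <- blk$state
    h <- blk$out
    for (si in seq_along(cfg$skip)) {
      if (cfg$skip[[si]][2] == b) {
        span <- cfg$skip[[si]][2] - cfg$skip[[si]][1] + 1L
        sk <- skip_connect(skip_in[[si]], h, model$projs[[si]],
                           cfg$pool_factor^span)
        h <- sk$out
        skip_caches[[si]] <- sk$cache
      }
    }
    if (!all(is.finite(h))) {
      stop_maacnn(sprintf("non-finite activations after block %d", b))
    }
  }
  n <- dim(h)[1]
  flat <- matrix(aperm(h, c(1L, 3L, 2L)), n, prod(dim(h)[2:3]))
  d1 <- dense_forward(flat, model$dense1)
  a1 <- relu(d1$out)
  d2 <- dense_forward(a1, model$dense2)
  probs <- softmax_rows(d2$out)
  list(probs = probs, logits = d2$out,
       cache = list(blocks = caches, skips = skip_caches, flat = flat,
                    d1 = d1$cache, a1_pre = d1$out, a1 = a1, d2 = d2$cache,
                    hdim = dim(h)),
       state = states)
}

# Backward pass from dlogits; returns grads mirroring the model structure
# plus the gradient w.r.t. the input feature map (needed to train the
# attention block jointly).
cnn_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  b2 <- dense_backward(dlogits, model$dense2, cache$d2)
  da1 <- b2$dx * (cache$a1_pre > 0)
  b1 <- dense_backward(da1, model$dense1, cache$d1)
  n <- nrow(cache$flat)
  hdim <- cache$hdim
  dh <- aperm(array(b1$dx, c(n, hdim[3], hdim[2])), c(1L, 3L, 2L))
  block_grads <- vector("list", cfg$n_blocks)
  proj_grads <- vector("list", length(cfg$skip))
  dskip_in <- vector("list", length(cfg$skip))
  for (b in rev(seq_len(cfg$n_blocks))) {
    for (si in seq_along(cfg$skip)) {
      if (cfg$skip[[si]][2] == b) {
        sb <- skip_connect_backward(dh, model$projs[[si]], cache$skips[[si]])
        dh <- sb$dmain
        dskip_in[[si]] <- sb$dx
        proj_grads[[si]] <- sb$grads
      }
    }
    bb <- conv_block_backward(dh, model$blocks[[b]], cache$blocks[[b]])
    dh <- bb$dx
    block_grads[[b]] <- bb$grads
    for (si in seq_along(cfg$skip)) {
      if (cfg$skip[[si]][1] == b) dh <- dh + dskip_in[[si]]
    }
  }
  list(dx = dh, blocks = block_grads, projs = proj_grads,
       dense1 = list(W = b1$dW, b = b1$db),
       dense2 = list(W = b2$dW, b = b2$db))
}

#' L2 weight penalty
#'
#' `lambda * sum(w^2)` over convolution and dense weight matrices —
#' biases and batch-normalization parameters are exempt. Added to the
#' training loss.
#'
#' @param model A `"cnn_model"` (or any nested parameter list with `W`
#'   entries under `blocks`, `projs`, `dense1`, `dense2`).
#' @param lambda Nonnegative coefficient.
#' @return The penalty value.
#' @export
l2_penalty <- function(model, lambda) {
  if (lambda < 0) stop_maacnn("lambda must be nonnegative")
  if (lambda == 0) return(0)
  s <- 0
  for (blk in model$blocks) s <- s + sum(blk$conv$W^2)
  for (pj in model$projs) if (!is.null(pj)) s <- s + sum(pj$W^2)
  s <- s + sum(model$dense1$W^2) + sum(model$dense2$W^2)
  lambda * s
}

#' Predicted class labels from probabilities
#'
#' Threshold 0.5 on the ASD probability (column 2); a tie at exactly 0.5
#' is broken toward HC.
#'
#' @param probs `N x 2` probability matrix with columns (HC, ASD).
#' @return Integer vector of 0 (HC) / 1 (ASD).
#' @export
predict_labels <- function(probs) {
  as.integer(probs[, 2L] > 0.5)
}

#' Train the CNN alone on a feature matrix
#'
#' Minibatch SGD with momentum on softmax cross-entropy plus
#' [l2_penalty()]. This is the single-view classifier used by the
#' ablation arms; the full model trains the CNN jointly with the
#' attention block via [maacnn()].
#'
#' @param x `N x F` feature matrix.
#' @param y Integer labels, 0 = HC, 1 = ASD.
#' @param cfg A [cnn_config()].
#' @param seed Optional integer seed.
#' @return A `"cnn_fit"` with the trained `model` and per-epoch `loss`.
#' @export
cnn_train <- function(x, y, cfg, seed = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x))
  leakage_check(rownames(x), "cnn_train")
  with_seed(seed, {
    model <- cnn_init(cfg, ncol(x), seed = NULL)
    vel <- list()
    n <- nrow(x)
    bs <- min(cfg$batch_size, n)
    loss_hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq.int(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        step <- cnn_sgd_step(model, x[idx, , drop = FALSE], y[idx], vel)
        model <- step$model; vel <- step$vel
        ep_loss <- ep_loss + step$loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      loss_hist[ep] <- ep_loss / ep_n
    }
    structure(list(model = model, loss = loss_hist, config = cfg),
              class = "cnn_fit")
  })
}

# One SGD step of the stand-alone CNN (used by cnn_train).
cnn_sgd_step <- function(model, xb, yb, vel) {
  cfg <- model$config
  fw <- cnn_forward(model, xb, training = TRUE)
  sm <- softmax_xent(fw$logits, yb)
  loss <- sm$loss + l2_penalty(model, cfg$l2_coefficient)
  if (!is.finite(loss)) {
    stop_maacnn("CNN training diverged (non-finite loss); lower the learning rate")
  }
  gr <- cnn_backward(model, fw$cache, sm$dlogits)
  gr <- add_l2_grads(model, gr, cfg$l2_coefficient)
  model <- bn_commit(model, fw$state)
  upd <- sgd_update(
    params = model[c("blocks", "projs", "dense1", "dense2")],
    grads = list(blocks = gr$blocks, projs = gr$projs,
                 dense1 = gr$dense1, dense2 = gr$dense2),
    velocity = vel, lr = cfg$learning_rate, momentum = cfg$momentum)
  model[c("blocks", "projs", "dense1", "dense2")] <- upd$params
  list(model = model, vel = upd$velocity, loss = loss)
}

# Weight-decay gradient: d(lambda * sum(W^2))/dW = 2 lambda W.
add_l2_grads <- function(model, gr, lambda) {
  if (lambda == 0) return(gr)
  for (b in seq_along(model$blocks)) {
    gr$blocks[[b]]$conv$W <- gr$blocks[[b]]$conv$W + 2 * lambda * model$blocks[[b]]$conv$W
  }
  for (s in seq_along(model$projs)) {
    if (!is.null(model$projs[[s]])) {
      gr$projs[[s]]$W <- gr$projs[[s]]$W + 2 * lambda * model$projs[[s]]$W
    }
  }
  gr$dense1$W <- gr$dense1$W + 2 * lambda * model$dense1$W
  gr$dense2$W <- gr$dense2$W + 2 * lambda * model$dense2$W
  gr
}

# Fold updated batch-norm running statistics back into the model.
bn_commit <- function(model, states) {
  for (b in seq_along(states)) {
    if (!is.null(states[[b]])) {
      model$blocks[[b]]$bn$running_mean <- states[[b]]$running_mean
      model$blocks[[b]]$bn$running_var <- states[[b]]$running_var
    }
  }
  model
}
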