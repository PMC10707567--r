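test_that("configuration invariants are enforced", {
  expect_error(cnn_config(n_blocks = 2, channels = c(4, 8, 16)), "one entry per block")
  expect_error(cnn_config(kernel_size = 4), "odd")
  expect_error(cnn_config(dropout_rate = 1), "dropout")
  expect_error(cnn_config(skip = list(c(2, 1))), "skip")
  # pooling must leave at least one position
  cfg <- cnn_config(n_blocks = 3, channels = c(2, 2, 2), pool_factor = 4)
  expect_error(cnn_init(cfg, 8L), "pool factor")
})

test_that("a conv block halves length under pool 2 and respects eval mode", {
  cfg <- cnn_config(n_blocks = 1, channels = 4L, kernel_size = 3L,
                    dropout_rate = 0.5)
  mod <- cnn_init(cfg, 2000L, seed = 1)
  x <- array(rnorm(3 * 1 * 2000), c(3, 1, 2000))
  out <- conv_block(x, mod$blocks[[1]], pool_factor = 2L, dropout_rate = 0.5,
                    training = FALSE)
  expect_identical(dim(out$out), c(3L, 4L, 1000L))
  # eval-mode output is independent of the dropout RNG
  set.seed(1); o1 <- conv_block(x, mod$blocks[[1]], 2L, 0.5, training = FALSE)$out
  set.seed(2); o2 <- conv_block(x, mod$blocks[[1]], 2L, 0.5, training = FALSE)$out
  expect_identical(o1, o2)
})

test_that("zero convolution weights produce per-channel constants", {
  # conv -> relu -> bn on an all-zero pre-activation gives beta per channel
  cfg <- cnn_config(n_blocks = 1, channels = 2L, kernel_size = 3L,
                    dropout_rate = 0)
  mod <- cnn_init(cfg, 8L, seed = 1)
  mod$blocks[[1]]$conv$W[] <- 0
  mod$blocks[[1]]$conv$b[] <- 0
  x <- array(rnorm(8), c(1, 1, 8))
  out <- conv_block(x, mod$blocks[[1]], 2L, 0, training = TRUE)$out
  for (ch in 1:2) {
    expect_equal(unname(out[1, ch, ]),
                 rep(mod$blocks[[1]]$bn$beta[ch], 4),
                 tolerance = 1e-12)
  }
})

test_that("skip connection reduces to identity with a zero main path", {
  x <- array(rnorm(2 * 4 * 6), c(2, 4, 6))
  out <- skip_connect(x, main = 0 * x, proj = NULL, pool_total = 1L)
  expect_identical(out$out, x)
})

test_that("the 1x1 projection matches hand-computed arithmetic and shapes", {
  # hand-set projection on a 1 x 2 x 4 input, zero main path
  proj <- conv1d_init_for_test(2L, 3L, 1L)
  proj$W <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2)  # in_ch x out_ch
  proj$b <- c(0.5, 0, -0.5)
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(1, 2, 4))  # x[1,ch,l]
  out <- skip_connect(x, main = array(0, c(1, 3, 4)), proj = proj,
                      pool_total = 1L)
  for (l in 1:4) {
    want <- drop(x[1, , l] %*% proj$W) + proj$b
    expect_equal(unname(out$out[1, , l]), unname(want))
  }
  # channel/length mismatch resolved to the main path's shape
  main <- array(rnorm(1 * 8 * 2), c(1, 8, 2))
  proj2 <- conv1d_init_for_test(2L, 8L, 1L)
  out2 <- skip_connect(x, main, proj2, pool_total = 2L)
  expect_identical(dim(out2$out), c(1L, 8L, 2L))
  # irreconcilable lengths raise an architecture error
  expect_error(skip_connect(x, array(0, c(1, 8, 3)), proj2, pool_total = 2L),
               "irreconcilable")
})

test_that("shortcut shapes align across a sweep of configurations", {
  set.seed(10)
  for (pool in c(2L, 3L)) {
    for (span in list(c(1L, 1L), c(1L, 2L), c(2L, 2L))) {
      cfg <- cnn_config(n_blocks = 2L, channels = c(3L, 5L), kernel_size = 3L,
                        pool_factor = pool, dropout_rate = 0,
                        skip = list(span), dense_width = 8L)
      mod <- cnn_init(cfg, 24L, seed = 1)
      out <- cnn_forward(mod, matrix(rnorm(4 * 24), 4, 24))
      expect_identical(dim(out$probs), c(4L, 2L))
      expect_equal(rowSums(out$probs), rep(1, 4), tolerance = 1e-6)
    }
  }
})

test_that("forward output is a probability table with documented tie-break", {
  cfg <- cnn_config(n_blocks = 2, channels = c(4L, 8L), kernel_size = 3L,
                    dense_width = 16L, dropout_rate = 0.3)
  mod <- cnn_init(cfg, 32L, seed = 2)
  x <- matrix(rnorm(6 * 32), 6, 32)
  out <- cnn_forward(mod, x)
  expect_equal(rowSums(out$probs), rep(1, 6), tolerance = 1e-6)
  # duplicated rows give duplicated outputs in eval mode
  x2 <- x[c(1, 1, 2), ]
  out2 <- cnn_forward(mod, x2)
  expect_equal(out2$probs[1, ], out2$probs[2, ])
  # all-zero weights give perfectly symmetric logits
  z <- mod
  for (b in seq_along(z$blocks)) { z$blocks[[b]]$conv$W[] <- 0; z$blocks[[b]]$conv$b[] <- 0 }
  for (s in seq_along(z$projs)) if (!is.null(z$projs[[s]])) { z$projs[[s]]$W[] <- 0; z$projs[[s]]$b[] <- 0 }
  z$dense1$W[] <- 0; z$dense1$b[] <- 0; z$dense2$W[] <- 0; z$dense2$b[] <- 0
  pz <- cnn_forward(z, x[1, , drop = FALSE])$probs
  expect_equal(unname(pz), matrix(0.5, 1, 2))
  # ties at 0.5 resolve to HC
  expect_identical(predict_labels(pz), 0L)
})

test_that("L2 penalty covers weights only and matches a sum-square oracle", {
  cfg <- cnn_config(n_blocks = 2, channels = c(3L, 4L), kernel_size = 3L,
                    dense_width = 8L)
  mod <- cnn_init(cfg, 16L, seed = 3)
  expect_identical(l2_penalty(mod, 0), 0)
  # single weight 2.0 at lambda 0.5 contributes 2.0
  tiny <- mod
  for (b in seq_along(tiny$blocks)) { tiny$blocks[[b]]$conv$W[] <- 0 }
  for (s in seq_along(tiny$projs)) if (!is.null(tiny$projs[[s]])) tiny$projs[[s]]$W[] <- 0
  tiny$dense1$W[] <- 0; tiny$dense2$W[] <- 0
  tiny$dense1$W[1, 1] <- 2
  expect_equal(l2_penalty(tiny, 0.5), 2)
  # oracle: flatten-square-sum over all weight matrices
  oracle <- sum(unlist(lapply(mod$blocks, function(b) b$conv$W^2))) +
    sum(unlist(lapply(mod$projs, function(p) if (is.null(p)) 0 else p$W^2))) +
    sum(mod$dense1$W^2) + sum(mod$dense2$W^2)
  expect_equal(l2_penalty(mod, 0.3), 0.3 * oracle)
  # biases and batch-norm parameters are exempt
  pert <- mod
  pert$dense1$b <- pert$dense1$b + 100
  pert$blocks[[1]]$bn$gamma <- pert$blocks[[1]]$bn$gamma * 9
  expect_equal(l2_penalty(pert, 0.3), l2_penalty(mod, 0.3))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- cnn_config(n_blocks = 2, channels = c(3L, 5L), kernel_size = 3L,
                    pool_factor = 2L, dropout_rate = 0, l2_coefficient = 0,
                    dense_width = 7L, skip = list(c(1L, 2L)))
  mod <- cnn_init(cfg, 12L, seed = 2)
  x <- matrix(rnorm(4 * 12), 4, 12)
  y <- c(0L, 1L, 1L, 0L)
  lossfn <- function(m) {
    fw <- cnn_forward(m, x, training = TRUE)
    maacnn:::softmax_xent(fw$logits, y)$loss
  }
  fw <- cnn_forward(mod, x, training = TRUE)
  sm <- maacnn:::softmax_xent(fw$logits, y)
  gr <- maacnn:::cnn_backward(mod, fw$cache, sm$dlogits)
  eps <- 1e-6
  relerr <- function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b))
  paths <- list(
    list(get = function(m) m$blocks[[1]]$conv$W,
         set = function(m, g) { m$blocks[[1]]$conv$W <- g; m },
         grad = gr$blocks[[1]]$conv$W),
    list(get = function(m) m$blocks[[2]]$bn$gamma,
         set = function(m, g) { m$blocks[[2]]$bn$gamma <- g; m },
         grad = gr$blocks[[2]]$bn$gamma),
    list(get = function(m) m$projs[[1]]$W,
         set = function(m, g) { m$projs[[1]]$W <- g; m },
         grad = gr$projs[[1]]$W),
    list(get = function(m) m$dense1$W,
         set = function(m, g) { m$dense1$W <- g; m },
         grad = gr$dense1$W)
  )
  for (p in paths) {
    for (t in 1:3) {
      i <- sample(length(p$get(mod)), 1)
      mp <- mod; g <- p$get(mp); g[i] <- g[i] + eps; mp <- p$set(mp, g)
      mm <- mod; g <- p$get(mm); g[i] <- g[i] - eps; mm <- p$set(mm, g)
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_lt(relerr(num, p$grad[i]), 1e-5)
    }
  }
})

test_that("the CNN can overfit a small separable training set", {
  toy <- encoded_toy_views(n_per_class = 15L, f = 16L, shift = 1.5, seed = 2)
  cfg <- cnn_config(n_blocks = 2, channels = c(4L, 8L), kernel_size = 3L,
                    pool_factor = 2L, dropout_rate = 0.1, l2_coefficient = 1e-4,
                    dense_width = 16L, skip = list(c(1L, 2L)),
                    learning_rate = 0.01, epochs = 200L, batch_size = 10L)
  fit <- cnn_train(toy$views$v1, toy$y, cfg, seed = 5)
  acc <- mean(predict_labels(cnn_forward(fit$model, toy$views$v1)$probs) == toy$y)
  expect_gte(acc, 0.9)
  expect_true(all(is.finite(fit$loss)))
})
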