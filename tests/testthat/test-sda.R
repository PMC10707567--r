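test_that("default SDA configurations reproduce the published widths", {
  aal <- default_sda_config(atlas_spec("AAL", 116))
  expect_identical(aal$dae1$input_dim, 6670L)
  expect_identical(aal$dae1$hidden_dim, 3330L)
  expect_identical(aal$dae2$input_dim, 3330L)
  expect_identical(aal$dae2$hidden_dim, 2000L)
  expect_equal(aal$dae1$corruption_rate, 0.30)
  expect_equal(aal$dae2$corruption_rate, 0.10)
  expect_equal(aal$dae1$learning_rate, 1e-4)
  expect_equal(aal$dae1$momentum, 0.9)
  expect_identical(aal$dae1$epochs, 200L)

  cc <- default_sda_config(atlas_spec("CC200", 200))
  expect_identical(cc$dae1$hidden_dim, 9950L)
  expect_identical(cc$dae2$hidden_dim, 2000L)

  # halving rule for custom atlases, with a test-scale F override
  cus <- default_sda_config(atlas_spec("CUSTOM", 15), f_dim = 20L)
  expect_identical(cus$dae1$input_dim, 105L)
  expect_identical(cus$dae1$hidden_dim, 53L)
  expect_identical(cus$dae2$hidden_dim, 20L)

  # non-compressive stage 2 is rejected
  expect_error(default_sda_config(atlas_spec("SMALL", 10), f_dim = 30L),
               "non-compressive")
  expect_error(dae_config(10, 10, 0.3), "non-compressive")
  expect_error(dae_config(10, 5, 1.5), "corruption_rate")
})

test_that("masking corruption hits its nominal rate and its edge cases", {
  x <- rnorm(50)
  expect_identical(corrupt(x, 0), x)
  expect_identical(corrupt(x, 1), x * 0)
  set.seed(8)
  big <- rep(1, 1e5)
  frac <- mean(corrupt(big, 0.3) == 0)
  expect_lt(abs(frac - 0.3), 0.01)
  expect_error(corrupt(x, -0.1), "rate")
})

test_that("a DAE reconstructs low-rank data nearly losslessly", {
  set.seed(1)
  x <- rnorm(40) %*% t(rnorm(6))  # rank-1
  cfg <- dae_config(6L, 5L, 0, learning_rate = 0.05, epochs = 500L,
                    batch_size = 8L)
  d <- train_dae(x, cfg, seed = 2)
  expect_length(d$loss, 500L)
  expect_true(all(is.finite(d$loss)))
  expect_lt(tail(d$loss, 1), 1e-3)
})

test_that("DAE training beats the mean-predictor baseline on factor data", {
  set.seed(2)
  z <- matrix(rnorm(60 * 5), 60, 5) %*% matrix(rnorm(5 * 30), 5, 30) +
    matrix(rnorm(60 * 30, sd = 0.1), 60, 30)
  z <- scale(z)
  baseline <- mean(sweep(z, 2, colMeans(z))^2)  # mean predictor MSE
  cfg <- dae_config(30L, 8L, 0.1, learning_rate = 0.02, epochs = 150L,
                    batch_size = 16L)
  d <- train_dae(z, cfg, seed = 3)
  code <- dae_encode(d, z)
  recon <- sweep(code %*% d$W2, 2, d$b2, `+`)
  expect_lt(mean((recon - z)^2), baseline)
  expect_lt(tail(d$loss, 1), d$loss[1])
})

test_that("DAE training is bit-reproducible under a fixed seed", {
  set.seed(4)
  z <- matrix(rnorm(20 * 12), 20, 12)
  cfg <- dae_config(12L, 5L, 0.3, learning_rate = 0.01, epochs = 20L,
                    batch_size = 8L)
  d1 <- train_dae(z, cfg, seed = 7)
  d2 <- train_dae(z, cfg, seed = 7)
  expect_identical(d1$loss, d2$loss)
  expect_identical(d1$W1, d2$W1)
  expect_error(train_dae(z, dae_config(13L, 5L, 0.3)), "13")
})

test_that("two-stage pretraining yields the configured code width", {
  set.seed(5)
  x <- matrix(rnorm(20 * 30), 20, 30)
  rownames(x) <- sprintf("s%02d", 1:20)
  cfg <- list(dae1 = dae_config(30L, 10L, 0.3, learning_rate = 0.02,
                                epochs = 10L, batch_size = 8L),
              dae2 = dae_config(10L, 4L, 0.1, learning_rate = 0.02,
                                epochs = 10L, batch_size = 8L))
  sda <- pretrain_sda(x, config = cfg, seed = 9)
  codes <- sda_transform(sda, x)
  expect_identical(dim(codes), c(20L, 4L))
  expect_identical(rownames(codes), rownames(x))
  expect_length(sda$dae1$loss, 10L)
  expect_length(sda$dae2$loss, 10L)
  # identical seeds give identical codes
  sda2 <- pretrain_sda(x, config = cfg, seed = 9)
  expect_identical(sda_transform(sda2, x), codes)
  expect_error(pretrain_sda(x[, 1:29], config = cfg), "29")
})

test_that("the encoder is deterministic and row-wise independent", {
  set.seed(6)
  x <- matrix(rnorm(12 * 20), 12, 20)
  cfg <- list(dae1 = dae_config(20L, 8L, 0.3, learning_rate = 0.02,
                                epochs = 5L, batch_size = 6L),
              dae2 = dae_config(8L, 3L, 0.1, learning_rate = 0.02,
                                epochs = 5L, batch_size = 6L))
  sda <- pretrain_sda(x, config = cfg, seed = 1)
  t1 <- sda_transform(sda, x)
  t2 <- sda_transform(sda, x)
  expect_identical(t1, t2)  # no corruption at inference
  a <- x[1:5, , drop = FALSE]; b <- x[6:12, , drop = FALSE]
  # row-wise independence up to floating-point reassociation in the BLAS
  expect_equal(rbind(sda_transform(sda, a), sda_transform(sda, b)), t1,
               tolerance = 1e-12)
})

test_that("encoded features of a separable cohort stay linearly separable", {
  cohort <- make_cohort(cohort_preset("separable", seed = 21))
  views <- cohort_features(cohort)
  y <- cohort$phenotypes$label
  cfg <- tiny_config()
  x <- views[[1]]
  tr <- c(1:28, 41:68); te <- setdiff(seq_along(y), tr)
  sda <- pretrain_sda(x[tr, ], config = view_sda_config_for_test(ncol(x), cfg),
                      seed = 3)
  ztr <- sda_transform(sda, x[tr, ]); zte <- sda_transform(sda, x[te, ])
  # simple ridge classifier on the codes (independent of the CNN path)
  beta <- solve(crossprod(scale(ztr)) + diag(1, ncol(ztr)),
                crossprod(scale(ztr), ifelse(y[tr] == 1, 1, -1)))
  sc <- scale(zte, center = attr(scale(ztr), "scaled:center"),
              scale = attr(scale(ztr), "scaled:scale")) %*% beta
  acc <- mean((sc > 0) == (y[te] == 1))
  expect_gte(acc, 0.7)  # at least 20 points over chance
})
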