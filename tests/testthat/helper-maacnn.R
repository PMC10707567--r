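# Shared fixtures, all built in code at test time.

# A small aligned multi-view cohort of already-encoded features with a
# class shift on the first view, for classifier-level tests.
encoded_toy_views <- function(n_per_class = 15L, f = 16L, shift = 1.5, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  mk <- function(sh) {
    x <- matrix(rnorm(n * f), n, f)
    x[y == 1L, seq_len(4)] <- x[y == 1L, seq_len(4)] + sh
    rownames(x) <- sprintf("s%02d", seq_len(n))
    x
  }
  list(views = list(v1 = mk(shift), v2 = mk(shift / 2)), y = y)
}

# Random symmetric correlation-like matrix with unit diagonal.
random_symmetric <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# Independent textbook implementation of the product-moment correlation,
# coded separately from the package path.
oracle_pearson <- function(u, v) {
  du <- u - sum(u) / length(u)
  dv <- v - sum(v) / length(v)
  sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
}

view_sda_config_for_test <- function(m, config) {
  maacnn:::view_sda_config(m, config)
}

conv1d_init_for_test <- function(in_ch, out_ch, k) {
  maacnn:::conv1d_init(in_ch, out_ch, k)
}

# A tiny reduced configuration for fast end-to-end tests.
tiny_config <- function(joint_epochs = 30L) {
  maacnn_config(
    f_dim = 8L,
    sda = list(learning_rate = 0.02, epochs = 15L, batch_size = 16L),
    cnn = list(n_blocks = 2L, channels = c(4L, 8L), kernel_size = 3L,
               pool_factor = 2L, dropout_rate = 0.1, l2_coefficient = 1e-4,
               dense_width = 16L, skip = list(c(1L, 2L)),
               learning_rate = 0.01, epochs = joint_epochs, batch_size = 16L)
  )
}
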