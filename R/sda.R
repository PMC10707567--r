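# Stacked denoising autoencoder: two chained DAEs trained greedily and
# layerwise. Each DAE corrupts its input with masking noise, encodes
# through a rectified bottleneck, and reconstructs the *clean* input with
# a linear decoder under mean-squared error. Stage two compresses the
# stage-one codes to the common width F shared by all views.

#' Configuration of one denoising autoencoder
#'
#' @param input_dim Width of the (clean) input.
#' @param hidden_dim Bottleneck width; must be smaller than `input_dim`.
#' @param corruption_rate Probability that an input coordinate is masked
#'   (set to 0) during training; in `[0, 1]`.
#' @param learning_rate SGD learning rate. The published setting is 1e-4;
#'   desk-scale runs on small synthetic cohorts use a larger rate (see
#'   [maacnn_desk_config()]).
#' @param momentum SGD momentum in `[0, 1)`.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @return A `"dae_config"` list.
#' @export
dae_config <- function(input_dim, hidden_dim, corruption_rate,
                       learning_rate = 1e-4, momentum = 0.9,
                       epochs = 200L, batch_size = 32L) {
  input_dim <- as.integer(input_dim); hidden_dim <- as.integer(hidden_dim)
  if (hidden_dim >= input_dim) {
    stop_maacnn("non-compressive autoencoder: hidden_dim must be < input_dim")
  }
  if (corruption_rate < 0 || corruption_rate > 1) {
    stop_maacnn("corruption_rate must be in [0, 1]")
  }
  if (momentum < 0 || momentum >= 1) stop_maacnn("momentum must be in [0, 1)")
  structure(list(input_dim = input_dim, hidden_dim = hidden_dim,
                 corruption_rate = corruption_rate,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size)),
            class = "dae_config")
}

# Published bottleneck widths for the named parcellations. Input widths
# always derive from the atlas ROI count as n (n - 1) / 2.
.sda_named_hidden <- c(AAL = 3330L, CC200 = 9950L, HO = 3050L,
                       Dosenbach160 = 6440L, EZ = 3380L)

#' Default two-stage SDA configuration for an atlas
#'
#' For the five named parcellations (AAL, CC200, HO, Dosenbach160, EZ) the
#' published stage-one bottleneck widths are used; for any other atlas the
#' stage-one bottleneck is half the input width (rounded up). Stage two
#' always compresses to the common width `f_dim` (2000 by default).
#' Corruption rates are 0.30 for stage one and 0.10 for stage two.
#'
#' @param atlas An [atlas_spec()].
#' @param f_dim Common encoded width shared by all views (default 2000).
#' @param ... Optimizer overrides passed to [dae_config()]
#'   (`learning_rate`, `momentum`, `epochs`, `batch_size`).
#' @return A list with elements `dae1` and `dae2`, both [dae_config()]s.
#' @examples
#' cfg <- default_sda_config(atlas_spec("AAL", 116))
#' cfg$dae1$input_dim  # 6670
#' cfg$dae2$hidden_dim # 2000
#' @export
default_sda_config <- function(atlas, f_dim = 2000L, ...) {
  stopifnot(inherits(atlas, "atlas_spec"))
  m <- atlas$feature_dim
  h1 <- if (atlas$name %in% names(.sda_named_hidden)) {
    .sda_named_hidden[[atlas$name]]
  } else {
    as.integer(ceiling(m / 2))
  }
  f_dim <- as.integer(f_dim)
  if (f_dim >= h1) {
    stop_maacnn(sprintf(
      "non-compressive stage 2: f_dim (%d) must be < stage-1 bottleneck (%d)",
      f_dim, h1))
  }
  list(dae1 = dae_config(m, h1, 0.30, ...),
       dae2 = dae_config(h1, f_dim, 0.10, ...))
}

#' Masking corruption
#'
#' Independently sets each coordinate to 0 with probability `rate`,
#' leaving it unchanged otherwise. Used only during DAE training; the
#' encoder at inference sees clean input.
#'
#' @param x Numeric vector or matrix.
#' @param rate Masking probability in `[0, 1]`.
#' @return Corrupted copy of `x`.
#' @export
corrupt <- function(x, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1) {
    stop_maacnn("corruption rate must be a single number in [0, 1]")
  }
  if (rate == 0) return(x)
  keep <- stats::runif(length(x)) >= rate
  x * keep
}

#' Train one denoising autoencoder
#'
#' Minimizes the mean-squared reconstruction error of the clean input from
#' the corrupted input with minibatch SGD and momentum. A fresh corruption
#' mask is drawn per sample per epoch.
#'
#' @param x Subject-by-feature numeric matrix (>= 2 rows).
#' @param cfg A [dae_config()]; `cfg$input_dim` must equal `ncol(x)`.
#' @param seed Optional integer seed making the run bit-reproducible.
#' @return A `"dae"` object with weights `W1, b1, W2, b2`, the config and
#'   the per-epoch mean reconstruction loss in `$loss`.
#' @export
train_dae <- function(x, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "dae_config"))
  x <- as.matrix(x)
  if (ncol(x) != cfg$input_dim) {
    stop_maacnn(sprintf("x has %d columns but config expects %d",
                        ncol(x), cfg$input_dim))
  }
  if (nrow(x) < 2L) stop_maacnn("need at least 2 training rows")
  leakage_check(rownames(x), "train_dae")
  with_seed(seed, {
    m <- cfg$input_dim; h <- cfg$hidden_dim
    W1 <- nn_init_mat(m, h); b1 <- numeric(h)
    W2 <- nn_init_mat(h, m); b2 <- numeric(m)
    vel <- list(W1 = 0 * W1, b1 = 0 * b1, W2 = 0 * W2, b2 = 0 * b2)
    n <- nrow(x)
    bs <- min(cfg$batch_size, n)
    loss_hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq.int(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        xc <- corrupt(xb, cfg$corruption_rate)
        pre <- sweep(xc %*% W1, 2L, b1, `+`)
        code <- relu(pre)
        recon <- sweep(code %*% W2, 2L, b2, `+`)
        err <- recon - xb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop_maacnn(sprintf(
            "DAE training diverged (non-finite loss at epoch %d); lower the learning rate", ep))
        }
        drecon <- 2 * err / length(err)
        dW2 <- crossprod(code, drecon); db2 <- colSums(drecon)
        dcode <- (drecon %*% t(W2)) * (pre > 0)
        dW1 <- crossprod(xc, dcode); db1 <- colSums(dcode)
        vel$W1 <- cfg$momentum * vel$W1 - cfg$learning_rate * dW1
        vel$b1 <- cfg$momentum * vel$b1 - cfg$learning_rate * db1
        vel$W2 <- cfg$momentum * vel$W2 - cfg$learning_rate * dW2
        vel$b2 <- cfg$momentum * vel$b2 - cfg$learning_rate * db2
        W1 <- W1 + vel$W1; b1 <- b1 + vel$b1
        W2 <- W2 + vel$W2; b2 <- b2 + vel$b2
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      loss_hist[ep] <- ep_loss / ep_n
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   config = cfg, loss = loss_hist),
              class = "dae")
  })
}

#' Encode data through a trained DAE's bottleneck
#'
#' Applies the encoder only (no corruption, no decoder); deterministic.
#'
#' @param dae A trained `"dae"` from [train_dae()].
#' @param x Matrix with `dae$config$input_dim` columns.
#' @return Matrix of bottleneck codes, one row per input row.
#' @export
dae_encode <- function(dae, x) {
  stopifnot(inherits(dae, "dae"))
  x <- as.matrix(x)
  if (ncol(x) != dae$config$input_dim) {
    stop_maacnn(sprintf("x has %d columns but DAE expects %d",
                        ncol(x), dae$config$input_dim))
  }
  out <- relu(sweep(x %*% dae$W1, 2L, dae$b1, `+`))
  rownames(out) <- rownames(x)
  out
}

# Per-feature standardization statistics fit on training data only.
fit_scaler <- function(x) {
  leakage_check(rownames(x), "fit_scaler")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(scaler, x) {
  out <- sweep(sweep(x, 2L, scaler$mean, `-`), 2L, scaler$sd, `/`)
  rownames(out) <- rownames(x)
  out
}

#' Pretrain the two-stage SDA for one view
#'
#' Greedy layerwise pretraining: per-feature standardization statistics
#' are fit on the training rows, DAE-1 is trained on the standardized
#' features, the data are encoded through DAE-1's bottleneck, and DAE-2 is
#' trained on those codes. Encoders are frozen afterwards; the classifier
#' never backpropagates into them.
#'
#' @param x Raw subject-by-feature matrix for one view.
#' @param atlas Optional [atlas_spec()]; when given, `ncol(x)` is checked
#'   against `atlas$feature_dim` and defaults come from
#'   [default_sda_config()].
#' @param config Optional list with `dae1` and `dae2` [dae_config()]s,
#'   overriding the atlas defaults (used for reduced-dimension runs).
#' @param standardize Fit and apply per-feature standardization (default
#'   `TRUE`).
#' @param seed Optional integer seed.
#' @return An `"sda_model"` with the scaler, both DAEs, their loss
#'   histories and the encoded width `f_dim`.
#' @export
pretrain_sda <- function(x, atlas = NULL, config = NULL,
                         standardize = TRUE, seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "atlas_spec"))
    if (ncol(x) != atlas$feature_dim) {
      stop_maacnn(sprintf("atlas '%s' expects %d features, got %d",
                          atlas$name, atlas$feature_dim, ncol(x)))
    }
  }
  if (is.null(config)) {
    if (is.null(atlas)) stop_maacnn("either atlas or config must be supplied")
    config <- default_sda_config(atlas)
  }
  if (config$dae1$input_dim != ncol(x)) {
    stop_maacnn(sprintf("config expects %d input features, got %d",
                        config$dae1$input_dim, ncol(x)))
  }
  scaler <- if (standardize) fit_scaler(x) else NULL
  z <- if (standardize) apply_scaler(scaler, x) else x
  dae1 <- train_dae(z, config$dae1, seed = child_seed(seed, "dae1"))
  h <- dae_encode(dae1, z)
  dae2 <- train_dae(h, config$dae2, seed = child_seed(seed, "dae2"))
  structure(list(atlas = atlas, scaler = scaler, dae1 = dae1, dae2 = dae2,
                 f_dim = config$dae2$hidden_dim, config = config, seed = seed),
            class = "sda_model")
}

#' Encode raw view features to the common width F
#'
#' Applies (optionally) the stored standardization and the two frozen
#' encoders; no corruption, no decoding. Deterministic and row-wise
#' independent: encoding subjects separately or together gives identical
#' results.
#'
#' @param model An `"sda_model"` from [pretrain_sda()].
#' @param x Raw feature matrix with the model's input width.
#' @return An `N x F` matrix of encoded features.
#' @export
sda_transform <- function(model, x) {
  stopifnot(inherits(model, "sda_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$dae1$config$input_dim) {
    stop_maacnn(sprintf("x has %d columns but model expects %d",
                        ncol(x), model$dae1$config$input_dim))
  }
  z <- if (!is.null(model$scaler)) apply_scaler(model$scaler, x) else x
  dae_encode(model$dae2, dae_encode(model$dae1, z))
}

#' @export
print.sda_model <- function(x, ...) {
  cat(sprintf(
    "Stacked denoising autoencoder%s: %d -> %d -> %d\n",
    if (!is.null(x$atlas)) paste0(" (", x$atlas$name, ")") else "",
    x$dae1$config$input_dim, x$dae1$config$hidden_dim, x$f_dim))
  cat(sprintf("  stage-1 final loss %.4g, stage-2 final loss %.4g\n",
              utils::tail(x$dae1$loss, 1), utils::tail(x$dae2$loss, 1)))
  invisible(x)
}
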