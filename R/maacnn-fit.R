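# The user-facing model: per-view SDA encoding, attention fusion and the
# CNN head, fitted by maacnn() and returned as a classed object with the
# usual print / summary / predict / plot methods.

#' Full model configuration
#'
#' Bundles the per-stage settings: the common encoded width `f_dim`, the
#' SDA optimizer/corruption settings, the [cnn_config()] (whose optimizer
#' settings also drive the joint attention + CNN training), and the
#' attention block options.
#'
#' The defaults mirror the published full-scale settings (F = 2000,
#' corruption 0.30/0.10, SGD with momentum 0.9 and learning rate 1e-4 for
#' 200 epochs). For small synthetic cohorts use [maacnn_desk_config()].
#'
#' @param f_dim Common encoded width for all views.
#' @param sda Named list overriding `learning_rate`, `momentum`, `epochs`,
#'   `batch_size`, `corruption` (length 2) and `hidden1` (stage-1
#'   bottleneck; `NULL` = atlas default or half the input width).
#' @param cnn Named list of [cnn_config()] overrides.
#' @param attention Named list overriding `hidden` (`NULL` = `max(4, 2n)`),
#'   `normalize` (`"softmax"` or `"none"`) and `global_weights`.
#' @return A `"maacnn_config"` list.
#' @export
maacnn_config <- function(f_dim = 2000L, sda = list(), cnn = list(),
                          attention = list()) {
  sda_def <- list(learning_rate = 1e-4, momentum = 0.9, epochs = 200L,
                  batch_size = 32L, corruption = c(0.30, 0.10), hidden1 = NULL)
  sda_def[names(sda)] <- sda
  att_def <- list(hidden = NULL, normalize = "softmax", global_weights = FALSE)
  att_def[names(attention)] <- attention
  structure(list(f_dim = as.integer(f_dim), sda = sda_def,
                 cnn = do.call(cnn_config, cnn), attention = att_def),
            class = "maacnn_config")
}

#' Desk-scale configuration for synthetic cohorts
#'
#' Reduced dimensions and an optimizer sized for cohorts of tens of
#' subjects with small parcellations (10-15 ROIs): encoded width 16,
#' two conv blocks of 8/16 channels with kernel 3, and a larger learning
#' rate so SGD converges within the short epoch budget. Used by the test
#' harnesses and the synthetic-preset pipeline.
#'
#' @param f_dim Encoded width (default 16).
#' @param epochs Joint-training epochs (default 80).
#' @return A `"maacnn_config"`.
#' @export
maacnn_desk_config <- function(f_dim = 16L, epochs = 80L) {
  maacnn_config(
    f_dim = f_dim,
    sda = list(learning_rate = 0.02, epochs = 40L, batch_size = 16L),
    cnn = list(n_blocks = 2L, channels = c(8L, 16L), kernel_size = 3L,
               pool_factor = 2L, dropout_rate = 0.1, l2_coefficient = 1e-4,
               dense_width = 32L, skip = list(c(1L, 2L)),
               learning_rate = 0.01, epochs = as.integer(epochs),
               batch_size = 16L)
  )
}

# Build the two-stage SDA config for one view under a maacnn_config.
view_sda_config <- function(m, config, atlas = NULL) {
  h1 <- config$sda$hidden1
  if (is.null(h1)) {
    h1 <- if (!is.null(atlas) && atlas$name %in% names(.sda_named_hidden)) {
      .sda_named_hidden[[atlas$name]]
    } else {
      as.integer(ceiling(m / 2))
    }
  }
  opt <- config$sda
  list(dae1 = dae_config(m, h1, opt$corruption[1], opt$learning_rate,
                         opt$momentum, opt$epochs, opt$batch_size),
       dae2 = dae_config(h1, config$f_dim, opt$corruption[2], opt$learning_rate,
                         opt$momentum, opt$epochs, opt$batch_size))
}

#' Fit the multi-atlas attention CNN
#'
#' End-to-end fit on one training set: per view, standardization
#' statistics and a two-stage denoising autoencoder are fit and the view
#' is encoded to the common width F; the attention block and the CNN are
#' then trained jointly by minibatch SGD on softmax cross-entropy with L2
#' weight decay. The encoders stay frozen during joint training.
#'
#' @param x Named list of raw subject-by-feature matrices, one per view,
#'   with identical subject order (rownames are subject ids).
#' @param y Class labels: integers 0 (HC) / 1 (ASD), or a factor/character
#'   vector with levels HC/ASD.
#' @param config A [maacnn_config()].
#' @param atlases Optional named list of [atlas_spec()]s matching `x`.
#' @param seed Integer master seed fanned out to the per-view SDA and the
#'   joint-training streams.
#' @return An object of class `"maacnn"`.
#' @examples
#' \donttest{
#' cohort <- make_cohort(cohort_preset("separable", seed = 1))
#' views <- cohort_features(cohort)
#' fit <- maacnn(views, cohort$phenotypes$label,
#'               config = maacnn_desk_config(), seed = 1)
#' print(fit)
#' head(predict(fit, views))
#' }
#' @export
maacnn <- function(x, y, config = maacnn_config(), atlases = NULL, seed = NULL) {
  stopifnot(inherits(config, "maacnn_config"))
  if (!is.list(x) || length(x) < 1L) stop_maacnn("x must be a non-empty list of view matrices")
  if (is.null(names(x))) names(x) <- paste0("view", seq_along(x))
  x <- lapply(x, as.matrix)
  check_view_alignment(x)
  y <- normalize_labels(y)
  if (length(y) != nrow(x[[1]])) stop_maacnn("length(y) must match the subject count")

  sda_models <- vector("list", length(x))
  names(sda_models) <- names(x)
  encoded <- vector("list", length(x))
  names(encoded) <- names(x)
  for (v in names(x)) {
    atlas <- atlases[[v]]
    vcfg <- view_sda_config(ncol(x[[v]]), config, atlas)
    sda_models[[v]] <- pretrain_sda(x[[v]], atlas = atlas, config = vcfg,
                                    seed = child_seed(seed, paste0("sda-", v)))
    encoded[[v]] <- sda_transform(sda_models[[v]], x[[v]])
  }

  joint <- train_joint(encoded, y, config, seed = child_seed(seed, "joint"))

  fit <- structure(list(
    views = names(x), sda = sda_models, attention = joint$attention,
    cnn = joint$cnn, config = config, seed = seed, loss = joint$loss,
    train_weights = joint$train_weights, levels = c("HC", "ASD"),
    n_subjects = length(y)
  ), class = "maacnn")
  fit$train_accuracy <- mean(predict(fit, x, type = "class") == y)
  fit
}

normalize_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    up <- trimws(toupper(y))
    out <- rep(NA_integer_, length(y))
    out[up %in% c("ASD", "1")] <- 1L
    out[up %in% c("HC", "CONTROL", "0")] <- 0L
    if (anyNA(out)) stop_maacnn("labels must be ASD/HC or 1/0")
    return(out)
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop_maacnn("labels must be 0 (HC) or 1 (ASD)")
  y
}

# Joint SGD training of attention block + CNN on frozen encoded views.
train_joint <- function(encoded, y, config, seed = NULL) {
  leakage_check(rownames(encoded[[1]]), "train_joint")
  nv <- length(encoded)
  f_dim <- ncol(encoded[[1]])
  cfg <- config$cnn
  att_cfg <- config$attention
  with_seed(seed, {
    att <- attention_init(nv, hidden = att_cfg$hidden %||% max(4L, 2L * nv))
    cnn <- cnn_init(cfg, f_dim)
    n <- length(y)
    bs <- min(cfg$batch_size, n)
    vel_cnn <- list(); vel_att <- list()
    loss_hist <- numeric(cfg$epochs)
    lam <- cfg$l2_coefficient
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq.int(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        vb <- lapply(encoded, function(e) e[idx, , drop = FALSE])
        yb <- y[idx]
        s <- global_average_pool(vb)
        af <- attention_forward(s, att, att_cfg$normalize, att_cfg$global_weights)
        stopifnot(all(af$weights >= 0))
        fused <- fuse(vb, af$weights)
        fw <- cnn_forward(cnn, fused, training = TRUE)
        sm <- softmax_xent(fw$logits, yb)
        loss <- sm$loss + l2_penalty(cnn, lam) +
          lam * (sum(att$W1^2) + sum(att$W2^2))
        if (!is.finite(loss)) {
          stop_maacnn("joint training diverged (non-finite loss); lower the learning rate")
        }
        gr <- cnn_backward(cnn, fw$cache, sm$dlogits)
        gr <- add_l2_grads(cnn, gr, lam)
        dfused <- matrix(gr$dx, length(idx), f_dim)
        dweights <- vapply(seq_len(nv),
                           function(i) rowSums(dfused * vb[[i]]),
                           numeric(length(idx)))
        if (!is.matrix(dweights)) dweights <- matrix(dweights, nrow = 1L)
        agr <- attention_backward(dweights, att, af$cache)
        agr$W1 <- agr$W1 + 2 * lam * att$W1
        agr$W2 <- agr$W2 + 2 * lam * att$W2
        cnn <- bn_commit(cnn, fw$state)
        upd <- sgd_update(cnn[c("blocks", "projs", "dense1", "dense2")],
                          list(blocks = gr$blocks, projs = gr$projs,
                               dense1 = gr$dense1, dense2 = gr$dense2),
                          vel_cnn, cfg$learning_rate, cfg$momentum)
        cnn[c("blocks", "projs", "dense1", "dense2")] <- upd$params
        vel_cnn <- upd$velocity
        upd_att <- sgd_update(att[c("W1", "b1", "W2", "b2")],
                           agr[c("W1", "b1", "W2", "b2")],
                           vel_att, cfg$learning_rate, cfg$momentum)
        att[c("W1", "b1", "W2", "b2")] <- upd_att$params
        vel_att <- upd_att$velocity
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      loss_hist[ep] <- ep_loss / ep_n
    }
    s_all <- global_average_pool(encoded)
    w_all <- view_weights(s_all, att, att_cfg$normalize, att_cfg$global_weights)
    colnames(w_all) <- names(encoded)
    list(attention = att, cnn = cnn, loss = loss_hist,
         train_weights = colMeans(w_all))
  })
}

# Shared forward path for prediction: encode, weight, fuse, classify.
maacnn_forward_views <- function(object, newdata) {
  if (!is.list(newdata)) stop_maacnn("newdata must be a named list of view matrices")
  miss <- setdiff(object$views, names(newdata))
  if (length(miss)) {
    stop_maacnn(sprintf("missing view(s) in newdata: %s", paste(miss, collapse = ", ")))
  }
  enc <- lapply(object$views, function(v) sda_transform(object$sda[[v]], as.matrix(newdata[[v]])))
  names(enc) <- object$views
  check_view_alignment(enc)
  s <- global_average_pool(enc)
  w <- view_weights(s, object$attention, object$config$attention$normalize,
                    object$config$attention$global_weights)
  colnames(w) <- object$views
  fused <- fuse(enc, w)
  probs <- cnn_forward(object$cnn, fused, training = FALSE)$probs
  colnames(probs) <- object$levels
  rownames(probs) <- rownames(enc[[1]])
  list(probs = probs, weights = w, fused = fused)
}

#' Predict method for maacnn fits
#'
#' @param object A fitted `"maacnn"`.
#' @param newdata Named list of raw view matrices (same views and feature
#'   widths as at fit time).
#' @param type `"prob"` for the `N x 2` (HC, ASD) probability matrix,
#'   `"class"` for 0/1 labels (threshold 0.5 on the ASD probability, ties
#'   toward HC), `"score"` for the ASD probability, or `"weights"` for
#'   the per-subject attention weights.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.maacnn <- function(object, newdata,
                           type = c("prob", "class", "score", "weights"), ...) {
  type <- match.arg(type)
  fw <- maacnn_forward_views(object, newdata)
  switch(type,
         prob = fw$probs,
         class = predict_labels(fw$probs),
         score = fw$probs[, 2L],
         weights = fw$weights)
}

#' @export
print.maacnn <- function(x, ...) {
  cat("Multi-atlas attention CNN fit\n")
  cat(sprintf("  views: %s\n", paste(x$views, collapse = ", ")))
  cat(sprintf("  subjects: %d, encoded width F = %d\n",
              x$n_subjects, x$config$f_dim))
  cat(sprintf("  training accuracy: %.3f\n", x$train_accuracy))
  cat(sprintf("  mean view weights: %s\n",
              paste(sprintf("%s=%.3f", names(x$train_weights), x$train_weights),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.maacnn <- function(object, ...) {
  out <- list(
    views = object$views,
    n_subjects = object$n_subjects,
    f_dim = object$config$f_dim,
    train_accuracy = object$train_accuracy,
    train_weights = object$train_weights,
    final_joint_loss = utils::tail(object$loss, 1),
    sda_final_losses = vapply(object$sda, function(m) {
      c(stage1 = utils::tail(m$dae1$loss, 1), stage2 = utils::tail(m$dae2$loss, 1))
    }, numeric(2))
  )
  class(out) <- "summary.maacnn"
  out
}

#' @export
print.summary.maacnn <- function(x, ...) {
  cat("Multi-atlas attention CNN\n")
  cat(sprintf("  %d subjects, %d views (%s), F = %d\n", x$n_subjects,
              length(x$views), paste(x$views, collapse = ", "), x$f_dim))
  cat(sprintf("  joint training loss (final): %.4f\n", x$final_joint_loss))
  cat("  SDA reconstruction losses (final):\n")
  for (v in colnames(x$sda_final_losses)) {
    cat(sprintf("    %s: stage1 %.4f, stage2 %.4f\n", v,
                x$sda_final_losses["stage1", v], x$sda_final_losses["stage2", v]))
  }
  cat(sprintf("  training accuracy %.3f; mean view weights: %s\n",
              x$train_accuracy,
              paste(sprintf("%s=%.3f", names(x$train_weights), x$train_weights),
                    collapse = ", ")))
  invisible(x)
}

#' Plot training diagnostics
#'
#' Draws the joint-training loss curve and, optionally, the per-view SDA
#' reconstruction losses.
#'
#' @param x A fitted `"maacnn"`.
#' @param which `"joint"` or `"sda"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.maacnn <- function(x, which = c("joint", "sda"), ...) {
  which <- match.arg(which)
  if (which == "joint") {
    graphics::plot(seq_along(x$loss), x$loss, type = "l",
                   xlab = "epoch", ylab = "training loss",
                   main = "Joint attention + CNN training", ...)
  } else {
    losses <- lapply(x$sda, function(m) m$dae1$loss)
    graphics::plot(NULL, xlim = c(1, max(lengths(losses))),
                   ylim = range(unlist(losses)),
                   xlab = "epoch", ylab = "reconstruction MSE",
                   main = "Stage-1 DAE training", ...)
    for (i in seq_along(losses)) {
      graphics::lines(seq_along(losses[[i]]), losses[[i]], col = i)
    }
    graphics::legend("topright", legend = names(losses), col = seq_along(losses),
                     lty = 1, bty = "n")
  }
  invisible(x)
}
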