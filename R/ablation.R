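# Ablation harness: four model variants evaluated under identical folds
# and seeds, isolating the contribution of the SDA and of the multi-view
# attention block. Arms without the SDA use recursive feature
# elimination to reach the same input width F, keeping the classifier
# hyperparameters comparable.

#' Run the four-arm ablation study
#'
#' Evaluates, under identical stratified folds and seeds:
#' \enumerate{
#'   \item \strong{CNN} — single view (the first in `x`), RFE to F, CNN.
#'   \item \strong{CNN + SDA} — single view, SDA encoding, CNN.
#'   \item \strong{CNN + attention (RFE features)} — all views, RFE to F
#'     per view, attention fusion + CNN (no SDA).
#'   \item \strong{full model} — all views, SDA, attention fusion + CNN.
#' }
#'
#' @param x Named list of raw view matrices (>= 2 views for the attention
#'   arms).
#' @param y 0/1 labels.
#' @param k Number of folds.
#' @param config A [maacnn_config()]; `config$f_dim` is the common width.
#' @param seed Master seed; the fold split is identical across arms.
#' @return A `"maacnn_ablation"` data frame of mean ACC (%) and AUC per
#'   arm, with per-arm fold digests in `attr(, "fold_digest")`.
#' @export
ablation_suite <- function(x, y, k = 10L, config = maacnn_config(), seed = NULL) {
  x <- lapply(x, as.matrix)
  if (is.null(names(x))) names(x) <- paste0("view", seq_along(x))
  check_view_alignment(x)
  if (length(x) < 2L) stop_maacnn("ablation needs at least 2 views for the attention arms")
  y <- normalize_labels(y)
  n <- length(y)
  ids <- rownames(x[[1]]) %||% as.character(seq_len(n))
  x <- lapply(x, function(m) { rownames(m) <- ids; m })
  folds <- stratified_kfold(y, k, seed = child_seed(seed, "split"))
  f_dim <- config$f_dim

  arms <- list(
    "CNN" = function(train, test, fs) {
      v <- x[[1]]
      sel <- rfe_select(v[train, , drop = FALSE], y[train], f_dim)
      sc <- fit_scaler(v[train, sel, drop = FALSE])
      cnn <- cnn_train(apply_scaler(sc, v[train, sel, drop = FALSE]), y[train],
                       config$cnn, seed = fs)
      cnn_forward(cnn$model, apply_scaler(sc, v[test, sel, drop = FALSE]))$probs
    },
    "CNN + SDA" = function(train, test, fs) {
      v <- x[[1]]
      sda <- pretrain_sda(v[train, , drop = FALSE],
                          config = view_sda_config(ncol(v), config), seed = fs)
      cnn <- cnn_train(sda_transform(sda, v[train, , drop = FALSE]), y[train],
                       config$cnn, seed = child_seed(fs, "cnn"))
      cnn_forward(cnn$model, sda_transform(sda, v[test, , drop = FALSE]))$probs
    },
    "CNN + attention (RFE features)" = function(train, test, fs) {
      enc_tr <- list(); enc_te <- list()
      for (v in names(x)) {
        sel <- rfe_select(x[[v]][train, , drop = FALSE], y[train], f_dim)
        sc <- fit_scaler(x[[v]][train, sel, drop = FALSE])
        enc_tr[[v]] <- apply_scaler(sc, x[[v]][train, sel, drop = FALSE])
        enc_te[[v]] <- apply_scaler(sc, x[[v]][test, sel, drop = FALSE])
      }
      joint <- train_joint(enc_tr, y[train], config, seed = fs)
      s <- global_average_pool(enc_te)
      w <- view_weights(s, joint$attention, config$attention$normalize,
                        config$attention$global_weights)
      cnn_forward(joint$cnn, fuse(enc_te, w))$probs
    },
    "full model" = function(train, test, fs) {
      fit <- maacnn(lapply(x, function(m) m[train, , drop = FALSE]), y[train],
                    config = config, seed = fs)
      maacnn_forward_views(fit, lapply(x, function(m) m[test, , drop = FALSE]))$probs
    }
  )

  rows <- vector("list", length(arms))
  digests <- character(length(arms))
  for (a in seq_along(arms)) {
    leakage_reset()
    accs <- numeric(length(folds)); aucs <- numeric(length(folds))
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      leakage_guard_begin(ids[test])
      probs <- arms[[a]](train, test, child_seed(seed, paste0("arm", a, "fold", f)))
      leakage_guard_end()
      met <- suppressWarnings(
        classification_metrics(confusion_counts(y[test], predict_labels(probs))))
      accs[f] <- 100 * met["acc"]
      aucs[f] <- suppressWarnings(auc_score(y[test], probs[, 2L]))
    }
    rows[[a]] <- data.frame(arm = names(arms)[a], acc = mean(accs),
                            auc = mean(aucs, na.rm = TRUE))
    digests[a] <- object_digest(folds)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fold_digest") <- digests
  attr(out, "seed") <- seed
  class(out) <- c("maacnn_ablation", "data.frame")
  out
}

#' @export
print.maacnn_ablation <- function(x, ...) {
  cat("Ablation study (identical folds across arms)\n")
  df <- as.data.frame(x)
  df$acc <- sprintf("%.2f", df$acc)
  df$auc <- sprintf("%.3f", df$auc)
  print(df, row.names = FALSE)
  invisible(x)
}
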