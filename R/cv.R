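# Cross-validation protocols, evaluation metrics and the leakage guard.
#
# The leakage guard is an instrumentation layer: every fit routine
# (standardization, DAE training, RFE, joint training) reports the subject
# ids of the rows it was given; while a guard is active with a fold's
# test ids, any overlap is recorded as a violation. A clean CV run must
# report zero violations.

.maacnn_state <- new.env(parent = emptyenv())
.maacnn_state$leakage <- list(active = FALSE, test_ids = character(),
                              violations = 0L, fits = 0L, details = character())

leakage_reset <- function() {
  .maacnn_state$leakage <- list(active = FALSE, test_ids = character(),
                                violations = 0L, fits = 0L, details = character())
  invisible(NULL)
}

leakage_guard_begin <- function(test_ids) {
  st <- .maacnn_state$leakage
  st$active <- TRUE
  st$test_ids <- as.character(test_ids)
  .maacnn_state$leakage <- st
  invisible(NULL)
}

leakage_guard_end <- function() {
  st <- .maacnn_state$leakage
  st$active <- FALSE
  st$test_ids <- character()
  .maacnn_state$leakage <- st
  invisible(NULL)
}

# Called by every fit routine with the row ids it is about to fit on.
leakage_check <- function(ids, what) {
  st <- .maacnn_state$leakage
  st$fits <- st$fits + 1L
  if (st$active && !is.null(ids)) {
    bad <- intersect(as.character(ids), st$test_ids)
    if (length(bad)) {
      st$violations <- st$violations + length(bad)
      st$details <- c(st$details,
                      sprintf("%s saw test row(s): %s", what,
                              paste(bad, collapse = ", ")))
    }
  }
  .maacnn_state$leakage <- st
  invisible(NULL)
}

#' Report of the leakage instrumentation
#'
#' Summarizes what the fit-routine instrumentation recorded since the
#' last cross-validation run started: how many fit calls were observed
#' and how many test-fold rows (if any) reached a fit routine. A clean
#' run has zero violations.
#'
#' @return List with `fits`, `violations` and `details`.
#' @export
leakage_report <- function() {
  st <- .maacnn_state$leakage
  list(fits = st$fits, violations = st$violations, details = st$details)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals subjects round-robin into
#' k folds, so per-fold class counts differ from perfect proportionality
#' by at most one subject.
#'
#' @param labels 0/1 (or ASD/HC) label vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed making the split reproducible.
#' @return List of k integer vectors of test indices partitioning
#'   `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = NULL) {
  y <- normalize_labels(labels)
  k <- as.integer(k)
  if (k < 2L) stop_maacnn("k must be at least 2")
  counts <- table(y)
  if (any(counts < k)) {
    stop_maacnn(sprintf(
      "smallest class has %d subjects, fewer than k = %d folds; use a smaller k",
      min(counts), k))
  }
  with_seed(seed, {
    folds <- vector("list", k)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      for (j in seq_along(idx)) {
        f <- ((j - 1L) %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[j])
      }
    }
    lapply(folds, sort)
  })
}

#' Confusion counts with ASD as the positive class
#'
#' @param truth True 0/1 labels.
#' @param pred Predicted 0/1 labels.
#' @return A `"confusion_counts"` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- normalize_labels(truth); pred <- normalize_labels(pred)
  stopifnot(length(truth) == length(pred))
  structure(list(TP = sum(truth == 1 & pred == 1),
                 FP = sum(truth == 0 & pred == 1),
                 TN = sum(truth == 0 & pred == 0),
                 FN = sum(truth == 1 & pred == 0)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `SEN = TP / (TP + FN)`,
#' `SPEC = TN / (TN + FP)`. When a fold contains no positives (or no
#' negatives) the corresponding rate is undefined and reported as `NA`
#' with a warning; fold averaging skips such values.
#'
#' @param cc A [confusion_counts()].
#' @return Named numeric vector `c(acc, sen, spec)` as fractions.
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$TP + cc$FP + cc$TN + cc$FN
  if (total == 0) stop_maacnn("no evaluated subjects")
  acc <- (cc$TP + cc$TN) / total
  sen <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else {
    warning("no positive subjects: sensitivity undefined", call. = FALSE)
    NA_real_
  }
  spec <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else {
    warning("no negative subjects: specificity undefined", call. = FALSE)
    NA_real_
  }
  c(acc = acc, sen = sen, spec = spec)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' random positive subject's score exceeds a random negative's, with ties
#' counted one half.
#'
#' @param labels 0/1 labels.
#' @param scores Positive-class (ASD) scores.
#' @return AUC in `[0, 1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
auc_score <- function(labels, scores) {
  y <- normalize_labels(labels)
  stopifnot(length(y) == length(scores))
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    warning("AUC undefined with a single class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cross-validated evaluation of the full model
#'
#' Stratified k-fold cross-validation with strictly in-fold fitting: for
#' each fold, standardization, SDA pretraining and joint attention + CNN
#' training see only the training subjects (enforced by the leakage
#' instrumentation), test subjects are scored, and accuracy, sensitivity,
#' specificity (percent) and AUC are computed per fold and averaged.
#'
#' @param x Named list of raw view matrices with subject ids as rownames.
#' @param y Labels (0/1 or HC/ASD).
#' @param k Number of folds (default 10).
#' @param config A [maacnn_config()].
#' @param seed Master seed (fold split, initialization, corruption).
#' @param atlases Optional named [atlas_spec()] list.
#' @return A `"maacnn_cv"` report: per-fold and mean metrics, fold
#'   assignments, attention weights per fold, seed, config digest and the
#'   leakage report.
#' @export
maacnn_cv <- function(x, y, k = 10L, config = maacnn_config(), seed = NULL,
                      atlases = NULL) {
  x <- lapply(x, as.matrix)
  if (is.null(names(x))) names(x) <- paste0("view", seq_along(x))
  check_view_alignment(x)
  y <- normalize_labels(y)
  n <- length(y)
  ids <- rownames(x[[1]]) %||% as.character(seq_len(n))
  x <- lapply(x, function(m) { rownames(m) <- ids; m })
  folds <- stratified_kfold(y, k, seed = child_seed(seed, "split"))
  leakage_reset()
  fold_rows <- vector("list", length(folds))
  weight_rows <- vector("list", length(folds))
  scores <- numeric(n); preds <- integer(n)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    leakage_guard_begin(ids[test])
    xtr <- lapply(x, function(m) m[train, , drop = FALSE])
    fit <- maacnn(xtr, y[train], config = config, atlases = atlases,
                  seed = child_seed(seed, paste0("fold", f)))
    leakage_guard_end()
    xte <- lapply(x, function(m) m[test, , drop = FALSE])
    fw <- maacnn_forward_views(fit, xte)
    sc <- fw$probs[, 2L]
    pr <- predict_labels(fw$probs)
    scores[test] <- sc; preds[test] <- pr
    cc <- confusion_counts(y[test], pr)
    met <- suppressWarnings(classification_metrics(cc))
    fold_rows[[f]] <- data.frame(fold = f, n = length(test),
                                 acc = 100 * met["acc"], sen = 100 * met["sen"],
                                 spec = 100 * met["spec"],
                                 auc = suppressWarnings(auc_score(y[test], sc)))
    weight_rows[[f]] <- fit$train_weights
  }
  per_fold <- do.call(rbind, fold_rows)
  rownames(per_fold) <- NULL
  weights <- do.call(rbind, weight_rows)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[, c("acc", "sen", "spec", "auc")], na.rm = TRUE),
    folds = folds, k = length(folds), n = n, seed = seed,
    scores = scores, predictions = preds, labels = y,
    view_weights = weights,
    aggregation = "fold-averaged",
    config_digest = object_digest(config),
    leakage = leakage_report()
  ), class = "maacnn_cv")
}

#' Leave-one-out cross-validation
#'
#' N folds of one held-out subject each; because per-fold rates are
#' undefined for singleton test sets, metrics are computed from the
#' pooled confusion counts over all folds (and AUC from the pooled
#' held-out scores).
#'
#' @inheritParams maacnn_cv
#' @return A `"maacnn_loocv"` report with pooled counts and metrics.
#' @export
maacnn_loocv <- function(x, y, config = maacnn_config(), seed = NULL,
                         atlases = NULL) {
  x <- lapply(x, as.matrix)
  if (is.null(names(x))) names(x) <- paste0("view", seq_along(x))
  check_view_alignment(x)
  y <- normalize_labels(y)
  n <- length(y)
  if (n < 3L) stop_maacnn("LOOCV needs at least 3 subjects")
  ids <- rownames(x[[1]]) %||% as.character(seq_len(n))
  x <- lapply(x, function(m) { rownames(m) <- ids; m })
  leakage_reset()
  scores <- numeric(n); preds <- integer(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    leakage_guard_begin(ids[i])
    fit <- maacnn(lapply(x, function(m) m[train, , drop = FALSE]), y[train],
                  config = config, atlases = atlases,
                  seed = child_seed(seed, paste0("loo", i)))
    leakage_guard_end()
    fw <- maacnn_forward_views(fit, lapply(x, function(m) m[i, , drop = FALSE]))
    scores[i] <- fw$probs[, 2L]
    preds[i] <- predict_labels(fw$probs)
  }
  cc <- confusion_counts(y, preds)
  met <- classification_metrics(cc)
  structure(list(
    counts = cc,
    metrics = c(acc = 100 * unname(met["acc"]), sen = 100 * unname(met["sen"]),
                spec = 100 * unname(met["spec"]),
                auc = auc_score(y, scores)),
    n = n, seed = seed, scores = scores, predictions = preds, labels = y,
    aggregation = "pooled", config_digest = object_digest(config),
    leakage = leakage_report()
  ), class = "maacnn_loocv")
}

#' @export
print.maacnn_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (%d subjects, %s)\n",
              x$k, x$n, x$aggregation))
  print(round(x$per_fold, 2))
  cat(sprintf("mean: ACC %.2f%%  SEN %.2f%%  SPEC %.2f%%  AUC %.3f\n",
              x$mean["acc"], x$mean["sen"], x$mean["spec"], x$mean["auc"]))
  if (x$leakage$violations > 0) {
    cat(sprintf("WARNING: %d leakage violation(s) recorded\n", x$leakage$violations))
  }
  invisible(x)
}

#' @export
print.maacnn_loocv <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (%d subjects, pooled counts)\n", x$n))
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n",
              x$counts$TP, x$counts$FP, x$counts$TN, x$counts$FN))
  cat(sprintf("ACC %.2f%%  SEN %.2f%%  SPEC %.2f%%  AUC %.3f\n",
              x$metrics["acc"], x$metrics["sen"], x$metrics["spec"],
              x$metrics["auc"]))
  invisible(x)
}
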