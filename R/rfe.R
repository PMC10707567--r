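# Recursive feature elimination driven by an L2-regularized linear
# classifier: fit, rank features by absolute coefficient, drop the
# weakest 10% of those remaining, refit, until the target dimension is
# reached. Used by the ablation arms that replace the SDA.

# Ridge coefficients for labels coded -1/+1; primal or dual form
# depending on which Gram matrix is smaller. Deterministic.
ridge_coef <- function(x, y, lambda = 1) {
  x <- as.matrix(x)
  yy <- ifelse(normalize_labels(y) == 1, 1, -1)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, `-`)
  yc <- yy - mean(yy)
  p <- ncol(xc); n <- nrow(xc)
  if (p <= n) {
    beta <- solve(crossprod(xc) + diag(lambda, p), crossprod(xc, yc))
  } else {
    beta <- t(xc) %*% solve(tcrossprod(xc) + diag(lambda, n), yc)
  }
  drop(beta)
}

#' Recursive feature elimination baseline
#'
#' Ranks features by the absolute coefficients of a ridge-regularized
#' linear classifier and removes 10% of the remaining features per round
#' (at least one, never overshooting the target) until `target_dim`
#' remain. Fit strictly on the rows provided — in cross-validation that
#' means the training fold only.
#'
#' @param x Subject-by-feature matrix.
#' @param y 0/1 labels.
#' @param target_dim Number of features to keep; must be `< ncol(x)`.
#' @param step_frac Fraction of remaining features removed per round.
#' @param lambda Ridge penalty of the internal linear fit.
#' @return Sorted integer vector of selected column indices.
#' @export
rfe_select <- function(x, y, target_dim, step_frac = 0.1, lambda = 1) {
  x <- as.matrix(x)
  target_dim <- as.integer(target_dim)
  if (target_dim >= ncol(x)) {
    stop_maacnn(sprintf("target_dim (%d) must be smaller than the feature count (%d)",
                        target_dim, ncol(x)))
  }
  if (target_dim < 1L) stop_maacnn("target_dim must be positive")
  leakage_check(rownames(x), "rfe_select")
  keep <- seq_len(ncol(x))
  while (length(keep) > target_dim) {
    beta <- ridge_coef(x[, keep, drop = FALSE], y, lambda)
    drop_n <- max(1L, min(floor(step_frac * length(keep)),
                          length(keep) - target_dim))
    ord <- order(abs(beta))  # weakest first
    keep <- sort(keep[-ord[seq_len(drop_n)]])
  }
  keep
}
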