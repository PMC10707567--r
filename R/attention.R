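# Multi-view attention fusion: each encoded view is collapsed to a scalar
# summary per subject by global average pooling; a small MLP maps the
# n summaries to n logits; a softmax over views yields nonnegative
# weights summing to 1; the fused representation is the weighted
# (convex) combination of the view vectors. The block is trained jointly
# with the CNN by backpropagation.

#' Global average pooling over view features
#'
#' Collapses each subject's encoded feature vector in each view to its
#' mean, producing the `N x n` summary matrix that drives the attention
#' weights.
#'
#' @param views Named list of `N x F` encoded feature matrices, one per
#'   view, with identical subject order.
#' @return `N x n` matrix of view summaries (columns follow the view
#'   order).
#' @export
global_average_pool <- function(views) {
  check_view_alignment(views)
  if (ncol(views[[1]]) < 1L) stop_maacnn("empty feature dimension")
  s <- vapply(views, rowMeans, numeric(nrow(views[[1]])))
  if (!is.matrix(s)) s <- matrix(s, nrow = 1L)
  colnames(s) <- names(views)
  s
}

check_view_alignment <- function(views) {
  if (length(views) < 1L) stop_maacnn("need at least one view")
  n <- nrow(views[[1]])
  rn <- rownames(views[[1]])
  for (i in seq_along(views)) {
    if (nrow(views[[i]]) != n) {
      stop_maacnn(sprintf("view %d has %d subjects, expected %d",
                          i, nrow(views[[i]]), n))
    }
    if (!is.null(rn) && !is.null(rownames(views[[i]])) &&
        !identical(rownames(views[[i]]), rn)) {
      bad <- rownames(views[[i]])[rownames(views[[i]]) != rn]
      stop_maacnn(sprintf("subject order differs across views (e.g. %s)",
                          paste(utils::head(bad, 3), collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Initialize the attention MLP
#'
#' One rectified hidden layer of width `max(4, 2n)` by default, mapping
#' the n view summaries to n view logits.
#'
#' @param n_views Number of views.
#' @param hidden Hidden width.
#' @param seed Optional integer seed.
#' @return An `"attention_params"` list.
#' @export
attention_init <- function(n_views, hidden = max(4L, 2L * n_views), seed = NULL) {
  with_seed(seed, {
    structure(list(W1 = nn_init_mat(n_views, hidden), b1 = numeric(hidden),
                   W2 = nn_init_mat(hidden, n_views), b2 = numeric(n_views),
                   n_views = as.integer(n_views)),
              class = "attention_params")
  })
}

#' Compute attention weights from view summaries
#'
#' The MLP maps each subject's n summaries to n logits; a softmax over
#' views turns them into nonnegative weights summing to 1. With
#' `global_weights = TRUE` the summaries are first averaged over the
#' batch, giving a single weight vector shared by all subjects. With
#' `normalize = "none"` the raw logits are returned unnormalized.
#'
#' @param summaries `N x n` summary matrix from [global_average_pool()].
#' @param params An `"attention_params"`.
#' @param normalize `"softmax"` (default) or `"none"`.
#' @param global_weights Average summaries over the batch before the MLP.
#' @return `N x n` weight matrix (rows identical in global mode).
#' @export
view_weights <- function(summaries, params, normalize = c("softmax", "none"),
                         global_weights = FALSE) {
  normalize <- match.arg(normalize)
  fw <- attention_forward(summaries, params, normalize, global_weights)
  fw$weights
}

attention_forward <- function(summaries, params, normalize = "softmax",
                              global_weights = FALSE) {
  s <- as.matrix(summaries)
  if (ncol(s) != params$n_views) {
    stop_maacnn(sprintf("%d summary columns but params expect %d views",
                        ncol(s), params$n_views))
  }
  n <- nrow(s)
  sin <- if (global_weights) matrix(colMeans(s), 1L, ncol(s)) else s
  pre <- sweep(sin %*% params$W1, 2L, params$b1, `+`)
  h <- relu(pre)
  logits <- sweep(h %*% params$W2, 2L, params$b2, `+`)
  w <- if (normalize == "softmax") softmax_rows(logits) else logits
  if (global_weights) w <- matrix(w, n, ncol(s), byrow = TRUE)
  list(weights = w,
       cache = list(sin = sin, pre = pre, h = h, logits = logits,
                    normalize = normalize, global_weights = global_weights,
                    n = n))
}

# Backprop from the gradient w.r.t. the (broadcast) weight matrix.
attention_backward <- function(dweights, params, cache) {
  w_rows <- if (cache$global_weights) {
    matrix(colSums(dweights), 1L)
  } else {
    dweights
  }
  if (cache$normalize == "softmax") {
    wmat <- softmax_rows(cache$logits)
    dlogits <- wmat * (w_rows - rowSums(w_rows * wmat))
  } else {
    dlogits <- w_rows
  }
  dW2 <- crossprod(cache$h, dlogits)
  db2 <- colSums(dlogits)
  dh <- (dlogits %*% t(params$W2)) * (cache$pre > 0)
  dW1 <- crossprod(cache$sin, dh)
  db1 <- colSums(dh)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Fuse encoded views with attention weights
#'
#' Per subject, the fused representation is the weighted sum of the view
#' vectors. When the weights are softmax-normalized this is a convex
#' combination, so every fused coordinate lies between the per-coordinate
#' minimum and maximum across views.
#'
#' @param views Named list of `N x F` encoded matrices (aligned subjects).
#' @param weights `N x n` weight matrix (or length-n vector, recycled to
#'   all subjects).
#' @return `N x F` fused feature matrix.
#' @export
fuse <- function(views, weights) {
  check_view_alignment(views)
  n <- nrow(views[[1]])
  if (is.vector(weights) && is.numeric(weights)) {
    weights <- matrix(weights, n, length(weights), byrow = TRUE)
  }
  if (ncol(weights) != length(views) || nrow(weights) != n) {
    stop_maacnn(sprintf("weights are %dx%d but need %dx%d",
                        nrow(weights), ncol(weights), n, length(views)))
  }
  out <- 0
  for (i in seq_along(views)) {
    out <- out + weights[, i] * views[[i]]
  }
  rownames(out) <- rownames(views[[1]])
  out
}
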