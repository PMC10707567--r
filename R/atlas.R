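#' Define a brain parcellation (atlas)
#'
#' An atlas divides the brain into `n_rois` regions of interest; each atlas
#' defines one "view" of a subject. The number of functional-connectivity
#' features per subject under an atlas is the size of the strict lower
#' triangle of the ROI-by-ROI correlation matrix, `n (n - 1) / 2`.
#'
#' @param name Atlas identifier, e.g. `"AAL"` or `"CC200"`.
#' @param n_rois Number of regions of interest; must be at least 2.
#' @return An object of class `"atlas_spec"` with fields `name`, `n_rois`
#'   and `feature_dim`.
#' @examples
#' aal <- atlas_spec("AAL", 116)
#' aal$feature_dim  # 6670
#' @export
atlas_spec <- function(name, n_rois) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_maacnn("atlas name must be a non-empty string")
  }
  n_rois <- as.integer(n_rois)
  if (is.na(n_rois) || n_rois < 2L) {
    stop_maacnn("invalid atlas: n_rois must be an integer >= 2")
  }
  structure(
    list(name = name, n_rois = n_rois, feature_dim = feature_count(n_rois)),
    class = "atlas_spec"
  )
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("Atlas '%s': %d ROIs, %d connectivity features\n",
              x$name, x$n_rois, x$feature_dim))
  invisible(x)
}

#' Number of connectivity features for an atlas
#'
#' The strict lower triangle of a symmetric `n x n` correlation matrix has
#' `n (n - 1) / 2` entries; this is the raw feature dimension per view.
#'
#' @param n_rois Number of ROIs (integer, >= 2).
#' @return The feature count as an integer.
#' @examples
#' feature_count(116) # 6670
#' feature_count(200) # 19900
#' @export
feature_count <- function(n_rois) {
  n_rois <- as.integer(n_rois)
  if (any(is.na(n_rois)) || any(n_rois < 2L)) {
    stop_maacnn("invalid atlas: n_rois must be an integer >= 2")
  }
  as.integer((n_rois * (n_rois - 1L)) %/% 2L)
}

#' Registry of the standard parcellations
#'
#' The five parcellations commonly used with the ABIDE preprocessed
#' releases. Feature dimensions are always derived as `n (n - 1) / 2` from
#' the ROI count.
#'
#' @return A named list of [atlas_spec()] objects.
#' @export
default_atlases <- function() {
  list(
    AAL          = atlas_spec("AAL", 116L),
    CC200        = atlas_spec("CC200", 200L),
    HO           = atlas_spec("HO", 111L),
    Dosenbach160 = atlas_spec("Dosenbach160", 160L),
    EZ           = atlas_spec("EZ", 116L)
  )
}

#' Per-subject ROI time series
#'
#' Wraps a `T x n_rois` numeric matrix of BOLD-derived region signals.
#' Subjects with missing values are rejected: incomplete series must be
#' excluded upstream.
#'
#' @param subject_id Subject identifier.
#' @param atlas An [atlas_spec()].
#' @param data Numeric matrix, time points in rows, ROIs in columns.
#' @return An object of class `"roi_timeseries"`.
#' @export
roi_timeseries <- function(subject_id, atlas, data) {
  stopifnot(inherits(atlas, "atlas_spec"))
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_maacnn("time-series data must be numeric")
  if (ncol(data) != atlas$n_rois) {
    stop_maacnn(sprintf(
      "subject '%s': %d columns but atlas '%s' has %d ROIs",
      subject_id, ncol(data), atlas$name, atlas$n_rois))
  }
  if (nrow(data) < 2L) {
    stop_maacnn(sprintf("subject '%s': need at least 2 time points", subject_id))
  }
  if (anyNA(data)) {
    stop_maacnn(sprintf("subject '%s': missing values in time series", subject_id))
  }
  structure(
    list(subject_id = as.character(subject_id), atlas = atlas, data = data),
    class = "roi_timeseries"
  )
}

#' Pearson correlation with a defined value for degenerate input
#'
#' The standard product-moment correlation between two equal-length
#' series. When either series has zero variance the correlation is
#' undefined; it is reported as 0 with a warning rather than NaN, so that
#' degenerate ROIs cannot propagate missing values into later stages.
#'
#' @param u,v Numeric vectors of equal length (>= 2).
#' @return A number in `[-1, 1]`.
#' @export
fc_correlation <- function(u, v) {
  if (length(u) != length(v)) stop_maacnn("series must have equal length")
  if (length(u) < 2L) stop_maacnn("correlation needs at least 2 time points")
  su <- stats::sd(u)
  sv <- stats::sd(v)
  if (su == 0 || sv == 0) {
    warning("zero-variance series: correlation defined as 0", call. = FALSE)
    return(0)
  }
  r <- stats::cor(u, v)
  # guard against tiny numerical overshoot
  max(-1, min(1, r))
}

#' Functional-connectivity matrix of one subject
#'
#' All pairwise Pearson correlations between ROI time courses. Constant
#' (zero-variance) ROI columns yield undefined correlations; every entry
#' involving such a column, including its diagonal entry, is set to 0 and
#' a warning names the offending ROI indices.
#'
#' @param ts A [roi_timeseries()], or a plain numeric matrix
#'   (time points x ROIs).
#' @return A symmetric `n x n` correlation matrix with unit diagonal for
#'   non-degenerate ROIs.
#' @export
connectivity_matrix <- function(ts) {
  x <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  if (nrow(x) < 2L) stop_maacnn("need at least 2 time points")
  sds <- apply(x, 2L, stats::sd)
  bad <- which(sds == 0)
  m <- suppressWarnings(stats::cor(x))
  if (length(bad)) {
    warning(sprintf("constant ROI column(s) %s: affected correlations set to 0",
                    paste(bad, collapse = ", ")), call. = FALSE)
    m[bad, ] <- 0
    m[, bad] <- 0
  }
  m[m > 1] <- 1
  m[m < -1] <- -1
  ok <- setdiff(seq_len(ncol(x)), bad)
  m[cbind(ok, ok)] <- 1
  m
}

#' Vectorize the strict lower triangle of a connectivity matrix
#'
#' By symmetry only the strict lower triangle of the correlation matrix
#' carries information; it is flattened row-major over pairs `(i, j)` with
#' `i > j`: (2,1), (3,1), (3,2), (4,1), ... The diagonal and upper
#' triangle never appear.
#'
#' @param m Square symmetric numeric matrix, `n >= 2`.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @seealso [unvectorize_lower_triangle()] for the inverse map.
#' @export
vectorize_lower_triangle <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_maacnn("connectivity matrix must be square")
  n <- nrow(m)
  if (n < 2L) stop_maacnn("need at least 2 ROIs")
  # upper triangle of t(m) taken column-major enumerates the lower
  # triangle of m row-major: (2,1), (3,1), (3,2), (4,1), ...
  tm <- t(m)
  tm[upper.tri(tm)]
}

#' Rebuild the off-diagonal connectivity matrix from a feature vector
#'
#' Inverse of [vectorize_lower_triangle()]: places the features back on
#' the strict lower triangle in row-major pair order, mirrors them to the
#' upper triangle, and sets a unit diagonal.
#'
#' @param v Feature vector of length `n (n - 1) / 2`.
#' @param n_rois The ROI count `n`.
#' @return A symmetric `n x n` matrix with unit diagonal.
#' @export
unvectorize_lower_triangle <- function(v, n_rois) {
  n_rois <- as.integer(n_rois)
  if (length(v) != feature_count(n_rois)) {
    stop_maacnn("feature vector length does not match n (n - 1) / 2")
  }
  tm <- diag(1, n_rois)
  tm[upper.tri(tm)] <- v
  m <- t(tm)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Build the raw feature table for one view
#'
#' Runs every subject of a cohort through [connectivity_matrix()] and
#' [vectorize_lower_triangle()], producing the subject-by-feature matrix
#' that feeds the denoising autoencoders.
#'
#' @param cohort List of [roi_timeseries()] objects sharing one atlas.
#' @param atlas The [atlas_spec()] all subjects must share.
#' @return A numeric matrix with one row per subject (rownames are subject
#'   ids) and `atlas$feature_dim` columns.
#' @export
build_view_features <- function(cohort, atlas) {
  stopifnot(inherits(atlas, "atlas_spec"))
  s <- atlas$feature_dim
  if (length(cohort) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = s,
                  dimnames = list(NULL, paste0("f", seq_len(s)))))
  }
  rows <- lapply(cohort, function(ts) {
    if (!inherits(ts, "roi_timeseries")) stop_maacnn("cohort entries must be roi_timeseries")
    if (!identical(ts$atlas$name, atlas$name) || ts$atlas$n_rois != atlas$n_rois) {
      stop_maacnn(sprintf("subject '%s' uses atlas '%s', expected '%s'",
                          ts$subject_id, ts$atlas$name, atlas$name))
    }
    vectorize_lower_triangle(connectivity_matrix(ts))
  })
  x <- do.call(rbind, rows)
  rownames(x) <- unname(vapply(cohort, function(ts) ts$subject_id, character(1)))
  colnames(x) <- paste0("f", seq_len(s))
  x
}
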