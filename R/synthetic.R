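# Synthetic multi-atlas cohort generator. Subjects are zero-mean
# multivariate-normal ROI time series whose correlation matrix is a
# shared per-view base, plus a class shift of magnitude delta on a
# planted set of edges (informative views only), plus a per-site random
# perturbation. The pipeline consumes only pairwise correlations, so no
# temporal autocorrelation is simulated.

#' Specification of a synthetic multi-atlas cohort
#'
#' @param n_per_class Length-2 vector `c(HC, ASD)` of subjects per class.
#' @param atlases List of [atlas_spec()]s, one per view.
#' @param t_len Time points per subject.
#' @param n_affected_edges Number of planted class-different edges per
#'   informative view; must not exceed the smallest informative view's
#'   feature dimension. May be a vector with one entry per informative
#'   view (recycled otherwise) to give views different informativeness.
#' @param delta Correlation shift on affected edges (ASD minus HC);
#'   scalar or one entry per informative view.
#' @param informative_views Names of the atlases that carry the class
#'   effect (default: all).
#' @param n_sites Number of acquisition sites.
#' @param site_scale Standard deviation of the per-site additive
#'   perturbation of the correlation matrix.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_per_class = c(HC = 40L, ASD = 40L),
                        atlases = list(atlas_spec("SIM10", 10L),
                                       atlas_spec("SIM12", 12L),
                                       atlas_spec("SIM14", 14L)),
                        t_len = 120L, n_affected_edges = 20L, delta = 0.6,
                        informative_views = NULL, n_sites = 2L,
                        site_scale = 0.05, seed = NULL) {
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 1L))
  anames <- vapply(atlases, function(a) a$name, character(1))
  names(atlases) <- anames
  if (is.null(informative_views)) informative_views <- anames
  if (!all(informative_views %in% anames)) {
    stop_maacnn("informative_views must name atlases in the spec")
  }
  if (any(delta < 0) || any(delta > 1.9)) stop_maacnn("delta must be in [0, 1.9]")
  nv_inf <- length(informative_views)
  if (nv_inf) {
    delta <- rep_len(delta, nv_inf)
    n_affected_edges <- rep_len(as.integer(n_affected_edges), nv_inf)
    dims <- vapply(atlases[informative_views], function(a) a$feature_dim, numeric(1))
    if (any(delta > 0 & n_affected_edges > dims)) {
      stop_maacnn(sprintf(
        "n_affected_edges (%s) exceeds an informative view's feature count (%s)",
        paste(n_affected_edges, collapse = "/"), paste(dims, collapse = "/")))
    }
  }
  structure(list(n_per_class = stats::setNames(as.integer(n_per_class), c("HC", "ASD")),
                 atlases = atlases, t_len = as.integer(t_len),
                 n_affected_edges = as.integer(n_affected_edges), delta = delta,
                 informative_views = informative_views,
                 n_sites = as.integer(n_sites), site_scale = site_scale,
                 seed = seed),
            class = "cohort_spec")
}

#' Canned cohort specifications
#'
#' Fixed study conditions used by the test harnesses and the pipeline
#' presets:
#' \describe{
#'   \item{null}{No class effect (`delta = 0`); downstream CV accuracy
#'     should sit at chance.}
#'   \item{separable}{Three informative views of 10/12/14 ROIs with a
#'     strong shift (`delta = 0.6` on 20 edges per view).}
#'   \item{complementary-views}{Two views of unequal informativeness:
#'     the first carries a weak effect (`delta = 0.3` on 3 edges), the
#'     second a strong one (`delta = 0.55` on 12 edges), so the
#'     first-view classifier trails the fused multi-view model (checked
#'     against a ridge oracle per view vs pooled).}
#'   \item{noise-view}{One informative view (`delta = 0.6`, 20 edges) and
#'     one pure-noise view; attention should favor the informative one.}
#' }
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
cohort_preset <- function(name = c("null", "separable", "complementary-views",
                                   "noise-view"), seed = NULL) {
  name <- match.arg(name)
  switch(name,
    "null" = cohort_spec(delta = 0, seed = seed),
    "separable" = cohort_spec(delta = 0.6, n_affected_edges = 20L, seed = seed),
    "complementary-views" = cohort_spec(
      atlases = list(atlas_spec("SIM10", 10L), atlas_spec("SIM12", 12L)),
      t_len = 100L, delta = c(0.3, 0.55), n_affected_edges = c(3L, 12L),
      seed = seed),
    "noise-view" = cohort_spec(
      atlases = list(atlas_spec("SIM10", 10L), atlas_spec("SIM12", 12L)),
      delta = 0.6, n_affected_edges = 20L,
      informative_views = "SIM10", seed = seed)
  )
}

# (i, j) ROI pairs in the feature-vector order of
# vectorize_lower_triangle: row-major over the strict lower triangle.
lt_index_pairs <- function(n) {
  do.call(rbind, lapply(2:n, function(i) cbind(i = i, j = seq_len(i - 1L))))
}

# Random base correlation matrix from a 3-factor model.
random_base_corr <- function(n) {
  w <- matrix(stats::rnorm(n * 3L, sd = 0.6), n, 3L)
  s <- tcrossprod(w) + diag(stats::runif(n, 0.5, 1.5))
  stats::cov2cor(s)
}

# Clip eigenvalues to keep the matrix positive definite, then renormalize
# to unit diagonal. Returns the matrix and whether a repair was needed.
repair_pd <- function(m, floor_ev = 1e-4) {
  ev <- eigen(m, symmetric = TRUE)
  repaired <- any(ev$values < floor_ev)
  if (repaired) {
    vals <- pmax(ev$values, floor_ev)
    m <- ev$vectors %*% (vals * t(ev$vectors))
    m <- stats::cov2cor(m)
  }
  list(m = (m + t(m)) / 2, repaired = repaired)
}

#' Generate a synthetic multi-atlas cohort
#'
#' Draws every subject's ROI time series in every view from a
#' multivariate normal whose correlation matrix encodes the planted class
#' and site structure of the [cohort_spec()]. Optionally writes the
#' cohort to disk in the same formats the readers consume: one
#' whitespace-delimited `.1D` file per subject per view plus a phenotype
#' CSV. Fully reproducible from `spec$seed` (byte-identical files).
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; created if missing.
#' @return A `"maacnn_cohort"`: per-view lists of [roi_timeseries()], the
#'   phenotype data frame (`subject_id`, `label`, `site`), the generating
#'   correlation matrices, planted edge indices, and a repair log.
#' @export
make_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n_hc <- spec$n_per_class[["HC"]]; n_asd <- spec$n_per_class[["ASD"]]
    n <- n_hc + n_asd
    ids <- sprintf("sub%03d", seq_len(n))
    labels <- c(rep(0L, n_hc), rep(1L, n_asd))
    sites <- rep(seq_len(spec$n_sites), length.out = n)
    phen <- data.frame(subject_id = ids, label = labels, site = sites,
                       stringsAsFactors = FALSE)

    views <- list(); gens <- list(); affected <- list()
    n_repairs <- 0L
    for (a in spec$atlases) {
      nroi <- a$n_rois
      base <- random_base_corr(nroi)
      vi <- match(a$name, spec$informative_views)
      dlt <- if (!is.na(vi)) spec$delta[vi] else 0
      n_edges <- if (!is.na(vi)) spec$n_affected_edges[vi] else 0L
      informative <- !is.na(vi) && dlt > 0 && n_edges > 0L
      edges <- integer(0)
      c_hc <- base
      c_asd <- base
      if (informative) {
        edges <- sort(sample.int(a$feature_dim, n_edges))
        pairs <- lt_index_pairs(nroi)[edges, , drop = FALSE]
        for (r in seq_len(nrow(pairs))) {
          i <- pairs[r, 1L]; j <- pairs[r, 2L]
          r0 <- min(c_hc[i, j], 0.98 - dlt)
          r1 <- r0 + dlt
          if (abs(r0) > 0.99 || abs(r1) > 0.99) {
            stop_maacnn(sprintf(
              "delta = %.2f leaves no headroom for edge (%d,%d); reduce delta",
              dlt, i, j))
          }
          c_hc[i, j] <- c_hc[j, i] <- r0
          c_asd[i, j] <- c_asd[j, i] <- r1
        }
      }
      # per-site symmetric perturbations shared by both classes
      site_mats <- lapply(seq_len(spec$n_sites), function(s) {
        e <- matrix(stats::rnorm(nroi * nroi, sd = spec$site_scale), nroi, nroi)
        e <- (e + t(e)) / 2
        diag(e) <- 0
        e
      })
      corrs <- list(HC = list(), ASD = list())
      for (s in seq_len(spec$n_sites)) {
        for (cls in c("HC", "ASD")) {
          tgt <- (if (cls == "HC") c_hc else c_asd) + site_mats[[s]]
          rp <- repair_pd(tgt)
          if (rp$repaired) n_repairs <- n_repairs + 1L
          corrs[[cls]][[s]] <- rp$m
        }
      }
      chols <- lapply(corrs, function(cl) lapply(cl, chol))
      subj <- vector("list", n)
      for (k in seq_len(n)) {
        cls <- if (labels[k] == 1L) "ASD" else "HC"
        z <- matrix(stats::rnorm(spec$t_len * nroi), spec$t_len, nroi)
        subj[[k]] <- roi_timeseries(ids[k], a, z %*% chols[[cls]][[sites[k]]])
      }
      names(subj) <- ids
      views[[a$name]] <- subj
      gens[[a$name]] <- corrs
      affected[[a$name]] <- edges
    }

    cohort <- structure(list(spec = spec, timeseries = views, phenotypes = phen,
                             generators = gens, affected_edges = affected,
                             n_repairs = n_repairs),
                        class = "maacnn_cohort")
    if (!is.null(dir)) write_cohort(cohort, dir)
    cohort
  })
}

# Write the cohort in the on-disk dialect the readers consume.
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (v in names(cohort$timeseries)) {
    for (ts in cohort$timeseries[[v]]) {
      path <- file.path(dir, sprintf("%s_rois_%s.1D", ts$subject_id, v))
      header <- sprintf("# %s ROI time series, %d x %d", v,
                        nrow(ts$data), ncol(ts$data))
      rows <- apply(ts$data, 1L, function(r) paste(sprintf("%.6f", r), collapse = "\t"))
      writeLines(c(header, rows), path)
    }
  }
  ph <- cohort$phenotypes
  ph$label <- ifelse(ph$label == 1L, "ASD", "HC")
  utils::write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Raw connectivity features of a synthetic cohort
#'
#' Convenience wrapper running [build_view_features()] per view.
#'
#' @param cohort A `"maacnn_cohort"` from [make_cohort()].
#' @return Named list of subject-by-feature matrices.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "maacnn_cohort"))
  out <- lapply(names(cohort$timeseries), function(v) {
    build_view_features(cohort$timeseries[[v]], cohort$spec$atlases[[v]])
  })
  names(out) <- names(cohort$timeseries)
  out
}

#' Diagnostic verification of a generated cohort
#'
#' Recomputes connectivity features and checks that the planted structure
#' is recoverable: per affected edge, a Welch two-sample comparison of
#' the ASD and HC feature values (flagged at the 1% level), the observed
#' mean class difference, the false-positive rate on unaffected edges,
#' class balance, and the across-site variance of edge means.
#'
#' @param cohort A `"maacnn_cohort"`.
#' @return A `"cohort_report"` list; printing gives a compact summary.
#' @export
verify_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "maacnn_cohort"))
  spec <- cohort$spec
  y <- cohort$phenotypes$label
  per_view <- list()
  for (v in names(cohort$timeseries)) {
    feats <- build_view_features(cohort$timeseries[[v]], spec$atlases[[v]])
    edges <- cohort$affected_edges[[v]]
    p_all <- apply(feats, 2L, function(col) {
      if (stats::sd(col[y == 1]) == 0 && stats::sd(col[y == 0]) == 0) return(1)
      stats::t.test(col[y == 1], col[y == 0])$p.value
    })
    diff_all <- colMeans(feats[y == 1, , drop = FALSE]) -
      colMeans(feats[y == 0, , drop = FALSE])
    site_var <- mean(apply(feats, 2L, function(col) {
      stats::var(tapply(col, cohort$phenotypes$site, mean))
    }))
    per_view[[v]] <- list(
      affected = data.frame(edge = edges, mean_diff = diff_all[edges],
                            p = p_all[edges], flagged = p_all[edges] < 0.01),
      prop_affected_flagged = if (length(edges)) mean(p_all[edges] < 0.01) else NA_real_,
      prop_null_flagged = {
        nulls <- setdiff(seq_along(p_all), edges)
        mean(p_all[nulls] < 0.01)
      },
      mean_observed_shift = if (length(edges)) mean(diff_all[edges]) else NA_real_,
      site_variance = site_var
    )
  }
  structure(list(per_view = per_view,
                 class_balance = table(factor(y, levels = c(0, 1),
                                              labels = c("HC", "ASD"))),
                 delta = spec$delta, n_repairs = cohort$n_repairs),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Synthetic cohort report (delta = %s, %d PD repairs)\n",
              paste(sprintf("%.2f", x$delta), collapse = "/"), x$n_repairs))
  cat(sprintf("  class balance: HC %d / ASD %d\n",
              x$class_balance[["HC"]], x$class_balance[["ASD"]]))
  for (v in names(x$per_view)) {
    pv <- x$per_view[[v]]
    cat(sprintf(
      "  %s: affected flagged %.0f%%, null flagged %.1f%%, observed shift %.3f\n",
      v, 100 * (pv$prop_affected_flagged %||% NA), 100 * pv$prop_null_flagged,
      pv$mean_observed_shift %||% NA))
  }
  invisible(x)
}
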