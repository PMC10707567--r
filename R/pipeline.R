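# Config-driven orchestration: simulate or load a cohort, extract
# features, run cross-validated training, and write artifacts (feature
# tables, evaluation report, attention diagnostics) with provenance.

#' Run the full pipeline from a configuration
#'
#' The configuration is a nested list (typically from [read_config()])
#' with entries:
#' \describe{
#'   \item{seed}{Integer master seed.}
#'   \item{simulate}{Optional: `list(preset = "separable")` (or any
#'     [cohort_preset()] name) to generate a synthetic cohort.}
#'   \item{data}{Otherwise: `list(views = list(<name> = list(dir, n_rois)),
#'     phenotypes = <csv path>)`; each view directory holds one
#'     `<subject>_rois_<name>.1D` file per subject.}
#'   \item{model}{Optional overrides: `scale` (`"desk"` or `"full"`),
#'     `f_dim`, plus `sda` / `cnn` / `attention` sublists passed to
#'     [maacnn_config()].}
#'   \item{evaluate}{`list(folds = 5)` or `list(loocv = TRUE)`.}
#'   \item{out}{Output directory (optional).}
#' }
#'
#' @param config Configuration list.
#' @return The evaluation report (a `"maacnn_cv"` or `"maacnn_loocv"`),
#'   invisibly when `out` is set.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  out <- config$out

  if (!is.null(config$simulate)) {
    spec <- cohort_preset(config$simulate$preset %||% "separable", seed = seed)
    cohort <- make_cohort(spec, dir = config$simulate$dir)
    views <- cohort_features(cohort)
    y <- cohort$phenotypes$label
    ids <- cohort$phenotypes$subject_id
  } else if (!is.null(config$data)) {
    vd <- config$data$views
    if (is.null(vd) || !length(vd)) stop_maacnn("config$data$views is empty")
    for (v in names(vd)) {
      if (is.null(vd[[v]]$dir) || !dir.exists(vd[[v]]$dir)) {
        stop_maacnn(sprintf("view '%s': data directory not found: %s",
                            v, vd[[v]]$dir %||% "<missing>"))
      }
    }
    phen <- read_phenotypes(config$data$phenotypes)
    ids <- phen$subject_id
    y <- phen$label
    views <- list()
    for (v in names(vd)) {
      atlas <- atlas_spec(v, vd[[v]]$n_rois)
      cohort_v <- lapply(ids, function(id) {
        path <- file.path(vd[[v]]$dir, sprintf("%s_rois_%s.1D", id, v))
        if (!file.exists(path)) {
          stop_maacnn(sprintf("missing time-series file for subject %s: %s", id, path))
        }
        read_roi_timeseries(path, atlas, subject_id = id)
      })
      views[[v]] <- build_view_features(cohort_v, atlas)
    }
  } else {
    stop_maacnn("config must contain either 'simulate' or 'data'")
  }

  mc <- config$model %||% list()
  mcfg <- if (identical(mc$scale %||% "desk", "desk")) {
    maacnn_desk_config()
  } else {
    maacnn_config()
  }
  if (!is.null(mc$f_dim)) mcfg$f_dim <- as.integer(mc$f_dim)
  if (!is.null(mc$sda)) mcfg$sda[names(mc$sda)] <- mc$sda
  if (!is.null(mc$attention)) mcfg$attention[names(mc$attention)] <- mc$attention
  if (!is.null(mc$cnn)) {
    cl <- unclass(mcfg$cnn)
    cl[names(mc$cnn)] <- mc$cnn
    mcfg$cnn <- do.call(cnn_config, cl[names(formals(cnn_config))])
  }

  ev <- config$evaluate %||% list(folds = 5L)
  report <- if (isTRUE(ev$loocv)) {
    maacnn_loocv(views, y, config = mcfg, seed = seed)
  } else {
    maacnn_cv(views, y, k = ev$folds %||% 5L, config = mcfg, seed = seed)
  }

  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    for (v in names(views)) {
      write_view_features(views[[v]], file.path(out, sprintf("features_%s.csv", v)))
    }
    provenance <- list(seed = seed, config_digest = object_digest(config),
                       package_version = as.character(utils::packageVersion("maacnn")),
                       r_version = paste(R.version$major, R.version$minor, sep = "."))
    if (inherits(report, "maacnn_cv")) {
      utils::write.csv(report$per_fold, file.path(out, "per_fold_metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(fold = seq_len(nrow(report$view_weights)), report$view_weights),
        file.path(out, "attention_weights.csv"), row.names = FALSE)
      payload <- list(provenance = provenance,
                      mean = as.list(report$mean),
                      aggregation = report$aggregation,
                      leakage_violations = report$leakage$violations)
    } else {
      payload <- list(provenance = provenance,
                      metrics = as.list(report$metrics),
                      counts = report$counts[c("TP", "FP", "TN", "FN")],
                      aggregation = report$aggregation,
                      leakage_violations = report$leakage$violations)
    }
    jsonlite::write_json(payload, file.path(out, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
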