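# Readers and writers for the plain-text formats the pipeline consumes:
# ABIDE-PCP style `.1D` ROI time-series files, phenotype CSVs, per-view
# feature tables, and the YAML run configuration.

#' Read an ROI time-series file (`.1D` dialect)
#'
#' Parses a whitespace-delimited numeric matrix, one row per time point and
#' one column per ROI in atlas order. Leading lines starting with `#` (an
#' optional header) are skipped. Column order is trusted to match the
#' atlas ROI order; the files carry no usable region names.
#'
#' @param path File path.
#' @param atlas [atlas_spec()] the column count is validated against.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, atlas, subject_id = NULL) {
  if (!file.exists(path)) stop_maacnn(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  first_data <- which(keep)[1]
  if (is.na(first_data)) stop_maacnn(sprintf("%s: no data rows", path))
  data_lines <- lines[keep]
  toks <- strsplit(trimws(data_lines), "\\s+")
  widths <- lengths(toks)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop_maacnn(sprintf("%s: ragged row at line %d", path, which(keep)[bad]))
  }
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- which(vapply(toks, function(tk) anyNA(suppressWarnings(as.numeric(tk))), logical(1)))[1]
    stop_maacnn(sprintf("%s: non-numeric token at line %d", path, which(keep)[bad_row]))
  }
  x <- matrix(vals, nrow = length(toks), ncol = widths[1], byrow = TRUE)
  if (ncol(x) != atlas$n_rois) {
    stop_maacnn(sprintf("%s: %d columns but atlas '%s' expects %d",
                        path, ncol(x), atlas$name, atlas$n_rois))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  roi_timeseries(subject_id, atlas, x)
}

#' Read a phenotype table
#'
#' Expects a CSV with columns `subject_id` and `label` plus optional
#' `site`, `age`, `sex`. Labels are normalized to 0 = HC (control) and
#' 1 = ASD (positive class); accepted encodings are `ASD`/`HC` (case
#' insensitive) or `1`/`0`. Subjects with a missing label are dropped and
#' listed in the `"excluded"` attribute of the result; duplicate subject
#' ids are an error.
#'
#' @param path CSV file path.
#' @return A data frame with normalized `label` column and any covariates,
#'   with excluded subject ids in `attr(, "excluded")`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_maacnn(sprintf("file not found: %s", path))
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "label")
  miss <- setdiff(req, names(ph))
  if (length(miss)) {
    stop_maacnn(sprintf("%s: missing required column(s): %s",
                        path, paste(miss, collapse = ", ")))
  }
  ph$subject_id <- as.character(ph$subject_id)
  if (anyDuplicated(ph$subject_id)) {
    dup <- unique(ph$subject_id[duplicated(ph$subject_id)])
    stop_maacnn(sprintf("%s: duplicate subject_id: %s",
                        path, paste(dup, collapse = ", ")))
  }
  raw <- trimws(toupper(as.character(ph$label)))
  lab <- rep(NA_integer_, nrow(ph))
  lab[raw %in% c("ASD", "1")] <- 1L
  lab[raw %in% c("HC", "CONTROL", "0")] <- 0L
  excluded <- ph$subject_id[is.na(lab) | raw == "" | is.na(ph$label)]
  keep <- !(ph$subject_id %in% excluded)
  out <- ph[keep, , drop = FALSE]
  out$label <- lab[keep]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  if (length(excluded)) {
    warning(sprintf("excluded %d subject(s) with missing/unknown label: %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Write / read a per-view feature table
#'
#' Feature tables are CSV files with a `subject_id` column followed by one
#' column per connectivity feature (`f1`, `f2`, ...).
#'
#' @param x Subject-by-feature numeric matrix with subject ids as rownames.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); the feature matrix (reader).
#' @export
write_view_features <- function(x, path) {
  df <- data.frame(subject_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                   x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_view_features
#' @export
read_view_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop_maacnn(sprintf("%s: no subject_id column", path))
  x <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(x) <- as.character(df$subject_id)
  storage.mode(x) <- "double"
  x
}

#' Read / write a run configuration
#'
#' Run configurations are YAML files mirroring the nested list returned by
#' [maacnn_config()], optionally with `views` (dataset path per view) and
#' `seed` entries. Configurations round-trip through serialization
#' unchanged.
#'
#' @param path YAML file path.
#' @param config Configuration list to write.
#' @return The configuration list (reader); `path` invisibly (writer).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_maacnn(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
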