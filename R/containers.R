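#' Vertex-by-timepoint BOLD matrix
#'
#' @param data numeric matrix, vertices x timepoints (arbitrary BOLD units).
#' @param tr_seconds repetition time in seconds (> 0).
#' @param subject_id,session_id,run_id identifiers carried along the pipeline.
#' @return An object of class `fc_timeseries`: the data matrix with
#'   repetition-time and identifier attributes.
#' @export
timeseries_matrix <- function(data, tr_seconds, subject_id = NA_character_,
                              session_id = NA_character_, run_id = NA_character_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) {
    fc_abort("time series must be finite everywhere", "fcparc_validation_error")
  }
  if (ncol(data) < 2L) {
    fc_abort("time series needs at least 2 timepoints", "fcparc_validation_error")
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    fc_abort("tr_seconds must be > 0", "fcparc_parameter_error")
  }
  structure(
    data,
    tr_seconds = as.numeric(tr_seconds),
    subject_id = as.character(subject_id),
    session_id = as.character(session_id),
    run_id = as.character(run_id),
    class = c("fc_timeseries", "matrix", "array")
  )
}

ts_meta <- function(ts) {
  list(
    tr_seconds = attr(ts, "tr_seconds"),
    subject_id = attr(ts, "subject_id"),
    session_id = attr(ts, "session_id"),
    run_id = attr(ts, "run_id")
  )
}

rewrap_ts <- function(data, template) {
  m <- ts_meta(template)
  timeseries_matrix(data, m$tr_seconds, m$subject_id, m$session_id, m$run_id)
}

#' @export
print.fc_timeseries <- function(x, ...) {
  cat(sprintf(
    "<fc_timeseries> %d vertices x %d timepoints, TR %.3g s (subject %s, session %s, run %s)\n",
    nrow(x), ncol(x), attr(x, "tr_seconds"),
    attr(x, "subject_id"), attr(x, "session_id"), attr(x, "run_id")
  ))
  invisible(x)
}

#' Concatenate runs in time
#'
#' Column-binds conditioned runs from the same subject into a single
#' time-series matrix (run-wise conditioning followed by temporal
#' concatenation is how multi-run resting-state data enter the parcellation).
#'
#' @param runs list of `fc_timeseries` with identical vertex counts and TR.
#' @return A single `fc_timeseries`.
#' @export
concat_runs <- function(runs) {
  stopifnot(length(runs) >= 1L)
  nv <- vapply(runs, nrow, integer(1))
  if (length(unique(nv)) != 1L) {
    fc_abort("runs must share the vertex count", "fcparc_dimension_error")
  }
  rewrap_ts(do.call(cbind, lapply(runs, unclass)), runs[[1]])
}

#' Network parcellation of the ROI
#'
#' A labeling of the region-of-interest vertices into K networks. Labels are
#' 1..K (0 is reserved for "outside ROI" in full-surface exports).
#'
#' @param labels integer vector of network labels, one per ROI vertex, values
#'   in 1..k with every label present.
#' @param roi_vertices 1-based mesh vertex indices of the ROI, aligned with
#'   `labels`.
#' @param k network count.
#' @param n_vertices_total vertex count of the underlying mesh.
#' @param level `"group"` or `"individual"`.
#' @param provenance free-text record of inputs and seeds.
#' @param require_complete error when some label in 1..k has no vertex
#'   (default); adapted individual parcellations may switch this off since
#'   reassignment can legitimately empty a network.
#' @return An object of class `fc_parcellation`.
#' @export
parcellation <- function(labels, roi_vertices, k = max(labels),
                         n_vertices_total = max(roi_vertices),
                         level = c("group", "individual"),
                         provenance = "", require_complete = TRUE) {
  level <- match.arg(level)
  labels <- as.integer(labels)
  roi_vertices <- as.integer(roi_vertices)
  if (length(labels) != length(roi_vertices)) {
    fc_abort("labels and roi_vertices must align", "fcparc_dimension_error")
  }
  if (any(labels < 1L) || any(labels > k)) {
    fc_abort("labels must lie in 1..k", "fcparc_validation_error")
  }
  if (require_complete && !all(seq_len(k) %in% labels)) {
    fc_abort("labels 1..k must be contiguous (every network non-empty)",
             "fcparc_validation_error")
  }
  structure(
    list(
      labels = labels, roi_vertices = roi_vertices, k = as.integer(k),
      n_vertices_total = as.integer(n_vertices_total), level = level,
      provenance = provenance
    ),
    class = "fc_parcellation"
  )
}

#' @export
print.fc_parcellation <- function(x, ...) {
  cat(sprintf(
    "<fc_parcellation> %s level, %d networks over %d ROI vertices\n",
    x$level, x$k, length(x$labels)
  ))
  print(table(network = x$labels))
  invisible(x)
}

#' Tidy a parcellation into a vertex-level tibble
#'
#' @param x an `fc_parcellation`.
#' @param ... unused.
#' @return A tibble with columns `vertex` (1-based mesh index) and `network`.
#' @export
tidy.fc_parcellation <- function(x, ...) {
  tibble::tibble(vertex = x$roi_vertices, network = x$labels)
}

same_roi <- function(a, b) {
  identical(a$roi_vertices, b$roi_vertices)
}

#' Task activation z-map over the ROI
#'
#' @param z numeric vector of z-scores, one per ROI vertex.
#' @param roi_vertices aligned 1-based mesh vertex indices.
#' @param contrast_name,subject_id identifiers.
#' @return An object of class `fc_zmap`.
#' @export
task_zmap <- function(z, roi_vertices, contrast_name = "contrast",
                      subject_id = NA_character_) {
  if (!all(is.finite(z))) {
    fc_abort("z-map must be finite", "fcparc_validation_error")
  }
  if (length(z) != length(roi_vertices)) {
    fc_abort("z and roi_vertices must align", "fcparc_dimension_error")
  }
  structure(
    list(z = as.numeric(z), roi_vertices = as.integer(roi_vertices),
         contrast_name = contrast_name, subject_id = subject_id),
    class = "fc_zmap"
  )
}

#' Subject-by-subject similarity matrix
#'
#' @param values symmetric numeric matrix (subjects x subjects).
#' @param metric_name e.g. `"dice"`, `"spearman-thickness"`.
#' @param subject_ids character vector of row/column identities.
#' @return An object of class `fc_similarity`.
#' @export
similarity_matrix <- function(values, metric_name, subject_ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) ||
      max(abs(values - t(values))) > 1e-12) {
    fc_abort("similarity matrix must be symmetric", "fcparc_validation_error")
  }
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(values)))
  dimnames(values) <- list(subject_ids, subject_ids)
  structure(
    list(values = values, metric_name = metric_name, subject_ids = subject_ids),
    class = "fc_similarity"
  )
}

#' @export
print.fc_similarity <- function(x, ...) {
  cat(sprintf("<fc_similarity> %s, %d subjects\n", x$metric_name, nrow(x$values)))
  invisible(x)
}
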