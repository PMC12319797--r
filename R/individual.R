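# Iterative confidence-weighted adaptation of the group atlas to a single
# subject. One iteration: reassign every ROI vertex to the network whose
# reference signal it correlates with most; compute a per-vertex confidence
# as the ratio of the largest to second-largest correlation; rebuild each
# network's "high-confidence signal" from the vertices whose confidence
# exceeds the threshold (default 1.3); average it with the reference signal
# to form the next iteration's references.

#' Network reference signals
#'
#' Per network: standardize every member vertex time course (mean 0, sd 1),
#' average them, and re-standardize the average.
#'
#' @param ts conditioned `fc_timeseries`.
#' @param parc an [parcellation()]; members are its ROI vertices.
#' @return An object of class `fc_reference`: k x timepoints matrix of
#'   standardized reference signals.
#' @export
compute_reference_signals <- function(ts, parc) {
  x <- standardize_rows(unclass(ts)[parc$roi_vertices, , drop = FALSE])
  refs <- matrix(0, parc$k, ncol(ts))
  for (l in seq_len(parc$k)) {
    members <- which(parc$labels == l)
    if (length(members) == 0) {
      fc_abort(sprintf("network %d has no member vertices", l),
               "fcparc_validation_error")
    }
    avg <- colMeans(x[members, , drop = FALSE])
    std <- standardize_vec(avg)
    if (isTRUE(attr(std, "degenerate"))) {
      fc_abort(sprintf("network %d reference signal degenerates (sd < 1e-6)", l),
               "fcparc_validation_error")
    }
    refs[l, ] <- std
  }
  structure(refs, class = c("fc_reference", "matrix", "array"))
}

#' Reassign vertices by maximal reference correlation
#'
#' Each ROI vertex is assigned to the network whose reference signal it
#' correlates with most (ties resolve to the lowest label). Confidence is
#' the largest correlation divided by the second largest, with the divisor
#' floored at `1e-6` so non-positive runner-up correlations yield very high
#' confidence; vertices whose best correlation is itself non-positive get
#' confidence 1.
#'
#' @param ts conditioned `fc_timeseries`.
#' @param refs an `fc_reference` matrix (k x timepoints).
#' @param roi_vertices 1-based ROI vertex indices.
#' @return A list with `labels` (integer per ROI vertex) and `confidence`
#'   tibble (`vertex`, `confidence`, `best_label`, `second_label`,
#'   `flagged`).
#' @export
assign_by_correlation <- function(ts, refs, roi_vertices) {
  x <- unclass(ts)[roi_vertices, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  flagged <- sds < 1e-12
  r <- matrix(-1, length(roi_vertices), nrow(refs))
  if (any(!flagged)) {
    r[!flagged, ] <- stats::cor(t(x[!flagged, , drop = FALSE]), t(unclass(refs)))
  }
  best <- max.col(r, ties.method = "first")
  r_best <- r[cbind(seq_len(nrow(r)), best)]
  r2 <- r
  r2[cbind(seq_len(nrow(r)), best)] <- -Inf
  second <- max.col(r2, ties.method = "first")
  r_second <- r2[cbind(seq_len(nrow(r)), second)]
  conf <- r_best / pmax(r_second, 1e-6)
  conf[conf < 1 | !is.finite(conf)] <- 1
  best[flagged] <- 1L
  conf[flagged] <- 1
  list(
    labels = best,
    confidence = tibble::tibble(
      vertex = as.integer(roi_vertices), confidence = conf,
      best_label = as.integer(best), second_label = as.integer(second),
      flagged = flagged
    )
  )
}

#' High-confidence network signals
#'
#' Per network, the standardized average of the member vertices whose
#' confidence strictly exceeds the threshold; a network with no such vertex
#' keeps a copy of its current reference signal (so the subsequent averaging
#' leaves that reference unchanged).
#'
#' @param ts conditioned `fc_timeseries`.
#' @param labels current ROI labels.
#' @param confidence per-vertex confidence values (aligned with `labels`).
#' @param refs current `fc_reference`.
#' @param roi_vertices ROI vertex indices.
#' @param threshold confidence cut (strict inequality; default 1.3).
#' @return A k x timepoints matrix.
#' @export
high_confidence_signal <- function(ts, labels, confidence, refs, roi_vertices,
                                   threshold = 1.3) {
  x <- standardize_rows(unclass(ts)[roi_vertices, , drop = FALSE])
  out <- unclass(refs)
  for (l in seq_len(nrow(refs))) {
    members <- which(labels == l & confidence > threshold)
    if (length(members) == 0) next
    std <- standardize_vec(colMeans(x[members, , drop = FALSE]))
    if (!isTRUE(attr(std, "degenerate"))) out[l, ] <- std
  }
  out
}

#' Individualize a group atlas
#'
#' Iterative confidence-weighted adaptation: references start from the group
#' parcellation; each iteration reassigns vertices by maximal correlation,
#' forms high-confidence signals, and averages them with the reference
#' signals (equal weights, re-standardized) to produce the next references.
#'
#' @param ts the subject's conditioned, concatenated `fc_timeseries`.
#' @param group_atlas an `fc_group_atlas` or a group-level
#'   [parcellation()] on the same mesh.
#' @param n_iter number of iterations (default 10).
#' @param threshold confidence threshold (default 1.3).
#' @param ref_update `"current"` averages the high-confidence signal with the
#'   running reference (loop semantics); `"original"` always averages with
#'   the initial group reference.
#' @return An object of class `fc_individual`: `parcellation` (level
#'   `"individual"`), `confidence` tibble, and `trace` tibble with the Dice
#'   coefficient between consecutive-iteration labelings.
#' @export
individualize <- function(ts, group_atlas, n_iter = 10, threshold = 1.3,
                          ref_update = c("current", "original")) {
  ref_update <- match.arg(ref_update)
  if (n_iter < 1) fc_abort("n_iter must be >= 1", "fcparc_parameter_error")
  parc0 <- if (inherits(group_atlas, "fc_group_atlas")) {
    group_atlas$parcellation
  } else {
    group_atlas
  }
  roi <- parc0$roi_vertices
  refs <- compute_reference_signals(ts, parc0)
  refs0 <- refs
  prev_labels <- parc0$labels
  trace <- numeric(n_iter)
  labels <- prev_labels
  conf <- NULL
  for (it in seq_len(n_iter)) {
    asg <- assign_by_correlation(ts, refs, roi)
    labels <- asg$labels
    conf <- asg$confidence
    trace[it] <- mean_dice_labels(prev_labels, labels, parc0$k)
    hc <- high_confidence_signal(ts, labels, conf$confidence, refs, roi,
                                 threshold)
    base <- if (ref_update == "current") unclass(refs) else unclass(refs0)
    refs <- structure(standardize_rows((hc + base) / 2),
                      class = c("fc_reference", "matrix", "array"))
    prev_labels <- labels
  }
  parc <- parcellation(
    labels, roi, k = parc0$k, n_vertices_total = parc0$n_vertices_total,
    level = "individual", require_complete = FALSE,
    provenance = sprintf(
      "individualize(n_iter=%d, threshold=%g, ref_update=%s) of [%s]",
      n_iter, threshold, ref_update, parc0$provenance
    )
  )
  structure(
    list(parcellation = parc, confidence = conf,
         trace = tibble::tibble(iteration = seq_len(n_iter),
                                dice_vs_previous = trace),
         n_iter = n_iter, threshold = threshold, ref_update = ref_update),
    class = "fc_individual"
  )
}

#' @export
print.fc_individual <- function(x, ...) {
  cat(sprintf(
    "<fc_individual> k=%d, %d iterations (final consecutive-iteration Dice %.3f)\n",
    x$parcellation$k, x$n_iter, utils::tail(x$trace$dice_vs_previous, 1)
  ))
  invisible(x)
}
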