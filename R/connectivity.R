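# Signal conditioning and vertex functional-connectivity profiles.
#
# Pipeline order: band-pass filter -> nuisance regression -> Pearson
# connectivity profiles. Multiple runs are conditioned per run and then
# concatenated in time before profiles are computed.

# steady-state filter state for a unit step input (the lfilter_zi trick), so
# zero-phase filtering does not ring at the series edges
filter_zi <- function(b, a) {
  K <- length(a)
  ns <- K - 1L
  A <- matrix(0, ns, ns)
  B <- numeric(ns)
  for (i in seq_len(ns)) {
    A[i, 1] <- -a[i + 1]
    if (i < ns) A[i, i + 1] <- 1
    B[i] <- b[i + 1] - a[i + 1] * b[1]
  }
  solve(diag(ns) - A, B)
}

# direct-form II transposed ARMA filtering, vectorized over columns of a
# time x channels matrix; one R-level loop over timepoints only. The state
# is initialized at the step steady state scaled by each channel's first
# sample.
arma_filter_cols <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  K <- max(length(a), length(b))
  b <- c(b, rep(0, K - length(b)))
  a <- c(a, rep(0, K - length(a)))
  n <- nrow(x)
  m <- ncol(x)
  z <- filter_zi(b, a) %o% x[1, ]
  y <- matrix(0, n, m)
  for (t in seq_len(n)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (K > 2) {
      for (i in seq_len(K - 2)) {
        z[i, ] <- b[i + 1] * xt + z[i + 1, ] - a[i + 1] * yt
      }
    }
    z[K - 1, ] <- b[K] * xt - a[K] * yt
    y[t, ] <- yt
  }
  y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward (zero
#' phase) to every vertex time course, with odd-reflective edge padding. The
#' pass band defaults to the standard resting-state analysis band
#' 0.01-0.08 Hz; DC is fully rejected.
#'
#' @param ts an `fc_timeseries`.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)`.
#' @param order Butterworth prototype order (default 4).
#' @return A filtered `fc_timeseries` with per-vertex mean ~ 0.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08, order = 4) {
  tr <- attr(ts, "tr_seconds")
  nyq <- 1 / (2 * tr)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    fc_abort("need 0 < low_hz < high_hz", "fcparc_parameter_error")
  }
  if (high_hz >= nyq) {
    fc_abort(sprintf("high_hz (%g) must be below the Nyquist frequency %g Hz",
                     high_hz, nyq), "fcparc_parameter_error")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  x <- t(unclass(ts)) # time x vertices
  n <- nrow(x)
  pad <- 3L * (max(length(bf$a), length(bf$b)) - 1L)
  if (n <= pad + 1L) {
    fc_abort("time series too short for the filter edge padding",
             "fcparc_parameter_error")
  }
  top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[pad + 1L - seq_len(pad), , drop = FALSE]
  bot <- 2 * x[rep(n, pad), , drop = FALSE] - x[n - seq_len(pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- arma_filter_cols(bf$b, bf$a, xp)
  y <- arma_filter_cols(bf$b, bf$a, y[rev(seq_len(nrow(y))), , drop = FALSE])
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE][pad + seq_len(n), , drop = FALSE]
  y <- t(y)
  y <- y - rowMeans(y) # remove residual numerical DC
  rewrap_ts(y, ts)
}

#' Regress nuisance signals out of every vertex time course
#'
#' Ordinary-least-squares residualization against the given regressors plus
#' an intercept. Rank-deficient regressor sets are handled by the pivoted QR
#' (equivalent to the pseudoinverse solution) with a warning.
#'
#' @param ts an `fc_timeseries`.
#' @param regressors numeric matrix, timepoints x q.
#' @return A residual `fc_timeseries`, orthogonal to every regressor.
#' @export
regress_nuisance <- function(ts, regressors) {
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != ncol(ts)) {
    fc_abort("regressor rows must equal timepoints", "fcparc_dimension_error")
  }
  if (ncol(regressors) >= ncol(ts)) {
    fc_abort("need fewer regressors than timepoints", "fcparc_parameter_error")
  }
  x <- cbind(1, regressors)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("rank-deficient regressor matrix; using pseudoinverse projection")
  }
  m <- t(unclass(ts))
  res <- qr.resid(qx, m)
  rewrap_ts(t(res), ts)
}

#' Condition a set of runs for parcellation
#'
#' Band-pass filters and (optionally) nuisance-regresses each run, then
#' concatenates runs in time.
#'
#' @param runs list of `fc_timeseries` (or a single one).
#' @param low_hz,high_hz band edges in Hz.
#' @param regressors optional per-run list of nuisance matrices.
#' @return A single conditioned `fc_timeseries`.
#' @export
condition_runs <- function(runs, low_hz = 0.01, high_hz = 0.08,
                           regressors = NULL) {
  if (inherits(runs, "fc_timeseries")) runs <- list(runs)
  out <- lapply(seq_along(runs), function(i) {
    r <- bandpass_filter(runs[[i]], low_hz, high_hz)
    if (!is.null(regressors)) r <- regress_nuisance(r, regressors[[i]])
    r
  })
  concat_runs(out)
}

#' Vertex functional-connectivity profiles
#'
#' For every ROI vertex, the Pearson correlation between its time course and
#' that of every cortical vertex: an ROI x cortex matrix stored full-length
#' with the self-correlation entry masked to 0, so profiles live in one
#' common vector space and can be averaged across subjects. Zero-variance
#' vertices get all-zero rows/columns and are reported in the `excluded`
#' attribute rather than silently dropped.
#'
#' @param ts conditioned `fc_timeseries` over all cortex vertices.
#' @param roi_vertices 1-based indices of the ROI vertices (rows).
#' @return An `fc_profiles` matrix (ROI x cortex) with attributes
#'   `roi_vertices` and `excluded`.
#' @export
connectivity_profiles <- function(ts, roi_vertices) {
  roi_vertices <- as.integer(roi_vertices)
  x <- unclass(ts)
  sds <- sqrt(rowSums((x - rowMeans(x))^2))
  bad <- which(sds < 1e-12)
  good <- setdiff(seq_len(nrow(x)), bad)
  vals <- matrix(0, length(roi_vertices), nrow(x))
  roi_good <- roi_vertices[roi_vertices %in% good]
  if (length(roi_good) > 0 && length(good) > 0) {
    cc <- stats::cor(t(x[roi_good, , drop = FALSE]), t(x[good, , drop = FALSE]))
    vals[match(roi_good, roi_vertices), good] <- cc
  }
  vals[cbind(seq_along(roi_vertices), roi_vertices)] <- 0
  structure(
    vals,
    roi_vertices = roi_vertices,
    excluded = intersect(bad, roi_vertices),
    class = c("fc_profiles", "matrix", "array")
  )
}

#' @export
print.fc_profiles <- function(x, ...) {
  cat(sprintf("<fc_profiles> %d ROI vertices x %d cortex vertices (%d excluded)\n",
              nrow(x), ncol(x), length(attr(x, "excluded"))))
  invisible(x)
}

#' Fisher r-to-z transformation
#'
#' `atanh` of a correlation, with clipping at `1 - 1e-7` in absolute value so
#' perfect correlations map to a large finite z.
#'
#' @param r correlations in `[-1, 1]`.
#' @return z-values.
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    fc_abort("correlations must lie in [-1, 1]", "fcparc_domain_error")
  }
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' End-to-end profiles for one subject
#'
#' Convenience wrapper: condition all runs of the given sessions and compute
#' connectivity profiles of the ROI on the concatenated series.
#'
#' @param runs list of `fc_timeseries` runs.
#' @param mesh a [surface_mesh()].
#' @param low_hz,high_hz band edges.
#' @return An `fc_profiles` matrix.
#' @export
subject_profiles <- function(runs, mesh, low_hz = 0.01, high_hz = 0.08) {
  ts <- condition_runs(runs, low_hz, high_hz)
  connectivity_profiles(ts, which(mesh$roi_mask))
}
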