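# Synthetic surface-fMRI cohorts with known ground-truth network layouts.
#
# The generator emulates the statistical structure the parcellation analysis
# assumes: a cohort of subjects sharing a group-level network layout with
# subject-specific boundary perturbations, several sessions per subject,
# band-limited (0.01-0.08 Hz) network latent time courses with controllable
# SNR and inter-network correlation, task activation z-maps concentrated in
# chosen networks, and smooth anatomy fields statistically independent of
# network membership.

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param sessions_per_subject sessions per subject.
#' @param runs_per_session runs per session.
#' @param timepoints_per_run timepoints per run.
#' @param tr_seconds repetition time (s).
#' @param k_true true network count in the ROI.
#' @param mesh_subdivisions icosphere refinement level (level 3 gives 642
#'   vertices, a desk-scale analog of a standard average surface).
#' @param boundary_jitter expected fraction of ROI vertices whose true label
#'   differs from the group template (0-0.5).
#' @param snr ratio of latent-signal sd to vertex noise sd (`Inf` = noise
#'   free).
#' @param latent_correlation pairwise correlation among network latent time
#'   courses (0-0.9).
#' @param seed master seed; all per-subject/per-session seeds derive from it.
#' @return An object of class `fc_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 8, sessions_per_subject = 2,
                        runs_per_session = 1, timepoints_per_run = 200,
                        tr_seconds = 2.8, k_true = 4, mesh_subdivisions = 3,
                        boundary_jitter = 0.2, snr = 1,
                        latent_correlation = 0.2, seed = 1) {
  counts <- c(n_subjects, sessions_per_subject, runs_per_session,
              timepoints_per_run, k_true)
  if (any(counts < 1)) {
    fc_abort("all counts must be >= 1", "fcparc_parameter_error")
  }
  if (boundary_jitter < 0 || boundary_jitter > 0.5) {
    fc_abort("boundary_jitter must lie in [0, 0.5]", "fcparc_parameter_error")
  }
  if (!(snr > 0)) {
    fc_abort("snr must be > 0", "fcparc_parameter_error")
  }
  if (latent_correlation < 0 || latent_correlation >= 1) {
    fc_abort("latent_correlation must lie in [0, 1)", "fcparc_parameter_error")
  }
  structure(
    list(
      n_subjects = n_subjects, sessions_per_subject = sessions_per_subject,
      runs_per_session = runs_per_session,
      timepoints_per_run = timepoints_per_run, tr_seconds = tr_seconds,
      k_true = k_true, mesh_subdivisions = mesh_subdivisions,
      boundary_jitter = boundary_jitter, snr = snr,
      latent_correlation = latent_correlation, seed = seed
    ),
    class = "fc_cohort_spec"
  )
}

#' Grow a spatially contiguous group template parcellation
#'
#' Farthest-point sampling of k seed vertices on the ROI neighbor graph
#' followed by simultaneous breadth-first region growing, producing k
#' contiguous patches that cover the chosen vertex set.
#'
#' @param mesh a [surface_mesh()].
#' @param k number of networks (>= 2).
#' @param seed RNG seed (first patch seed is drawn at random).
#' @param vertices vertex set to partition; defaults to the mesh ROI.
#' @param level parcellation level stamp.
#' @return An [parcellation()] covering `vertices`.
#' @export
make_group_template <- function(mesh, k, seed = 1,
                                vertices = which(mesh$roi_mask),
                                level = "group") {
  if (k < 2) fc_abort("k must be >= 2", "fcparc_parameter_error")
  if (k > length(vertices)) {
    fc_abort("k cannot exceed the vertex count", "fcparc_parameter_error")
  }
  set.seed(seed)
  nv <- length(mesh$neighbors)
  in_set <- logical(nv)
  in_set[vertices] <- TRUE

  bfs_dist <- function(src) {
    d <- rep(NA_integer_, nv)
    d[src] <- 0L
    frontier <- src
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in mesh$neighbors[[u]]) {
          if (in_set[w] && is.na(d[w])) {
            d[w] <- d[u] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    d
  }

  seeds <- sample(vertices, 1)
  min_d <- bfs_dist(seeds)
  for (i in seq_len(k - 1)) {
    cand <- vertices[which.max(min_d[vertices])]
    seeds <- c(seeds, cand)
    min_d <- pmin(min_d, bfs_dist(cand), na.rm = TRUE)
  }

  # simultaneous BFS growth: each vertex takes the label of the patch whose
  # frontier reaches it first (ties to the lower label), so patches stay
  # contiguous
  lab <- integer(nv)
  lab[seeds] <- seq_len(k)
  frontier <- seeds
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in mesh$neighbors[[u]]) {
        if (in_set[w] && lab[w] == 0L) {
          lab[w] <- lab[u]
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }

  parcellation(lab[vertices], vertices, k = k, n_vertices_total = nv,
               level = level,
               provenance = sprintf("synthetic template (k=%d, seed=%d)", k, seed))
}

#' Perturb a template at network boundaries
#'
#' Flips labels only at patch boundaries (vertices with at least one ROI
#' neighbor of another network), each flip taking a neighboring network's
#' label, until the fraction of vertices disagreeing with the template
#' reaches the target. No network is ever emptied; if the target is
#' unreachable the function stops early with a warning.
#'
#' @param template an [parcellation()].
#' @param mesh the [surface_mesh()] the template lives on.
#' @param boundary_jitter target disagreement fraction (0-0.5).
#' @param seed RNG seed.
#' @return A perturbed `fc_parcellation` (level `"individual"`).
#' @export
perturb_individual <- function(template, mesh, boundary_jitter, seed = 1) {
  if (boundary_jitter < 0 || boundary_jitter > 0.5) {
    fc_abort("boundary_jitter must lie in [0, 0.5]", "fcparc_parameter_error")
  }
  set.seed(seed)
  roi <- template$roi_vertices
  nv <- length(mesh$neighbors)
  full <- rep(NA_integer_, nv)
  full[roi] <- template$labels
  labels <- template$labels
  counts <- tabulate(labels, template$k)
  target <- round(boundary_jitter * length(labels))
  n_flipped <- 0L

  while (n_flipped < target) {
    cand <- which(vapply(seq_along(roi), function(i) {
      if (labels[i] != template$labels[i]) return(FALSE) # already flipped
      if (counts[labels[i]] <= 1L) return(FALSE)         # would empty network
      nb <- full[mesh$neighbors[[roi[i]]]]
      any(!is.na(nb) & nb != labels[i])
    }, logical(1)))
    if (length(cand) == 0L) {
      warning("boundary jitter target unreachable; stopped early at ",
              n_flipped, " flips")
      break
    }
    i <- if (length(cand) == 1L) cand else sample(cand, 1)
    nb <- full[mesh$neighbors[[roi[i]]]]
    alt <- unique(nb[!is.na(nb) & nb != labels[i]])
    new_lab <- if (length(alt) == 1L) alt else sample(alt, 1)
    counts[labels[i]] <- counts[labels[i]] - 1L
    counts[new_lab] <- counts[new_lab] + 1L
    labels[i] <- new_lab
    full[roi[i]] <- new_lab
    n_flipped <- n_flipped + 1L
  }

  parcellation(labels, roi, k = template$k,
               n_vertices_total = template$n_vertices_total,
               level = "individual",
               provenance = sprintf("perturbed template (jitter=%.3g, seed=%d)",
                                    boundary_jitter, seed))
}

# band-limited Gaussian signals: random spectrum restricted to [low, high] Hz,
# inverse FFT, standardized rows
bandlimited_signals <- function(n_signals, n_t, tr, low = 0.01, high = 0.08) {
  freqs <- (seq_len(n_t) - 1) / (n_t * tr)
  half <- seq(2L, floor(n_t / 2) + 1L)
  band <- half[freqs[half] >= low & freqs[half] <= high]
  if (length(band) < 2L) {
    fc_abort("too few timepoints to realize the frequency band",
             "fcparc_parameter_error")
  }
  out <- matrix(0, n_signals, n_t)
  for (i in seq_len(n_signals)) {
    spec <- complex(length.out = n_t)
    spec[band] <- complex(real = stats::rnorm(length(band)),
                          imaginary = stats::rnorm(length(band)))
    spec[n_t - band + 2L] <- Conj(spec[band])
    out[i, ] <- standardize_vec(Re(stats::fft(spec, inverse = TRUE)))
  }
  out
}

# K standardized latents with pairwise correlation rho (shared-component
# construction)
correlated_latents <- function(k, n_t, tr, rho, low = 0.01, high = 0.08) {
  shared <- bandlimited_signals(1, n_t, tr, low, high)
  own <- bandlimited_signals(k, n_t, tr, low, high)
  lat <- sqrt(rho) * matrix(shared, k, n_t, byrow = TRUE) + sqrt(1 - rho) * own
  standardize_rows(lat)
}

#' Simulate one resting-state session
#'
#' Each ROI vertex receives its network's latent time course plus white
#' Gaussian noise of sd `1/snr` (latents are standardized); non-ROI cortex
#' vertices receive the same latents through a second, spatially independent
#' network layout, so connectivity profiles carry genuine long-range
#' structure. The matrix is demeaned per vertex.
#'
#' @param truth subject ground-truth [parcellation()] over the ROI.
#' @param mesh the [surface_mesh()].
#' @param nonroi_template [parcellation()] of the non-ROI cortex (shared
#'   across the cohort).
#' @param spec an [cohort_spec()].
#' @param seed session seed.
#' @param subject_id,session_id,run_id identifiers stamped on the output.
#' @return An `fc_timeseries` covering every mesh vertex.
#' @export
simulate_session <- function(truth, mesh, nonroi_template, spec, seed = 1,
                             subject_id = NA, session_id = NA, run_id = NA) {
  n_t <- spec$timepoints_per_run
  if (n_t < 10) {
    fc_abort("need at least 10 timepoints per run", "fcparc_parameter_error")
  }
  set.seed(seed)
  lat_roi <- correlated_latents(spec$k_true, n_t, spec$tr_seconds,
                                spec$latent_correlation)
  k2 <- nonroi_template$k
  nv <- length(mesh$neighbors)

  lat_row <- integer(nv)
  lat_row[truth$roi_vertices] <- truth$labels
  lat_row[nonroi_template$roi_vertices] <- nonroi_template$labels
  data <- lat_roi[lat_row, , drop = FALSE]
  noise_sd <- if (is.infinite(spec$snr)) 0 else 1 / spec$snr
  if (noise_sd > 0) {
    data <- data + matrix(stats::rnorm(nv * n_t, sd = noise_sd), nv, n_t)
  }
  data <- data - rowMeans(data)
  timeseries_matrix(data, spec$tr_seconds, subject_id, session_id, run_id)
}

#' Simulate a task activation z-map
#'
#' z equals `effect_size` on vertices of the effect networks and 0 elsewhere,
#' plus N(0, noise_sd) noise.
#'
#' @param truth subject ground-truth [parcellation()].
#' @param effect_networks non-empty subset of `1..k` carrying activation.
#' @param effect_size activation level in z units.
#' @param noise_sd measurement noise sd.
#' @param seed RNG seed.
#' @param contrast_name,subject_id identifiers.
#' @return An [task_zmap()].
#' @export
simulate_task_zmap <- function(truth, effect_networks, effect_size = 3,
                               noise_sd = 0.5, seed = 1,
                               contrast_name = "task", subject_id = NA) {
  effect_networks <- as.integer(effect_networks)
  if (length(effect_networks) == 0) {
    fc_abort("effect_networks must be non-empty", "fcparc_parameter_error")
  }
  if (!all(effect_networks %in% seq_len(truth$k))) {
    fc_abort("effect_networks must be a subset of 1..k", "fcparc_parameter_error")
  }
  set.seed(seed)
  z <- ifelse(truth$labels %in% effect_networks, effect_size, 0)
  if (noise_sd > 0) z <- z + stats::rnorm(length(z), sd = noise_sd)
  task_zmap(z, truth$roi_vertices, contrast_name, subject_id)
}

#' Simulate smooth anatomy fields
#'
#' Thickness (mm; mean 2.5, sd 0.3) and curvature (1/mm; mean 0, sd 0.15) as
#' smooth Gaussian random fields on the mesh, generated independently of any
#' network labels (graph-diffusion smoothing of white noise, rescaled).
#'
#' @param mesh a [surface_mesh()].
#' @param seed RNG seed.
#' @param n_smooth diffusion smoothing iterations.
#' @return A tibble with columns `vertex`, `thickness`, `curvature`.
#' @export
simulate_anatomy <- function(mesh, seed = 1, n_smooth = 20) {
  set.seed(seed)
  nv <- length(mesh$neighbors)
  from <- rep(seq_len(nv), lengths(mesh$neighbors))
  to <- unlist(mesh$neighbors)
  deg <- lengths(mesh$neighbors)
  smooth_field <- function() {
    x <- stats::rnorm(nv)
    for (i in seq_len(n_smooth)) {
      nb_mean <- as.numeric(rowsum(x[to], from)) / deg
      x <- 0.5 * x + 0.5 * nb_mean
    }
    as.numeric(standardize_vec(x))
  }
  tibble::tibble(
    vertex = seq_len(nv),
    thickness = 2.5 + 0.3 * smooth_field(),
    curvature = 0.15 * smooth_field()
  )
}

#' Simulate a full cohort
#'
#' Builds the mesh, the group template and its non-ROI counterpart, a
#' perturbed ground-truth parcellation per subject, all resting-state runs,
#' per-subject anatomy fields, and one task z-map per subject concentrated in
#' `effect_networks`.
#'
#' @param spec an [cohort_spec()].
#' @param effect_networks networks carrying the simulated task effect
#'   (default: the first half of the networks).
#' @return An object of class `fc_cohort` with elements `spec`, `mesh`,
#'   `template`, `nonroi_template`, `truths`, `runs`
#'   (`runs[[subject]][[session]][[run]]`), `anatomy`, `zmaps`,
#'   `effect_networks`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_subjects = 2, mesh_subdivisions = 2,
#'                                   timepoints_per_run = 60, seed = 7))
#' co$truths[[1]]
#' @export
simulate_cohort <- function(spec,
                            effect_networks = seq_len(max(1, spec$k_true %/% 2))) {
  mesh <- build_mesh(spec$mesh_subdivisions)
  template <- make_group_template(mesh, spec$k_true,
                                  seed = derive_seed(spec$seed, 1))
  nonroi_template <- make_group_template(
    mesh, spec$k_true, seed = derive_seed(spec$seed, 2),
    vertices = which(!mesh$roi_mask), level = "group"
  )
  truths <- lapply(seq_len(spec$n_subjects), function(s) {
    perturb_individual(template, mesh, spec$boundary_jitter,
                       seed = derive_seed(spec$seed, 10, s))
  })
  runs <- lapply(seq_len(spec$n_subjects), function(s) {
    lapply(seq_len(spec$sessions_per_subject), function(ses) {
      lapply(seq_len(spec$runs_per_session), function(r) {
        simulate_session(
          truths[[s]], mesh, nonroi_template, spec,
          seed = derive_seed(spec$seed, 100, s, ses, r),
          subject_id = sprintf("sub%02d", s),
          session_id = sprintf("ses%d", ses), run_id = sprintf("run%d", r)
        )
      })
    })
  })
  anatomy <- lapply(seq_len(spec$n_subjects), function(s) {
    simulate_anatomy(mesh, seed = derive_seed(spec$seed, 200, s))
  })
  zmaps <- lapply(seq_len(spec$n_subjects), function(s) {
    simulate_task_zmap(truths[[s]], effect_networks,
                       seed = derive_seed(spec$seed, 300, s),
                       subject_id = sprintf("sub%02d", s))
  })
  structure(
    list(spec = spec, mesh = mesh, template = template,
         nonroi_template = nonroi_template, truths = truths, runs = runs,
         anatomy = anatomy, zmaps = zmaps,
         effect_networks = as.integer(effect_networks)),
    class = "fc_cohort"
  )
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf(
    "<fc_cohort> %d subjects x %d sessions x %d runs, %d timepoints/run, k_true=%d, snr=%.3g, jitter=%.3g\n",
    x$spec$n_subjects, x$spec$sessions_per_subject, x$spec$runs_per_session,
    x$spec$timepoints_per_run, x$spec$k_true, x$spec$snr, x$spec$boundary_jitter
  ))
  invisible(x)
}
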