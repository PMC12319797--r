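# Group-level parcellation: spherical k-means over subject-averaged
# connectivity profiles, split-half model-order selection, small-cluster
# cleanup.

#' Average connectivity profiles across subjects
#'
#' @param per_subject list of `fc_profiles` with identical shape, vertex
#'   order and ROI.
#' @return The element-wise mean `fc_profiles` (self entries stay 0).
#' @export
average_profiles <- function(per_subject) {
  stopifnot(length(per_subject) >= 1)
  dims <- lapply(per_subject, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    fc_abort("profile matrices must share their shape", "fcparc_dimension_error")
  }
  acc <- Reduce(`+`, lapply(per_subject, unclass)) / length(per_subject)
  structure(
    acc,
    roi_vertices = attr(per_subject[[1]], "roi_vertices"),
    excluded = sort(unique(unlist(lapply(per_subject, attr, "excluded")))),
    class = c("fc_profiles", "matrix", "array")
  )
}

normalize_rows_l2 <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm < 1e-12
  nrm[zero] <- 1
  structure(x / nrm, zero_rows = which(zero))
}

#' Spherical k-means on connectivity profiles
#'
#' L2-normalizes profile rows and runs Lloyd iterations assigning each vertex
#' to the centroid of maximal cosine similarity; centroids are normalized
#' means of their members. The clustering is restarted `n_restarts` times
#' from random initial centroids and the solution with the smallest
#' aggregate distance (sum over vertices of 1 minus the cosine similarity to
#' the assigned centroid) is kept. Empty clusters are repaired by seizing
#' the vertex farthest from its current centroid.
#'
#' @param profiles an `fc_profiles` matrix (or plain matrix) of ROI vertices
#'   x features.
#' @param k number of networks (>= 2).
#' @param n_restarts random restarts (default 500).
#' @param seed RNG seed.
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `fc_group_atlas`: `parcellation`, unit-norm
#'   `centroids` (k x features), `aggregate_distance`, `objective_trace` for
#'   the winning restart, and provenance fields.
#' @export
kmeans_cosine <- function(profiles, k, n_restarts = 500, seed = 1,
                          max_iter = 300) {
  if (k < 2) fc_abort("k must be >= 2", "fcparc_parameter_error")
  x <- unclass(profiles)
  n <- nrow(x)
  if (n <= k) fc_abort("need more vertices than clusters", "fcparc_parameter_error")
  xn <- normalize_rows_l2(x)
  zero_rows <- attr(xn, "zero_rows")
  if (length(zero_rows) > 0) {
    warning(length(zero_rows), " all-zero profile row(s); assigned by tie-break")
  }
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    cent <- xn[sample(n, k), , drop = FALSE]
    labels <- integer(n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      sim <- xn %*% t(cent)
      new_labels <- max.col(sim, ties.method = "first")
      # repair empty clusters: seize the vertex farthest from its centroid
      repeat {
        cnt <- tabulate(new_labels, k)
        empty <- which(cnt == 0L)
        if (length(empty) == 0L) break
        own_sim <- sim[cbind(seq_len(n), new_labels)]
        own_sim[cnt[new_labels] <= 1L] <- Inf # do not empty another cluster
        victim <- which.min(own_sim)
        new_labels[victim] <- empty[1L]
      }
      obj <- sum(1 - sim[cbind(seq_len(n), new_labels)])
      trace <- c(trace, obj)
      converged <- identical(new_labels, labels)
      labels <- new_labels
      cent <- rowsum(xn, labels)
      cent <- cent / pmax(sqrt(rowSums(cent^2)), 1e-300)
      if (converged) break
    }
    sim <- xn %*% t(cent)
    obj <- sum(1 - sim[cbind(seq_len(n), labels)])
    if (is.null(best) || obj < best$obj - 1e-12) {
      best <- list(obj = obj, labels = labels, cent = cent, trace = trace)
    }
  }

  dimnames(best$cent) <- NULL
  roi <- attr(profiles, "roi_vertices") %||% seq_len(n)
  parc <- parcellation(best$labels, roi, k = k, level = "group",
                       provenance = sprintf("kmeans_cosine(k=%d, restarts=%d, seed=%d)",
                                            k, n_restarts, seed))
  structure(
    list(parcellation = parc, centroids = best$cent,
         aggregate_distance = best$obj, objective_trace = best$trace,
         k = k, seed = seed, n_restarts = n_restarts,
         flagged_vertices = zero_rows),
    class = "fc_group_atlas"
  )
}

#' @export
print.fc_group_atlas <- function(x, ...) {
  cat(sprintf("<fc_group_atlas> k=%d, aggregate distance %.4f (%d restarts)\n",
              x$k, x$aggregate_distance, x$n_restarts))
  invisible(x)
}

#' Mean silhouette width under cosine distance
#'
#' Per-vertex Rousseeuw silhouette with distance `1 - cosine similarity`:
#' `a` is the mean distance to the vertex's own cluster (excluding itself),
#' `b` the smallest mean distance to any other cluster, and
#' `s = (b - a) / max(a, b)`. Singleton clusters and exact `a = b = 0` ties
#' score 0. Returns the mean over vertices; per-vertex values are attached
#' as an attribute.
#'
#' @param profiles profile matrix (rows will be L2-normalized).
#' @param labels integer cluster labels, 1..k with k >= 2 and every cluster
#'   non-empty.
#' @return Mean silhouette in `[-1, 1]` with attribute `per_vertex`.
#' @export
silhouette_cosine <- function(profiles, labels) {
  x <- normalize_rows_l2(unclass(profiles))
  labels <- as.integer(labels)
  k <- max(labels)
  if (length(unique(labels)) < 2L) {
    fc_abort("silhouette undefined for a single cluster", "fcparc_parameter_error")
  }
  n <- nrow(x)
  d <- 1 - x %*% t(x) # cosine distance
  cnt <- tabulate(labels, k)
  # mean distance from each vertex to each cluster
  sums <- rowsum(t(d), labels)           # k x n: sum of distances to cluster
  means <- sums / cnt                    # naive mean including self for own cluster
  a <- numeric(n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    a[i] <- if (cnt[li] > 1L) (sums[li, i] - 0) / (cnt[li] - 1L) else NA_real_
    b[i] <- min(means[-li, i])
  }
  s <- ifelse(is.na(a) | pmax(a, b) < 1e-15, 0, (b - a) / pmax(a, b))
  structure(mean(s), per_vertex = s)
}

#' Match network labels between two parcellations
#'
#' Solves the label-permutation problem with a Hungarian (maximum-weight
#' bipartite) assignment on the vertex-overlap count matrix, and returns the
#' second parcellation relabeled into the first one's label space. Labels of
#' `parc_b` left unmatched (when it has more networks) keep fresh labels
#' above `parc_a$k`.
#'
#' @param parc_a,parc_b parcellations over the same ROI.
#' @return A list with `mapping` (for each label of `parc_b`, the assigned
#'   label of `parc_a`, `NA` if none) and `parcellation` (relabeled
#'   `parc_b`).
#' @export
match_labels <- function(parc_a, parc_b) {
  if (!same_roi(parc_a, parc_b)) {
    fc_abort("parcellations must cover the same ROI", "fcparc_validation_error")
  }
  ka <- parc_a$k
  kb <- parc_b$k
  ov <- table(factor(parc_a$labels, levels = seq_len(ka)),
              factor(parc_b$labels, levels = seq_len(kb)))
  el <- expand.grid(a = seq_len(ka), b = seq_len(kb))
  g <- igraph::graph_from_edgelist(
    cbind(sprintf("a%d", el$a), sprintf("b%d", el$b)), directed = FALSE
  )
  igraph::V(g)$type <- grepl("^b", igraph::V(g)$name)
  w <- as.numeric(ov)[(el$b - 1L) * ka + el$a] + 1e-9
  m <- igraph::max_bipartite_match(g, weights = w)
  mapping <- rep(NA_integer_, kb)
  for (bl in seq_len(kb)) {
    hit <- m$matching[[sprintf("b%d", bl)]]
    if (!is.na(hit)) mapping[bl] <- as.integer(sub("^a", "", hit))
  }
  un <- which(is.na(mapping))
  if (length(un) > 0) mapping[un] <- ka + seq_along(un)
  new_labels <- mapping[parc_b$labels]
  parc <- parcellation(new_labels, parc_b$roi_vertices, k = max(new_labels),
                       n_vertices_total = parc_b$n_vertices_total,
                       level = parc_b$level,
                       provenance = paste0(parc_b$provenance, " [labels matched]"))
  list(mapping = mapping, parcellation = parc)
}

#' Split-half reproducibility of the group atlas
#'
#' Splits every conditioned run in half in time (the first half keeps the
#' extra timepoint for odd lengths), concatenates first halves and last
#' halves separately, builds one group atlas from each, matches labels and
#' returns the network-mean Dice coefficient.
#'
#' @param subject_runs list (per subject) of lists of `fc_timeseries` runs.
#' @param mesh a [surface_mesh()].
#' @param k network count.
#' @param n_restarts,seed clustering parameters.
#' @param condition logical; band-pass the runs first (default TRUE).
#' @return Mean Dice with attributes `atlas_first`, `atlas_last`.
#' @export
split_half_dice <- function(subject_runs, mesh, k, n_restarts = 100, seed = 1,
                            condition = TRUE) {
  roi <- which(mesh$roi_mask)
  halves <- function(which_half) {
    prof <- lapply(subject_runs, function(runs) {
      parts <- lapply(runs, function(run) {
        if (ncol(run) < 20) {
          fc_abort("runs must have at least 20 timepoints to split",
                   "fcparc_parameter_error")
        }
        r <- if (condition) bandpass_filter(run) else run
        n <- ncol(r)
        cut <- ceiling(n / 2)
        idx <- if (which_half == 1L) seq_len(cut) else (cut + 1L):n
        rewrap_ts(unclass(r)[, idx, drop = FALSE], r)
      })
      connectivity_profiles(concat_runs(parts), roi)
    })
    average_profiles(prof)
  }
  atl1 <- kmeans_cosine(halves(1L), k, n_restarts, seed = derive_seed(seed, 1))
  atl2 <- kmeans_cosine(halves(2L), k, n_restarts, seed = derive_seed(seed, 2))
  matched <- match_labels(atl1$parcellation, atl2$parcellation)
  d <- dice_coefficient(atl1$parcellation, matched$parcellation, matched = TRUE)
  structure(glance(d)$mean_value, atlas_first = atl1, atlas_last = atl2)
}

#' Model-order table and selection
#'
#' `model_order_table()` assembles the per-K reproducibility (Dice) and
#' separation (silhouette) values and their product; `select_model_order()`
#' returns the K at strict interior local maxima of the product (endpoints
#' are never selected; ties across a plateau resolve to the smallest K).
#'
#' @param k_values,dice_values,silhouette_values aligned numeric vectors over
#'   the candidate network counts.
#' @return `model_order_table()`: a tibble with columns `k`, `dice`,
#'   `silhouette`, `product`, `selected`. `select_model_order()`: integer
#'   vector of selected K.
#' @export
model_order_table <- function(k_values, dice_values, silhouette_values) {
  if (length(k_values) < 3) {
    fc_abort("need at least 3 candidate model orders", "fcparc_parameter_error")
  }
  stopifnot(length(k_values) == length(dice_values),
            length(k_values) == length(silhouette_values))
  p <- dice_values * silhouette_values
  n <- length(p)
  selected <- logical(n)
  i <- 2L
  while (i <= n - 1L) {
    if (p[i] > p[i - 1L]) {
      j <- i
      while (j < n && p[j + 1L] == p[i]) j <- j + 1L # plateau scan
      if (j < n && p[j + 1L] < p[i]) selected[i] <- TRUE # smallest-K tie rule
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(k = k_values, dice = dice_values,
                 silhouette = silhouette_values, product = p,
                 selected = selected)
}

#' @rdname model_order_table
#' @export
select_model_order <- function(k_values, dice_values, silhouette_values) {
  tab <- model_order_table(k_values, dice_values, silhouette_values)
  tab$k[tab$selected]
}

#' Reassign spatially small clusters
#'
#' Finds per-label connected components on the ROI neighbor graph and, for
#' every component whose summed vertex area is `min_area_mm2` or smaller,
#' relabels each member to the most frequent label among its ROI neighbors.
#' Neighbor-count ties are broken by the Pearson correlation between the
#' vertex's connectivity profile and the mean profile of each tied network.
#' Passes repeat until no small component remains (or 100 passes).
#'
#' @param parc an [parcellation()].
#' @param mesh the [surface_mesh()].
#' @param min_area_mm2 area threshold (components of exactly this area are
#'   reassigned too).
#' @param profiles optional `fc_profiles` used for tie-breaking; without it,
#'   ties resolve to the smallest label with a warning.
#' @return The cleaned `fc_parcellation`.
#' @export
reassign_small_clusters <- function(parc, mesh, min_area_mm2 = 10,
                                    profiles = NULL) {
  roi <- parc$roi_vertices
  nv <- length(mesh$neighbors)
  pos <- integer(nv)
  pos[roi] <- seq_along(roi)
  labels <- parc$labels

  for (pass in seq_len(100)) {
    changed <- FALSE
    small_members <- integer(0)
    for (l in seq_len(parc$k)) {
      members <- roi[labels == l]
      if (length(members) == 0) next
      comp <- graph_components(mesh$neighbors, members)
      for (cid in unique(comp)) {
        cm <- members[comp == cid]
        if (sum(mesh$vertex_area[cm]) <= min_area_mm2) {
          if (length(cm) == length(roi)) {
            warning("ROI is a single small component; nothing to reassign")
          } else {
            small_members <- c(small_members, cm)
          }
        }
      }
    }
    if (length(small_members) == 0) break
    new_labels <- labels
    for (v in small_members) {
      nb <- mesh$neighbors[[v]]
      nb <- nb[pos[nb] > 0L]
      if (length(nb) == 0) next
      votes <- tabulate(labels[pos[nb]], parc$k)
      top <- which(votes == max(votes))
      pick <- if (length(top) == 1L) {
        top
      } else if (!is.null(profiles)) {
        prof_v <- unclass(profiles)[pos[v], ]
        cors <- vapply(top, function(l) {
          members <- which(labels == l)
          stats::cor(prof_v, colMeans(unclass(profiles)[members, , drop = FALSE]))
        }, numeric(1))
        top[which.max(cors)]
      } else {
        warning("neighbor-vote tie without profiles; taking the smallest label")
        top[1L]
      }
      if (pick != labels[pos[v]]) changed <- TRUE
      new_labels[pos[v]] <- pick
    }
    if (!changed) break
    labels <- new_labels
  }

  # an entirely absorbed small network leaves its label empty; ids are kept
  # so networks stay comparable with the input parcellation
  parcellation(labels, roi, k = parc$k,
               n_vertices_total = parc$n_vertices_total, level = parc$level,
               require_complete = FALSE,
               provenance = paste0(parc$provenance, " [small clusters reassigned]"))
}
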