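# Network-seeded whole-cortex connectivity: per-subject Fisher-z maps,
# one-sample group t-maps, permutation cluster-extent correction
# (sign-flipping), and paired contrasts between adjacent networks' maps.

#' Seed-based connectivity map
#'
#' The seed signal is the mean of the standardized member time courses of
#' the seed network; the map is the Fisher z-transformed Pearson correlation
#' between the seed signal and every cortex vertex (clipped, so seed members
#' take values near the atanh clip bound).
#'
#' @param ts conditioned `fc_timeseries` over all cortex vertices.
#' @param parc an [parcellation()].
#' @param seed_label network to use as seed.
#' @return Numeric per-vertex z vector with attribute `seed_label`.
#' @export
seed_map <- function(ts, parc, seed_label) {
  members <- parc$roi_vertices[parc$labels == seed_label]
  if (length(members) == 0) {
    fc_abort(sprintf("seed network %d is empty", seed_label),
             "fcparc_validation_error")
  }
  x <- unclass(ts)
  seed_sig <- colMeans(standardize_rows(x[members, , drop = FALSE]))
  sds <- apply(x, 1, stats::sd)
  r <- numeric(nrow(x))
  ok <- sds > 1e-12
  r[ok] <- as.numeric(stats::cor(seed_sig, t(x[ok, , drop = FALSE])))
  structure(fisher_z(r), seed_label = seed_label)
}

#' One-sample group t-map
#'
#' Per vertex, `t = mean / (sd / sqrt(n))` across subjects. Vertices with
#' zero across-subject sd are undefined and masked to `NA`.
#'
#' @param maps numeric matrix, subjects x vertices (Fisher-z values).
#' @return Numeric per-vertex t vector (NA where undefined).
#' @export
group_onesample <- function(maps) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 3) fc_abort("need at least 3 subjects", "fcparc_parameter_error")
  mu <- colMeans(maps)
  s <- sqrt(colSums((maps - rep(mu, each = n))^2) / (n - 1))
  t <- mu / (s / sqrt(n))
  t[s < 1e-15] <- NA_real_
  t
}

# max cluster extent (vertex count) among connected components of the
# supra-threshold set
max_cluster_extent <- function(tvals, neighbors, forming_threshold) {
  supra <- which(!is.na(tvals) & abs(tvals) > forming_threshold)
  if (length(supra) == 0) return(0L)
  comp <- graph_components(neighbors, supra)
  max(tabulate(comp))
}

#' Permutation cluster-extent correction
#'
#' Clusters are connected components of `|t| > forming_threshold` on the
#' mesh graph. The null distribution of the maximum cluster extent is built
#' by randomly sign-flipping the subject maps (valid for the symmetric
#' one-sample null); a cluster is significant when its add-one permutation
#' p-value is at or below `alpha`.
#'
#' @param maps subjects x vertices matrix of Fisher-z maps.
#' @param mesh a [surface_mesh()].
#' @param forming_threshold cluster-forming threshold on `|t|` (default 8).
#' @param n_perm number of sign-flip permutations (default 5000).
#' @param seed RNG seed.
#' @param alpha cluster-wise significance level.
#' @return An object of class `fc_clusters`: `t_map`, `clusters` tibble
#'   (`cluster`, `extent`, `peak_vertex`, `peak_t`, `p_value`,
#'   `significant`), `significant_mask` (per-vertex logical), `null_max_extent`.
#' @export
cluster_extent_correct <- function(maps, mesh, forming_threshold = 8,
                                   n_perm = 5000, seed = 1, alpha = 0.05) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  tvals <- group_onesample(maps)
  supra <- which(!is.na(tvals) & abs(tvals) > forming_threshold)
  nv <- ncol(maps)
  mask <- logical(nv)
  if (length(supra) == 0) {
    return(structure(
      list(t_map = tvals, clusters = tibble::tibble(
        cluster = integer(0), extent = integer(0), peak_vertex = integer(0),
        peak_t = numeric(0), p_value = numeric(0), significant = logical(0)),
        significant_mask = mask, null_max_extent = numeric(0)),
      class = "fc_clusters"
    ))
  }
  comp <- graph_components(mesh$neighbors, supra)

  set.seed(seed)
  ss <- colSums(maps^2) # invariant under sign flips
  null_max <- vapply(seq_len(n_perm), function(i) {
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    mu <- as.numeric(sgn %*% maps) / n
    s2 <- (ss - n * mu^2) / (n - 1)
    tp <- mu / sqrt(s2 / n)
    tp[s2 < 1e-30] <- NA_real_
    as.numeric(max_cluster_extent(tp, mesh$neighbors, forming_threshold))
  }, numeric(1))

  cl <- tibble::tibble(cluster = as.integer(unique(comp)))
  cl <- dplyr::mutate(cl, info = purrr::map(.data$cluster, function(cid) {
    verts <- supra[comp == cid]
    peak <- verts[which.max(abs(tvals[verts]))]
    ext <- length(verts)
    p <- (1 + sum(null_max >= ext)) / (1 + n_perm)
    tibble::tibble(extent = ext, peak_vertex = as.integer(peak),
                   peak_t = tvals[peak], p_value = p,
                   significant = p <= alpha)
  }))
  cl <- tidyr::unnest(cl, "info")
  for (cid in cl$cluster[cl$significant]) {
    mask[supra[comp == cid]] <- TRUE
  }
  structure(
    list(t_map = tvals, clusters = cl, significant_mask = mask,
         null_max_extent = null_max),
    class = "fc_clusters"
  )
}

#' @export
print.fc_clusters <- function(x, ...) {
  cat(sprintf("<fc_clusters> %d supra-threshold cluster(s), %d significant\n",
              nrow(x$clusters), sum(x$clusters$significant)))
  invisible(x)
}

#' @rdname tidy.fc_metric
#' @export
tidy.fc_clusters <- function(x, ...) x$clusters

# do the two networks share a mesh edge?
networks_adjacent <- function(parc, mesh, label_a, label_b) {
  full <- integer(length(mesh$neighbors))
  full[parc$roi_vertices] <- parc$labels
  va <- parc$roi_vertices[parc$labels == label_a]
  any(vapply(va, function(v) any(full[mesh$neighbors[[v]]] == label_b),
             logical(1)))
}

#' Vertex-wise contrast between seed maps of adjacent networks
#'
#' Per-vertex paired Wilcoxon signed-rank test between the two sets of
#' subject seed maps, Benjamini-Hochberg corrected across vertices and
#' thresholded at adjusted p < 0.05. The two networks must share a mesh
#' edge on the parcellation.
#'
#' @param maps_a,maps_b subjects x vertices matrices for the two seed
#'   networks (same subjects, same order).
#' @param parc the [parcellation()] defining the networks.
#' @param mesh the [surface_mesh()].
#' @param label_a,label_b the two network labels.
#' @param alpha significance threshold on adjusted p.
#' @return A tibble with columns `vertex`, `p`, `p_adjusted`, `significant`,
#'   `direction`.
#' @export
adjacent_map_difference <- function(maps_a, maps_b, parc, mesh,
                                    label_a, label_b, alpha = 0.05) {
  maps_a <- as.matrix(maps_a)
  maps_b <- as.matrix(maps_b)
  if (!all(dim(maps_a) == dim(maps_b))) {
    fc_abort("map sets must share dimensions", "fcparc_dimension_error")
  }
  if (!networks_adjacent(parc, mesh, label_a, label_b)) {
    fc_abort(sprintf("networks %d and %d are not adjacent on the mesh",
                     label_a, label_b), "fcparc_validation_error")
  }
  if (nrow(maps_a) < 6) {
    warning("fewer than 6 subjects: vertex-wise signed-rank tests are underpowered")
  }
  d <- maps_a - maps_b
  p <- vapply(seq_len(ncol(d)), function(v) {
    dv <- d[, v]
    if (all(dv == 0)) return(1)
    suppressWarnings(stats::wilcox.test(dv)$p.value)
  }, numeric(1))
  adj <- bh_adjust(p, alpha)
  tibble::tibble(
    vertex = seq_len(ncol(d)), p = p, p_adjusted = adj$p_adjusted,
    significant = adj$reject,
    direction = dplyr::case_when(
      colMeans(d) > 0 ~ "a_greater",
      colMeans(d) < 0 ~ "b_greater",
      TRUE ~ "none"
    )
  )
}
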