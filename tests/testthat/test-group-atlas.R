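test_that("profile averaging is an element-wise mean preserving masked self entries", {
  set.seed(1)
  mk <- function(shift) {
    x <- matrix(rnorm(4 * 40), 4, 40)
    ts <- timeseries_matrix(x + shift, 2)
    connectivity_profiles(ts, roi_vertices = 1:2)
  }
  a <- mk(0)
  b <- mk(0.5)
  avg <- average_profiles(list(a, b))
  expect_equal(unclass(avg)[, ], (unclass(a)[, ] + unclass(b)[, ]) / 2)
  expect_identical(avg[1, 1], 0)
  expect_equal(unclass(average_profiles(list(a, a)))[, ], unclass(a)[, ])
  # order invariance
  expect_equal(unclass(average_profiles(list(b, a)))[, ], unclass(avg)[, ],
               tolerance = 1e-12)
})

test_that("spherical k-means recovers orthogonal structure exactly", {
  # 3 mutually orthogonal directions, duplicated -> exact pair partition
  base <- diag(3)
  x <- base[rep(1:3, each = 2), ]
  fit <- kmeans_cosine(x, 3, n_restarts = 20, seed = 1)
  expect_equal(fit$aggregate_distance, 0, tolerance = 1e-12)
  labs <- fit$parcellation$labels
  expect_equal(labs[c(1, 3, 5)], labs[c(2, 4, 6)])
  expect_equal(length(unique(labs)), 3)
  expect_equal(sqrt(rowSums(fit$centroids^2)), rep(1, 3), tolerance = 1e-10)
})

test_that("k-means finds the optimum found by exhaustive partition search (k=2, n=8)", {
  set.seed(7)
  x <- rbind(matrix(rnorm(4 * 6, mean = 3), 4, 6),
             matrix(rnorm(4 * 6, mean = -3), 4, 6))
  xn <- x / sqrt(rowSums(x^2))
  # brute force over all 2^8 assignments
  best_obj <- Inf
  best_assign <- NULL
  for (code in 0:(2^8 - 1)) {
    assign <- as.integer(intToBits(code))[1:8] + 1L
    if (length(unique(assign)) < 2) next
    cent <- rowsum(xn, assign)
    cent <- cent / sqrt(rowSums(cent^2))
    obj <- sum(1 - rowSums(xn * cent[assign, ]))
    if (obj < best_obj) {
      best_obj <- obj
      best_assign <- assign
    }
  }
  fit <- kmeans_cosine(x, 2, n_restarts = 50, seed = 3)
  expect_equal(fit$aggregate_distance, best_obj, tolerance = 1e-10)
  agree <- mean(fit$parcellation$labels == best_assign)
  expect_true(agree %in% c(0, 1)) # identical up to label swap
})

test_that("k-means is deterministic under a fixed seed and its objective never increases", {
  set.seed(8)
  x <- matrix(rnorm(30 * 12), 30, 12)
  f1 <- kmeans_cosine(x, 3, n_restarts = 25, seed = 42)
  f2 <- kmeans_cosine(x, 3, n_restarts = 25, seed = 42)
  expect_identical(f1$parcellation$labels, f2$parcellation$labels)
  expect_identical(f1$aggregate_distance, f2$aggregate_distance)
  expect_true(all(diff(f1$objective_trace) <= 1e-10))
})

test_that("cosine silhouette matches the naive double-loop oracle", {
  set.seed(9)
  for (rep in 1:5) {
    x <- matrix(rnorm(7 * 5), 7, 5)
    labels <- c(1, 1, 2, 2, 3, 3, sample(1:3, 1))
    s <- silhouette_cosine(x, labels)
    expect_equal(as.numeric(s), oracle_silhouette(x, labels), tolerance = 1e-12)
  }

  # two tight orthogonal clusters separate cleanly
  tight <- rbind(matrix(rep(c(1, 0), each = 5), 5) + matrix(rnorm(10, sd = 0.01), 5),
                 matrix(rep(c(0, 1), each = 5), 5) + matrix(rnorm(10, sd = 0.01), 5))
  s2 <- silhouette_cosine(tight, rep(1:2, each = 5))
  expect_gt(as.numeric(s2), 0.9)

  # all points identical across 2 clusters: a = b = 0 -> s = 0 by the tie rule
  same <- matrix(1, 6, 3)
  expect_equal(as.numeric(silhouette_cosine(same, rep(1:2, 3))), 0)

  expect_error(silhouette_cosine(tight, rep(1, 10)),
               class = "fcparc_parameter_error")
})

test_that("label matching recovers permutations and agrees with brute force", {
  roi <- 1:10
  a <- parcellation(c(1, 1, 1, 2, 2, 2, 3, 3, 3, 1), roi, n_vertices_total = 10)
  perm <- c(3L, 1L, 2L) # 1->3, 2->1, 3->2
  b <- parcellation(perm[a$labels], roi, n_vertices_total = 10)
  m <- match_labels(a, b)
  expect_identical(m$parcellation$labels, a$labels)
  expect_equal(glance(dice_coefficient(a, m$parcellation))$mean_value, 1)

  ident <- match_labels(a, a)
  expect_identical(ident$mapping, 1:3)

  set.seed(10)
  for (rep in 1:20) {
    la <- c(1:3, sample(1:3, 7, replace = TRUE))
    lb <- c(1:3, sample(1:3, 7, replace = TRUE))
    pa <- parcellation(la, roi, n_vertices_total = 10)
    pb <- parcellation(lb, roi, n_vertices_total = 10)
    got <- match_labels(pa, pb)
    ov_got <- sum(pa$labels == got$parcellation$labels)
    expect_equal(ov_got, oracle_match(la, lb, 3)$overlap)
  }
})

test_that("model-order selection keeps strict interior local maxima with the smaller-K tie rule", {
  expect_identical(select_model_order(2:6, c(.5, .7, .6, .8, .4), rep(1, 5)),
                   c(3L, 5L))
  expect_identical(select_model_order(2:6, seq(.1, .5, .1), rep(1, 5)),
                   integer(0))
  expect_identical(select_model_order(2:5, c(.5, .7, .7, .4), rep(1, 4)), 3L)
  # endpoints never selected even when largest
  expect_identical(select_model_order(2:4, c(.9, .5, .95), rep(1, 3)),
                   integer(0))
  expect_error(model_order_table(2:3, c(.1, .2), c(1, 1)),
               class = "fcparc_parameter_error")
  tab <- model_order_table(2:6, c(.5, .7, .6, .8, .4), c(1, 1, 1, 1, 1))
  expect_identical(tab$product, tab$dice * tab$silhouette)
})

test_that("small spatial clusters are reassigned by neighbor vote with profile tie-break", {
  mesh <- small_mesh()
  roi <- which(mesh$roi_mask)
  tpl <- make_group_template(mesh, 3, seed = 5)

  # plant a singleton of network 2 inside network 1 territory
  labels <- tpl$labels
  interior <- which(vapply(seq_along(roi), function(i) {
    nb <- mesh$neighbors[[roi[i]]]
    nb_in <- nb[nb %in% roi]
    length(nb_in) >= 5 && all(tpl$labels[match(nb_in, roi)] == 1) &&
      labels[i] == 1
  }, logical(1)))
  v <- interior[1]
  labels[v] <- 2L
  parc <- parcellation(labels, roi, n_vertices_total = tpl$n_vertices_total)
  area <- mesh$vertex_area[roi[v]]
  cleaned <- reassign_small_clusters(parc, mesh, min_area_mm2 = area + 1)
  expect_identical(cleaned$labels[v], 1L)
  # threshold is inclusive: a component of exactly the threshold area moves
  cleaned_eq <- reassign_small_clusters(parc, mesh, min_area_mm2 = area)
  expect_identical(cleaned_eq$labels[v], 1L)
  # below the component's area nothing changes
  cleaned_no <- reassign_small_clusters(parc, mesh, min_area_mm2 = area / 2)
  expect_identical(cleaned_no$labels[v], 2L)
  # never invents labels, never empties the largest network
  expect_true(all(cleaned$labels %in% 1:3))
  big <- which.max(tabulate(parc$labels, 3))
  expect_gt(sum(cleaned$labels == big), 0)
})

test_that("neighbor-vote ties are resolved by profile correlation", {
  # hand-built 9-vertex graph: vertex 1 has 6 neighbors, 3 of network 2 and
  # 3 of network 3 (tie); its profile matches network 3's mean. The outer
  # vertices 8 and 9 bulk up networks 2 and 3 so only the singleton is small.
  coords <- rbind(c(0, 0, 1), c(1, 0, 1), c(0.5, 0.87, 1), c(-0.5, 0.87, 1),
                  c(-1, 0, 1), c(-0.5, -0.87, 1), c(0.5, -0.87, 1),
                  c(3, 3, 1), c(-3, -3, 1))
  tri <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 6), c(1, 6, 7),
               c(1, 7, 2), c(2, 8, 3), c(5, 9, 6))
  mesh <- surface_mesh(coords, tri)
  labels <- c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 2L, 3L)
  parc <- parcellation(labels, 1:9)
  prof <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 1, 0, 0), c(0, 1, 0.2, 0),
                c(1, 0, 0.1, 0), c(0.9, 0, 0, 0.1), c(1, 0.05, 0, 0),
                c(0, 1, 0, 0.3), c(1, 0, 0.05, 0))
  small_area <- mesh$vertex_area[1]
  out <- reassign_small_clusters(parc, mesh, min_area_mm2 = small_area + 0.1,
                                 profiles = prof)
  expect_identical(out$labels[1], 3L) # profile matches network 3, not 2
})

test_that("split-half atlases agree perfectly on noise-free cohorts", {
  # jitter 0: all subjects share the template, so both halves carry identical
  # cluster structure and must reproduce it exactly
  spec <- cohort_spec(n_subjects = 2, mesh_subdivisions = 2,
                      timepoints_per_run = 80, snr = Inf, boundary_jitter = 0,
                      seed = 21)
  co <- simulate_cohort(spec)
  runs <- lapply(co$runs, function(bysess) unlist(bysess, recursive = FALSE))
  d <- split_half_dice(runs, co$mesh, k = 4, n_restarts = 30, seed = 2)
  expect_equal(as.numeric(d), 1)
  expect_error(
    split_half_dice(list(list(toy_ts(matrix(rnorm(20), 2, 10)))), co$mesh, 2),
    class = "fcparc_parameter_error"
  )
})
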