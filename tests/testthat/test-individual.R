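test_that("reference signal arithmetic matches a hand oracle and flags degenerate cases", {
  std <- function(v) (v - mean(v)) / sd(v)
  x <- rbind(c(1, 2, 3, 4), c(1, 5, 2, 8), c(5, 4, 3, 2))
  ts <- toy_ts(x)
  parc <- parcellation(c(1L, 1L, 2L), 1:3, k = 2, n_vertices_total = 3)
  refs <- compute_reference_signals(ts, parc)
  oracle1 <- std((std(x[1, ]) + std(x[2, ])) / 2)
  expect_equal(refs[1, ], oracle1, tolerance = 1e-12)
  expect_equal(refs[2, ], std(x[3, ]), tolerance = 1e-12)

  # identical courses in one network: reference equals the standardized course
  x2 <- rbind(c(1, 3, 2, 5), c(2, 6, 4, 10), c(0, 1, 0, 1))
  parc2 <- parcellation(c(1L, 1L, 2L), 1:3, k = 2, n_vertices_total = 3)
  refs2 <- compute_reference_signals(toy_ts(x2), parc2)
  expect_equal(refs2[1, ], std(x2[1, ]), tolerance = 1e-12)

  # anti-phase courses cancel -> degenerate reference is an error
  t <- seq(0, 2 * pi, length.out = 20)
  x3 <- rbind(sin(t), -sin(t), cos(t))
  parc3 <- parcellation(c(1L, 1L, 2L), 1:3, k = 2, n_vertices_total = 3)
  expect_error(compute_reference_signals(toy_ts(x3), parc3),
               class = "fcparc_validation_error")

  # an empty network at initialization names the label
  parc4 <- parcellation(c(1L, 1L, 3L), 1:3, k = 3, n_vertices_total = 3,
                        require_complete = FALSE)
  expect_error(compute_reference_signals(toy_ts(x), parc4), "network 2")
})

test_that("correlation assignment and the confidence ratio follow the flooring rules", {
  # build references and a vertex whose correlations with them are known
  set.seed(2)
  n <- 60
  r1 <- rnorm(n)
  r2 <- rnorm(n)
  make_target <- function(c1, c2) {
    # construct signal with prescribed correlations to orthogonalized refs
    q <- qr.Q(qr(cbind(r1, r2)))
    resid <- rnorm(n)
    resid <- resid - q %*% (t(q) %*% resid)
    v <- c1 * q[, 1] + c2 * q[, 2] +
      sqrt(max(0, 1 - c1^2 - c2^2)) * resid / sqrt(sum(resid^2))
    as.numeric(v)
  }
  refs <- structure(rbind((q1 <- qr.Q(qr(cbind(r1, r2)))[, 1]),
                          qr.Q(qr(cbind(r1, r2)))[, 2]),
                    class = c("fc_reference", "matrix", "array"))
  refs <- structure(fcparc:::standardize_rows(unclass(refs)),
                    class = c("fc_reference", "matrix", "array"))

  v_clear <- make_target(0.9, 0.3)
  ts <- toy_ts(rbind(v_clear, v_clear))
  asg <- assign_by_correlation(ts, refs, roi_vertices = 1:2)
  expect_identical(asg$labels, c(1L, 1L))
  r_obs <- cor(v_clear, t(unclass(refs)))
  expect_equal(asg$confidence$confidence[1], max(r_obs) / sort(r_obs, decreasing = TRUE)[2],
               tolerance = 1e-10)

  # negative runner-up: divisor floored at 1e-6
  v_neg <- make_target(0.4, -0.3)
  asg2 <- assign_by_correlation(toy_ts(rbind(v_neg, v_neg)), refs, 1:2)
  r2_obs <- cor(v_neg, t(unclass(refs)))
  expect_equal(asg2$confidence$confidence[1], max(r2_obs) / 1e-6,
               tolerance = 1e-6)

  # exact tie takes the lowest label with confidence 1
  refs_tie <- structure(rbind(refs[1, ], refs[1, ]),
                        class = c("fc_reference", "matrix", "array"))
  asg3 <- assign_by_correlation(toy_ts(rbind(v_clear, v_clear)), refs_tie, 1:2)
  expect_identical(asg3$labels, c(1L, 1L))
  expect_equal(asg3$confidence$confidence, c(1, 1))

  # zero-variance vertex: label 1, confidence 1, flagged
  ts0 <- toy_ts(rbind(rep(0, n), v_clear))
  asg4 <- assign_by_correlation(ts0, refs, 1:2)
  expect_identical(asg4$labels[1], 1L)
  expect_equal(asg4$confidence$confidence[1], 1)
  expect_true(asg4$confidence$flagged[1])

  # confidence is always >= 1
  expect_true(all(asg$confidence$confidence >= 1))
  expect_true(all(asg2$confidence$confidence >= 1))
})

test_that("high-confidence signals respect the strict threshold and fall back to references", {
  set.seed(3)
  n <- 40
  x <- matrix(rnorm(4 * n), 4, n)
  ts <- toy_ts(x)
  parc <- parcellation(c(1L, 1L, 2L, 2L), 1:4, k = 2, n_vertices_total = 4)
  refs <- compute_reference_signals(ts, parc)
  labels <- parc$labels

  # all confidences above threshold: equals reference recomputation
  hc_all <- high_confidence_signal(ts, labels, rep(2, 4), refs, 1:4)
  expect_equal(hc_all, unclass(compute_reference_signals(ts, parc)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # none above: every network falls back to the current reference
  hc_none <- high_confidence_signal(ts, labels, rep(1, 4), refs, 1:4)
  expect_equal(hc_none, unclass(refs), ignore_attr = TRUE)

  # exactly at the threshold is excluded ("exceeded" is strict)
  hc_eq <- high_confidence_signal(ts, labels, rep(1.3, 4), refs, 1:4)
  expect_equal(hc_eq, unclass(refs), ignore_attr = TRUE)
})

test_that("individualization recovers ground truth on noise-free subjects", {
  co <- small_cohort()
  spec_nf <- cohort_spec(n_subjects = 1, mesh_subdivisions = 2,
                         timepoints_per_run = 100, snr = Inf, seed = 31)
  ts <- condition_runs(list(
    simulate_session(co$truths[[1]], co$mesh, co$nonroi_template, spec_nf,
                     seed = 77)
  ))
  fit <- individualize(ts, co$template)
  expect_equal(glance(dice_coefficient(co$truths[[1]], fit$parcellation))$mean_value, 1)
  expect_equal(nrow(fit$trace), 10)
  expect_equal(fit$trace$dice_vs_previous[10], 1)
})

test_that("data generated from the group parcellation is a fixed point", {
  co <- small_cohort()
  spec_nf <- cohort_spec(n_subjects = 1, mesh_subdivisions = 2,
                         timepoints_per_run = 100, snr = Inf, seed = 32)
  ts <- condition_runs(list(
    simulate_session(co$template, co$mesh, co$nonroi_template, spec_nf,
                     seed = 78)
  ))
  fit <- individualize(ts, co$template)
  expect_identical(fit$parcellation$labels, co$template$labels)
})

test_that("an infinite threshold freezes the references at the iteration-1 assignment", {
  co <- small_cohort()
  ts <- condition_runs(unlist(co$runs[[1]], recursive = FALSE))
  fit_inf <- individualize(ts, co$template, n_iter = 6, threshold = Inf)
  refs0 <- compute_reference_signals(ts, co$template)
  one_step <- assign_by_correlation(ts, refs0, co$template$roi_vertices)
  expect_identical(fit_inf$parcellation$labels, one_step$labels)
  # labels stop changing after iteration 1
  expect_true(all(fit_inf$trace$dice_vs_previous[-1] == 1))
})

test_that("only ROI vertices are reassigned and both reference-update variants run", {
  co <- small_cohort()
  ts <- condition_runs(unlist(co$runs[[2]], recursive = FALSE))
  fit_cur <- individualize(ts, co$template, ref_update = "current")
  fit_orig <- individualize(ts, co$template, ref_update = "original")
  expect_identical(fit_cur$parcellation$roi_vertices, co$template$roi_vertices)
  expect_identical(fit_orig$parcellation$roi_vertices, co$template$roi_vertices)
  expect_s3_class(fit_cur$confidence, "tbl_df")
  expect_error(individualize(ts, co$template, n_iter = 0),
               class = "fcparc_parameter_error")
})
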