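rand_parc <- function(n, k, seed) {
  set.seed(seed)
  labs <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
  parcellation(labs, seq_len(n), n_vertices_total = n)
}

test_that("Dice matches its printed formula, the counting oracle, and is symmetric", {
  a <- rand_parc(12, 3, 1)
  ident <- dice_coefficient(a, a)
  expect_true(all(tidy(ident)$value == 1))
  expect_equal(glance(ident)$mean_value, 1)

  # V1=10, V2=10, overlap=5 -> 0.5
  p1 <- parcellation(rep(c(1L, 2L), each = 10), 1:20, n_vertices_total = 20)
  p2 <- parcellation(c(rep(1L, 5), rep(2L, 10), rep(1L, 5)), 1:20,
                     n_vertices_total = 20)
  d <- dice_coefficient(p1, p2)
  expect_equal(tidy(d)$value[1], 2 * 5 / (10 + 10))

  for (rep in 1:25) {
    pa <- rand_parc(12, 3, rep)
    pb <- rand_parc(12, 3, rep + 100)
    got <- dice_coefficient(pa, pb)
    orc <- oracle_dice(pa$labels, pb$labels, 3)
    expect_identical(tidy(got)$value, orc$per_network)
    expect_identical(glance(got)$mean_value, orc$mean)
    # symmetry is exact
    expect_identical(glance(dice_coefficient(pb, pa))$mean_value,
                     glance(got)$mean_value)
  }
})

test_that("functional inhomogeneity follows the size-weighted sd formula", {
  # networks {1,1} and {0,2}: (0*2 + sqrt(2)*2)/4
  parc <- parcellation(c(1L, 1L, 2L, 2L), 1:4, n_vertices_total = 4)
  zm <- task_zmap(c(1, 1, 0, 2), 1:4)
  got <- glance(functional_inhomogeneity(zm, parc))$mean_value
  expect_equal(got, (0 * 2 + sqrt(2) * 2) / 4, tolerance = 1e-12)
  expect_equal(got, 0.70711, tolerance = 1e-5)

  # constant z within every network -> 0
  zm0 <- task_zmap(c(3, 3, -1, -1), 1:4)
  expect_equal(glance(functional_inhomogeneity(zm0, parc))$mean_value, 0)

  # random toys vs direct oracle
  for (rep in 1:20) {
    set.seed(rep)
    parc3 <- rand_parc(10, 3, rep + 7)
    zm3 <- task_zmap(rnorm(10), 1:10)
    expect_equal(suppressWarnings(
      glance(functional_inhomogeneity(zm3, parc3))$mean_value),
      oracle_inhomogeneity(zm3$z, parc3$labels), tolerance = 1e-12)
  }
  # merging two differently-activated (network-constant) networks always
  # increases the value: within-network spread appears where there was none
  for (rep in 1:10) {
    set.seed(rep + 50)
    parc3 <- rand_parc(10, 3, rep + 70)
    levels <- sample(seq(-3, 3), 3)
    zc <- task_zmap(levels[parc3$labels], 1:10)
    expect_equal(suppressWarnings(
      glance(functional_inhomogeneity(zc, parc3))$mean_value), 0)
    merged <- parcellation(pmin(parc3$labels, 2L), 1:10, n_vertices_total = 10)
    expect_gt(suppressWarnings(
      glance(functional_inhomogeneity(zc, merged))$mean_value), 0)
  }

  # single-vertex networks contribute sd 0 with a warning
  p1v <- parcellation(c(1L, 2L, 2L), 1:3, n_vertices_total = 3)
  expect_warning(functional_inhomogeneity(task_zmap(c(1, 0, 2), 1:3), p1v),
                 "single-vertex")
})

test_that("connectional homogeneity equals the size-weighted mean pairwise Fisher z", {
  # 2-vertex network with r = 0.5 -> atanh(0.5)
  set.seed(5)
  n <- 400
  a <- rnorm(n)
  make_r <- function(target, base) {
    e <- rnorm(n)
    e <- e - base * sum(e * base) / sum(base^2)
    v <- target * base / sd(base) + sqrt(1 - target^2) * e / sd(e)
    v
  }
  # exact r = 0.5 pair via construction on small vectors
  x <- rbind(c(1, 0, 1, 0, 1, 0), c(1, 0, 0.5, 0.5, 1, 0))
  r_actual <- cor(x[1, ], x[2, ])
  parc2 <- parcellation(c(1L, 1L), 1:2, k = 1, n_vertices_total = 2,
                        require_complete = TRUE)
  got <- glance(connectional_homogeneity(toy_ts(x), parc2))$mean_value
  expect_equal(got, atanh(r_actual), tolerance = 1e-12)

  # weighted combination of two 2-vertex networks matches hand arithmetic
  y <- rbind(x, matrix(rnorm(12), 2, 6))
  parc4 <- parcellation(c(1L, 1L, 2L, 2L), 1:4, n_vertices_total = 4)
  r2 <- cor(y[3, ], y[4, ])
  expect_equal(glance(connectional_homogeneity(toy_ts(y), parc4))$mean_value,
               (atanh(r_actual) * 2 + atanh(r2) * 2) / 4, tolerance = 1e-12)

  # 5-vertex toys against the double-loop oracle
  for (rep in 1:10) {
    set.seed(rep)
    x5 <- matrix(rnorm(5 * 12), 5, 12)
    labs <- c(1L, 1L, 2L, 2L, sample(1:2, 1))
    parc5 <- parcellation(labs, 1:5, n_vertices_total = 5)
    expect_equal(glance(connectional_homogeneity(toy_ts(x5), parc5))$mean_value,
                 oracle_homogeneity(x5, labs), tolerance = 1e-12)
  }

  # networks with < 2 vertices are excluded with a warning
  p1v <- parcellation(c(1L, 2L, 2L), 1:3, n_vertices_total = 3)
  expect_warning(connectional_homogeneity(toy_ts(matrix(rnorm(18), 3, 6)), p1v),
                 "excluded")
})

test_that("the generating parcellation maximizes connectional homogeneity on noise-free data", {
  co <- small_cohort()
  spec_nf <- cohort_spec(n_subjects = 1, mesh_subdivisions = 2,
                         timepoints_per_run = 100, snr = Inf, seed = 41)
  ts <- simulate_session(co$truths[[1]], co$mesh, co$nonroi_template, spec_nf,
                         seed = 91)
  truth <- co$truths[[1]]
  h_true <- glance(connectional_homogeneity(ts, truth))$mean_value
  set.seed(1)
  for (rep in 1:5) {
    shuffled <- parcellation(sample(truth$labels), truth$roi_vertices,
                             n_vertices_total = truth$n_vertices_total)
    expect_gt(h_true, glance(connectional_homogeneity(ts, shuffled))$mean_value)
  }
})

test_that("percent effect divides network sums by the total and conserves 100%", {
  parc <- parcellation(c(1L, 1L, 2L, 3L, 4L), 1:5, n_vertices_total = 5)
  eff <- c(2, 1, 1, 0, 0)
  got <- percent_effect(eff, parc)
  expect_equal(tidy(got)$value, c(75, 25, 0, 0))

  single <- percent_effect(c(0, 0, 5, 0, 0), parc)
  expect_equal(tidy(single)$value[2], 100)

  for (rep in 1:10) {
    set.seed(rep)
    e <- rnorm(5)
    if (abs(sum(e)) < 1e-6) next
    expect_equal(sum(tidy(suppressMessages(percent_effect(e, parc)))$value),
                 100, tolerance = 1e-9)
  }
  expect_error(percent_effect(c(1, -1, 0, 0, 0), parc),
               class = "fcparc_domain_error")
})

test_that("variability summary reproduces hand-computed intra/inter Dice", {
  mk <- function(labs) parcellation(labs, 1:6, k = 2, n_vertices_total = 6)
  # 2 subjects x 2 sessions with hand-set labels
  s1a <- mk(c(1, 1, 1, 2, 2, 2))
  s1b <- mk(c(1, 1, 2, 2, 2, 2))
  s2a <- mk(c(2, 2, 2, 1, 1, 1))
  s2b <- mk(c(2, 2, 2, 1, 1, 1))
  vs <- variability_summary(list(s1 = list(s1a, s1b), s2 = list(s2a, s2b)))

  hand_dice <- function(a, b) {
    mean(c(2 * sum(a$labels == 1 & b$labels == 1) /
             (sum(a$labels == 1) + sum(b$labels == 1)),
           2 * sum(a$labels == 2 & b$labels == 2) /
             (sum(a$labels == 2) + sum(b$labels == 2))))
  }
  expect_equal(vs$by_subject$intra,
               c(hand_dice(s1a, s1b), hand_dice(s2a, s2b)))
  inter1 <- mean(c(hand_dice(s1a, s2a), hand_dice(s1a, s2b),
                   hand_dice(s1b, s2a), hand_dice(s1b, s2b)))
  expect_equal(vs$by_subject$inter, rep(inter1, 2))
  expect_equal(unname(vs$similarity$values[1, 2]), inter1)

  # identical parcellations everywhere -> intra = inter = 1
  vs1 <- variability_summary(list(a = list(s1a, s1a), b = list(s1a, s1a)))
  expect_equal(vs1$by_subject$intra, c(1, 1))
  expect_equal(vs1$by_subject$inter, c(1, 1))
})

test_that("synthetic cohorts show higher intra- than inter-subject reproducibility", {
  co <- small_cohort()
  atlas_parc <- co$template
  tab <- tibble::tibble(
    subject = rep(sprintf("s%d", 1:3), each = 2),
    session = rep(c("1", "2"), 3),
    parcellation = unlist(lapply(1:3, function(s) {
      lapply(1:2, function(ses) {
        ts <- condition_runs(co$runs[[s]][[ses]])
        individualize(ts, atlas_parc)$parcellation
      })
    }), recursive = FALSE)
  )
  vs <- variability_summary(tab)
  expect_gt(mean(vs$by_subject$intra), mean(vs$by_subject$inter))
})
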