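# Permutation and multiple-comparison machinery: Mantel test between
# subject similarity matrices, Benjamini-Hochberg step-up, and
# Friedman/Wilcoxon paired condition comparisons.

#' Mantel permutation test between two similarity matrices
#'
#' The observed statistic is the Spearman correlation between the upper
#' triangles (diagonal excluded). The null distribution jointly permutes
#' rows and columns of the first matrix by a random subject relabeling and
#' recomputes the statistic; the two-sided p-value uses the add-one
#' convention `(1 + #(|null| >= |obs|)) / (1 + n_perm)`.
#'
#' @param mat_a,mat_b [similarity_matrix()] objects (or plain symmetric
#'   matrices) over the same subjects in the same order.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return An object of class `fc_permutation` with `observed_stat`,
#'   `null_stats`, `p_value`, `n_perm`, `seed`.
#' @export
mantel_test <- function(mat_a, mat_b, n_perm = 10000, seed = 1) {
  a <- if (inherits(mat_a, "fc_similarity")) mat_a$values else as.matrix(mat_a)
  b <- if (inherits(mat_b, "fc_similarity")) mat_b$values else as.matrix(mat_b)
  if (!all(dim(a) == dim(b))) {
    fc_abort("similarity matrices must share dimensions", "fcparc_dimension_error")
  }
  n <- nrow(a)
  if (n < 4) fc_abort("need at least 4 subjects", "fcparc_parameter_error")
  ut <- upper.tri(a)
  if (stats::sd(a[ut]) < 1e-15 || stats::sd(b[ut]) < 1e-15) {
    fc_abort("constant upper triangle; correlation undefined",
             "fcparc_domain_error")
  }
  obs <- stats::cor(a[ut], b[ut], method = "spearman")
  set.seed(seed)
  b_ut <- b[ut]
  null_stats <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(a[p, p][ut], b_ut, method = "spearman")
  }, numeric(1))
  p_value <- (1 + sum(abs(null_stats) >= abs(obs))) / (1 + n_perm)
  structure(
    list(observed_stat = obs, null_stats = null_stats, p_value = p_value,
         n_perm = n_perm, seed = seed, statistic_name = "spearman_upper_triangle"),
    class = "fc_permutation"
  )
}

#' @export
print.fc_permutation <- function(x, ...) {
  cat(sprintf("<fc_permutation> observed %s = %.4f, p = %.4g (%d permutations)\n",
              x$statistic_name, x$observed_stat, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname tidy.fc_metric
#' @export
glance.fc_permutation <- function(x, ...) {
  tibble::tibble(statistic = x$observed_stat, p_value = x$p_value,
                 n_perm = x$n_perm, seed = x$seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control (via [stats::p.adjust()]),
#' returned in the original order together with rejection flags.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return A tibble with columns `p`, `p_adjusted`, `reject`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    fc_abort("p-values must lie in [0, 1]", "fcparc_domain_error")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, p_adjusted = adj, reject = adj <= alpha)
}

#' Paired comparison of conditions across subjects
#'
#' Friedman omnibus test followed by all pairwise Wilcoxon signed-rank
#' tests, BH-adjusted, with the direction of each difference.
#'
#' @param conditions numeric matrix or data frame, subjects x conditions
#'   (no missing cells), or a tibble with columns `subject`, `condition`,
#'   `value`.
#' @param alpha FDR level for the pairwise flags.
#' @return An object of class `fc_paired`: `friedman` one-row tibble
#'   (`statistic`, `df`, `p_value`) and `pairwise` tibble (`condition_a`,
#'   `condition_b`, `statistic`, `p`, `p_adjusted`, `reject`, `larger`).
#' @export
paired_compare <- function(conditions, alpha = 0.05) {
  if (tibble::is_tibble(conditions) &&
      all(c("subject", "condition", "value") %in% names(conditions))) {
    conditions <- tidyr::pivot_wider(conditions, names_from = "condition",
                                     values_from = "value")
    conditions <- as.data.frame(conditions[, -1, drop = FALSE])
  }
  m <- as.matrix(conditions)
  if (ncol(m) < 2) fc_abort("need at least 2 conditions", "fcparc_parameter_error")
  if (nrow(m) < 6) fc_abort("need at least 6 subjects", "fcparc_parameter_error")
  if (anyNA(m)) fc_abort("no missing cells allowed", "fcparc_validation_error")
  cn <- colnames(m) %||% paste0("condition_", seq_len(ncol(m)))
  colnames(m) <- cn
  fr <- stats::friedman.test(m)
  if (!is.finite(fr$statistic)) {
    # all ranks tie in every row (identical conditions): no evidence at all
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  pairs <- utils::combn(ncol(m), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    d <- m[, i1] - m[, i2]
    n_ties <- sum(d == 0)
    if (n_ties > 0) {
      message(sprintf("%d zero difference(s) excluded for %s vs %s",
                      n_ties, cn[i1], cn[i2]))
    }
    wt <- suppressWarnings(stats::wilcox.test(m[, i1], m[, i2], paired = TRUE))
    tibble::tibble(
      condition_a = cn[i1], condition_b = cn[i2],
      statistic = unname(wt$statistic), p = wt$p.value,
      larger = dplyr::case_when(
        stats::median(d) > 0 ~ cn[i1],
        stats::median(d) < 0 ~ cn[i2],
        TRUE ~ NA_character_
      )
    )
  })
  adj <- bh_adjust(pw$p, alpha)
  pw$p_adjusted <- adj$p_adjusted
  pw$reject <- adj$reject
  structure(
    list(
      friedman = tibble::tibble(statistic = unname(fr$statistic),
                                df = unname(fr$parameter),
                                p_value = fr$p.value),
      pairwise = pw
    ),
    class = "fc_paired"
  )
}

#' @export
print.fc_paired <- function(x, ...) {
  cat(sprintf("<fc_paired> Friedman chi-squared %.3f (df %d), p = %.4g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @rdname tidy.fc_metric
#' @export
tidy.fc_paired <- function(x, ...) x$pairwise

#' @rdname tidy.fc_metric
#' @export
glance.fc_paired <- function(x, ...) x$friedman
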