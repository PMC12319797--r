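# Quantitative evaluation of parcellations: overlap (Dice), task alignment
# (functional inhomogeneity, percent effect), connectional homogeneity, and
# intra/inter-subject variability summaries.

new_metric_report <- function(per_network, summary_value, metric_name,
                              summary_type = c("weighted_mean", "unweighted_mean")) {
  structure(
    list(per_network = per_network, summary_value = summary_value,
         metric_name = metric_name, summary_type = match.arg(summary_type)),
    class = "fc_metric"
  )
}

#' @export
print.fc_metric <- function(x, ...) {
  cat(sprintf("<fc_metric> %s: %s %.5f over %d networks\n", x$metric_name,
              sub("_", " ", x$summary_type), x$summary_value,
              nrow(x$per_network)))
  invisible(x)
}

#' Tidy / glance methods for metric reports
#'
#' @param x an `fc_metric`.
#' @param ... unused.
#' @return `tidy()`: the per-network tibble. `glance()`: a one-row tibble
#'   with `metric`, `mean_value`, `n_networks`.
#' @export
tidy.fc_metric <- function(x, ...) x$per_network

#' @rdname tidy.fc_metric
#' @export
glance.fc_metric <- function(x, ...) {
  tibble::tibble(metric = x$metric_name, mean_value = x$summary_value,
                 n_networks = nrow(x$per_network))
}

# fast path used inside iteration loops: unweighted network-mean Dice of two
# aligned label vectors
mean_dice_labels <- function(a, b, k) {
  va <- tabulate(a, k)
  vb <- tabulate(b, k)
  ov <- vapply(seq_len(k), function(l) sum(a == l & b == l), numeric(1))
  d <- ifelse(va + vb == 0, 0, 2 * ov / (va + vb))
  mean(d)
}

#' Dice overlap between two parcellations
#'
#' Per network l: `2 * V_overlap / (V1 + V2)`, where `V_overlap` counts
#' vertices carrying label l in both parcellations and `V1`, `V2` its vertex
#' counts in each. The parcellation-level value is the unweighted mean over
#' networks. A network absent from one parcellation scores 0.
#'
#' @param parc_a,parc_b parcellations over the same ROI.
#' @param matched set to `FALSE` to run [match_labels()] first (required
#'   when the two parcellations were clustered independently).
#' @return An `fc_metric` with per-network tibble (`network`, `value`,
#'   `n_a`, `n_b`, `overlap`).
#' @export
dice_coefficient <- function(parc_a, parc_b, matched = TRUE) {
  if (!same_roi(parc_a, parc_b)) {
    fc_abort("parcellations must cover the same ROI", "fcparc_validation_error")
  }
  if (!matched) parc_b <- match_labels(parc_a, parc_b)$parcellation
  k <- max(parc_a$k, parc_b$k)
  va <- tabulate(parc_a$labels, k)
  vb <- tabulate(parc_b$labels, k)
  ov <- vapply(seq_len(k), function(l) {
    sum(parc_a$labels == l & parc_b$labels == l)
  }, numeric(1))
  d <- ifelse(va + vb == 0, 0, 2 * ov / (va + vb))
  per <- tibble::tibble(network = seq_len(k), value = d, n_a = va, n_b = vb,
                        overlap = as.integer(ov))
  new_metric_report(per, mean(d), "dice", "unweighted_mean")
}

#' Functional inhomogeneity of task activation under a parcellation
#'
#' The sample standard deviation (denominator N-1) of the task z-scores
#' within each network, averaged across networks weighted by network vertex
#' count: `sum(sd_l * |l|) / sum(|l|)`. Lower values mean parcellation
#' boundaries align with the task topography. Single-vertex networks
#' contribute sd 0 with a warning.
#'
#' @param zmap an [task_zmap()] over the ROI.
#' @param parc an [parcellation()] on the same ROI.
#' @return An `fc_metric` (per-network tibble: `network`, `value`, `n`).
#' @export
functional_inhomogeneity <- function(zmap, parc) {
  if (!identical(zmap$roi_vertices, parc$roi_vertices)) {
    fc_abort("z-map and parcellation must cover the same ROI",
             "fcparc_validation_error")
  }
  ks <- seq_len(parc$k)
  n <- vapply(ks, function(l) sum(parc$labels == l), numeric(1))
  sds <- vapply(ks, function(l) {
    z <- zmap$z[parc$labels == l]
    if (length(z) < 2) return(0)
    stats::sd(z)
  }, numeric(1))
  if (any(n == 1)) {
    warning("single-vertex network(s) contribute sd 0: ",
            paste(ks[n == 1], collapse = ", "))
  }
  keep <- n > 0
  per <- tibble::tibble(network = ks[keep], value = sds[keep], n = n[keep])
  new_metric_report(per, sum(per$value * per$n) / sum(per$n),
                    "functional_inhomogeneity", "weighted_mean")
}

#' Connectional homogeneity of a parcellation
#'
#' Within each network, the Pearson correlations between all unordered
#' distinct vertex pairs are Fisher z-transformed and averaged; the
#' network values are then averaged weighted by network vertex count:
#' `sum(rho_l * |l|) / sum(|l|)`. Networks with fewer than 2 vertices are
#' excluded from the weighted mean with a warning.
#'
#' @param ts the subject's conditioned, concatenated `fc_timeseries`.
#' @param parc an [parcellation()].
#' @return An `fc_metric` (per-network tibble: `network`, `value`, `n`).
#' @export
connectional_homogeneity <- function(ts, parc) {
  x <- unclass(ts)[parc$roi_vertices, , drop = FALSE]
  ks <- seq_len(parc$k)
  n <- vapply(ks, function(l) sum(parc$labels == l), numeric(1))
  rho <- vapply(ks, function(l) {
    members <- which(parc$labels == l)
    if (length(members) < 2) return(NA_real_)
    cc <- stats::cor(t(x[members, , drop = FALSE]))
    mean(fisher_z(cc[upper.tri(cc)]))
  }, numeric(1))
  if (any(n < 2)) {
    warning("network(s) with < 2 vertices excluded from the weighted mean: ",
            paste(ks[n < 2], collapse = ", "))
  }
  keep <- n >= 2
  per <- tibble::tibble(network = ks[keep], value = rho[keep], n = n[keep])
  new_metric_report(per, sum(per$value * per$n) / sum(per$n),
                    "connectional_homogeneity", "weighted_mean")
}

#' Percent of total task effect per network
#'
#' Signed sum of the effect map within each network divided by the signed
#' sum over the whole parcellation, times 100. Values can leave [0, 100]
#' when signs mix (logged via a message).
#'
#' @param effect_map numeric vector of per-ROI-vertex effect sizes, or an
#'   [task_zmap()].
#' @param parc an [parcellation()].
#' @return An `fc_metric`; percentages sum to 100.
#' @export
percent_effect <- function(effect_map, parc) {
  eff <- if (inherits(effect_map, "fc_zmap")) effect_map$z else effect_map
  if (length(eff) != length(parc$labels)) {
    fc_abort("effect map must cover the ROI", "fcparc_dimension_error")
  }
  total <- sum(eff)
  if (abs(total) < 1e-12) {
    fc_abort("total effect is ~0; percentages undefined", "fcparc_domain_error")
  }
  ks <- seq_len(parc$k)
  sums <- vapply(ks, function(l) sum(eff[parc$labels == l]), numeric(1))
  pct <- 100 * sums / total
  if (any(pct < 0 | pct > 100)) {
    message("mixed-sign effects: percentages outside [0, 100]")
  }
  per <- tibble::tibble(network = ks, value = pct,
                        n = vapply(ks, function(l) sum(parc$labels == l), numeric(1)))
  new_metric_report(per, sum(pct), "percent_effect", "unweighted_mean")
}

#' Intra- and inter-subject parcellation variability
#'
#' Given one parcellation per subject and session (all sharing the group
#' atlas label space), computes for each subject the mean Dice between its
#' own sessions (intra) and the mean Dice between its sessions and every
#' other subject's sessions, pooled over all cross-session pairings (inter).
#' Also returns the subject-by-subject Dice similarity matrix (mean over
#' session pairings) for Mantel-type analyses.
#'
#' @param parcs either a tibble with columns `subject`, `session`,
#'   `parcellation` (a list column), or a nested list
#'   `parcs[[subject]][[session]]`.
#' @return An object of class `fc_variability` with `by_subject` tibble
#'   (`subject`, `intra`, `inter`), and `similarity` (`fc_similarity`).
#' @export
variability_summary <- function(parcs) {
  if (!tibble::is_tibble(parcs)) {
    parcs <- purrr::imap_dfr(parcs, function(sessions, s) {
      tibble::tibble(subject = as.character(s),
                     session = as.character(seq_along(sessions)),
                     parcellation = sessions)
    })
  }
  subjects <- unique(parcs$subject)
  n_sess <- table(parcs$subject)
  usable <- names(n_sess)[n_sess >= 2]
  skipped <- setdiff(subjects, usable)
  if (length(skipped) > 0) {
    warning("subject(s) skipped for missing sessions: ",
            paste(skipped, collapse = ", "))
  }
  if (length(usable) < 2) {
    fc_abort("need at least 2 subjects with 2 sessions each",
             "fcparc_parameter_error")
  }
  get_parcs <- function(s) parcs$parcellation[parcs$subject == s]

  pair_dice <- function(pa, pb) {
    k <- max(pa$k, pb$k)
    mean_dice_labels(pa$labels, pb$labels, k)
  }

  intra <- vapply(usable, function(s) {
    ps <- get_parcs(s)
    combs <- utils::combn(length(ps), 2)
    mean(vapply(seq_len(ncol(combs)), function(j) {
      pair_dice(ps[[combs[1, j]]], ps[[combs[2, j]]])
    }, numeric(1)))
  }, numeric(1))

  nsub <- length(usable)
  cross <- matrix(NA_real_, nsub, nsub, dimnames = list(usable, usable))
  for (i in seq_len(nsub - 1)) {
    for (j in (i + 1):nsub) {
      pi <- get_parcs(usable[i])
      pj <- get_parcs(usable[j])
      vals <- as.vector(outer(seq_along(pi), seq_along(pj),
                              Vectorize(function(a, b) pair_dice(pi[[a]], pj[[b]]))))
      cross[i, j] <- cross[j, i] <- mean(vals)
    }
  }
  inter <- vapply(seq_len(nsub), function(i) mean(cross[i, -i]), numeric(1))
  diag(cross) <- 1

  structure(
    list(
      by_subject = tibble::tibble(subject = usable, intra = unname(intra),
                                  inter = inter),
      similarity = similarity_matrix(cross, "dice", usable)
    ),
    class = "fc_variability"
  )
}

#' @export
print.fc_variability <- function(x, ...) {
  cat(sprintf(
    "<fc_variability> %d subjects: mean intra %.3f, mean inter %.3f\n",
    nrow(x$by_subject), mean(x$by_subject$intra), mean(x$by_subject$inter)
  ))
  invisible(x)
}

#' @rdname tidy.fc_metric
#' @export
tidy.fc_variability <- function(x, ...) {
  tidyr::pivot_longer(x$by_subject, c("intra", "inter"),
                      names_to = "comparison", values_to = "dice")
}
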