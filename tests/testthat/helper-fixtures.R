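# Shared fixtures and independent oracles. Expensive objects are memoized in
# this environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_mesh <- function() memo("small_mesh", build_mesh(2))

small_cohort <- function() {
  memo("small_cohort", simulate_cohort(
    cohort_spec(n_subjects = 3, sessions_per_subject = 2,
                timepoints_per_run = 100, mesh_subdivisions = 2, seed = 11)
  ))
}

# toy time series with fixed values
toy_ts <- function(data, tr = 2) timeseries_matrix(data, tr_seconds = tr)

# --- independent oracles ----------------------------------------------------

# brute-force per-network Dice by direct counting
oracle_dice <- function(a, b, k = max(a, b)) {
  per <- vapply(seq_len(k), function(l) {
    va <- sum(a == l)
    vb <- sum(b == l)
    if (va + vb == 0) return(0)
    2 * sum(a == l & b == l) / (va + vb)
  }, numeric(1))
  list(per_network = per, mean = mean(per))
}

# naive O(n^2) silhouette with cosine distance
oracle_silhouette <- function(x, labels) {
  xn <- x / sqrt(rowSums(x^2))
  n <- nrow(xn)
  d <- function(i, j) 1 - sum(xn[i, ] * xn[j, ])
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      ms <- which(labels == l)
      b <- min(b, mean(vapply(ms, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) < 1e-15) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# brute-force label matching over all permutations (small k only)
oracle_match <- function(a, b, k) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  best <- NULL
  best_ov <- -1
  for (p in perms(seq_len(k))) {
    ov <- sum(a == p[b])
    if (ov > best_ov) {
      best_ov <- ov
      best <- p
    }
  }
  list(mapping = best, overlap = best_ov)
}

# BH step-up by direct enumeration
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(sorted[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# mean pairwise within-network Fisher z by double loop
oracle_homogeneity <- function(x, labels) {
  ks <- sort(unique(labels))
  vals <- c()
  sizes <- c()
  for (l in ks) {
    ms <- which(labels == l)
    if (length(ms) < 2) next
    zs <- c()
    for (i in seq_along(ms)) {
      for (j in seq_along(ms)) {
        if (j <= i) next
        r <- oracle_pearson(x[ms[i], ], x[ms[j], ])
        r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
        zs <- c(zs, atanh(r))
      }
    }
    vals <- c(vals, mean(zs))
    sizes <- c(sizes, length(ms))
  }
  sum(vals * sizes) / sum(sizes)
}

# size-weighted within-network sd of a z-map
oracle_inhomogeneity <- function(z, labels) {
  ks <- sort(unique(labels))
  sds <- vapply(ks, function(l) {
    zz <- z[labels == l]
    if (length(zz) < 2) 0 else sd(zz)
  }, numeric(1))
  sizes <- vapply(ks, function(l) sum(labels == l), numeric(1))
  sum(sds * sizes) / sum(sizes)
}
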