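# shared internal helpers

fc_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fcparc_error"))
}

#' @importFrom stats sd cor
standardize_vec <- function(x, tol = 1e-12) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s < tol) {
    return(structure(x * 0, degenerate = TRUE))
  }
  x / s
}

# row-wise standardization (mean 0, sd 1); zero-variance rows left at 0 and
# reported in the "zero_variance" attribute
standardize_rows <- function(m, tol = 1e-12) {
  m <- m - rowMeans(m)
  s <- sqrt(rowSums(m^2) / (ncol(m) - 1))
  bad <- !is.finite(s) | s < tol
  s[bad] <- 1
  out <- m / s
  attr(out, "zero_variance") <- which(bad)
  out
}

# deterministic sub-seed derivation; stays below 2^31 - 1
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 17
  for (v in ids) {
    h <- (h * 1000003 + (abs(as.numeric(v)) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# connected components of the subgraph induced by `subset` on the mesh
# neighbor lists; returns integer component id per subset member (named by
# vertex index). Plain BFS -- called in permutation loops, so kept allocation
# light.
graph_components <- function(neighbors, subset) {
  if (length(subset) == 0L) {
    return(integer(0))
  }
  in_set <- logical(length(neighbors))
  in_set[subset] <- TRUE
  comp <- integer(length(neighbors))
  cid <- 0L
  for (v in subset) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue) > 0L) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (w in neighbors[[u]]) {
        if (in_set[w] && comp[w] == 0L) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  structure(comp[subset], names = subset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
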