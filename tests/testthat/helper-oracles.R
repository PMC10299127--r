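# Independent oracles and small fixture builders shared across the suite.

# Exhaustive spanning-tree enumeration: checks every (n-1)-edge subset with
# union-find and returns the extremal weights and edge sets. Independent of
# the Kruskal implementation under test.
enumerate_spanning_trees <- function(g) {
  e <- g$edges
  n <- g$n_vertices
  combos <- utils::combn(nrow(e), n - 1L)
  weights <- numeric(0)
  trees <- list()
  for (k in seq_len(ncol(combos))) {
    sel <- combos[, k]
    sub <- e[sel, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (r in seq_len(nrow(sub))) {
      ri <- find(sub[r, 1]); rj <- find(sub[r, 2])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) {
      trees[[length(trees) + 1L]] <- sub
      weights[length(weights) + 1L] <- sum(sub[, 3])
    }
  }
  list(weights = weights, trees = trees)
}

edge_key <- function(edges) sort(paste(edges[, 1], edges[, 2], sep = "-"))

# Random connected weighted graph on n vertices with distinct continuous
# weights (each complete-graph edge kept with probability keep_p; resampled
# until connected).
random_connected_graph <- function(n, keep_p = 0.8) {
  repeat {
    full <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(full)) < keep_p
    if (sum(keep) < n - 1) next
    e <- cbind(full[keep, , drop = FALSE], stats::runif(sum(keep), -1, 1))
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in seq_len(nrow(e))) {
      ri <- find(e[r, 1]); rj <- find(e[r, 2])
      if (ri != rj) parent[ri] <- rj
    }
    if (length(unique(vapply(seq_len(n), find, numeric(1)))) == 1L)
      return(weighted_graph(n, e))
  }
}

# Random SPD matrix with eigenvalues bounded away from zero.
random_spd <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) / n + diag(0.5, n)
}

make_ts <- function(m, id = "s1", atlas = "toy") roi_timeseries(m, id, atlas)

# Small deterministic cohort for pipeline-level tests.
tiny_cohort_spec <- function(seed = 5L, n_per_group = 6L, n_rois = 12L,
                             n_timepoints = 40L, effect = 0.4) {
  cohort_spec(n_per_group = n_per_group, n_rois = n_rois,
              n_timepoints = n_timepoints, effect = effect, seed = seed)
}
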