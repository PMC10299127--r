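#' Weighted undirected graph
#'
#' Edge-list container used by the spanning-tree machinery. Vertices are
#' 1-based ROI indices; each unordered pair appears at most once (stored
#' with i < j), with no self-loops.
#'
#' @param n_vertices Number of vertices.
#' @param edges Numeric matrix with columns (i, j, w).
#' @return Object of class `weighted_graph`.
#' @export
weighted_graph <- function(n_vertices, edges) {
  if (!is_count(n_vertices)) stopf("n_vertices must be a positive integer")
  edges <- matrix(as.numeric(as.matrix(edges)), ncol = 3)
  i <- pmin(edges[, 1], edges[, 2]); j <- pmax(edges[, 1], edges[, 2])
  if (any(i == j)) stopf("self-loops are not allowed")
  if (any(i < 1 | j > n_vertices)) stopf("vertex index out of range")
  if (anyDuplicated(paste(i, j))) stopf("duplicate edge between a vertex pair")
  edges <- cbind(i = as.integer(i), j = as.integer(j), w = edges[, 3])
  structure(list(n_vertices = as.integer(n_vertices), edges = edges),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d vertices, %d edges\n",
              x$n_vertices, nrow(x$edges)))
  invisible(x)
}

#' Connectivity matrix to complete weighted graph
#'
#' Vertices are the ROIs; the edge between i and j carries the signed
#' matrix entry (i, j). The diagonal is discarded. Set `absolute = TRUE`
#' to rank edges by magnitude instead of signed value.
#'
#' @param cm A [connectivity_matrix()] (or plain symmetric matrix).
#' @param absolute Use absolute values as weights.
#' @return A [weighted_graph()] with N(N-1)/2 edges.
#' @export
matrix_to_graph <- function(cm, absolute = FALSE) {
  M <- if (inherits(cm, "connectivity_matrix")) cm$M else cm
  if (!is.matrix(M) || nrow(M) != ncol(M)) stopf("cm must be square")
  if (max(abs(M - t(M))) > 1e-10)
    stopf("cm is asymmetric beyond tolerance (max deviation %.3e)",
          max(abs(M - t(M))))
  N <- nrow(M)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[idx]
  if (absolute) w <- abs(w)
  weighted_graph(N, cbind(idx[, 1], idx[, 2], w))
}

# Union-find check that an edge set on n vertices is a spanning tree
# (acyclic + connected). Used by the validator and property tests.
is_spanning_tree_edges <- function(edges_ij, n) {
  if (nrow(edges_ij) != n - 1L) return(FALSE)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(edges_ij))) {
    ri <- find(edges_ij[k, 1]); rj <- find(edges_ij[k, 2])
    if (ri == rj) return(FALSE)         # cycle
    parent[ri] <- rj
  }
  TRUE                                  # n-1 acyclic edges => spanning
}

#' Kruskal minimum / maximum spanning tree
#'
#' Greedy Kruskal: edges are sorted (ascending for `"min"`, descending for
#' `"max"`, ties broken by lexicographic (i, j) for reproducibility) and an
#' edge joins the tree iff its endpoints lie in different union-find
#' components. Signed weights are used as-is, so on a correlation graph the
#' minimum tree collects the weakest / most negative links
#' (under-connectivity) and the maximum tree the strongest
#' (over-connectivity).
#'
#' @param g A [weighted_graph()]; must be connected.
#' @param variant `"min"` or `"max"`.
#' @return Object of class `spanning_tree` with fields `variant`, `edges`
#'   (matrix (i, j, w), exactly n_vertices - 1 rows), `total_weight`,
#'   `n_vertices`.
#' @examples
#' kruskal_spanning_tree(toy_graph_fixture(), "min")$total_weight  # 6
#' @export
kruskal_spanning_tree <- function(g, variant = c("min", "max")) {
  stopifnot(inherits(g, "weighted_graph"))
  variant <- match.arg(variant)
  e <- g$edges
  ord <- order(if (variant == "min") e[, "w"] else -e[, "w"],
               e[, "i"], e[, "j"])
  e <- e[ord, , drop = FALSE]

  parent <- seq_len(g$n_vertices)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  keep <- logical(nrow(e))
  n_joined <- 0L
  for (k in seq_len(nrow(e))) {
    ri <- find(e[k, "i"]); rj <- find(e[k, "j"])
    if (ri != rj) {
      parent[ri] <- rj
      keep[k] <- TRUE
      n_joined <- n_joined + 1L
      if (n_joined == g$n_vertices - 1L) break
    }
  }
  if (n_joined != g$n_vertices - 1L) {
    comp <- vapply(seq_len(g$n_vertices), find, numeric(1))
    members <- which(comp == comp[1])
    stopf("graph is disconnected: no spanning tree (one component is {%s})",
          paste(members, collapse = ", "))
  }
  edges <- e[keep, , drop = FALSE]
  structure(list(variant = variant, edges = edges,
                 total_weight = sum(edges[, "w"]),
                 n_vertices = g$n_vertices),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> variant=%s, %d vertices, total weight %.4g\n",
              x$variant, x$n_vertices, x$total_weight))
  invisible(x)
}

#' Spanning-tree layer matrix
#'
#' Expands a spanning tree back into an N x N symmetric matrix holding the
#' original connectivity weight at (i, j) and (j, i) for every tree edge
#' and zero elsewhere (including the diagonal).
#'
#' @param tree A [kruskal_spanning_tree()] result.
#' @param cm The [connectivity_matrix()] (or matrix) the tree was derived
#'   from; supplies the stored weights so that `absolute` ranking never
#'   alters the layer values.
#' @return Numeric N x N matrix.
#' @export
tree_layer <- function(tree, cm) {
  stopifnot(inherits(tree, "spanning_tree"))
  M <- if (inherits(cm, "connectivity_matrix")) cm$M else cm
  N <- nrow(M)
  if (tree$n_vertices != N) stopf("tree and matrix dimensions differ")
  if (any(tree$edges[, "j"] > N)) stopf("tree edge outside matrix index range")
  L <- matrix(0, N, N)
  ij <- tree$edges[, c("i", "j"), drop = FALSE]
  L[ij] <- M[ij]
  L[ij[, 2:1, drop = FALSE]] <- M[ij]
  L
}

#' 3-channel connectivity stack
#'
#' The N x N x 3 tensor fed to the classifier. `strategy = "enhanced"`
#' layers the original matrix (channel 1), its maximum spanning tree
#' (channel 2) and its minimum spanning tree (channel 3);
#' `strategy = "plain"` splits the matrix into three row bands that sum
#' back to the original.
#'
#' @param channels N x N x 3 numeric array.
#' @param strategy `"plain"` or `"enhanced"`.
#' @param method,subject_id,atlas Metadata inherited from the source matrix.
#' @return Object of class `stack3d`.
#' @export
stack3d <- function(channels, strategy, method = "", subject_id = "",
                    atlas = "") {
  strategy <- match.arg(strategy, c("plain", "enhanced"))
  if (!(is.array(channels) && length(dim(channels)) == 3L))
    stopf("channels must be a 3-dimensional array")
  d <- dim(channels)
  if (d[1] != d[2]) stopf("stack channels must be square (got %dx%d)", d[1], d[2])
  if (d[3] != 3L) stopf("stack must have exactly 3 channels, got %d", d[3])
  structure(list(channels = channels, strategy = strategy, method = method,
                 subject_id = as.character(subject_id),
                 atlas = as.character(atlas), N = d[1]),
            class = "stack3d")
}

validate_stack3d <- function(x) {
  if (!inherits(x, "stack3d")) stopf("not a stack3d object")
  d <- dim(x$channels)
  if (length(d) != 3L || d[3] != 3L)
    stopf("stack has %d channels, expected 3", if (length(d) == 3) d[3] else NA)
  if (d[1] != d[2]) stopf("stack channels are not square")
  invisible(x)
}

#' @export
print.stack3d <- function(x, ...) {
  cat(sprintf("<stack3d> %dx%dx3 strategy=%s method=%s subject=%s atlas=%s\n",
              x$N, x$N, x$strategy, x$method, x$subject_id, x$atlas))
  invisible(x)
}

#' Enhanced 3-channel stack
#'
#' Channel 1 is the source connectivity matrix; channel 2 the maximum
#' spanning tree layer (over-connectivity); channel 3 the minimum spanning
#' tree layer (under-connectivity). Tree layers retain the original signed
#' weights.
#'
#' @param cm A [connectivity_matrix()].
#' @param absolute Rank spanning-tree edges by absolute weight.
#' @return A [stack3d()] with strategy `"enhanced"`.
#' @export
build_enhanced_stack <- function(cm, absolute = FALSE) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  g <- matrix_to_graph(cm, absolute = absolute)
  maxst <- kruskal_spanning_tree(g, "max")
  minst <- kruskal_spanning_tree(g, "min")
  ch <- array(0, c(cm$N, cm$N, 3))
  ch[, , 1] <- cm$M
  ch[, , 2] <- tree_layer(maxst, cm)
  ch[, , 3] <- tree_layer(minst, cm)
  stack3d(ch, "enhanced", cm$method, cm$subject_id, cm$atlas)
}

# Row-band sizes for the plain thirds split: the first bands absorb the
# remainder (116 -> 39, 39, 38).
plain_band_sizes <- function(N) {
  b1 <- ceiling(N / 3)
  b2 <- ceiling((N - b1) / 2)
  c(b1, b2, N - b1 - b2)
}

#' Plain thirds 3-channel stack
#'
#' Partitions the matrix rows into three contiguous bands (sizes
#' `ceiling`-first, e.g. 39/39/38 for N = 116); channel k holds the matrix
#' on its band's rows and zero elsewhere, so the channels sum elementwise
#' to the source matrix.
#'
#' @param cm A [connectivity_matrix()] with N >= 3.
#' @return A [stack3d()] with strategy `"plain"`.
#' @export
build_plain_stack <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (cm$N < 3L) stopf("plain stack needs at least 3 ROIs, got %d", cm$N)
  sizes <- plain_band_sizes(cm$N)
  bounds <- cumsum(sizes)
  starts <- c(1L, bounds[-3] + 1L)
  ch <- array(0, c(cm$N, cm$N, 3))
  for (k in 1:3) ch[starts[k]:bounds[k], , k] <- cm$M[starts[k]:bounds[k], ]
  stack3d(ch, "plain", cm$method, cm$subject_id, cm$atlas)
}

#' Build the stack for one connectivity matrix
#'
#' Dispatcher over the two stacking strategies.
#'
#' @param cm A [connectivity_matrix()].
#' @param strategy `"plain"` or `"enhanced"`.
#' @param absolute Passed to [build_enhanced_stack()].
#' @return A [stack3d()].
#' @export
build_stack <- function(cm, strategy = c("enhanced", "plain"),
                        absolute = FALSE) {
  strategy <- match.arg(strategy)
  if (strategy == "enhanced") build_enhanced_stack(cm, absolute = absolute)
  else build_plain_stack(cm)
}
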