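test_that("matrix_to_graph builds the complete signed graph without the diagonal", {
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  m[1, 3] <- m[3, 1] <- -0.9
  g <- matrix_to_graph(connectivity_matrix(m, "correlation"))
  expect_equal(g$n_vertices, 4L)
  expect_equal(nrow(g$edges), 6L)                       # N(N-1)/2
  expect_false(any(g$edges[, "i"] == g$edges[, "j"]))   # no self-loops
  w13 <- g$edges[g$edges[, "i"] == 1 & g$edges[, "j"] == 3, "w"]
  expect_equal(unname(w13), -0.9)                       # sign preserved
  g_abs <- matrix_to_graph(m, absolute = TRUE)
  expect_equal(unname(g_abs$edges[g_abs$edges[, "i"] == 1 &
                                  g_abs$edges[, "j"] == 3, "w"]), 0.9)
  asym <- m; asym[1, 2] <- 0.7
  expect_error(matrix_to_graph(asym), "asymmetric")
})

test_that("Kruskal reproduces the enumerated optimum on the toy fixture", {
  g <- toy_graph_fixture()
  mn <- kruskal_spanning_tree(g, "min")
  mx <- kruskal_spanning_tree(g, "max")
  expect_equal(mn$total_weight, 6)
  expect_equal(edge_key(mn$edges), c("1-2", "1-4", "2-3"))
  expect_equal(mx$total_weight, 15)
  expect_equal(edge_key(mx$edges), c("1-3", "2-4", "3-4"))
  expect_equal(sum(mn$edges[, "w"]), mn$total_weight)
})

test_that("a tree input is its own unique spanning tree for both variants", {
  n <- 7
  path <- weighted_graph(n, cbind(1:(n - 1), 2:n, rnorm(n - 1)))
  for (v in c("min", "max")) {
    tr <- kruskal_spanning_tree(path, v)
    expect_equal(edge_key(tr$edges), edge_key(path$edges))
  }
})

test_that("disconnected graphs are rejected, naming a component", {
  g <- weighted_graph(4, rbind(c(1, 2, 1), c(3, 4, 2)))
  expect_error(kruskal_spanning_tree(g, "min"), "disconnected.*component")
})

test_that("Kruskal matches exhaustive enumeration on 200 random graphs", {
  set.seed(2024)
  for (rep in 1:200) {
    n <- sample(4:6, 1)
    g <- random_connected_graph(n)
    oracle <- enumerate_spanning_trees(g)
    mn <- kruskal_spanning_tree(g, "min")
    mx <- kruskal_spanning_tree(g, "max")
    expect_equal(mn$total_weight, min(oracle$weights))
    expect_equal(mx$total_weight, max(oracle$weights))
    # continuous weights: the optimum is unique, so edge sets must agree
    expect_equal(edge_key(mn$edges),
                 edge_key(oracle$trees[[which.min(oracle$weights)]]))
    expect_equal(edge_key(mx$edges),
                 edge_key(oracle$trees[[which.max(oracle$weights)]]))
    expect_equal(nrow(mn$edges), n - 1L)
    expect_true(connstack:::is_spanning_tree_edges(
      mn$edges[, 1:2, drop = FALSE], n))
  }
})

test_that("MaxST(w) equals MST(-w) on distinct-weight graphs", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    g <- random_connected_graph(n)
    neg <- weighted_graph(n, cbind(g$edges[, 1:2], -g$edges[, "w"]))
    expect_equal(edge_key(kruskal_spanning_tree(g, "max")$edges),
                 edge_key(kruskal_spanning_tree(neg, "min")$edges))
  }
})

test_that("tree_layer symmetrically stores original weights on tree edges only", {
  m <- matrix(c(0, 1, 4, 3,
                1, 0, 2, 5,
                4, 2, 0, 6,
                3, 5, 6, 0), 4, 4)
  cm <- connectivity_matrix(m, "tangent")
  mn <- kruskal_spanning_tree(matrix_to_graph(cm), "min")
  L <- tree_layer(mn, cm)
  expect_equal(L, t(L))
  expect_equal(sum(L != 0), 2L * (4L - 1L))
  nz <- which(L != 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]),
                  c("1 2", "2 1", "2 3", "3 2", "1 4", "4 1"))
  expect_equal(L[1, 2], m[1, 2])
  expect_error(tree_layer(mn, matrix(0, 6, 6)), "differ")
})

test_that("a zero-weight tree edge contributes support but numeric zero", {
  m <- matrix(c(0, 0, 4,
                0, 0, 2,
                4, 2, 0), 3, 3)
  cm <- connectivity_matrix(m, "tangent")
  mn <- kruskal_spanning_tree(matrix_to_graph(cm), "min")
  expect_equal(nrow(mn$edges), 2L)              # edge membership, not nonzeros
  L <- tree_layer(mn, cm)
  expect_lt(sum(L != 0), 2L * 2L)               # the 0-weight edge is invisible
})

test_that("enhanced stack layers original | MaxST | MST", {
  set.seed(5)
  m <- matrix(rnorm(100), 10); m <- (m + t(m)) / 2; diag(m) <- 0
  cm <- connectivity_matrix(m, "tangent", "s1", "toy")
  st <- build_enhanced_stack(cm)
  expect_equal(st$strategy, "enhanced")
  expect_identical(st$channels[, , 1], cm$M)
  for (k in 2:3) {
    ch <- st$channels[, , k]
    expect_equal(ch, t(ch))
    expect_equal(sum(ch != 0), 2L * (10L - 1L))
  }
  expect_identical(build_enhanced_stack(cm)$channels, st$channels)  # deterministic
})

test_that("MaxST and MST supports are disjoint when brute force confirms it", {
  set.seed(31)
  for (rep in 1:20) {
    g <- random_connected_graph(5, keep_p = 1)   # complete, distinct weights
    oracle <- enumerate_spanning_trees(g)
    key_min <- edge_key(oracle$trees[[which.min(oracle$weights)]])
    key_max <- edge_key(oracle$trees[[which.max(oracle$weights)]])
    if (length(intersect(key_min, key_max)) == 0L) {
      M <- matrix(0, 5, 5)
      M[g$edges[, 1:2]] <- g$edges[, "w"]
      M <- M + t(M)
      st <- build_enhanced_stack(connectivity_matrix(M, "tangent"))
      sup <- function(k) which(st$channels[, , k] != 0)
      expect_length(intersect(sup(2), sup(3)), 0L)
    }
  }
})

test_that("plain stack row bands partition the matrix", {
  set.seed(9)
  m <- matrix(rnorm(36), 6); m <- (m + t(m)) / 2
  cm <- connectivity_matrix(m, "tangent")
  st <- build_plain_stack(cm)
  expect_equal(st$channels[, , 1] + st$channels[, , 2] + st$channels[, , 3],
               cm$M)
  # N = 6: bands {1,2}, {3,4}, {5,6}
  expect_true(all(st$channels[1:2, , 1] == cm$M[1:2, ]))
  expect_true(all(st$channels[3:4, , 2] == cm$M[3:4, ]))
  expect_true(all(st$channels[5:6, , 3] == cm$M[5:6, ]))
  # every entry is nonzero in at most one channel
  nz <- (st$channels[, , 1] != 0) + (st$channels[, , 2] != 0) +
        (st$channels[, , 3] != 0)
  expect_true(all(nz <= 1))
  expect_equal(connstack:::plain_band_sizes(116L), c(39, 39, 38))
  expect_equal(connstack:::plain_band_sizes(161L), c(54, 54, 53))
  expect_equal(connstack:::plain_band_sizes(200L), c(67, 67, 66))
  tiny <- connectivity_matrix(diag(2) * 0, "tangent")
  expect_error(build_plain_stack(tiny), "at least 3")
})
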