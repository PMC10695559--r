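test_that("modularity matches direct evaluation", {
  # two disconnected unit-weight triangles
  tri2 <- make_net(c("A1", "A2", "A3", "B1", "B2", "B3"), list(
    list("A1", "A2", 1), list("A1", "A3", 1), list("A2", "A3", 1),
    list("B1", "B2", 1), list("B1", "B3", 1), list("B2", "B3", 1)))
  correct <- setNames(c(0, 0, 0, 1, 1, 1), tri2$nodes)
  expect_equal(modularity_score(tri2, correct), 0.5)
  expect_equal(modularity_score(tri2, correct),
               oracle_modularity(tri2, correct))

  # one community: Q = 0; scrambled split across components: Q < 0
  one <- setNames(rep(0, 6), tri2$nodes)
  expect_equal(modularity_score(tri2, one), 0)
  crossed <- setNames(c(0, 0, 1, 1, 0, 1), tri2$nodes)
  expect_lt(modularity_score(tri2, crossed), 0)
  expect_equal(modularity_score(tri2, crossed),
               oracle_modularity(tri2, crossed))

  expect_error(modularity_score(make_net(c("a", "b"), list()), c(a = 0, b = 0)),
               "undefined")
})

test_that("leading_eigenvector recovers two weakly bridged triangles", {
  net <- two_triangle_net(bridge = 0.1)
  part <- leading_eigenvector(net)
  expect_equal(part$n_communities, 2L)
  m <- part$membership
  expect_equal(length(unique(m[c("A1", "A2", "A3")])), 1L)
  expect_equal(length(unique(m[c("B1", "B2", "B3")])), 1L)
  expect_false(m[["A1"]] == m[["B1"]])
  # matches the exhaustive 2-partition optimum
  best <- oracle_best_bisection(net)
  expect_equal(part$modularity, best$q, tolerance = 1e-9)
  # stored modularity is recomputable from membership
  expect_equal(part$modularity, modularity_score(net, part$membership))
})

test_that("degenerate and symmetric cases are handled deterministically", {
  comp <- complete_network(6)
  expect_equal(leading_eigenvector(comp)$n_communities, 1L)
  expect_equal(leading_eigenvector(comp)$modularity, 0)

  # disconnected components never share a community; isolates are singletons
  iso <- make_net(paste0("v", 1:5),
                  list(list("v1", "v2", 1), list("v3", "v4", 1)))
  part <- leading_eigenvector(iso)
  m <- part$membership
  expect_false(m[["v1"]] == m[["v3"]])
  expect_equal(sum(m == m[["v5"]]), 1L)
  # community ids contiguous from 0
  expect_setequal(unique(unname(m)), seq_len(part$n_communities) - 1L)

  edgeless <- make_net(paste0("v", 1:4), list())
  expect_warning(p0 <- leading_eigenvector(edgeless), "singleton")
  expect_equal(p0$n_communities, 4L)
  expect_equal(p0$modularity, 0)

  # determinism and permutation invariance of Q
  p1 <- leading_eigenvector(two_triangle_net())
  p2 <- leading_eigenvector(two_triangle_net())
  expect_identical(p1$membership, p2$membership)
  relabel <- 1L - p1$membership  # swap community labels
  expect_equal(modularity_score(two_triangle_net(), relabel), p1$modularity)
})

test_that("planted bisections are recovered on random weighted graphs", {
  set.seed(77)
  hits <- 0L
  for (i in 1:50) {
    nodes <- paste0("v", 1:12)
    planted <- setNames(rep(c(0L, 1L), each = 6L), nodes)
    pairs <- utils::combn(nodes, 2L)
    spec <- lapply(seq_len(ncol(pairs)), function(j) {
      same <- planted[[pairs[1L, j]]] == planted[[pairs[2L, j]]]
      w <- (if (same) 0.9 else 0.1) + runif(1, -0.05, 0.05)
      list(pairs[1L, j], pairs[2L, j], w)
    })
    net <- make_net(nodes, spec)
    part <- leading_eigenvector(net)
    agree <- part$membership == part$membership[[1L]]
    planted_agree <- planted == planted[[1L]]
    if (identical(unname(agree), unname(planted_agree))) hits <- hits + 1L
    best <- oracle_best_bisection(net)
    expect_gte(part$modularity, best$q - 0.02)
    expect_gte(part$modularity, 0)
  }
  expect_gte(hits, 45L)  # >= 90% exact recovery
})
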