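test_that("degree counts incident edges", {
  star <- star_network(12)
  d <- degree(star)
  expect_equal(unname(d["v1"]), 11L)
  expect_true(all(d[-1] == 1L))

  comp <- complete_network(12)
  expect_true(all(degree(comp) == 11L))

  pth <- path_network(c(0.5, 0.5))
  expect_equal(degree(pth, "v2"), 2L)
  expect_equal(degree(make_net("a", list()), "a"), 0L)
  expect_error(degree(star, "nope"), "unknown node")
})

test_that("betweenness matches closed forms", {
  star <- star_network(12)
  b <- betweenness(star)
  expect_equal(unname(b["v1"]), 11 * 10 / 2)  # (n-1)(n-2)/2 = 55
  expect_true(all(b[-1] == 0))

  pth <- path_network(c(0.5, 0.5))
  expect_equal(betweenness(pth, "v2"), 1)  # single (v1, v3) geodesic

  # fractional credit: a 4-cycle has two geodesics between opposite corners
  ring4 <- make_net(paste0("v", 1:4),
                    list(list("v1", "v2", 1), list("v2", "v3", 1),
                         list("v3", "v4", 1), list("v4", "v1", 1)))
  expect_equal(unname(betweenness(ring4)), rep(0.5, 4))
})

test_that("weighted distances use 1/r edge lengths", {
  single <- make_net(c("a", "b"), list(list("a", "b", 0.8)))
  D <- weighted_distances(single)
  expect_equal(D["a", "b"], 1.25)
  expect_equal(diag(D), c(a = 0, b = 0))

  vee <- make_net(c("a", "b", "c"),
                  list(list("a", "b", 0.5), list("b", "c", 0.5)))
  expect_equal(weighted_distances(vee)["a", "c"], 4)  # 2 + 2 via b

  two_comp <- make_net(c("a", "b", "c"), list(list("a", "b", 0.5)))
  expect_equal(weighted_distances(two_comp)["a", "c"], Inf)

  bad <- make_net(c("a", "b"), list(list("a", "b", 1)))
  bad$edges$weight <- -0.2
  expect_error(weighted_distances(bad), "strictly positive")
})

test_that("nodal and global efficiency follow the 1/d convention", {
  single <- make_net(c("a", "b"), list(list("a", "b", 0.8)))
  expect_equal(unname(nodal_efficiency(single)), c(0.8, 0.8))

  comp <- complete_network(5, w = 1)
  expect_equal(global_efficiency(comp), 1)

  iso <- make_net(c("a", "b", "c"), list(list("a", "b", 1)))
  expect_equal(nodal_efficiency(iso, "c"), 0)

  # path a-b-c with r = 0.5 on both edges: (0.375 + 0.5 + 0.375) / 3
  pth <- path_network(c(0.5, 0.5))
  expect_equal(global_efficiency(pth), mean(c(0.375, 0.5, 0.375)))

  empty <- make_net(c("a", "b", "c"), list())
  expect_equal(global_efficiency(empty), 0)
})

test_that("clustering coefficient matches closed forms", {
  tri <- complete_network(3)
  expect_equal(clustering_coefficient(tri), 1)
  expect_equal(clustering_coefficient(path_network(c(1, 1))), 0)
  # ring lattice n = 12, k = 4: 3(k-2) / (4(k-1)) = 0.5
  lat <- watts_strogatz(12, 4, 0)
  expect_equal(clustering_coefficient(lat), 0.5)
})

test_that("oracle equivalence on random graphs", {
  set.seed(314)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    net <- random_network(n, p_edge = runif(1, 0.2, 0.9))
    expect_equal(weighted_distances(net), oracle_distances(net),
                 tolerance = 1e-12)
    expect_equal(betweenness(net), oracle_betweenness(net),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(net), oracle_global_efficiency(net),
                 tolerance = 1e-12)
  }
})

test_that("efficiency properties: hop bound and edge monotonicity", {
  set.seed(159)
  for (i in 1:25) {
    net <- random_network(7, p_edge = 0.4)
    eff <- nodal_efficiency(net)
    adj <- adjacency_matrix(net)
    for (v in net$nodes) {
      best_hop <- if (any(adj[v, ] > 0)) max(adj[v, ]) else 0
      expect_lte(eff[[v]], best_hop + 1e-12)
    }
    # adding an edge never decreases global efficiency
    missing <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(missing)) {
      pick <- missing[sample(nrow(missing), 1), ]
      edges2 <- rbind(net$edges,
                      data.frame(from = net$nodes[pick[1]],
                                 to = net$nodes[pick[2]],
                                 weight = runif(1, 0.1, 1)))
      net2 <- functional_network(net$nodes, edges2)
      expect_gte(global_efficiency(net2), global_efficiency(net) - 1e-12)
    }
  }
})

test_that("metrics agree with an independent graph library", {
  set.seed(271)
  for (i in 1:20) {
    net <- random_network(8, p_edge = 0.5)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    expect_equal(unname(degree(net)),
                 unname(igraph::degree(g)[net$nodes]))
    expect_equal(unname(betweenness(net)),
                 unname(igraph::betweenness(g, weights = NA)[net$nodes]),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(net),
                 igraph::transitivity(g, type = "localaverageundirected",
                                      isolates = "zero"),
                 tolerance = 1e-12)
    D <- weighted_distances(net)
    Dig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(D, Dig[net$nodes, net$nodes], tolerance = 1e-12)
  }
})

test_that("betweenness sums on trees match the enumeration oracle", {
  set.seed(90)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    # random tree: connect each node to a random earlier node
    spec <- lapply(2:n, function(v)
      list(paste0("v", sample(v - 1, 1)), paste0("v", v), runif(1, 0.5, 1)))
    tree <- make_net(paste0("v", 1:n), spec)
    expect_equal(sum(betweenness(tree)), sum(oracle_betweenness(tree)))
  }
})

test_that("metric_table ranks nodes descending with average ties", {
  star <- star_network(12)
  mt <- metric_table(star)
  expect_equal(mt$rank_degree[mt$node == "v1"], 1)
  expect_equal(mt$rank_betweenness[mt$node == "v1"], 1)
  expect_equal(mt$rank_nodal_efficiency[mt$node == "v1"], 1)

  comp <- complete_network(12)
  mtc <- metric_table(comp)
  expect_true(all(mtc$rank_degree == 6.5))  # 12-way tie averages to 6.5

  empty <- make_net(paste0("v", 1:12), list())
  mte <- metric_table(empty)
  expect_true(all(mte$degree == 0))
  expect_equal(attr(mte, "global_efficiency"), 0)
})

test_that("compare_group_metrics follows the shared protocol", {
  t1 <- metric_table(complete_network(12))
  attr(t1, "group") <- "full"
  t2 <- metric_table(make_net(paste0("v", 1:12), list()))
  attr(t2, "group") <- "empty"
  res <- compare_group_metrics(list(t2, t1), "degree")
  expect_lt(res$omnibus$p_value, 0.05)
  # complete separation: the lower group wins no pairs
  expect_equal(res$pairwise[["empty vs full"]]$statistic, 0)

  same <- compare_group_metrics(list(t1, t1), "degree")
  expect_equal(same$omnibus$statistic, 0)

  expect_error(compare_group_metrics(list(t1, t2), "pagerank"))
})
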