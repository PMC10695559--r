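#' Graph metrics with immediate-early-gene connectomics conventions
#'
#' Two different path definitions coexist deliberately: betweenness uses
#' unweighted geodesics (shortest = fewest edges, with fractional credit
#' when several geodesics tie), while nodal and global efficiency use
#' weighted shortest paths with edge length 1/r — a strong correlation is a
#' short functional distance. Disconnected node pairs contribute exactly 0
#' to efficiency (the 1/infinity limit), never NA.
#'
#' @name graph_metrics
NULL

node_index <- function(net, node) {
  i <- match(node, net$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  i
}

#' Degree centrality
#'
#' @param net A `fos_network`.
#' @param node Optional single node name; if omitted, all degrees are
#'   returned as a named integer vector.
#' @return Integer count(s) of incident edges.
#' @export
degree <- function(net, node = NULL) {
  adj <- adjacency_matrix(net, weighted = FALSE)
  d <- as.integer(rowSums(adj))
  names(d) <- net$nodes
  if (is.null(node)) d else d[[node_index(net, node)]]
}

# Brandes' algorithm on unweighted graphs; returns unnormalized betweenness
# for unordered pairs (the directed accumulation halved).
brandes_betweenness <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); sigma <- numeric(n)
    dist[s] <- 0L; sigma[s] <- 1
    preds <- vector("list", n)
    order <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      order <- c(order, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

#' Betweenness centrality (unweighted geodesics, fractional credit)
#'
#' For every unordered pair of other nodes (s, t), a node v accumulates
#' `sigma_st(v) / sigma_st`, the fraction of s-t geodesics passing through
#' v. Pairs in different components contribute 0. Unnormalized.
#'
#' @inheritParams degree
#' @return Numeric value(s).
#' @export
betweenness <- function(net, node = NULL) {
  adj <- adjacency_matrix(net, weighted = FALSE)
  b <- brandes_betweenness(adj)
  names(b) <- net$nodes
  if (is.null(node)) b else b[[node_index(net, node)]]
}

# Dijkstra from every source over a non-negative length matrix
# (Inf = no edge); O(n^3) total, fine at brain-region scale.
dijkstra_all <- function(len) {
  n <- nrow(len)
  D <- matrix(Inf, n, n, dimnames = dimnames(len))
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    done <- logical(n)
    repeat {
      cand <- ifelse(done, Inf, d)
      u <- which.min(cand)
      if (!is.finite(cand[u])) break  # every reachable node settled
      done[u] <- TRUE
      relax <- d[u] + len[u, ]
      upd <- relax < d
      d[upd] <- relax[upd]
    }
    D[s, ] <- d
  }
  D
}

#' Weighted shortest-path distances (edge length 1/r)
#'
#' @param net A `fos_network` with strictly positive edge weights.
#' @return A node-by-node matrix of distances; `Inf` for pairs in different
#'   components, 0 on the diagonal.
#' @export
weighted_distances <- function(net) {
  stopifnot(inherits(net, "fos_network"))
  if (nrow(net$edges) && any(net$edges$weight <= 0))
    stop("edge weights must be strictly positive to define 1/r distances")
  adj <- adjacency_matrix(net, weighted = TRUE)
  len <- ifelse(adj > 0, 1 / adj, Inf)
  diag(len) <- Inf  # no self-loops; diagonal distance is fixed to 0 below
  D <- dijkstra_all(len)
  diag(D) <- 0
  D
}

#' Nodal efficiency
#'
#' Mean of the inverse weighted shortest-path distance from a node to every
#' other node (0 contribution for unreachable nodes); an isolated node has
#' efficiency 0.
#'
#' @inheritParams degree
#' @return Numeric value(s) in `[0, 1]` for correlation-weighted networks.
#' @export
nodal_efficiency <- function(net, node = NULL) {
  D <- weighted_distances(net)
  n <- nrow(D)
  inv <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
  eff <- rowSums(inv) / (n - 1)
  names(eff) <- net$nodes
  if (is.null(node)) eff else eff[[node_index(net, node)]]
}

#' Global efficiency
#'
#' Arithmetic mean of the nodal efficiencies of all nodes.
#'
#' @param net A `fos_network` with at least two nodes.
#' @return Scalar in `[0, 1]` for correlation-weighted networks.
#' @export
global_efficiency <- function(net) {
  if (length(net$nodes) < 2L) stop("need at least two nodes")
  mean(nodal_efficiency(net))
}

# unweighted local clustering from a 0/1 adjacency matrix
local_clustering <- function(adj) {
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj)  # 2 * triangles through each node
  ifelse(k >= 2, tri / (k * (k - 1)), 0)
}

#' Average clustering coefficient
#'
#' Unweighted average local clustering over all nodes (nodes of degree < 2
#' contribute 0). This is the statistic matched when generating
#' Watts-Strogatz null networks. A weighted variant (Onnela geometric-mean
#' triangle intensity, weights normalized by the maximum) is available via
#' `weighted = TRUE` but is not used for null matching.
#'
#' @param net A `fos_network` with at least three nodes.
#' @param weighted Use the weighted (geometric-mean) local coefficient.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, weighted = FALSE) {
  if (length(net$nodes) < 3L) stop("need at least three nodes")
  if (!weighted) {
    adj <- adjacency_matrix(net, weighted = FALSE)
    return(mean(local_clustering(adj)))
  }
  w <- adjacency_matrix(net, weighted = TRUE)
  if (max(w) <= 0) return(0)
  wh <- (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  tri <- diag(wh %*% wh %*% wh)
  mean(ifelse(k >= 2, tri / (k * (k - 1)), 0))
}

#' Per-node metric table with rankings
#'
#' Degree, betweenness and nodal efficiency per node, each with a
#' descending rank (rank 1 = largest; ties share their average rank), plus
#' the network-level global efficiency and clustering coefficient as
#' attributes.
#'
#' @param net A `fos_network`.
#' @return A data frame of class `fos_metrics` with columns `node`,
#'   `degree`, `betweenness`, `nodal_efficiency` and the three
#'   `rank_*` columns; attributes `global_efficiency`,
#'   `clustering_coefficient`, `group`.
#' @export
metric_table <- function(net) {
  stopifnot(inherits(net, "fos_network"))
  deg <- degree(net)
  btw <- betweenness(net)
  eff <- nodal_efficiency(net)
  out <- data.frame(
    node = net$nodes,
    degree = unname(deg),
    betweenness = unname(btw),
    nodal_efficiency = unname(eff),
    rank_degree = rank(-deg, ties.method = "average"),
    rank_betweenness = rank(-btw, ties.method = "average"),
    rank_nodal_efficiency = rank(-eff, ties.method = "average"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out,
            global_efficiency = mean(eff),
            clustering_coefficient = clustering_coefficient(net),
            group = net$group,
            class = c("fos_metrics", "data.frame"))
}

#' Compare a node metric across group networks
#'
#' Kruskal-Wallis over the per-node values of each network, followed by
#' pairwise Mann-Whitney tests when the omnibus is significant.
#'
#' @param tables List of `fos_metrics` (one per group).
#' @param metric One of `"degree"`, `"betweenness"`, `"nodal_efficiency"`.
#' @return A `fos_group_comparison`.
#' @export
compare_group_metrics <- function(tables,
                                  metric = c("degree", "betweenness",
                                             "nodal_efficiency")) {
  metric <- match.arg(metric)
  if (length(tables) < 2L) stop("need at least two metric tables")
  samples <- lapply(tables, function(t) t[[metric]])
  names(samples) <- vapply(tables, function(t)
    as.character(attr(t, "group", exact = TRUE)), "")
  group_comparison(samples)
}
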