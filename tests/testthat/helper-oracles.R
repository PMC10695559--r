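# Independent oracles: deliberately naive algorithms used only to verify
# the package's implementations on small inputs.

# all-pairs shortest paths by repeated relaxation over every edge, n sweeps
oracle_distances <- function(net) {
  n <- length(net$nodes)
  D <- matrix(Inf, n, n, dimnames = list(net$nodes, net$nodes))
  diag(D) <- 0
  if (!nrow(net$edges)) return(D)
  ei <- match(net$edges$from, net$nodes)
  ej <- match(net$edges$to, net$nodes)
  len <- 1 / net$edges$weight
  for (sweep in seq_len(n)) {
    for (e in seq_along(len)) {
      i <- ei[e]; j <- ej[e]
      D[, j] <- pmin(D[, j], D[, i] + len[e])
      D[, i] <- pmin(D[, i], D[, j] + len[e])
    }
  }
  D
}

oracle_global_efficiency <- function(net) {
  D <- oracle_distances(net)
  n <- nrow(D)
  inv <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
  mean(rowSums(inv) / (n - 1))
}

# betweenness by exhaustive enumeration of all unweighted geodesics:
# recursively expands every shortest path for each unordered pair
oracle_betweenness <- function(net) {
  adj <- adjacency_matrix(net, weighted = FALSE)
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      for (w in nbrs[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) {
    ds <- bfs_dist(s)
    for (t in (s + 1L):n) {
      if (!is.finite(ds[t])) next
      dt <- bfs_dist(t)
      paths <- list()
      grow <- function(path) {
        v <- path[length(path)]
        if (v == t) { paths[[length(paths) + 1L]] <<- path; return() }
        for (w in nbrs[[v]])
          if (ds[w] == ds[v] + 1 && ds[w] + dt[w] == ds[t]) grow(c(path, w))
      }
      grow(s)
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(paths)
      }
    }
  }
  stats::setNames(bc, net$nodes)
}

# best 2-partition of a network by exhaustive search over sign assignments
oracle_best_bisection <- function(net) {
  n <- length(net$nodes)
  best_q <- -Inf; best <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    side <- c(0L, as.integer(intToBits(code))[seq_len(n - 1L)])
    mem <- stats::setNames(side, net$nodes)
    q <- modularity_score(net, mem)
    if (q > best_q) { best_q <- q; best <- mem }
  }
  list(q = best_q, membership = best)
}

# plain modularity evaluation written independently of the package
oracle_modularity <- function(net, membership) {
  A <- adjacency_matrix(net, weighted = TRUE)
  k <- rowSums(A); m2 <- sum(k)
  q <- 0
  mem <- membership[net$nodes]
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (mem[i] == mem[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  unname(q / m2)
}
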