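#' Community structure by the leading-eigenvector method
#'
#' Communities are found by recursive spectral bisection of the modularity
#' matrix B = A - k k' / 2m (with A the weighted adjacency, k the weighted
#' degrees and m the total edge weight), using the generalized form
#' B^(g)_ij = B_ij - delta_ij sum_l B_il for subgraphs. Each group splits by
#' the sign of the leading eigenvector; splitting stops when the leading
#' eigenvalue is non-positive or the split does not increase modularity.
#' No refinement pass is applied, keeping the procedure deterministic (the
#' eigenvector sign is fixed by making its largest-magnitude entry
#' positive). Isolated nodes form singleton communities.
#'
#' @name communities
NULL

membership_vector <- function(net, membership) {
  if (is.null(names(membership)))
    stop("membership must be a named vector over the network's nodes")
  if (!setequal(names(membership), net$nodes))
    stop("membership must assign every node exactly once")
  membership[net$nodes]
}

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]` with edge
#' weights as A.
#'
#' @param net A `fos_network` with at least one edge.
#' @param membership Named vector (region -> community id).
#' @return Scalar Q in `[-0.5, 1]`.
#' @export
modularity_score <- function(net, membership) {
  stopifnot(inherits(net, "fos_network"))
  if (nrow(net$edges) == 0L)
    stop("modularity is undefined for an edgeless network")
  mem <- membership_vector(net, membership)
  A <- adjacency_matrix(net, weighted = TRUE)
  k <- rowSums(A)
  two_m <- sum(k)
  same <- outer(mem, mem, `==`)
  sum((A - outer(k, k) / two_m) * same) / two_m
}

#' Leading-eigenvector community detection
#'
#' @param net A `fos_network`.
#' @param tol Numerical tolerance for "positive" eigenvalues and modularity
#'   gains (default 1e-9).
#' @return An object of class `fos_partition` with `group`, `membership`
#'   (named integer vector, community indices contiguous from 0),
#'   `n_communities` and `modularity` (0, with a warning, for an edgeless
#'   network).
#' @export
leading_eigenvector <- function(net, tol = 1e-9) {
  stopifnot(inherits(net, "fos_network"))
  nodes <- net$nodes
  n <- length(nodes)
  if (nrow(net$edges) == 0L) {
    warning("edgeless network: every node is a singleton community; Q taken as 0")
    mem <- stats::setNames(seq_len(n) - 1L, nodes)
    return(structure(list(group = net$group, membership = mem,
                          n_communities = n, modularity = 0),
                     class = "fos_partition"))
  }
  A <- adjacency_matrix(net, weighted = TRUE)
  k <- rowSums(A)
  two_m <- sum(k)
  B <- A - outer(k, k) / two_m

  # connected components (communities never span components)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }

  groups <- list()
  bisect <- function(idx) {
    if (length(idx) == 1L) { groups[[length(groups) + 1L]] <<- idx; return() }
    Bg <- B[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    e <- eigen(Bg, symmetric = TRUE)
    lead <- e$values[1L]
    if (lead <= tol) { groups[[length(groups) + 1L]] <<- idx; return() }
    v <- e$vectors[, 1L]
    v <- v * sign(v[which.max(abs(v))])  # deterministic sign convention
    s <- ifelse(v >= 0, 1, -1)
    if (all(s == s[1L])) { groups[[length(groups) + 1L]] <<- idx; return() }
    dq <- as.numeric(t(s) %*% Bg %*% s) / (2 * two_m)
    if (dq <= tol) { groups[[length(groups) + 1L]] <<- idx; return() }
    bisect(idx[s > 0])
    bisect(idx[s < 0])
  }
  for (c_i in seq_len(cid)) {
    idx <- which(comp == c_i)
    if (length(idx) == 1L) groups[[length(groups) + 1L]] <- idx
    else bisect(idx)
  }

  mem <- integer(n)
  # contiguous community indices from 0, ordered by first node appearance
  firsts <- vapply(groups, min, 0L)
  ord <- order(firsts)
  newid <- integer(length(groups))
  newid[ord] <- seq_along(groups) - 1L
  for (g in seq_along(groups)) mem[groups[[g]]] <- newid[g]
  mem <- stats::setNames(mem, nodes)
  structure(list(group = net$group, membership = mem,
                 n_communities = length(groups),
                 modularity = modularity_score(net, mem)),
            class = "fos_partition")
}

#' @export
print.fos_partition <- function(x, ...) {
  cat(sprintf("Partition%s: %d communities, Q = %.4f\n",
              if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
              x$n_communities, x$modularity))
  for (c_i in sort(unique(x$membership)))
    cat(sprintf("  [%d] %s\n", c_i,
                paste(names(x$membership)[x$membership == c_i],
                      collapse = ", ")))
  invisible(x)
}
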