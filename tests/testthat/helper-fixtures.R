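# Small named networks and schemes used across tests.

tiny_scheme <- function(p = 4L) {
  regions <- LETTERS[seq_len(p)]
  region_scheme(regions, collections = list(all = regions))
}

# network from a compact edge spec: list(c("A","B", 0.9), ...)
make_net <- function(nodes, edge_spec, threshold = NA_real_, group = "test") {
  edges <- if (length(edge_spec)) {
    data.frame(from = vapply(edge_spec, `[[`, "", 1L),
               to = vapply(edge_spec, `[[`, "", 2L),
               weight = vapply(edge_spec, function(e) as.numeric(e[[3L]]), 0),
               stringsAsFactors = FALSE)
  } else NULL
  functional_network(nodes, edges, threshold = threshold, group = group)
}

star_network <- function(n = 12L, w = 1) {
  nodes <- paste0("v", seq_len(n))
  make_net(nodes, lapply(nodes[-1L], function(x) list(nodes[1L], x, w)))
}

path_network <- function(weights) {
  n <- length(weights) + 1L
  nodes <- paste0("v", seq_len(n))
  make_net(nodes, lapply(seq_along(weights), function(i)
    list(nodes[i], nodes[i + 1L], weights[i])))
}

complete_network <- function(n, w = 1) {
  nodes <- paste0("v", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  make_net(nodes, lapply(seq_len(ncol(pairs)), function(i)
    list(pairs[1L, i], pairs[2L, i], w)))
}

# Erdos-Renyi-ish random weighted network on n nodes (uses current RNG)
random_network <- function(n, p_edge = 0.5, wmin = 0.1, wmax = 1) {
  nodes <- paste0("v", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  spec <- lapply(which(keep), function(i)
    list(pairs[1L, i], pairs[2L, i], stats::runif(1, wmin, wmax)))
  make_net(nodes, spec)
}

# two triangles (unit weights) joined by one weak bridge A3-B1
two_triangle_net <- function(bridge = 0.1, tri_w = 1) {
  nodes <- c("A1", "A2", "A3", "B1", "B2", "B3")
  make_net(nodes, list(
    list("A1", "A2", tri_w), list("A1", "A3", tri_w), list("A2", "A3", tri_w),
    list("B1", "B2", tri_w), list("B1", "B3", tri_w), list("B2", "B3", tri_w),
    list("A3", "B1", bridge)))
}

# a tiny hand-written counts CSV (returns the path)
write_fixture_csv <- function(path, scheme = tiny_scheme(3L)) {
  writeLines(c(
    "animal_id,group,A,B,C",
    "a1,g1,1,2,3", "a2,g1,2,4,5", "a3,g1,3,9,7", "a4,g1,4,8,11",
    "b1,g2,2,1,4", "b2,g2,4,2,9", "b3,g2,6,4,12", "b4,g2,8,9,20"),
    path)
  path
}
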