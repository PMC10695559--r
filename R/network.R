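#' Functional networks
#'
#' A functional network is an undirected weighted graph whose nodes are the
#' scheme's regions and whose edges are the correlations retained after
#' thresholding, weighted by the retained r value. Isolated nodes stay in
#' the node set — a region disconnected from the rest of the graph is a
#' finding, not a missing value.
#'
#' @param nodes Ordered character vector of region names.
#' @param edges Data frame with columns `from`, `to`, `weight` (no
#'   self-loops or duplicate pairs; weights are the source correlations).
#' @param threshold The applied cutoff (recorded for provenance).
#' @param group Group label.
#' @return An object of class `fos_network`.
#' @export
functional_network <- function(nodes, edges, threshold = NA_real_,
                               group = NA_character_) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    if (any(!edges$from %in% nodes) || any(!edges$to %in% nodes))
      stop("edge endpoint not in node set")
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  structure(list(nodes = nodes, edges = edges,
                 threshold = threshold, group = group),
            class = "fos_network")
}

#' Pooled edge-retention threshold
#'
#' The cutoff below which correlations are discarded: the mean plus one
#' sample standard deviation (n-1 denominator) of the upper-triangle r
#' values pooled across all supplied matrices. A single data-driven cutoff
#' is applied to every group's network so that the networks are comparable.
#'
#' @param matrices List of `fos_corr` (at least one; at least two pooled
#'   values overall).
#' @return The scalar threshold.
#' @examples
#' # mean 0.35 + sd 0.18708... of 0.1, 0.2, ..., 0.6
#' @export
compute_threshold <- function(matrices) {
  if (!length(matrices)) stop("need at least one correlation matrix")
  pooled <- unlist(lapply(matrices, function(m) offdiagonal_values(m)$r),
                   use.names = FALSE)
  if (length(pooled) < 2L)
    stop("fewer than two pooled correlations; SD is undefined")
  mean(pooled) + stats::sd(pooled)
}

#' Build a thresholded functional network
#'
#' Retains an edge for every region pair whose correlation strictly exceeds
#' the threshold (signed r, so negative correlations are never retained by
#' a positive cutoff). An empty edge set is legal.
#'
#' @param m A `fos_corr`.
#' @param threshold Scalar cutoff.
#' @return A `fos_network` over all of the matrix's regions.
#' @export
build_network <- function(m, threshold) {
  validate_corr(m)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  vals <- offdiagonal_values(m)
  keep <- vals$r > threshold
  functional_network(
    nodes = m$regions,
    edges = data.frame(from = vals$region_a[keep], to = vals$region_b[keep],
                       weight = vals$r[keep], stringsAsFactors = FALSE),
    threshold = threshold, group = m$group)
}

#' Weighted adjacency matrix of a network
#'
#' @param net A `fos_network`.
#' @param weighted If `FALSE`, entries are 0/1.
#' @return A symmetric matrix in node order with zero diagonal.
#' @export
adjacency_matrix <- function(net, weighted = TRUE) {
  stopifnot(inherits(net, "fos_network"))
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    w <- if (weighted) net$edges$weight else 1
    a[cbind(i, j)] <- w
    a[cbind(j, i)] <- w
  }
  a
}

#' Serialize a network as an edge-list CSV
#'
#' Columns `region_a`, `region_b`, `r` with r printed to 6 decimal places.
#'
#' @param net A `fos_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "fos_network"))
  df <- data.frame(region_a = net$edges$from, region_b = net$edges$to,
                   r = sprintf("%.6f", net$edges$weight),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Rebuild a network from a serialized edge list
#'
#' @param path Edge-list CSV written by [write_edge_list()].
#' @param nodes Full node set (isolated nodes are not present in the file).
#' @param threshold,group Provenance fields to restore.
#' @return A `fos_network`.
#' @export
read_edge_list <- function(path, nodes, threshold = NA_real_,
                           group = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  functional_network(nodes,
                     data.frame(from = df$region_a, to = df$region_b,
                                weight = df$r, stringsAsFactors = FALSE),
                     threshold = threshold, group = group)
}

#' Export a network as GraphML
#'
#' Minimal GraphML (nodes with a `name` attribute, edges with a `weight`
#' attribute) readable by external graph viewers.
#'
#' @param net A `fos_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "fos_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="name" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  for (i in seq_along(net$nodes))
    writeLines(sprintf('    <node id="n%d"><data key="name">%s</data></node>',
                       i, net$nodes[i]), con)
  if (nrow(net$edges)) {
    si <- match(net$edges$from, net$nodes)
    ti <- match(net$edges$to, net$nodes)
    writeLines(sprintf(
      '    <edge source="n%d" target="n%d"><data key="weight">%.6f</data></edge>',
      si, ti, net$edges$weight), con)
  }
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}

#' @export
print.fos_network <- function(x, ...) {
  cat(sprintf("Functional network%s: %d nodes, %d edges",
              if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
              length(x$nodes), nrow(x$edges)))
  if (!is.na(x$threshold)) cat(sprintf(", threshold r > %.4f", x$threshold))
  cat("\n")
  iso <- setdiff(x$nodes, c(x$edges$from, x$edges$to))
  if (length(iso)) cat("  isolated:", paste(iso, collapse = ", "), "\n")
  invisible(x)
}
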