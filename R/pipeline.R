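#' Run the full network analysis end-to-end
#'
#' From a count table to per-group correlation matrices, a pooled
#' mean-plus-SD edge threshold, thresholded functional networks, centrality
#' and efficiency tables with node rankings, clustering-matched
#' Watts-Strogatz null comparisons, leading-eigenvector partitions and the
#' nonparametric group statistics — writing every intermediate artifact to
#' an output directory. Deterministic given `(inputs, seed)`.
#'
#' @param counts A `fos_counts` table or a path to a counts CSV.
#' @param scheme A `fos_scheme` or path to a scheme file (defaults to the
#'   12-region scheme).
#' @param control Label of the control group used for count normalization.
#' @param replicates Null-model replicate count (default 1000).
#' @param seed Integer random seed.
#' @param out_dir Output directory; must not already exist unless
#'   `force = TRUE`.
#' @param force Overwrite an existing output directory.
#' @param collection_rule Pair-membership rule for collection-level r
#'   comparisons, see [collection_values()].
#' @return A list of class `fos_analysis` with elements `counts`,
#'   `normalized_counts`, `matrices`, `threshold`, `networks`, `metrics`,
#'   `r_comparisons`, `metric_comparisons`, `null_comparisons`,
#'   `partitions`, `out_dir` — the same objects that were serialized.
#' @export
run_full_analysis <- function(counts, scheme = fos_default_scheme(),
                              control = "NS", replicates = 1000L, seed = 1L,
                              out_dir = NULL, force = FALSE,
                              collection_rule = c("incident", "within")) {
  collection_rule <- match.arg(collection_rule)
  if (is.character(scheme)) scheme <- read_scheme(scheme)
  if (is.character(counts)) counts <- read_counts(counts, scheme)
  stopifnot(is_count_table(counts))

  if (!is.null(out_dir)) {
    if (dir.exists(out_dir)) {
      if (!force)
        stop("output directory exists: ", out_dir,
             " (use force = TRUE to overwrite)")
      unlink(out_dir, recursive = TRUE)
    }
    dir.create(out_dir, recursive = TRUE)
  }

  groups <- unique(counts$group)
  normalized <- if (control %in% groups)
    normalize_to_control(counts, control) else NULL

  matrices <- lapply(groups, function(g) correlation_matrix(counts, g))
  names(matrices) <- groups
  threshold <- compute_threshold(matrices)
  networks <- lapply(matrices, build_network, threshold = threshold)
  metrics <- lapply(networks, metric_table)

  r_comparisons <- list(all = compare_group_r(matrices, scheme, "all"))
  for (cl in names(scheme$collections))
    r_comparisons[[cl]] <-
      compare_group_r(matrices, scheme, cl, rule = collection_rule)

  metric_comparisons <- lapply(
    c(degree = "degree", betweenness = "betweenness",
      nodal_efficiency = "nodal_efficiency"),
    function(mt) compare_group_metrics(metrics, mt))

  null_comparisons <- vector("list", length(groups))
  names(null_comparisons) <- groups
  for (i in seq_along(groups)) {
    net <- networks[[i]]
    if (nrow(net$edges) == 0L) {
      null_comparisons[[i]] <- list(group = groups[i], skipped = TRUE,
                                    reason = "network has no edges")
    } else {
      null_comparisons[[i]] <- smallworld_comparison(
        net, replicates = replicates, seed = seed + i)
    }
  }

  partitions <- lapply(networks, function(net)
    withCallingHandlers(leading_eigenvector(net),
                        warning = function(w) invokeRestart("muffleWarning")))

  res <- structure(
    list(counts = counts, normalized_counts = normalized,
         matrices = matrices, threshold = threshold, networks = networks,
         metrics = metrics, r_comparisons = r_comparisons,
         metric_comparisons = metric_comparisons,
         null_comparisons = null_comparisons, partitions = partitions,
         scheme = scheme, seed = seed, out_dir = out_dir),
    class = "fos_analysis")

  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

comparison_record <- function(cmp) {
  list(
    omnibus = list(H = cmp$omnibus$statistic, df = cmp$omnibus$df,
                   p_value = cmp$omnibus$p_value),
    medians = as.list(cmp$medians),
    pairwise = lapply(cmp$pairwise, function(t)
      list(U = t$statistic, p_value = t$p_value))
  )
}

null_record <- function(nc) {
  if (isTRUE(nc$skipped)) return(list(skipped = TRUE, reason = nc$reason))
  list(memory_efficiency = nc$memory_efficiency, k = nc$k, p = nc$p,
       mean_difference = nc$mean_difference,
       ci_low = nc$ci_low, ci_high = nc$ci_high,
       matched_clustering = nc$matched_clustering,
       target_clustering = nc$target_clustering,
       small_world = nc$small_world,
       replicates = length(nc$replicate_efficiencies))
}

write_analysis <- function(res, out_dir) {
  sch <- res$scheme
  write_counts(res$counts, file.path(out_dir, "counts_raw.csv"))
  if (!is.null(res$normalized_counts))
    write_counts(res$normalized_counts,
                 file.path(out_dir, "counts_normalized.csv"))
  for (g in names(res$matrices)) {
    write_corr_matrix(res$matrices[[g]],
                      file.path(out_dir, sprintf("correlation_%s.csv", g)))
    write_edge_list(res$networks[[g]],
                    file.path(out_dir, sprintf("edges_%s.csv", g)))
    write_graphml(res$networks[[g]],
                  file.path(out_dir, sprintf("network_%s.graphml", g)))
    mt <- res$metrics[[g]]
    out <- as.data.frame(mt)
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], function(x) sprintf("%.10g", x))
    utils::write.table(out, file.path(out_dir, sprintf("metrics_%s.csv", g)),
                       sep = ",", quote = FALSE, row.names = FALSE)
    pt <- res$partitions[[g]]
    utils::write.table(
      data.frame(region = names(pt$membership),
                 community = unname(pt$membership)),
      file.path(out_dir, sprintf("partition_%s.csv", g)),
      sep = ",", quote = FALSE, row.names = FALSE)
    nc <- res$null_comparisons[[g]]
    if (!isTRUE(nc$skipped))
      utils::write.table(
        data.frame(replicate = seq_along(nc$replicate_efficiencies),
                   efficiency = sprintf("%.10g", nc$replicate_efficiencies)),
        file.path(out_dir, sprintf("null_efficiencies_%s.csv", g)),
        sep = ",", quote = FALSE, row.names = FALSE)
  }
  report <- list(
    seed = res$seed,
    threshold = res$threshold,
    groups = names(res$matrices),
    network_summary = lapply(res$metrics, function(mt) list(
      global_efficiency = attr(mt, "global_efficiency", exact = TRUE),
      clustering_coefficient = attr(mt, "clustering_coefficient", exact = TRUE),
      n_edges = sum(mt$degree) / 2)),
    r_comparisons = lapply(res$r_comparisons, comparison_record),
    metric_comparisons = lapply(res$metric_comparisons, comparison_record),
    null_comparisons = lapply(res$null_comparisons, null_record),
    partitions = lapply(res$partitions, function(p) list(
      n_communities = p$n_communities, modularity = p$modularity,
      membership = as.list(p$membership)))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fos_analysis <- function(x, ...) {
  cat("fosnet analysis\n")
  cat(sprintf("  groups: %s\n", paste(names(x$matrices), collapse = ", ")))
  cat(sprintf("  pooled edge threshold: r > %.4f\n", x$threshold))
  for (g in names(x$networks)) {
    mt <- x$metrics[[g]]
    cat(sprintf("  %s: %d edges, global efficiency %.3f",
                g, nrow(x$networks[[g]]$edges),
                attr(mt, "global_efficiency", exact = TRUE)))
    nc <- x$null_comparisons[[g]]
    if (!isTRUE(nc$skipped))
      cat(sprintf(", null mean diff %.3f [%.3f, %.3f]%s",
                  nc$mean_difference, nc$ci_low, nc$ci_high,
                  if (nc$small_world) " (small-world)" else ""))
    cat("\n")
  }
  invisible(x)
}
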