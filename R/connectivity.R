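#' Interregional correlation matrices
#'
#' Functional coupling between brain regions is estimated as the
#' across-animal Pearson correlation of regional c-fos counts within a
#' group. The matrix diagonal is zeroed by convention (self-correlations
#' carry no information and would distort the pooled edge-threshold).
#'
#' @param table A `fos_counts` table.
#' @param group Group label with at least 3 animals.
#' @return An object of class `fos_corr` with fields `group`, `regions`,
#'   `r` (symmetric matrix, zero diagonal) and `n_animals`.
#' @export
correlation_matrix <- function(table, group) {
  stopifnot(is_count_table(table))
  sel <- table$group == group
  if (!any(sel)) stop("group '", group, "' not present")
  n <- sum(sel)
  if (n < 3L)
    stop("group '", group, "' has only ", n,
         " animals; at least 3 are required for correlations")
  m <- count_matrix(table)[sel, , drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero variance in region(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "),
         " within group ", group)
  r <- stats::cor(m)
  diag(r) <- 0
  structure(list(group = group, regions = colnames(m), r = r,
                 n_animals = n),
            class = "fos_corr")
}

validate_corr <- function(m) {
  stopifnot(inherits(m, "fos_corr"))
  r <- m$r
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12)))
    stop("correlation matrix is not symmetric")
  if (any(diag(r) != 0))
    stop("correlation matrix diagonal must be zero")
  if (any(abs(r) > 1 + 1e-12))
    stop("correlation values must lie in [-1, 1]")
  invisible(m)
}

# index pairs of the upper triangle in row-major order: (1,2),(1,3),...,(2,3),...
upper_pairs <- function(p) {
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p))
  cbind(i, j)
}

#' Off-diagonal correlation values
#'
#' Returns the `p(p-1)/2` upper-triangle correlations in fixed row-major
#' order, labelled by region pair. This is the value list that feeds the
#' pooled threshold and all between-group r comparisons.
#'
#' @param m A `fos_corr` (validated: symmetric, zero diagonal).
#' @return A data frame with columns `region_a`, `region_b`, `r`.
#' @export
offdiagonal_values <- function(m) {
  validate_corr(m)
  p <- length(m$regions)
  ij <- upper_pairs(p)
  data.frame(region_a = m$regions[ij[, 1L]],
             region_b = m$regions[ij[, 2L]],
             r = m$r[ij],
             stringsAsFactors = FALSE)
}

#' Correlation values for a region collection
#'
#' Selects the upper-triangle r values associated with a named collection of
#' the scheme. Under the default `"incident"` rule a pair is included when
#' at least one endpoint belongs to the collection (so a 2-region collection
#' in a 12-region scheme yields 21 values); under `"within"` both endpoints
#' must belong.
#'
#' @param m A `fos_corr`.
#' @param scheme The `fos_scheme` declaring the collection.
#' @param collection Collection name, or `"all"` for every pair.
#' @param rule `"incident"` (default) or `"within"`.
#' @return A data frame with columns `region_a`, `region_b`, `r`.
#' @export
collection_values <- function(m, scheme, collection,
                              rule = c("incident", "within")) {
  rule <- match.arg(rule)
  vals <- offdiagonal_values(m)
  if (identical(collection, "all")) return(vals)
  stopifnot(inherits(scheme, "fos_scheme"))
  if (!collection %in% names(scheme$collections))
    stop("unknown collection: ", collection)
  members <- scheme$collections[[collection]]
  keep <- if (rule == "incident") {
    vals$region_a %in% members | vals$region_b %in% members
  } else {
    vals$region_a %in% members & vals$region_b %in% members
  }
  vals[keep, , drop = FALSE]
}

#' Compare correlation distributions across groups
#'
#' Pools each group's (collection-restricted) upper-triangle r values and
#' runs the omnibus-then-pairwise protocol: Kruskal-Wallis over all groups,
#' followed by unadjusted pairwise Mann-Whitney tests when the omnibus p
#' falls below 0.05. Matrix entries are treated as independent samples — a
#' descriptive convention of the field, not a strictly valid inference.
#'
#' @param matrices List of `fos_corr`, one per group.
#' @param scheme `fos_scheme` (needed unless `collection = "all"`).
#' @param collection Collection name or `"all"`.
#' @param rule Pair-membership rule, see [collection_values()].
#' @return A `fos_group_comparison` (see [group_comparison()]).
#' @export
compare_group_r <- function(matrices, scheme = NULL, collection = "all",
                            rule = c("incident", "within")) {
  rule <- match.arg(rule)
  if (length(matrices) < 2L) stop("need at least two groups to compare")
  samples <- lapply(matrices, function(m)
    collection_values(m, scheme, collection, rule)$r)
  names(samples) <- vapply(matrices, `[[`, "", "group")
  if (any(lengths(samples) == 0L)) stop("empty r-value list")
  group_comparison(samples)
}

#' Write a correlation matrix as CSV (regions in scheme order)
#'
#' @param m A `fos_corr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corr_matrix <- function(m, path) {
  validate_corr(m)
  df <- data.frame(region = m$regions,
                   formatC(m$r, format = "g", digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("region", m$regions)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.fos_corr <- function(x, ...) {
  cat(sprintf("Correlation matrix, group %s (%d animals, %d regions)\n",
              x$group, x$n_animals, length(x$regions)))
  vals <- offdiagonal_values(x)$r
  cat(sprintf("  r: median %.3f, range [%.3f, %.3f]\n",
              stats::median(vals), min(vals), max(vals)))
  invisible(x)
}
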