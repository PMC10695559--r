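#' Region schemes
#'
#' A region scheme fixes the set and order of brain regions used throughout
#' an analysis, together with named "collections" (disjoint groupings of
#' regions whose union is the full region list). The region order determines
#' the row/column order of every correlation matrix and the node order of
#' every network built from it.
#'
#' @param regions Character vector of region names (order is meaningful).
#' @param collections Named list of character vectors; must be pairwise
#'   disjoint and jointly cover `regions`.
#' @return An object of class `fos_scheme` with elements `regions` and
#'   `collections`.
#' @examples
#' sch <- fos_default_scheme()
#' sch$collections$Amyg
#' @export
region_scheme <- function(regions, collections) {
  if (!is.character(regions) || length(regions) < 2L)
    stop("`regions` must be a character vector of at least two region names")
  if (anyDuplicated(regions))
    stop("duplicate region names: ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  if (!is.list(collections) || is.null(names(collections)) ||
      any(names(collections) == ""))
    stop("`collections` must be a named list of region subsets")
  all_members <- unlist(collections, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("collections must be disjoint; shared regions: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  missing <- setdiff(all_members, regions)
  if (length(missing))
    stop("collections mention unknown regions: ",
         paste(missing, collapse = ", "))
  uncovered <- setdiff(regions, all_members)
  if (length(uncovered))
    stop("collections must cover every region; uncovered: ",
         paste(uncovered, collapse = ", "))
  structure(list(regions = regions, collections = collections),
            class = "fos_scheme")
}

#' @describeIn region_scheme The 12-region scheme used for contextual-fear
#'   c-fos mapping: hippocampal fields (DG, CA3, CA1), amygdala nuclei
#'   (BLA, CeA), cortical areas (RSC, IL, PL, Cg1, Cg2) and midline thalamic
#'   nuclei (Re, PV), grouped as Amyg / HPC / PFC / Other.
#' @export
fos_default_scheme <- function() {
  region_scheme(
    regions = c("DG", "CA3", "CA1", "BLA", "CeA", "RSC",
                "IL", "PL", "Cg1", "Cg2", "Re", "PV"),
    collections = list(
      Amyg  = c("BLA", "CeA"),
      HPC   = c("DG", "CA3", "CA1"),
      PFC   = c("PL", "IL", "Cg1", "Cg2"),
      Other = c("RSC", "PV", "Re")
    )
  )
}

#' Read a region scheme from a flat key-value file
#'
#' The format is intentionally minimal (one `key: value` pair per line,
#' comma-separated region lists, `#` comments):
#' ```
#' regions: DG, CA3, CA1, BLA
#' collection.HPC: DG, CA3, CA1
#' collection.Amyg: BLA
#' ```
#'
#' @param path Path to the scheme file.
#' @return A `fos_scheme`.
#' @export
read_scheme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("malformed scheme line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- lapply(kv, function(m) {
    v <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
    v[nzchar(v)]
  })
  names(vals) <- keys
  if (is.null(vals$regions))
    stop("scheme file must declare a `regions:` line")
  coll_keys <- grep("^collection\\.", keys, value = TRUE)
  if (!length(coll_keys))
    stop("scheme file must declare at least one `collection.<name>:` line")
  collections <- vals[coll_keys]
  names(collections) <- sub("^collection\\.", "", coll_keys)
  region_scheme(vals$regions, collections)
}

#' Write a region scheme to the flat key-value format
#'
#' @param scheme A `fos_scheme`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "fos_scheme"))
  lines <- c(
    paste0("regions: ", paste(scheme$regions, collapse = ", ")),
    vapply(names(scheme$collections), function(nm) {
      paste0("collection.", nm, ": ",
             paste(scheme$collections[[nm]], collapse = ", "))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.fos_scheme <- function(x, ...) {
  cat("Region scheme:", length(x$regions), "regions\n")
  cat(" ", paste(x$regions, collapse = ", "), "\n")
  for (nm in names(x$collections))
    cat(sprintf("  %-6s %s\n", nm, paste(x$collections[[nm]], collapse = ", ")))
  invisible(x)
}
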