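#' Count tables
#'
#' A count table holds, per animal, the number of c-fos positive cells in
#' each region of a scheme (one number per animal and region — typically
#' the per-animal mean over at least two bilateral slices) plus a group
#' label. Internally it is a data frame with columns `animal_id`, `group`
#' and one column per region, carrying the scheme and a `normalized` flag
#' as attributes.
#'
#' @param animal_id Character vector of animal identifiers (unique).
#' @param group Character vector of group labels.
#' @param counts Numeric matrix or data frame, one column per region in
#'   scheme order; all values must be non-negative and non-missing.
#' @param scheme A `fos_scheme`.
#' @param groups Optional declared set of admissible group labels; defaults
#'   to the labels present.
#' @param normalized Logical flag; `TRUE` after [normalize_to_control()].
#' @return A data frame of class `fos_counts`.
#' @export
count_table <- function(animal_id, group, counts, scheme,
                        groups = NULL, normalized = FALSE) {
  stopifnot(inherits(scheme, "fos_scheme"))
  counts <- as.data.frame(counts)
  if (!setequal(names(counts), scheme$regions) ||
      ncol(counts) != length(scheme$regions)) {
    missing <- setdiff(scheme$regions, names(counts))
    if (length(missing))
      stop("missing region column(s): ", paste(missing, collapse = ", "))
    stop("count columns do not match the scheme's regions")
  }
  counts <- counts[scheme$regions]  # enforce scheme order
  animal_id <- as.character(animal_id)
  group <- as.character(group)
  if (anyDuplicated(animal_id))
    stop("duplicate animal_id: ",
         paste(unique(animal_id[duplicated(animal_id)]), collapse = ", "))
  if (length(animal_id) != nrow(counts) || length(group) != nrow(counts))
    stop("animal_id, group and counts must have matching lengths")
  for (rg in scheme$regions) {
    v <- counts[[rg]]
    if (!is.numeric(v) || anyNA(v))
      stop("non-numeric or missing count in region ", rg)
    if (any(v < 0)) {
      i <- which(v < 0)[1L]
      stop(sprintf("negative count (%g) for animal %s, region %s",
                   v[i], animal_id[i], rg))
    }
  }
  if (is.null(groups)) groups <- unique(group)
  unknown <- setdiff(group, groups)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unique(unknown), collapse = ", "))
  out <- data.frame(animal_id = animal_id, group = group, counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(out, scheme = scheme, groups = groups,
            normalized = isTRUE(normalized),
            class = c("fos_counts", "data.frame"))
}

#' @rdname count_table
#' @param x Object to test.
#' @export
is_count_table <- function(x) inherits(x, "fos_counts")

count_scheme <- function(table) attr(table, "scheme", exact = TRUE)

count_matrix <- function(table) {
  sch <- count_scheme(table)
  as.matrix(as.data.frame(table)[sch$regions])
}

#' Read a count table from CSV
#'
#' Expects an RFC-4180 CSV with a header row and columns `animal_id`,
#' `group`, plus one column per region of `scheme` (matched
#' case-sensitively; extra columns are an error).
#'
#' @param path Path to the CSV file.
#' @param scheme A `fos_scheme`.
#' @param groups Optional declared group-label set (defaults to the labels
#'   present in the file).
#' @return A `fos_counts` table with `normalized = FALSE`.
#' @export
read_counts <- function(path, scheme, groups = NULL) {
  stopifnot(inherits(scheme, "fos_scheme"))
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, colClasses = NA)
  for (col in c("animal_id", "group"))
    if (!col %in% names(df))
      stop("missing required column: ", col)
  missing <- setdiff(scheme$regions, names(df))
  if (length(missing))
    stop("missing region column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c("animal_id", "group", scheme$regions))
  if (length(extra))
    stop("unexpected column(s): ", paste(extra, collapse = ", "))
  for (rg in scheme$regions) {
    v <- df[[rg]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        i <- which(is.na(vn))[1L]
        stop(sprintf("non-numeric count '%s' at row %d, column %s",
                     v[i], i, rg))
      }
      df[[rg]] <- vn
    }
    if (anyNA(df[[rg]]))
      stop(sprintf("missing count at row %d, column %s",
                   which(is.na(df[[rg]]))[1L], rg))
    if (any(df[[rg]] < 0)) {
      i <- which(df[[rg]] < 0)[1L]
      stop(sprintf("negative count (%g) at row %d, column %s",
                   df[[rg]][i], i, rg))
    }
  }
  count_table(df$animal_id, df$group, df[scheme$regions], scheme,
              groups = groups, normalized = FALSE)
}

#' Write a count table to CSV
#'
#' Numeric values are written with 17 significant digits so that
#' `read_counts(write_counts(x))` round-trips every double exactly.
#'
#' @param table A `fos_counts`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(is_count_table(table))
  sch <- count_scheme(table)
  out <- data.frame(animal_id = table$animal_id, group = table$group,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (rg in sch$regions) out[[rg]] <- sprintf("%.17g", table[[rg]])
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Normalize counts to a control group
#'
#' Divides every region column by the control group's arithmetic mean for
#' that region, so the control group's per-region mean becomes exactly 1.
#' Applying it twice is an error (the flag guards against accidental double
#' normalization).
#'
#' @param table A raw (`normalized = FALSE`) `fos_counts`.
#' @param control_group Label of the control group (must be present).
#' @return A `fos_counts` with `normalized = TRUE`.
#' @export
normalize_to_control <- function(table, control_group) {
  stopifnot(is_count_table(table))
  if (isTRUE(attr(table, "normalized")))
    stop("table is already normalized")
  if (!control_group %in% table$group)
    stop("control group '", control_group, "' not present")
  sch <- count_scheme(table)
  ctrl <- table$group == control_group
  out <- table
  for (rg in sch$regions) {
    m <- mean(table[[rg]][ctrl])
    if (m <= 0)
      stop("degenerate control: mean count for region ", rg,
           " in group ", control_group, " is ", m)
    out[[rg]] <- table[[rg]] / m
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Fear-generalization index
#'
#' The proportion of freezing expressed in the novel context:
#' `B / (A + B)` where `A` is percent time freezing in the trained context
#' and `B` in the novel context. Values near 0.5 and above indicate fear
#' that generalizes beyond the trained context.
#'
#' @param freezing_testA,freezing_testB Percent time freezing (0-100);
#'   vectors of equal length.
#' @return Numeric vector of proportions in `[0, 1]`.
#' @examples
#' generalization_index(30, 10) # 0.25
#' @export
generalization_index <- function(freezing_testA, freezing_testB) {
  a <- freezing_testA; b <- freezing_testB
  if (length(a) != length(b)) stop("inputs must have equal length")
  if (anyNA(a) || anyNA(b)) stop("freezing values must not be NA")
  if (any(a < 0 | a > 100) || any(b < 0 | b > 100))
    stop("freezing percentages must lie in [0, 100]")
  if (any(a + b == 0))
    stop("undefined index: freezing is zero in both tests for entry ",
         which(a + b == 0)[1L])
  b / (a + b)
}

#' @export
print.fos_counts <- function(x, ...) {
  sch <- count_scheme(x)
  cat(sprintf("c-fos count table: %d animals x %d regions%s\n",
              nrow(x), length(sch$regions),
              if (isTRUE(attr(x, "normalized"))) " (control-normalized)" else ""))
  tab <- table(x$group)
  cat("  groups:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  NextMethod()
}
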