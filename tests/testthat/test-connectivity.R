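make_group_table <- function(values, scheme) {
  # values: named list region -> numeric vector (same length = n animals)
  n <- length(values[[1L]])
  count_table(sprintf("a%d", seq_len(n)), rep("g1", n),
              as.data.frame(values), scheme)
}

test_that("correlation_matrix computes Pearson r with zeroed diagonal", {
  sch <- tiny_scheme(2L)
  tbl <- make_group_table(list(A = c(1, 2, 3, 4), B = c(2, 1, 4, 3)), sch)
  m <- correlation_matrix(tbl, "g1")
  expect_equal(m$r["A", "B"], 0.6)  # cov 1 / (sd 1.29 * sd 1.29), by hand
  expect_equal(diag(m$r), c(A = 0, B = 0))
  expect_equal(m$n_animals, 4L)

  anti <- make_group_table(list(A = c(1, 2, 5), B = 11 - 2 * c(1, 2, 5)), sch)
  expect_equal(correlation_matrix(anti, "g1")$r["A", "B"], -1)

  lin <- make_group_table(list(A = c(1, 2, 5), B = 3 * c(1, 2, 5) + 7), sch)
  expect_equal(correlation_matrix(lin, "g1")$r["A", "B"], 1)
})

test_that("correlation_matrix enforces preconditions", {
  sch <- tiny_scheme(2L)
  few <- count_table(c("a1", "a2"), c("g1", "g1"),
                     data.frame(A = c(1, 2), B = c(2, 1)), sch)
  expect_error(correlation_matrix(few, "g1"), "at least 3")
  flat <- make_group_table(list(A = c(1, 1, 1), B = c(2, 1, 4)), sch)
  expect_error(correlation_matrix(flat, "g1"), "zero variance.*A")
})

test_that("correlation is invariant to positive affine rescaling per region", {
  set.seed(11)
  sch <- tiny_scheme(4L)
  vals <- setNames(lapply(1:4, function(i) rnorm(6, 50, 10)), sch$regions)
  m1 <- correlation_matrix(make_group_table(vals, sch), "g1")
  vals2 <- Map(function(v, a, b) a * v + b, vals,
               c(2, 0.5, 10, 1), c(0, 3, -5, 100))
  m2 <- correlation_matrix(make_group_table(vals2, sch), "g1")
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
})

test_that("offdiagonal_values returns p(p-1)/2 values in row-major order", {
  sch <- tiny_scheme(3L)
  m <- structure(list(group = "g", regions = c("A", "B", "C"),
                      r = matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3,
                                 dimnames = list(c("A","B","C"), c("A","B","C"))),
                      n_animals = 5L), class = "fos_corr")
  v <- offdiagonal_values(m)
  expect_equal(v$r, c(0.1, 0.2, 0.3))
  expect_equal(v$region_a, c("A", "A", "B"))
  expect_equal(v$region_b, c("B", "C", "C"))

  for (p in c(2, 5, 12)) {
    sch <- tiny_scheme(p)
    set.seed(p)
    vals <- setNames(lapply(seq_len(p), function(i) rnorm(6, 10, 2)), sch$regions)
    mm <- correlation_matrix(make_group_table(vals, sch), "g1")
    expect_equal(nrow(offdiagonal_values(mm)), p * (p - 1) / 2)
  }

  # an asymmetric matrix is rejected, not silently read from one triangle
  bad <- m
  bad$r[2, 1] <- 0.9
  expect_error(offdiagonal_values(bad), "symmetric")
})

test_that("collection_values implements the incident and within rules", {
  sch <- fos_default_scheme()
  set.seed(3)
  vals <- setNames(lapply(seq_along(sch$regions), function(i) rnorm(8, 10, 2)),
                   sch$regions)
  tbl <- count_table(sprintf("a%d", 1:8), rep("g1", 8),
                     as.data.frame(vals), sch)
  m <- correlation_matrix(tbl, "g1")
  # Amyg = {BLA, CeA}: 1 within pair + 2 * 10 cross pairs = 21 incident pairs
  expect_equal(nrow(collection_values(m, sch, "Amyg")), 21L)
  expect_equal(nrow(collection_values(m, sch, "Amyg", rule = "within")), 1L)
  expect_equal(nrow(collection_values(m, sch, "HPC")), 3 * 9 + 3L)
  expect_equal(collection_values(m, sch, "all"), offdiagonal_values(m))
  expect_error(collection_values(m, sch, "nope"), "unknown collection")

  # singleton collection: 11 incident pairs in a 12-region scheme
  sch2 <- region_scheme(sch$regions,
                        list(RSConly = "RSC",
                             rest = setdiff(sch$regions, "RSC")))
  expect_equal(nrow(collection_values(m, sch2, "RSConly")), 11L)
})

test_that("compare_group_r runs the omnibus-then-pairwise protocol", {
  sch <- tiny_scheme(4L)
  set.seed(21)
  vals <- setNames(lapply(1:4, function(i) rnorm(6, 10, 2)), sch$regions)
  m <- correlation_matrix(make_group_table(vals, sch), "g1")
  m2 <- m; m2$group <- "g2"
  m3 <- m; m3$group <- "g3"
  res <- compare_group_r(list(m, m2, m3))
  expect_equal(res$omnibus$statistic, 0)  # identical matrices
  expect_length(res$pairwise, 0L)

  # fully separated r distributions: U = 0 for the lower group
  lo <- m; lo$r <- m$r * 0 + 0.1; diag(lo$r) <- 0; lo$group <- "lo"
  hi <- m; hi$r <- m$r * 0 + 0.9; diag(hi$r) <- 0; hi$group <- "hi"
  sep <- compare_group_r(list(lo, hi))
  expect_lt(sep$omnibus$p_value, 0.05)
  expect_equal(sep$pairwise[["lo vs hi"]]$statistic, 0)
})
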