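#' Nonparametric group statistics
#'
#' Native implementations of the rank tests used throughout the pipeline,
#' so that tie handling, exact-vs-approximate switching and quantile
#' conventions are fixed properties of this package rather than of whichever
#' statistics library happens to be loaded. The test suite cross-checks them
#' against an independent reference implementation.
#'
#' @name group_stats
NULL

new_test_result <- function(statistic, df, p_value, method, n_per_group) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         method = method, n_per_group = n_per_group),
    class = "fos_test"
  )
}

#' @export
print.fos_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g", x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %d", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  cat("  n =", paste(x$n_per_group, collapse = "/"), "\n")
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus test that k independent samples come from the same distribution.
#' The statistic uses the standard tie correction (division by
#' \eqn{1 - \sum(t^3 - t)/(N^3 - N)}) and is referred to a chi-squared
#' distribution with k-1 degrees of freedom.
#'
#' @param samples A list of numeric vectors, one per group (each non-empty).
#' @return A `fos_test` with fields `statistic` (H), `df`, `p_value`,
#'   `method`, `n_per_group`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic # 7.2
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("`samples` must be a list of at least two groups")
  n <- lengths(samples)
  if (any(n == 0L)) stop("every group must be non-empty")
  x <- unlist(samples, use.names = FALSE)
  if (!is.numeric(x) || anyNA(x)) stop("samples must be numeric without NA")
  g <- rep.int(seq_along(samples), n)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  tie_term <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_term <= 0) {
    # all pooled values identical: no evidence against the null by convention
    H <- 0
    p <- 1
  } else {
    H <- H / tie_term
    p <- stats::pchisq(H, df = length(samples) - 1L, lower.tail = FALSE)
  }
  new_test_result(H, length(samples) - 1L, p,
                  "Kruskal-Wallis rank-sum test", as.integer(n))
}

# Null distribution of the Mann-Whitney U statistic for sample sizes
# (m, n) without ties: counts of rank arrangements with U = 0..m*n via the
# recurrence N[i,j](u) = N[i-1,j](u-j) + N[i,j-1](u) (Gaussian binomial).
# Exact and independent of stats::*wilcox.
mw_null_counts <- function(m, n) {
  prev <- rep(list(1), n + 1L)  # i = 0: U is identically 0 for any j
  for (i in seq_len(m)) {
    cur <- vector("list", n + 1L)
    cur[[1L]] <- 1  # j = 0: U identically 0
    for (j in seq_len(n)) {
      a <- c(numeric(j), prev[[j + 1L]])                 # N[i-1,j] shifted by j
      b <- c(cur[[j]], numeric(length(a) - length(cur[[j]])))  # N[i,j-1] padded
      cur[[j + 1L]] <- a + b
    }
    prev <- cur
  }
  prev[[n + 1L]]
}

#' Mann-Whitney U test
#'
#' Two-sided rank test for two independent samples. The statistic is U for
#' the first sample (number of pairs with a > b, counting ties as 1/2).
#' P-values are exact (from the full null distribution of U) when the
#' combined sample size is at most 20 and there are no ties; otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return A `fos_test` with `statistic` = U for `a`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # exact two-sided 0.1
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(c(a, b))) stop("samples must not contain NA")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (N <= 20 && !has_ties) {
    counts <- mw_null_counts(na, nb)
    total <- sum(counts)
    u <- round(U)
    p <- if (U > na * nb / 2) {
      2 * sum(counts[(u + 1):(na * nb + 1)]) / total
    } else {
      2 * sum(counts[1:(u + 1)]) / total
    }
    p <- min(1, p)
    method <- "Mann-Whitney U test (exact)"
  } else {
    z0 <- U - na * nb / 2
    sigma2 <- (na * nb / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (z0 - sign(z0) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
    method <- "Mann-Whitney U test (normal approximation)"
  }
  new_test_result(U, NULL, p, method, c(na, nb))
}

#' Percentile interval for a difference against a reference value
#'
#' Given a sample of replicate statistics (for example the global
#' efficiencies of null networks) and a single reference value (the observed
#' network's efficiency), forms the per-replicate differences and summarises
#' them by their mean and a central percentile interval. Quantiles use
#' linear interpolation between order statistics (type 7).
#'
#' @param sample Numeric vector of replicate values (length >= 2).
#' @param reference Scalar reference value subtracted from each replicate.
#' @param level Interval coverage, default 0.95.
#' @return A list of class `fos_ci` with `mean_difference`, `ci_low`,
#'   `ci_high`, `level`, `contains_zero`.
#' @export
mean_difference_ci <- function(sample, reference, level = 0.95) {
  if (length(sample) < 2L) stop("`sample` must contain at least two values")
  stopifnot(is.numeric(reference), length(reference) == 1L,
            level > 0, level < 1)
  d <- sample - reference
  alpha <- (1 - level) / 2
  q <- stats::quantile(d, probs = c(alpha, 1 - alpha), type = 7, names = FALSE)
  structure(
    list(mean_difference = mean(d), ci_low = q[1L], ci_high = q[2L],
         level = level, contains_zero = q[1L] <= 0 && 0 <= q[2L]),
    class = "fos_ci"
  )
}

#' @export
print.fos_ci <- function(x, ...) {
  cat(sprintf("mean difference = %.4g, %.0f%% CI [%.4g, %.4g]%s\n",
              x$mean_difference, 100 * x$level, x$ci_low, x$ci_high,
              if (x$contains_zero) " (contains 0)" else ""))
  invisible(x)
}

#' Omnibus-then-pairwise comparison protocol
#'
#' Kruskal-Wallis across all groups; if the omnibus p-value is below
#' `alpha`, all pairwise Mann-Whitney tests are run (unadjusted).
#'
#' @param samples Named list of numeric vectors, one per group.
#' @param alpha Gate for running the post hoc tests (default 0.05).
#' @return A list of class `fos_group_comparison` with `omnibus`
#'   (`fos_test`), `pairwise` (named list of `fos_test`, possibly empty) and
#'   `medians` (named numeric).
#' @export
group_comparison <- function(samples, alpha = 0.05) {
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("`samples` must be a named list")
  omnibus <- kruskal_wallis(samples)
  pairwise <- list()
  if (omnibus$p_value < alpha) {
    cmb <- utils::combn(names(samples), 2L)
    for (i in seq_len(ncol(cmb))) {
      g1 <- cmb[1L, i]; g2 <- cmb[2L, i]
      pairwise[[paste(g1, "vs", g2)]] <-
        mann_whitney(samples[[g1]], samples[[g2]])
    }
  }
  structure(
    list(omnibus = omnibus, pairwise = pairwise,
         medians = vapply(samples, stats::median, 0)),
    class = "fos_group_comparison"
  )
}

#' @export
print.fos_group_comparison <- function(x, ...) {
  cat("Group comparison (Kruskal-Wallis + pairwise Mann-Whitney)\n")
  cat(sprintf("  omnibus: H = %.4g, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  cat("  medians:",
      paste(sprintf("%s = %.3g", names(x$medians), x$medians),
            collapse = ", "), "\n")
  if (length(x$pairwise)) {
    for (nm in names(x$pairwise))
      cat(sprintf("  %s: U = %.4g, p = %.4g\n",
                  nm, x$pairwise[[nm]]$statistic, x$pairwise[[nm]]$p_value))
  } else {
    cat("  (omnibus not significant; no pairwise tests run)\n")
  }
  invisible(x)
}
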