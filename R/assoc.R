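#' First-principles association tests
#'
#' The association machinery is implemented directly from the defining
#' formulas — hypergeometric enumeration for the Fisher exact test, the
#' Pearson chi-square statistic, the midrank Mann-Whitney U with exact
#' enumeration for small untied samples, and the Pearson correlation with
#' its t-distributed significance test. Only distribution tail functions
#' come from base R. Each test returns a `gistddr_test` object with
#' [tidy()] and [glance()] methods.
#'
#' @name association-tests
NULL

new_test_result <- function(statistic, p_value, method, exact, ...) {
  structure(
    c(list(statistic = statistic, p_value = p_value, method = method,
           exact = exact), list(...)),
    class = "gistddr_test"
  )
}

#' @export
print.gistddr_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%s)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "exact" else "approximate"))
  invisible(x)
}

#' @method tidy gistddr_test
#' @export
tidy.gistddr_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p_value,
    estimate = x$estimate %||% NA_real_,
    df = x$df %||% NA_real_,
    method = x$method,
    exact = x$exact
  )
}

#' @method glance gistddr_test
#' @export
glance.gistddr_test <- function(x, ...) tidy(x, ...)

#' Cross-tabulate two categorical variables
#'
#' Builds the r x c count table of label pairs, dropping rows with a
#' missing value in either variable (the dropped count is recorded as an
#' attribute and reported via a message).
#'
#' @param data A tibble.
#' @param row_var,col_var Column names (strings) of categorical variables.
#' @param quiet Suppress the dropped-rows message.
#' @return An integer matrix with dimnames; attributes `n` (rows counted)
#'   and `n_dropped`.
#' @export
crosstab <- function(data, row_var, col_var, quiet = FALSE) {
  assert_columns(data, c(row_var, col_var), "crosstab input")
  if (nrow(data) == 0) {
    stop_gistddr("cannot cross-tabulate an empty table",
                 class = "gistddr_validation_error")
  }
  r <- data[[row_var]]
  cc <- data[[col_var]]
  keep <- !is.na(r) & !is.na(cc)
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    rlang::inform(sprintf("crosstab: dropped %d row(s) with missing %s/%s",
                          n_dropped, row_var, col_var))
  }
  tab <- table(r[keep], cc[keep])
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  attr(out, "n") <- sum(keep)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fisher exact test for a 2 x 2 table
#'
#' Two-sided p-value by the "small-p" rule: with the margins fixed, all
#' tables whose hypergeometric point probability is at most that of the
#' observed table (within a 1e-7 relative slack against floating-point
#' ties) contribute to p. The odds ratio is the cross-product ratio
#' `(a d)/(b c)`, infinite when `b c = 0` with `a d > 0`. A table with any
#' zero margin carries no information: p = 1 and the odds ratio is
#' undefined.
#'
#' @param table A 2 x 2 matrix of non-negative integer counts.
#' @return A `gistddr_test` with `statistic` = odds ratio.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(26, 0, 11, 4), 2, byrow = TRUE))
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + b      # row-1 margin
  n <- c_ + d     # row-2 margin
  k <- a + c_     # column-1 margin
  or <- if (b * c_ == 0) {
    if (a * d > 0) Inf else NA_real_
  } else {
    (a * d) / (b * c_)
  }
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(new_test_result(NA_real_, 1, "Fisher exact (2x2)", TRUE,
                           estimate = NA_real_, or_undefined = TRUE))
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  new_test_result(or, p, "Fisher exact (2x2)", TRUE,
                  estimate = or, or_undefined = FALSE)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with `E` the product-margin expectation and
#' `df = (r - 1)(c - 1)`; no continuity correction. If any expected count
#' is zero the statistic is undefined and an error suggests the Fisher
#' exact test.
#'
#' @param table An r x c matrix of non-negative counts.
#' @return A `gistddr_test` with `statistic` = X^2 and `df`.
#' @export
chi_square <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0))
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected == 0)) {
    stop_gistddr("zero expected count; use fisher_exact_2x2() for sparse 2x2 tables",
                 class = "gistddr_validation_error")
  }
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new_test_result(stat, p, "Pearson chi-square", FALSE, df = df,
                  expected = expected)
}

# Exact two-sided rank-sum p by full enumeration of group assignments:
# the proportion of C(n1+n2, n1) assignments whose U deviates from its null
# mean by at least the observed deviation.
rank_sum_exact_p <- function(ranks, n1) {
  n <- length(ranks)
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  dev <- abs(u_obs - mu)
  combos <- utils::combn(n, n1)
  r_sorted <- sort(ranks)
  u_all <- colSums(matrix(r_sorted[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= dev - 1e-12)
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' The U statistic is computed via midranks, so `U_a + U_b = n1 n2` holds
#' with ties. In `auto` mode the two-sided p-value is exact — by full
#' enumeration of group assignments — when `n1 + n2 <= 12` and the pooled
#' data have no ties; otherwise a normal approximation with tie-adjusted
#' variance and continuity correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A `gistddr_test` with `statistic` = U of `group_a`.
#' @export
#' @examples
#' rank_sum(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
rank_sum <- function(group_a, group_b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 == 0 || n2 == 0) {
    stop_gistddr("both groups must be non-empty", class = "gistddr_validation_error")
  }
  pooled <- c(group_a, group_b)
  ranks <- rank(pooled)                     # midranks
  u <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  n <- n1 + n2

  use_exact <- switch(mode,
                      exact = TRUE,
                      approx = FALSE,
                      auto = n <= 12 && !has_ties)
  if (use_exact) {
    p <- rank_sum_exact_p(ranks, n1)
    return(new_test_result(u, p, "Wilcoxon rank-sum", TRUE, estimate = u))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) {
    return(new_test_result(u, 1, "Wilcoxon rank-sum", FALSE, estimate = u))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
  if (abs(u - mu) < 0.5) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result(u, p, "Wilcoxon rank-sum", FALSE, estimate = u, z = z)
}

#' Pearson correlation with t-based significance
#'
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`,
#' with the two-sided p-value from `t = r sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, each with nonzero
#'   variance.
#' @return A `gistddr_test` with `statistic` = r.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop_gistddr("pearson_r needs aligned vectors of length >= 3",
                 class = "gistddr_validation_error")
  }
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop_gistddr("zero variance in x or y", class = "gistddr_validation_error")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  new_test_result(r, p, "Pearson correlation", FALSE, estimate = r, n = n)
}

#' Select and run the appropriate categorical test
#'
#' Mirrors the reported analysis plan: a 2 x 2 table with any expected
#' count below 5 goes to the Fisher exact test, any other table to the
#' chi-square test (ordinal rows are treated as unordered categories; no
#' trend test). Raw p-values are returned without multiplicity correction.
#'
#' @param table An r x c count matrix.
#' @return A `gistddr_test`.
#' @export
categorical_test <- function(table) {
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (all(dim(table) == 2) && any(expected < 5)) {
    fisher_exact_2x2(table)
  } else {
    chi_square(table)
  }
}
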