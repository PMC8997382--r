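test_that("crosstab counts label pairs and logs dropped rows", {
  d <- tibble::tibble(a = c("x", "x", "y", "y", NA),
                      b = c("p", "q", "p", "p", "q"))
  expect_message(tab <- crosstab(d, "a", "b"), "dropped 1")
  expect_equal(unname(tab), matrix(c(1L, 2L, 1L, 0L), 2), ignore_attr = TRUE)
  expect_equal(attr(tab, "n"), 4L)
  expect_error(crosstab(d[0, ], "a", "b"), class = "gistddr_validation_error")

  # the Table-2 location x RB1 layout
  calls <- readr::read_csv(gistddr_extdata("mlpa_cohort_calls.csv"),
                           show_col_types = FALSE) %>%
    dplyr::mutate(location = binarize_site(site))
  tab2 <- crosstab(calls, "location", "rb1_call", quiet = TRUE)
  expect_equal(unname(tab2[, "normal"]), c(26L, 11L))
  expect_equal(unname(tab2[, "heterozygous_deletion"]), c(0L, 4L))
})

test_that("Fisher exact matches enumeration and the worked example", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p_value, 1)

  res <- fisher_exact_2x2(matrix(c(26, 0, 11, 4), 2, byrow = TRUE))
  expect_lt(abs(res$p_value - 0.013), 0.001)

  perfect <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(perfect$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(perfect$statistic, Inf)

  # zero margin: no information
  degenerate <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(degenerate$p_value, 1)
  expect_true(degenerate$or_undefined)

  # oracle: exhaustive enumeration over random tables with total <= 60,
  # cross-checked against the base implementation
  set.seed(31)
  for (i in 1:30) {
    tab <- matrix(rpois(4, sample(2:12, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_oracle_p(tab), tolerance = 1e-9)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("chi-square reproduces hand computation and base R", {
  # observed equal to expected
  flat <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  res <- chi_square(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)

  balanced <- chi_square(matrix(c(5, 5, 5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(balanced$statistic, 0)

  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 2)
    mine <- chi_square(tab)
    base <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, base$p.value, tolerance = 1e-12)
  }

  expect_error(chi_square(matrix(c(1, 0, 2, 0), 2)),
               class = "gistddr_validation_error")
})

test_that("rank-sum handles exact enumeration, ties and symmetry", {
  exact <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p_value, 0.1)
  expect_true(exact$exact)

  # identical multisets: U at its null mean, p = 1
  same <- rank_sum(c(1, 2, 3), c(1, 2, 3), mode = "exact")
  expect_equal(same$p_value, 1)

  # U_a + U_b = n1 * n2 with midranks, and p is symmetric in the groups
  set.seed(41)
  for (i in 1:20) {
    a <- sample(1:8, sample(3:6, 1), TRUE)
    b <- sample(1:8, sample(3:6, 1), TRUE)
    ra <- rank_sum(a, b, mode = "approx")
    rb <- rank_sum(b, a, mode = "approx")
    expect_equal(ra$statistic + rb$statistic, length(a) * length(b))
    expect_equal(ra$p_value, rb$p_value, tolerance = 1e-12)
  }

  # exact mode equals the independent permutation oracle
  set.seed(42)
  for (i in 1:10) {
    a <- runif(4); b <- runif(5)
    expect_equal(rank_sum(a, b, mode = "exact")$p_value,
                 rank_sum_oracle_p(a, b), tolerance = 1e-12)
  }

  # normal approximation converges to exact for moderate tie-free samples
  set.seed(43)
  for (i in 1:5) {
    a <- rnorm(9); b <- rnorm(8, 0.4)
    p_exact <- rank_sum(a, b, mode = "exact")$p_value
    p_approx <- rank_sum(a, b, mode = "approx")$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }

  expect_error(rank_sum(numeric(0), 1:3), class = "gistddr_validation_error")
})

test_that("Pearson correlation matches the closed form and base R", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$statistic, 1)
  expect_equal(pearson_r(1:10, -(1:10))$statistic, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))$statistic, 0.6,
               tolerance = 1e-12)

  set.seed(13)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  mine <- pearson_r(x, y)
  base <- stats::cor.test(x, y)
  expect_equal(mine$statistic, unname(base$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, base$p.value, tolerance = 1e-10)

  # invariance under positive affine transforms
  expect_equal(pearson_r(3 * x + 7, 0.2 * y - 4)$statistic, mine$statistic,
               tolerance = 1e-12)

  expect_error(pearson_r(rep(1, 5), 1:5), class = "gistddr_validation_error")
  expect_error(pearson_r(1:2, 1:2), class = "gistddr_validation_error")
})

test_that("categorical test selection follows the sparse-table rule", {
  sparse <- matrix(c(26, 0, 11, 4), 2, byrow = TRUE)
  expect_equal(categorical_test(sparse)$method, "Fisher exact (2x2)")
  dense <- matrix(c(30, 25, 20, 35), 2, byrow = TRUE)
  expect_equal(categorical_test(dense)$method, "Pearson chi-square")
  rxc <- matrix(c(10, 2, 8, 4, 6, 6), 3, byrow = TRUE)
  expect_equal(categorical_test(rxc)$method, "Pearson chi-square")
})

test_that("test results tidy into one-row tibbles", {
  td <- tidy(fisher_exact_2x2(matrix(c(5, 1, 2, 6), 2)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("statistic", "p.value", "method") %in% names(td)))
})
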