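test_that("H-score evaluates the shifted intensity-weighted sum", {
  expect_equal(h_score(100, 0, 0, 0), 100)
  expect_equal(h_score(0, 0, 0, 100), 400)
  expect_equal(h_score(50, 20, 20, 10), 190)
  expect_equal(h_score(50, 20, 20, 10, weighting = "conventional"), 90)
  expect_error(h_score(50, 20, 20, 5), class = "gistddr_validation_error")
  expect_error(h_score(-1, 51, 30, 20), class = "gistddr_validation_error")
})

test_that("H-score is bounded and strictly increases when mass shifts upward", {
  set.seed(11)
  for (i in 1:50) {
    p <- as.numeric(stats::rmultinom(1, 100, runif(4)))
    h <- h_score(p[1], p[2], p[3], p[4])
    expect_gte(h, 100)
    expect_lte(h, 400)
    # shift one unit of mass from intensity i to i+1: score rises by exactly 1
    from <- which(p[1:3] > 0)[1]
    if (!is.na(from)) {
      q <- p
      q[from] <- q[from] - 1
      q[from + 1] <- q[from + 1] + 1
      expect_equal(h_score(q[1], q[2], q[3], q[4]), h + 1)
    }
  }
})

test_that("focus positivity uses a strict 1.0 um short-axis threshold", {
  expect_false(if_cell_positive(c(0.5, 0.8)))
  expect_true(if_cell_positive(1.2))
  expect_false(if_cell_positive(numeric(0)))
  expect_false(if_cell_positive(1.0))          # boundary is strict
  expect_error(if_cell_positive(-0.2), class = "gistddr_validation_error")
})

test_that("IF expression percent counts supra-threshold nuclei over >= 100 cells", {
  profiles <- tibble::tibble(
    nucleus_id = sprintf("c%03d", 1:100),
    focus_short_axis_um = NA_real_
  )
  expect_equal(if_expression_percent(profiles)$percent_positive, 0)

  # 200 nuclei, 14 positive -> 7.0%
  prof2 <- tibble::tibble(
    nucleus_id = sprintf("c%03d", 1:200),
    focus_short_axis_um = c(rep(1.4, 14), rep(0.6, 186))
  )
  res <- if_expression_percent(prof2)
  expect_equal(res$percent_positive, 7.0)
  expect_equal(res$n_cells_scored, 200L)

  expect_error(if_expression_percent(profiles[1:99, ]),
               class = "gistddr_insufficient_cells_error")

  # oracle: brute-force recount over per-nucleus maxima agrees
  set.seed(5)
  nuc <- rep(sprintf("n%04d", 1:150), times = sample(1:3, 150, TRUE))
  prof3 <- tibble::tibble(nucleus_id = nuc,
                          focus_short_axis_um = runif(length(nuc), 0, 2))
  manual <- tapply(prof3$focus_short_axis_um, prof3$nucleus_id,
                   function(v) any(v > 1))
  expect_equal(if_expression_percent(prof3)$percent_positive,
               100 * mean(manual))
})

test_that("median dichotomization partitions the cohort with ties to low", {
  out <- dichotomize_at_median(tibble::tibble(tumor_id = 1:4, h_score = 1:4))
  expect_equal(out$level, c("low", "low", "high", "high"))
  expect_equal(out$cutoff, rep(2.5, 4))

  out3 <- dichotomize_at_median(tibble::tibble(tumor_id = 1:3,
                                               h_score = c(100, 200, 300)))
  expect_equal(out3$level, c("low", "low", "high"))

  expect_warning(
    flat <- dichotomize_at_median(tibble::tibble(tumor_id = 1:3, h_score = c(5, 5, 5))),
    class = "gistddr_degenerate_warning"
  )
  expect_true(all(flat$level == "low"))

  # partition property: |low| + |high| = n; balanced for even n, distinct values
  set.seed(21)
  for (i in 1:10) {
    n <- sample(c(10, 20, 50), 1)
    vals <- sample(1000, n)
    cls <- dichotomize_at_median(tibble::tibble(tumor_id = 1:n, h_score = vals))
    expect_equal(sum(cls$level == "low") + sum(cls$level == "high"), n)
    expect_equal(sum(cls$level == "low"), n / 2)
  }
})

test_that("dual-marker grouping maps classes deterministically", {
  g <- dual_group(c("low", "high", "low", "high"), c("low", "low", "high", "high"))
  expect_equal(g$group3, c("neither_high", "one_high", "one_high", "both_high"))
  expect_equal(g$group2, c("double_low", "any_high", "any_high", "any_high"))
  expect_true(is.na(dual_group(NA_character_, "low")$group3[1]))
  # group2 is double_low iff group3 is neither_high
  expect_equal(g$group2 == "double_low", g$group3 == "neither_high")
})

test_that("score_biomarkers assembles per-assay classes and dual groups", {
  st <- synth_study(synth_config(n = 40, seed = 3))
  out <- score_biomarkers(st$ihc)
  expect_setequal(unique(out$scores$marker), c("gH2AX", "TP53BP1"))
  expect_equal(nrow(out$groups), 40)
  # generated intensity tables invert the truth H-scores exactly
  gh <- out$scores[out$scores$marker == "gH2AX", ]
  expect_equal(gh$value[match(st$truth$tumor_id, gh$tumor_id)],
               st$truth$gh2ax_hscore, tolerance = 1e-9)
})
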