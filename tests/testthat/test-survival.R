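test_that("product-limit estimator matches hand-computed small examples", {
  # all censored: S stays at 1
  all_c <- km_fit(c(3, 5, 9), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(all_c), 0)
  expect_equal(km_rate_at(all_c, 4), 100)

  # n = 2: event at 1, censor at 2 -> S(1) = 0.5
  two <- km_fit(c(1, 2), c(TRUE, FALSE))
  expect_equal(two$surv, 0.5)
  expect_equal(km_rate_at(two, 1.5), 50)
  expect_equal(km_rate_at(two, 0), 100)

  # every subject events: S reaches 0 at the last event time
  all_e <- km_fit(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(all_e$surv[3], 0)

  # censored-at-t subjects still count at risk at t
  mix <- km_fit(c(2, 2, 4), c(TRUE, FALSE, TRUE))
  expect_equal(mix$surv, c(2 / 3, 0), tolerance = 1e-12)

  # extrapolation beyond follow-up warns
  expect_warning(km_rate_at(two, 99), class = "gistddr_extrapolation_warning")

  # zero follow-up is shifted to half the smallest positive time
  expect_warning(km_fit(c(0, 2, 3), c(TRUE, FALSE, TRUE)),
                 class = "gistddr_survival_warning")
})

test_that("km agrees with the survival package on random data", {
  set.seed(17)
  time <- round(rexp(40, 0.1), 1) + 0.5
  event <- runif(40) < 0.6
  mine <- km_fit(time, event)
  ref <- survival::survfit(survival::Surv(time, event) ~ 1)
  ref_surv <- summary(ref, times = mine$time)$surv
  expect_equal(mine$surv, ref_surv, tolerance = 1e-12)
})

test_that("log-rank behaves on degenerate and separated groups", {
  # two identical groups: no signal
  t0 <- c(1, 2, 3, 4)
  e0 <- c(TRUE, TRUE, FALSE, TRUE)
  same <- logrank(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  # early events vs late censoring separates clearly at n = 20
  time <- c(1:10, rep(50, 10))
  event <- c(rep(TRUE, 10), rep(FALSE, 10))
  grp <- rep(c("a", "b"), each = 10)
  sep <- logrank(time, event, grp)
  expect_lt(sep$p_value, 0.01)

  expect_error(logrank(1:4, c(TRUE, TRUE, FALSE, TRUE), rep("a", 4)),
               class = "gistddr_validation_error")
})

test_that("log-rank agrees with a permutation oracle and the survival package", {
  set.seed(23)
  time <- round(rexp(26, 0.2), 2) + 0.1
  event <- runif(26) < 0.7
  grp <- rep(c(TRUE, FALSE), each = 13)
  mine <- logrank(time, event, ifelse(grp, "a", "b"))

  ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)

  obs <- logrank_stat_simple(time, event, grp)
  perm <- replicate(10000, logrank_stat_simple(time, event, sample(grp)))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(mine$p_value - p_perm), 0.02)
})

test_that("Cox fit recovers parameters and matches the reference implementation", {
  set.seed(29)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(log(2) * x))
  cens <- runif(n, 0, 40)
  obs <- pmin(time, cens)
  event <- time <= cens
  d <- tibble::tibble(time = obs, event = event, x = as.numeric(x))
  fit <- cox_fit(d, "x")
  expect_true(fit$converged)
  hr <- fit$coefficients$hr
  expect_gt(hr, 1.6)
  expect_lt(hr, 2.5)
  expect_true(fit$coefficients$ci_lower < hr && hr < fit$coefficients$ci_upper)

  ref <- survival::coxph(survival::Surv(obs, event) ~ x, ties = "efron")
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)

  # duplicating every record leaves the estimate unchanged, shrinks the se
  # duplication introduces ties, so under Efron weights the estimate is
  # only near-invariant
  d2 <- dplyr::bind_rows(d, d)
  fit2 <- cox_fit(d2, "x")
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 5e-3)
  expect_lt(fit2$coefficients$se, fit$coefficients$se)
})

test_that("null covariates stay within three standard errors of zero", {
  set.seed(37)
  n <- 300
  x <- rnorm(n)
  time <- rexp(n, 0.08)
  cens <- runif(n, 0, 30)
  d <- tibble::tibble(time = pmin(time, cens), event = time <= cens, x = x)
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$coefficients$estimate), 3 * fit$coefficients$se)
})

test_that("the Cox score test equals the log-rank chi-square when untied", {
  set.seed(53)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.6 * x))   # continuous: no ties
  event <- rep(TRUE, n)
  d <- tibble::tibble(time = time, event = event, x = as.numeric(x))
  fit <- cox_fit(d, "x")
  lr <- logrank(time, event, ifelse(x == 1, "a", "b"))
  expect_lt(abs(fit$score_test - lr$statistic), 1e-6)
})

test_that("degenerate Cox inputs are refused or flagged", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = c(TRUE, TRUE, FALSE, TRUE),
                      x = c(1, 1, 1, 1))
  expect_error(cox_fit(d, "x"), class = "gistddr_validation_error")

  # complete separation: monotone likelihood flagged, no estimates
  sep <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                        event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                        x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(sep, "x")
  expect_true(fit$diverged)
  expect_true(all(is.na(fit$coefficients$estimate)))
})

test_that("the multivariate design follows the reported model structure", {
  st <- synth_study(synth_config(n = 285, seed = 2))
  ann <- dplyr::left_join(classify_risk(st$cohort),
                          score_biomarkers(st$ihc)$groups, by = "tumor_id")
  ann$genotype[1] <- "unknown"
  expect_message(design <- table4_design(ann), "dropped")
  expect_false(any(c("size_cm", "mitotic_count") %in% names(design)))
  expect_equal(sum(design$kit_ex11_del),
               sum(ann$genotype == "kit_ex11_5prime_del" &
                     !ann$nccn_risk %in% c("insufficient_data", "not_assessable")))
  # unassessable NCCN rows are excluded
  expect_lte(nrow(design), nrow(ann))

  # all-spindle cohort: zero-variance histology refused by the fit
  flat <- dplyr::mutate(ann, histology = "spindle")
  dflat <- suppressMessages(table4_design(flat))
  expect_error(cox_fit(dflat, "epithelioid_mixed"),
               class = "gistddr_validation_error")
})
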