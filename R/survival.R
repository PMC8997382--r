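#' Disease-free survival machinery
#'
#' Product-limit (Kaplan-Meier) estimation, the log-rank test, and a Cox
#' proportional-hazards fit with Efron tie handling, implemented directly
#' from the estimating equations. Survival records carry a positive `time`
#' (months), a logical/0-1 `event` (relapse), and optional covariates.
#' Records with zero follow-up are moved to half the smallest positive
#' time with a warning, since the product-limit estimator needs positive
#' times.
#'
#' @name survival-machinery
NULL

prepare_survival <- function(time, event) {
  stopifnot(length(time) == length(event))
  event <- as.logical(event)
  if (any(is.na(time) | is.na(event))) {
    stop_gistddr("missing time or event in survival records",
                 class = "gistddr_validation_error")
  }
  if (any(time < 0)) {
    stop_gistddr("negative survival times", class = "gistddr_validation_error")
  }
  if (any(time == 0)) {
    pos <- time[time > 0]
    if (length(pos) == 0) {
      stop_gistddr("all survival times are zero", class = "gistddr_validation_error")
    }
    rlang::warn(sprintf("%d record(s) with zero follow-up moved to %.4g",
                        sum(time == 0), min(pos) / 2),
                class = "gistddr_survival_warning")
    time[time == 0] <- min(pos) / 2
  }
  list(time = time, event = event)
}

#' Kaplan-Meier product-limit fit
#'
#' `S(t)` is the product of `(1 - d_i / n_i)` over event times up to `t`,
#' where `d_i` is the number of events and `n_i` the number at risk
#' (subjects censored at `t` still count as at risk at `t`). The curve is a
#' right-continuous step function, constant between event times.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical (or 0/1) relapse indicator.
#' @return A `gistddr_km` object: tibble of distinct event times with
#'   `n_risk`, `n_event`, `surv`, plus attributes `n` and `max_time`.
#' @export
#' @examples
#' km_fit(c(1, 2), c(TRUE, FALSE))
km_fit <- function(time, event) {
  s <- prepare_survival(time, event)
  times <- sort(unique(s$time[s$event]))
  rows <- tibble::tibble(
    time = times,
    n_risk = vapply(times, function(t) sum(s$time >= t), integer(1)),
    n_event = vapply(times, function(t) sum(s$time == t & s$event), integer(1))
  )
  rows$surv <- cumprod(1 - rows$n_event / rows$n_risk)
  structure(rows, class = c("gistddr_km", class(rows)),
            n = length(s$time), max_time = max(s$time))
}

#' Survival percentage at a time point
#'
#' `100 * S(t)` using the right-continuous step convention; `t = 0` (or any
#' time before the first event) returns 100. Evaluating beyond the last
#' observed follow-up returns the last value with an extrapolation warning.
#'
#' @param fit A `gistddr_km` object.
#' @param t Non-negative time.
#' @return Survival percent at `t`.
#' @export
km_rate_at <- function(fit, t) {
  stopifnot(inherits(fit, "gistddr_km"), t >= 0)
  if (t > attr(fit, "max_time")) {
    rlang::warn(sprintf("t = %.4g beyond last observed time %.4g; extrapolating",
                        t, attr(fit, "max_time")),
                class = "gistddr_extrapolation_warning")
  }
  i <- findInterval(t, fit$time)
  100 * if (i == 0) 1 else fit$surv[i]
}

#' @method tidy gistddr_km
#' @export
tidy.gistddr_km <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `gistddr_km` object or a named list of them (one per
#'   group).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gistddr_km
#' @export
autoplot.gistddr_km <- function(object, ...) {
  last <- if (nrow(object) > 0) object$surv[nrow(object)] else 1
  df <- tibble::tibble(
    time = c(0, object$time, attr(object, "max_time")),
    surv = c(1, object$surv, last)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "disease-free survival S(t)") +
    ggplot2::theme_minimal()
}

#' Log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled distinct
#' event times, with the hypergeometric variance-covariance of the
#' per-group event counts; `df = groups - 1`.
#'
#' @param time,event Survival records.
#' @param group Group labels (>= 2 non-empty groups; >= 1 event overall).
#' @return A `gistddr_test` with fields `observed` and `expected` per group.
#' @export
logrank <- function(time, event, group) {
  s <- prepare_survival(time, event)
  group <- as.character(group)
  levels <- sort(unique(group))
  k <- length(levels)
  if (k < 2) {
    stop_gistddr("log-rank needs at least two groups",
                 class = "gistddr_validation_error")
  }
  if (!any(s$event)) {
    stop_gistddr("log-rank needs at least one event",
                 class = "gistddr_validation_error")
  }
  g <- match(group, levels)
  times <- sort(unique(s$time[s$event]))
  obs <- exp_ <- numeric(k)
  v <- matrix(0, k - 1, k - 1)
  for (t in times) {
    at_risk <- s$time >= t
    n_t <- sum(at_risk)
    d_t <- sum(s$time == t & s$event)
    n_gt <- tabulate(g[at_risk], nbins = k)
    d_gt <- tabulate(g[s$time == t & s$event], nbins = k)
    obs <- obs + d_gt
    exp_ <- exp_ + d_t * n_gt / n_t
    if (n_t > 1) {
      frac <- n_gt[-k] / n_t
      vt <- d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, nrow = k - 1) - outer(frac, frac))
      v <- v + vt
    }
  }
  z <- (obs - exp_)[-k]
  stat <- tryCatch(as.numeric(t(z) %*% solve(v, z)),
                   error = function(e) {
                     qr_v <- qr(v)
                     as.numeric(t(z) %*% qr.coef(qr_v, z))
                   })
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  new_test_result(stat, p, "log-rank", FALSE, df = k - 1,
                  observed = stats::setNames(obs, levels),
                  expected = stats::setNames(exp_, levels))
}

# Efron partial-likelihood value, score and information at beta.
cox_partial <- function(beta, x, time, event) {
  p <- ncol(x)
  eta <- drop(x %*% beta)
  eta <- eta - max(eta)                      # guard exp overflow
  w <- exp(eta)
  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  for (t in sort(unique(time[event]))) {
    risk <- time >= t
    tied <- time == t & event
    d <- sum(tied)
    s0r <- sum(w[risk]); s0d <- sum(w[tied])
    s1r <- colSums(w[risk] * x[risk, , drop = FALSE])
    s1d <- colSums(w[tied] * x[tied, , drop = FALSE])
    xr <- x[risk, , drop = FALSE]; xd <- x[tied, , drop = FALSE]
    s2r <- crossprod(xr, xr * w[risk])
    s2d <- crossprod(xd, xd * w[tied])
    loglik <- loglik + sum(eta[tied])
    for (l in seq_len(d) - 1) {
      f <- l / d
      denom <- s0r - f * s0d
      num1 <- s1r - f * s1d
      num2 <- s2r - f * s2d
      loglik <- loglik - log(denom)
      score <- score - num1 / denom
      info <- info + num2 / denom - tcrossprod(num1) / denom^2
    }
  }
  score <- score + colSums(x[event, , drop = FALSE])
  list(loglik = loglik, score = score, info = info)
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the Efron-tie partial likelihood;
#' converged when the largest score component falls below `tol` (default
#' 1e-8) within `max_iter` (default 50) iterations. Hazard ratios are
#' `exp(beta)` with Wald 95% confidence intervals `exp(beta +- 1.96 se)`.
#' Monotone likelihood (complete separation) is flagged as divergence and
#' no estimates are reported. The score test statistic at `beta = 0` is
#' returned; with one untied binary covariate it equals the log-rank
#' chi-square.
#'
#' @param data Tibble of survival records and numeric covariates.
#' @param covariates Character vector of covariate column names (each
#'   numeric, nonzero variance).
#' @param time,event Column names of the follow-up time and event flag.
#' @param max_iter,tol Newton-Raphson controls.
#' @return A `gistddr_cox` object with elements `coefficients` (tibble:
#'   term, estimate, hr, se, ci_lower, ci_upper, p.value), `loglik`,
#'   `score_test`, `converged`, `diverged`, `n`, `n_event`.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    max_iter = 50, tol = 1e-8) {
  assert_columns(data, c(time, event, covariates), "survival table")
  keep <- stats::complete.cases(data[, c(time, event, covariates)])
  if (any(!keep)) {
    rlang::inform(sprintf("cox_fit: dropped %d record(s) with missing values",
                          sum(!keep)))
    data <- data[keep, ]
  }
  s <- prepare_survival(data[[time]], data[[event]])
  x <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(x) <- "double"
  if (!any(s$event)) {
    stop_gistddr("cox_fit needs at least one event", class = "gistddr_validation_error")
  }
  novar <- apply(x, 2, function(col) stats::var(col) == 0)
  if (any(novar)) {
    stop_gistddr(sprintf("zero-variance covariate(s): %s",
                         paste(covariates[novar], collapse = ", ")),
                 class = "gistddr_validation_error")
  }
  center <- colMeans(x)
  xc <- sweep(x, 2, center)

  beta <- numeric(ncol(xc))
  at0 <- cox_partial(beta, xc, s$time, s$event)
  score_test <- tryCatch(
    as.numeric(t(at0$score) %*% solve(at0$info, at0$score)),
    error = function(e) NA_real_
  )
  converged <- FALSE
  diverged <- FALSE
  fit <- at0
  for (iter in seq_len(max_iter)) {
    if (max(abs(fit$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(fit$info, fit$score), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    new_beta <- beta + step
    new_fit <- cox_partial(new_beta, xc, s$time, s$event)
    halvings <- 0
    while (new_fit$loglik < fit$loglik - 1e-10 && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_fit <- cox_partial(new_beta, xc, s$time, s$event)
      halvings <- halvings + 1
    }
    beta <- new_beta
    fit <- new_fit
    if (max(abs(beta)) > 15) { diverged <- TRUE; break }
  }
  if (!converged && !diverged && max(abs(fit$score)) < 1e-4) converged <- TRUE
  if (diverged) {
    coefs <- tibble::tibble(term = covariates, estimate = NA_real_, hr = NA_real_,
                            se = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                            p.value = NA_real_)
  } else {
    vcov <- solve(fit$info)
    se <- unname(sqrt(diag(vcov)))
    beta <- unname(beta)
    zval <- beta / se
    coefs <- tibble::tibble(
      term = covariates, estimate = beta, hr = exp(beta), se = se,
      ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
      p.value = 2 * stats::pnorm(-abs(zval))
    )
  }
  structure(
    list(coefficients = coefs, loglik = fit$loglik, score_test = score_test,
         converged = converged && !diverged, diverged = diverged,
         n = length(s$time), n_event = sum(s$event), iterations = iter),
    class = "gistddr_cox"
  )
}

#' @export
print.gistddr_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Efron ties): n = %d, events = %d\n",
              x$n, x$n_event))
  if (x$diverged) {
    cat("monotone likelihood detected; no estimates reported\n")
  } else {
    print(x$coefficients)
  }
  invisible(x)
}

#' @method tidy gistddr_cox
#' @export
tidy.gistddr_cox <- function(x, ...) x$coefficients

#' @method glance gistddr_cox
#' @export
glance.gistddr_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
                 score_test = x$score_test, converged = x$converged,
                 diverged = x$diverged, iterations = x$iterations)
}

#' Plot Cox hazard ratios
#'
#' Forest-style plot of hazard ratios with Wald 95% intervals.
#'
#' @param object A `gistddr_cox` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gistddr_cox
#' @export
autoplot.gistddr_cox <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Multivariate disease-free-survival design matrix
#'
#' Builds the covariate table for the multivariate Cox model: NCCN level
#' dummies against a none/very-low reference, the KIT exon-11 5-prime
#' deletion genotype, epithelioid/mixed histology against spindle,
#' non-gastric location, and the dual-marker expression group. Tumor size
#' and mitotic count are deliberately excluded: both are component factors
#' of the NCCN risk scheme. Records missing any covariate — including the
#' NCCN `insufficient_data`/`not_assessable` levels and tumors without
#' follow-up — are dropped with a log message.
#'
#' @param cohort Cohort annotated with `nccn_risk` (see [classify_risk()])
#'   and a dual-marker `group2` column (see [score_biomarkers()]).
#' @return Tibble with `tumor_id`, `time`, `event` and numeric 0/1
#'   covariate columns `nccn_low`, `nccn_moderate`, `nccn_high`,
#'   `kit_ex11_del`, `epithelioid_mixed`, `non_gastric`, `dual_any_high`.
#' @export
table4_design <- function(cohort) {
  assert_columns(cohort, c("tumor_id", "nccn_risk", "genotype", "histology",
                           "site", "group2", "followup_months", "relapse_event"),
                 "annotated cohort")
  usable <- !is.na(cohort$followup_months) & !is.na(cohort$relapse_event) &
    !cohort$nccn_risk %in% c("insufficient_data", "not_assessable") &
    !is.na(cohort$group2) & cohort$genotype != "unknown"
  if (any(!usable)) {
    rlang::inform(sprintf("table4_design: dropped %d record(s) lacking covariates",
                          sum(!usable)))
  }
  d <- cohort[usable, ]
  tibble::tibble(
    tumor_id = d$tumor_id,
    time = d$followup_months,
    event = as.logical(d$relapse_event),
    nccn_low = as.numeric(d$nccn_risk == "low"),
    nccn_moderate = as.numeric(d$nccn_risk == "moderate"),
    nccn_high = as.numeric(d$nccn_risk == "high"),
    kit_ex11_del = as.numeric(d$genotype == "kit_ex11_5prime_del"),
    epithelioid_mixed = as.numeric(d$histology %in% c("epithelioid", "mixed")),
    non_gastric = as.numeric(binarize_site(d$site) == "non_gastric"),
    dual_any_high = as.numeric(d$group2 == "any_high")
  )
}
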