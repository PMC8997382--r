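# Small in-code fixtures shared across test files.

tiny_cohort <- function() {
  tibble::tibble(
    tumor_id = c("T1", "T2", "T3"),
    age = c(55, 62, 71),
    sex = c("male", "female", "male"),
    site = c("gastric", "intestinal", "gastric"),
    size_cm = c(3.2, 8.5, 1.4),
    mitotic_count = c(2, 12, 1),
    histology = c("spindle", "epithelioid", "spindle"),
    specimen = c("primary_resection", "primary_resection", "primary_resection"),
    genotype = c("kit_ex11_5prime_del", "other_mutant", "wild_type"),
    followup_months = c(24, 10, 60),
    relapse_event = c(FALSE, TRUE, FALSE)
  )
}

tiny_panel <- function() {
  tibble::tibble(
    probe_id = c("A1", "A2", "B1", "r1", "r2"),
    gene = c("RB1", "RB1", "CHEK2", NA, NA),
    exon = c("e1", "e2", "e1", NA, NA),
    amplicon_size = c(130, 150, 170, 120, 200),
    is_reference = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

# Long peak table for one tumor + one reference normal, single replicate,
# areas chosen so every normalized signal is exactly `dq_by_probe`.
peaks_from_dq <- function(dq_by_probe, panel = tiny_panel()) {
  probe_ids <- panel$probe_id
  ref <- tibble::tibble(
    sample_id = "NORM", role = "reference_normal", replicate = 1L,
    probe_id = probe_ids, peak_area = 100
  )
  area <- rep(100, length(probe_ids))
  names(area) <- probe_ids
  area[names(dq_by_probe)] <- 100 * dq_by_probe
  tum <- tibble::tibble(
    sample_id = "TUM", role = "tumor", replicate = 1L,
    probe_id = probe_ids, peak_area = unname(area[probe_ids])
  )
  dplyr::bind_rows(tum, ref)
}

# Long call table from the packaged 41-sample MLPA summary file.
mlpa_calls_long_fixture <- function() {
  readr::read_csv(gistddr_extdata("mlpa_cohort_calls.csv"),
                  show_col_types = FALSE, progress = FALSE) %>%
    tidyr::pivot_longer(cols = dplyr::ends_with("_call"), names_to = "gene",
                        values_to = "call") %>%
    dplyr::mutate(gene = toupper(sub("_call$", "", gene))) %>%
    dplyr::select(sample_id, gene, call)
}

# Independent Fisher oracle: enumerate margin-fixed tables with choose().
fisher_oracle_p <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Independent rank-sum oracle: enumerate assignments of the pooled values.
rank_sum_oracle_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  mu <- n1 * (n - n1) / 2
  dev <- abs(u_of(seq_len(n1)) - mu)
  combos <- utils::combn(n, n1)
  devs <- apply(combos, 2, function(idx) abs(u_of(idx) - mu))
  mean(devs >= dev - 1e-12)
}

# Independent log-rank statistic for the permutation oracle (two groups).
logrank_stat_simple <- function(time, event, grp) {
  o <- e <- v <- 0
  for (t in sort(unique(time[event]))) {
    at <- time >= t
    n_t <- sum(at); n1 <- sum(at & grp)
    d_t <- sum(time == t & event)
    d1 <- sum(time == t & event & grp)
    o <- o + d1
    e <- e + d_t * n1 / n_t
    if (n_t > 1) {
      v <- v + d_t * (n_t - d_t) / (n_t - 1) * (n1 / n_t) * (1 - n1 / n_t)
    }
  }
  (o - e)^2 / v
}
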