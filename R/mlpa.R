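#' MLPA dosage-quotient analysis
#'
#' Multiplex ligation-dependent probe amplification (MLPA) measures relative
#' gene dosage from probe peak areas. Within each sample the gene-specific
#' peak areas are normalized by the average of the reference-probe areas
#' (probes targeting loci on other chromosomes, size-adjusted); the dosage
#' quotient (DQ) of a probe is the normalized tumor value divided by the
#' corresponding value of the pooled normal reference. A DQ near 1 indicates
#' two copies; `DQ <= 0.7` is read as heterozygous deletion, `DQ >= 1.3` as
#' heterozygous duplication, and a median DQ at or near zero as homozygous
#' deletion.
#'
#' Expected tables: a probe panel (`probe_id`, `gene`, `exon`,
#' `amplicon_size`, `is_reference`) and a long peak table (`sample_id`,
#' `role` = `tumor`/`reference_normal`, `replicate`, `probe_id`,
#' `peak_area`).
#'
#' @name mlpa
NULL

validate_panel <- function(panel) {
  assert_columns(panel, c("probe_id", "gene", "exon", "amplicon_size", "is_reference"),
                 "probe panel")
  if (anyDuplicated(panel$probe_id) > 0) {
    stop_gistddr("probe_id must be unique in the panel",
                 class = "gistddr_validation_error")
  }
  if (sum(panel$is_reference) < 2) {
    stop_gistddr("panel must contain at least 2 reference probes",
                 class = "gistddr_validation_error")
  }
  invisible(panel)
}

# Per-reference-probe scaling factors: the mean peak area of each reference
# probe across the reference_normal samples. Dividing by these factors puts
# reference probes of different amplicon sizes on a common scale before they
# are averaged (amplicon size biases raw peak area); a data-driven
# equalization rather than an explicit size-response curve.
reference_scaling <- function(peaks, panel) {
  ref_ids <- panel$probe_id[panel$is_reference]
  normals <- dplyr::filter(peaks, .data$role == "reference_normal",
                           .data$probe_id %in% ref_ids,
                           !is.na(.data$peak_area), .data$peak_area > 0)
  if (nrow(normals) == 0) {
    return(tibble::tibble(probe_id = ref_ids, scale = 1))
  }
  normals %>%
    dplyr::group_by(.data$probe_id) %>%
    dplyr::summarise(scale = mean(.data$peak_area), .groups = "drop")
}

#' Normalize one sample's peak areas
#'
#' Divides each probe's raw peak area by the mean of the sample's
#' size-adjusted reference-probe areas. The result is scale invariant:
#' multiplying every area of the sample by a constant leaves it unchanged.
#' Reference probes with zero or missing area are excluded with a warning
#' as long as at least one informative reference probe remains.
#'
#' @param areas Named numeric vector of peak areas (names = probe ids).
#' @param panel Probe panel tibble.
#' @param ref_scale Optional tibble (`probe_id`, `scale`) of reference-probe
#'   scaling factors; unit scaling when omitted.
#' @return Named numeric vector of normalized signals (all panel probes).
#' @export
#' @examples
#' panel <- tibble::tibble(
#'   probe_id = c("A", "r1", "r2"), gene = c("RB1", NA, NA),
#'   exon = c("e1", NA, NA), amplicon_size = c(200, 150, 300),
#'   is_reference = c(FALSE, TRUE, TRUE)
#' )
#' normalize_sample(c(A = 200, r1 = 100, r2 = 300), panel) # A = 1
normalize_sample <- function(areas, panel, ref_scale = NULL) {
  validate_panel(panel)
  ref_ids <- panel$probe_id[panel$is_reference]
  scale <- stats::setNames(rep(1, length(ref_ids)), ref_ids)
  if (!is.null(ref_scale)) {
    scale[ref_scale$probe_id] <- ref_scale$scale
  }
  ref_areas <- areas[ref_ids]
  usable <- !is.na(ref_areas) & ref_areas > 0
  if (!any(usable)) {
    stop_gistddr("all reference probes zero or missing; cannot normalize",
                 class = "gistddr_normalization_error")
  }
  if (!all(usable)) {
    rlang::warn(sprintf("excluding %d uninformative reference probe(s): %s",
                        sum(!usable), paste(ref_ids[!usable], collapse = ", ")),
                class = "gistddr_mlpa_warning")
  }
  denom <- mean(ref_areas[usable] / scale[ref_ids][usable])
  out <- areas[panel$probe_id] / denom
  stats::setNames(as.numeric(out), panel$probe_id)
}

# Normalize every sample x replicate of a long peak table.
normalize_peaks <- function(peaks, panel) {
  ref_scale <- reference_scaling(peaks, panel)
  peaks %>%
    dplyr::group_by(.data$sample_id, .data$role, .data$replicate) %>%
    dplyr::group_modify(function(d, key) {
      areas <- stats::setNames(d$peak_area, d$probe_id)
      norm <- normalize_sample(areas[panel$probe_id], panel, ref_scale)
      tibble::tibble(probe_id = names(norm), normalized = norm)
    }) %>%
    dplyr::ungroup()
}

#' Compute per-probe dosage quotients
#'
#' Normalizes every sample, builds the pooled reference (per-probe mean of
#' the normalized `reference_normal` samples), and divides each tumor
#' sample's normalized signal by it, per replicate. Replicate DQs are then
#' averaged; probes whose replicates disagree by more than
#' `replicate_tol` are flagged discordant and excluded from downstream
#' calling. Probes with a zero pooled-reference value are flagged
#' uninformative.
#'
#' @param peaks Long peak table (see [mlpa]).
#' @param panel Probe panel tibble.
#' @param replicate_tol Maximum allowed spread between replicate DQs
#'   (default 0.3).
#' @return Tibble `sample_id`, `probe_id`, `gene`, `exon`, `dq`,
#'   `informative` (logical; FALSE for discordant or reference-zero probes).
#' @export
compute_dq <- function(peaks, panel, replicate_tol = 0.3) {
  validate_panel(panel)
  assert_columns(peaks, c("sample_id", "role", "replicate", "probe_id", "peak_area"),
                 "peak table")
  if (!any(peaks$role == "reference_normal")) {
    stop_gistddr("peak table must contain at least one reference_normal sample",
                 class = "gistddr_validation_error")
  }
  norm <- normalize_peaks(peaks, panel)
  pooled <- norm %>%
    dplyr::filter(.data$role == "reference_normal") %>%
    dplyr::group_by(.data$probe_id) %>%
    dplyr::summarise(ref_norm = mean(.data$normalized), .groups = "drop")

  per_rep <- norm %>%
    dplyr::filter(.data$role == "tumor") %>%
    dplyr::left_join(pooled, by = "probe_id") %>%
    dplyr::mutate(dq = ifelse(.data$ref_norm > 0,
                              .data$normalized / .data$ref_norm, NA_real_))

  per_rep %>%
    dplyr::group_by(.data$sample_id, .data$probe_id) %>%
    dplyr::summarise(
      spread = if (sum(!is.na(.data$dq)) > 1) diff(range(.data$dq, na.rm = TRUE)) else 0,
      dq = mean(.data$dq),
      .groups = "drop"
    ) %>%
    dplyr::mutate(informative = !is.na(.data$dq) & .data$spread <= replicate_tol) %>%
    dplyr::left_join(dplyr::select(panel, "probe_id", "gene", "exon"),
                     by = "probe_id") %>%
    dplyr::filter(!is.na(.data$gene)) %>%
    dplyr::select("sample_id", "probe_id", "gene", "exon", "dq", "informative")
}

#' Copy-number call from per-probe DQs, median mode
#'
#' Used for genes with several exon probes (RB1, BRCA2): the median DQ
#' across informative probes is compared against the thresholds — at or
#' below `homdel_tol` ("equal to or near zero") is homozygous deletion,
#' at or below 0.7 heterozygous deletion, at or above 1.3 heterozygous
#' duplication, otherwise normal.
#'
#' @param dqs Numeric vector of informative per-probe DQs for one gene.
#' @param homdel_tol Median DQ at or below this is called homozygous
#'   deletion (default 0.2).
#' @param del_cut,dup_cut Heterozygous deletion/duplication thresholds
#'   (defaults 0.7 and 1.3).
#' @return One-row tibble `call`, `median_dq`, `n_probes`.
#' @export
#' @examples
#' call_gene_median(c(0.55, 0.60, 0.80)) # heterozygous_deletion
call_gene_median <- function(dqs, homdel_tol = 0.2, del_cut = 0.7, dup_cut = 1.3) {
  dqs <- dqs[!is.na(dqs)]
  if (length(dqs) == 0) {
    return(tibble::tibble(call = "no_call", median_dq = NA_real_, n_probes = 0L))
  }
  m <- stats::median(dqs)
  call <- if (m <= homdel_tol) "homozygous_deletion"
  else if (m <= del_cut) "heterozygous_deletion"
  else if (m >= dup_cut) "heterozygous_duplication"
  else "normal"
  tibble::tibble(call = call, median_dq = m, n_probes = length(dqs))
}

#' Copy-number call from per-probe DQs, any-probe mode
#'
#' Used for CHEK2, whose panel carries probes only for the representative
#' exons 1 and 9: any probe at or below the deletion threshold calls a
#' heterozygous deletion; otherwise any probe at or above the duplication
#' threshold calls a duplication. Deletion takes precedence when both
#' patterns occur (the deletion is the reported event); such mixed
#' patterns are flagged.
#'
#' @inheritParams call_gene_median
#' @return One-row tibble `call`, `median_dq`, `n_probes`, `mixed_pattern`.
#' @export
call_gene_anyprobe <- function(dqs, del_cut = 0.7, dup_cut = 1.3) {
  dqs <- dqs[!is.na(dqs)]
  if (length(dqs) == 0) {
    return(tibble::tibble(call = "no_call", median_dq = NA_real_,
                          n_probes = 0L, mixed_pattern = FALSE))
  }
  has_del <- any(dqs <= del_cut)
  has_dup <- any(dqs >= dup_cut)
  call <- if (has_del) "heterozygous_deletion"
  else if (has_dup) "heterozygous_duplication"
  else "normal"
  tibble::tibble(call = call, median_dq = stats::median(dqs),
                 n_probes = length(dqs), mixed_pattern = has_del && has_dup)
}

#' Call gene copy state for every tumor sample
#'
#' Runs [compute_dq()] and applies the per-gene calling mode: any-probe for
#' genes listed in `anyprobe_genes` (default CHEK2), median otherwise.
#'
#' @inheritParams compute_dq
#' @param anyprobe_genes Genes called in any-probe mode.
#' @param homdel_tol Homozygous-deletion threshold for median mode.
#' @return Tibble `sample_id`, `gene`, `call`, `median_dq`, `n_probes`.
#' @export
mlpa_call <- function(peaks, panel, anyprobe_genes = "CHEK2",
                      homdel_tol = 0.2, replicate_tol = 0.3) {
  dq <- compute_dq(peaks, panel, replicate_tol = replicate_tol)
  dq %>%
    dplyr::filter(.data$informative) %>%
    dplyr::group_by(.data$sample_id, .data$gene) %>%
    dplyr::group_modify(function(d, key) {
      if (key$gene %in% anyprobe_genes) {
        call_gene_anyprobe(d$dq)[, c("call", "median_dq", "n_probes")]
      } else {
        call_gene_median(d$dq, homdel_tol = homdel_tol)
      }
    }) %>%
    dplyr::ungroup()
}

#' Cohort prevalence of MLPA copy calls
#'
#' Per-gene counts and percentages of heterozygous deletions (one decimal,
#' half-up, matching clinical-report rounding), plus pairwise co-deletion
#' counts.
#'
#' @param calls Tibble `sample_id`, `gene`, `call` (from [mlpa_call()] or an
#'   encoded call table).
#' @return List with tibbles `per_gene` (`gene`, `n_called`, `n_hetdel`,
#'   `percent_hetdel`) and `co_deletion` (`gene_a`, `gene_b`, `n_co`,
#'   `percent_co`).
#' @export
summarize_mlpa <- function(calls) {
  assert_columns(calls, c("sample_id", "gene", "call"), "call table")
  n_samples <- dplyr::n_distinct(calls$sample_id)
  per_gene <- calls %>%
    dplyr::filter(.data$call != "no_call") %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_called = dplyr::n(),
      n_hetdel = sum(.data$call == "heterozygous_deletion"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(percent_hetdel = purrr::map2_dbl(.data$n_hetdel, .data$n_called,
                                                   report_percent))
  genes <- sort(unique(per_gene$gene))
  pairs <- if (length(genes) >= 2) utils::combn(genes, 2, simplify = FALSE) else list()
  co <- purrr::map_dfr(pairs, function(p) {
    dels <- calls %>%
      dplyr::filter(.data$gene %in% p, .data$call == "heterozygous_deletion")
    both <- dels %>%
      dplyr::distinct(.data$sample_id, .data$gene) %>%
      dplyr::count(.data$sample_id) %>%
      dplyr::filter(.data$n == 2)
    tibble::tibble(gene_a = p[1], gene_b = p[2], n_co = nrow(both),
                   percent_co = report_percent(nrow(both), n_samples))
  })
  list(per_gene = per_gene, co_deletion = co, n_samples = n_samples)
}
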