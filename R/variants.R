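#' Variant triage and aberration matrices
#'
#' Pre-annotated NGS variant tables (one row per variant call, annotation
#' columns already populated — no live database queries) are filtered on
#' allele fraction, screened for presumed germline polymorphisms, and
#' classified by an ordered pathogenicity rule set. Copy-number records are
#' mapped to discrete copy states, and both event streams are assembled into
#' a gene-by-sample aberration matrix grouped by DNA-damage-repair pathway.
#'
#' @name variant-triage
NULL

variant_effects <- c("missense", "nonsense", "frameshift", "splice_site",
                     "inframe_indel", "synonymous", "other")

#' Allele-fraction and population-frequency filter
#'
#' Retains variants with allele fraction at or above `min_af` (default 5%,
#' inclusive). Variants whose maximum population allele frequency exceeds
#' `max_popfreq` are excluded as presumed germline polymorphisms. Variants
#' with missing allele fraction are excluded with a warning.
#'
#' @param variants Tibble with at least `sample_id`, `gene`, `af`;
#'   optionally `popfreq_max`.
#' @param min_af Minimum somatic allele fraction, inclusive (default 0.05).
#' @param max_popfreq Population-frequency ceiling for the germline screen
#'   (default 0.01).
#' @return The retained rows, same schema. Idempotent.
#' @export
frequency_filter <- function(variants, min_af = 0.05, max_popfreq = 0.01) {
  assert_columns(variants, c("sample_id", "gene", "af"), "variant table")
  if (any(is.na(variants$af))) {
    rlang::warn(sprintf("excluding %d variant(s) with missing allele fraction",
                        sum(is.na(variants$af))),
                class = "gistddr_variant_warning")
  }
  keep <- !is.na(variants$af) & variants$af >= min_af
  if ("popfreq_max" %in% names(variants)) {
    keep <- keep & !(!is.na(variants$popfreq_max) & variants$popfreq_max > max_popfreq)
  }
  variants[keep, ]
}

#' Ordered pathogenicity classification
#'
#' Applies the triage rules in order; exactly one fires per variant, and the
#' fired rule is recorded for audit:
#' 1. A cancer-recurrent COSMIC identifier, or a frameshift, nonsense or
#'    splice-site effect, is `deleterious`.
#' 2. Damaging annotations — OncoKB oncogenic/likely oncogenic, SIFT
#'    deleterious, PolyPhen probably damaging, or a Grantham score above
#'    `grantham_cut` — give `probably_damaging`.
#' 3. A possibly-damaging PolyPhen annotation gives `vus` (variant of
#'    unknown significance).
#' 4. Everything else is `likely_benign`.
#'
#' @param variants A tibble of retained variants; recognized optional
#'   annotation columns: `cosmic_id`, `effect`, `oncokb_class`, `sift_call`,
#'   `polyphen_call`, `grantham_score`.
#' @param grantham_cut Grantham score above which a missense change counts
#'   as damaging (default 100).
#' @return The input with `pathogenicity` and `rule_fired` columns appended.
#' @export
classify_pathogenicity <- function(variants, grantham_cut = 100) {
  assert_columns(variants, c("sample_id", "gene", "effect"), "variant table")
  bad <- !variants$effect %in% variant_effects
  if (any(bad)) {
    stop_gistddr(sprintf("unknown effect value(s): %s",
                         paste(unique(variants$effect[bad]), collapse = ", ")),
                 class = "gistddr_validation_error")
  }
  col <- function(name) {
    if (name %in% names(variants)) variants[[name]] else rep(NA, nrow(variants))
  }
  cosmic <- !is.na(col("cosmic_id")) & col("cosmic_id") != ""
  truncating <- variants$effect %in% c("frameshift", "nonsense", "splice_site")
  damaging <- (!is.na(col("oncokb_class")) &
                 col("oncokb_class") %in% c("oncogenic", "likely_oncogenic")) |
    (!is.na(col("sift_call")) & col("sift_call") == "deleterious") |
    (!is.na(col("polyphen_call")) & col("polyphen_call") == "probably_damaging") |
    (!is.na(col("grantham_score")) & col("grantham_score") > grantham_cut)
  possibly <- !is.na(col("polyphen_call")) & col("polyphen_call") == "possibly_damaging"

  cls <- dplyr::case_when(
    cosmic | truncating ~ "deleterious",
    damaging ~ "probably_damaging",
    possibly ~ "vus",
    TRUE ~ "likely_benign"
  )
  rule <- dplyr::case_when(
    cosmic ~ "rule1: cancer-recurrent COSMIC id",
    truncating ~ "rule1: truncating effect",
    damaging ~ "rule2: damaging in-silico/knowledge-base annotation",
    possibly ~ "rule3: possibly damaging -> VUS",
    TRUE ~ "rule4: default likely benign"
  )
  dplyr::mutate(variants, pathogenicity = cls, rule_fired = rule)
}

#' Copy-number value to copy-state label
#'
#' Integer copy number mapped to a discrete state: 0 homozygous deletion,
#' 1 heterozygous deletion, 2 neutral, `gain_range` (default 3--5) gain,
#' and at or above `amp_min` (default 6) amplification. The defaults
#' bracket the anchor observations copy number 4 = gain and 7 =
#' amplification symmetrically.
#'
#' @param copy_number Non-negative integer vector.
#' @param gain_range Inclusive copy-number range called `gain`.
#' @param amp_min Minimum copy number called `amplification`.
#' @return Character vector of states `HomDel`, `HetDel`, `neutral`,
#'   `gain`, `amplification`.
#' @export
#' @examples
#' cnv_to_call(c(0, 1, 2, 4, 7))
cnv_to_call <- function(copy_number, gain_range = c(3, 5), amp_min = 6) {
  stopifnot(all(copy_number >= 0))
  dplyr::case_when(
    copy_number == 0 ~ "HomDel",
    copy_number == 1 ~ "HetDel",
    copy_number == 2 ~ "neutral",
    copy_number >= amp_min ~ "amplification",
    copy_number >= gain_range[1] & copy_number <= gain_range[2] ~ "gain",
    TRUE ~ "neutral"
  )
}

#' Assemble the gene-by-sample aberration matrix
#'
#' Unions classified SNV/indel events and copy-state events into one cell
#' per gene and sample (long form plus a nested cell-set view). SNVs
#' classed `deleterious`/`probably_damaging` are recorded as
#' `deleterious_snv`, `vus` as `vus_snv`; likely-benign variants carry no
#' event. Genes are ordered by event prevalence within pathway blocks,
#' drivers first; genes missing from the pathway map fall into an `other`
#' block with a warning. Contradictory copy states for one gene/sample
#' (deletion and gain/amplification together) raise a validation error.
#'
#' @param variants Classified variant tibble (from
#'   [classify_pathogenicity()]); may be empty.
#' @param cnv Tibble `sample_id`, `gene`, `copy_number`; may be empty.
#' @param pathway_map Named character vector or tibble (`gene`, `pathway`)
#'   assigning each gene to a pathway block (e.g. `damage_sensing`,
#'   `homologous_recombination`, `fanconi_anemia`, `NER`, `NHEJ`, `RB1`,
#'   `driver`).
#' @param samples Optional character vector fixing the full sample set
#'   (columns), so samples without events still appear.
#' @return An object of class `aberration_matrix`: a list with `events`
#'   (long tibble `sample_id`, `gene`, `pathway`, `event`), `genes`
#'   (ordered), `samples`, `n_samples`.
#' @export
build_matrix <- function(variants, cnv, pathway_map, samples = NULL) {
  if (is.data.frame(pathway_map)) {
    pathway_map <- stats::setNames(pathway_map$pathway, pathway_map$gene)
  }
  snv_events <- if (!is.null(variants) && nrow(variants) > 0) {
    assert_columns(variants, c("sample_id", "gene", "pathogenicity"), "variant table")
    variants %>%
      dplyr::filter(.data$pathogenicity != "likely_benign") %>%
      dplyr::transmute(
        sample_id = as.character(.data$sample_id), gene = .data$gene,
        event = ifelse(.data$pathogenicity == "vus", "vus_snv", "deleterious_snv")
      )
  } else {
    tibble::tibble(sample_id = character(), gene = character(), event = character())
  }
  cnv_events <- if (!is.null(cnv) && nrow(cnv) > 0) {
    assert_columns(cnv, c("sample_id", "gene", "copy_number"), "CNV table")
    cnv %>%
      dplyr::transmute(sample_id = as.character(.data$sample_id), gene = .data$gene,
                       event = cnv_to_call(.data$copy_number)) %>%
      dplyr::filter(.data$event != "neutral")
  } else {
    tibble::tibble(sample_id = character(), gene = character(), event = character())
  }

  contradiction <- cnv_events %>%
    dplyr::distinct(.data$sample_id, .data$gene, .data$event) %>%
    dplyr::group_by(.data$sample_id, .data$gene) %>%
    dplyr::summarise(
      bad = any(.data$event %in% c("HetDel", "HomDel")) &&
        any(.data$event %in% c("gain", "amplification")),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$bad)
  if (nrow(contradiction) > 0) {
    stop_gistddr(
      sprintf("contradictory copy states for %s",
              paste(sprintf("%s/%s", contradiction$sample_id, contradiction$gene),
                    collapse = ", ")),
      class = "gistddr_validation_error"
    )
  }

  events <- dplyr::distinct(dplyr::bind_rows(snv_events, cnv_events))
  unknown <- setdiff(unique(events$gene), names(pathway_map))
  if (length(unknown) > 0) {
    rlang::warn(sprintf("gene(s) not in pathway map placed in 'other' block: %s",
                        paste(unknown, collapse = ", ")),
                class = "gistddr_variant_warning")
  }
  events$pathway <- unname(pathway_map[events$gene])
  events$pathway[is.na(events$pathway)] <- "other"

  samples <- samples %||% sort(unique(events$sample_id))
  block_order <- c("driver", "damage_sensing", "homologous_recombination",
                   "fanconi_anemia", "NER", "NHEJ", "RB1", "other")
  gene_order <- events %>%
    dplyr::count(.data$pathway, .data$gene, name = "n_events") %>%
    dplyr::mutate(block = match(.data$pathway, block_order)) %>%
    dplyr::arrange(.data$block, dplyr::desc(.data$n_events), .data$gene)

  structure(
    list(events = events, genes = gene_order$gene, samples = samples,
         n_samples = length(samples)),
    class = "aberration_matrix"
  )
}

#' @export
print.aberration_matrix <- function(x, ...) {
  cat(sprintf("<aberration_matrix: %d genes x %d samples, %d events>\n",
              length(x$genes), x$n_samples, nrow(x$events)))
  invisible(x)
}

#' Prevalence of an event in the aberration matrix
#'
#' @param matrix An `aberration_matrix`.
#' @param gene Gene symbol.
#' @param event Event label (e.g. `"HetDel"`); or `"co_HetDel"` with
#'   `gene` a character vector of length 2 to count joint carriers.
#' @return One-row tibble `gene`, `event`, `n_carriers`, `n_samples`,
#'   `percent` (one decimal, half-up).
#' @export
matrix_prevalence <- function(matrix, gene, event = "HetDel") {
  stopifnot(inherits(matrix, "aberration_matrix"))
  if (length(gene) == 2) {
    carriers <- purrr::map(gene, function(g) {
      unique(matrix$events$sample_id[matrix$events$gene == g &
                                       matrix$events$event == event])
    })
    n <- length(intersect(carriers[[1]], carriers[[2]]))
    lab <- paste(gene, collapse = "+")
  } else {
    if (!gene %in% matrix$events$gene) {
      rlang::warn(sprintf("gene %s absent from matrix; zero prevalence", gene),
                  class = "gistddr_variant_warning")
    }
    n <- dplyr::n_distinct(matrix$events$sample_id[matrix$events$gene == gene &
                                                     matrix$events$event == event])
    lab <- gene
  }
  tibble::tibble(gene = lab, event = event, n_carriers = n,
                 n_samples = matrix$n_samples,
                 percent = report_percent(n, matrix$n_samples))
}

#' Plot an aberration matrix as an oncoprint-style grid
#'
#' @param object An `aberration_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aberration_matrix
#' @export
autoplot.aberration_matrix <- function(object, ...) {
  df <- object$events %>%
    dplyr::mutate(gene = factor(.data$gene, levels = rev(object$genes)),
                  sample_id = factor(.data$sample_id, levels = object$samples))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene,
                                   fill = .data$event)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.3) +
    ggplot2::labs(x = "sample", y = NULL, fill = "event") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
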