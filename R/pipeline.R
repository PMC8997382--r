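#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
gistddr_extdata <- function(file) {
  system.file("extdata", file, package = "gistddr", mustWork = TRUE)
}

read_mlpa_call_table <- function(path = gistddr_extdata("mlpa_cohort_calls.csv")) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

mlpa_calls_long <- function(tbl) {
  tbl %>%
    tidyr::pivot_longer(cols = dplyr::ends_with("_call"), names_to = "gene",
                        values_to = "call") %>%
    dplyr::mutate(gene = toupper(sub("_call$", "", .data$gene))) %>%
    dplyr::select("sample_id", "gene", "call")
}

read_ngs_tables <- function(cnv_path = gistddr_extdata("ngs_cnv.tsv"),
                            variant_path = gistddr_extdata("ngs_variants.tsv")) {
  cnv <- readr::read_tsv(cnv_path, show_col_types = FALSE, progress = FALSE)
  variants <- readr::read_tsv(variant_path, show_col_types = FALSE, progress = FALSE)
  list(cnv = cnv, variants = variants,
       samples = sort(union(cnv$sample_id, variants$sample_id)))
}

ngs_matrix <- function() {
  ngs <- read_ngs_tables()
  triaged <- ngs$variants %>%
    frequency_filter() %>%
    classify_pathogenicity()
  build_matrix(triaged, ngs$cnv, default_pathway_map(), samples = ngs$samples)
}

printed_recipes <- function() {
  counts_training <- function() {
    readr::read_csv(gistddr_extdata("training_biomarker_counts.csv"),
                    show_col_types = FALSE, progress = FALSE)
  }
  counts_tma <- function() {
    readr::read_csv(gistddr_extdata("tma_biomarker_counts.csv"),
                    show_col_types = FALSE, progress = FALSE)
  }
  counts_surv <- function() {
    readr::read_csv(gistddr_extdata("tma_survival_counts.csv"),
                    show_col_types = FALSE, progress = FALSE)
  }
  mlpa_summary <- function() summarize_mlpa(mlpa_calls_long(read_mlpa_call_table()))
  gene_pct <- function(summary, gene) {
    summary$per_gene$percent_hetdel[summary$per_gene$gene == gene]
  }
  list(
    mlpa_prevalence_chek2 = function() gene_pct(mlpa_summary(), "CHEK2"),
    mlpa_prevalence_rb1 = function() gene_pct(mlpa_summary(), "RB1"),
    mlpa_prevalence_brca2 = function() gene_pct(mlpa_summary(), "BRCA2"),
    mlpa_codeletion_count = function() {
      co <- mlpa_summary()$co_deletion
      co$n_co[co$gene_a == "BRCA2" & co$gene_b == "RB1"]
    },
    mlpa_n_samples = function() mlpa_summary()$n_samples,
    ngs_prevalence_chek2 = function() matrix_prevalence(ngs_matrix(), "CHEK2")$percent,
    ngs_prevalence_rb1 = function() matrix_prevalence(ngs_matrix(), "RB1")$percent,
    ngs_prevalence_brca2 = function() matrix_prevalence(ngs_matrix(), "BRCA2")$percent,
    ngs_codeletion_pct = function() {
      matrix_prevalence(ngs_matrix(), c("RB1", "BRCA2"))$percent
    },
    fisher_location_rb1 = function() {
      tbl <- read_mlpa_call_table() %>%
        dplyr::mutate(location = binarize_site(.data$site))
      fisher_exact_2x2(crosstab(tbl, "location", "rb1_call", quiet = TRUE))$p_value
    },
    training_nih_lowverylow_marginal = function() {
      d <- counts_training()
      row <- d[d$parameter == "nih" & d$level == "low_very_low", ]
      row$gh2ax_ihc_low + row$gh2ax_ihc_high
    },
    training_n = function() {
      d <- counts_training()
      sum(d[d$parameter == "sex", c("gh2ax_ihc_low", "gh2ax_ihc_high")])
    },
    tma_n = function() {
      d <- counts_tma()
      sum(d[d$parameter == "sex", c("gh2ax_ihc_low", "gh2ax_ihc_high")])
    },
    tma_kit_ex11_n = function() {
      d <- counts_surv()
      d$n_case[d$parameter == "genotype" & d$level == "kit_ex11_del"]
    }
  )
}

#' Recompute printed summary values
#'
#' Executes each target's named recipe against the encoded report tables
#' shipped with the package (MLPA call table, NGS aberration tables,
#' biomarker and survival count tables) and compares the result with the
#' expected value at the stated tolerance. Unknown recipes are reported as
#' `unevaluable`, not failed.
#'
#' @param targets A targets tibble (`id`, `recipe`, `expected`,
#'   `tolerance`) or path to such a CSV; default: the packaged target
#'   list.
#' @return Tibble `id`, `recipe`, `expected`, `computed`, `tolerance`,
#'   `status` (`pass`/`fail`/`unevaluable`).
#' @export
#' @examples
#' reproduce_printed()
reproduce_printed <- function(targets = gistddr_extdata("printed_targets.csv")) {
  if (is.character(targets)) {
    targets <- readr::read_csv(targets, show_col_types = FALSE, progress = FALSE)
  }
  assert_columns(targets, c("id", "recipe", "expected", "tolerance"), "targets")
  recipes <- printed_recipes()
  purrr::pmap_dfr(targets, function(id, recipe, expected, tolerance, ...) {
    if (!recipe %in% names(recipes)) {
      return(tibble::tibble(id = id, recipe = recipe, expected = expected,
                            computed = NA_real_, tolerance = tolerance,
                            status = "unevaluable"))
    }
    computed <- as.numeric(recipes[[recipe]]())
    ok <- abs(computed - expected) <= tolerance + 1e-12
    tibble::tibble(id = id, recipe = recipe, expected = expected,
                   computed = computed, tolerance = tolerance,
                   status = ifelse(ok, "pass", "fail"))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — biomarker scoring, MLPA dosage calling,
#' risk classification, association testing, disease-free-survival
#' analysis — on whatever inputs are supplied. Missing inputs skip their
#' stage with an explicit entry in the skip log; the report is a pure
#' function of the inputs.
#'
#' @param cohort A validated cohort tibble (or path to a cohort CSV).
#' @param ihc Optional IHC intensity table.
#' @param if_foci Optional IF foci table.
#' @param mlpa_peaks,mlpa_panel Optional MLPA peak table and probe panel.
#' @param variants,cnv Optional annotated variant and copy-number tables.
#' @param pathway_map Gene-to-pathway map for the aberration matrix.
#' @return A `gistddr_report` list with blocks `risk`, `biomarkers`,
#'   `mlpa`, `aberrations`, `associations`, `survival`, plus `skipped`
#'   and `log`.
#' @export
run_pipeline <- function(cohort, ihc = NULL, if_foci = NULL,
                         mlpa_peaks = NULL, mlpa_panel = NULL,
                         variants = NULL, cnv = NULL,
                         pathway_map = default_pathway_map()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  skipped <- character(0)
  log <- character(0)
  say <- function(stage, msg) {
    log <<- c(log, sprintf("[%s] %s", stage, msg))
  }

  # score
  biomarkers <- NULL
  if (!is.null(ihc)) {
    biomarkers <- score_biomarkers(ihc, if_foci)
    say("score", sprintf("scored %d tumors", dplyr::n_distinct(ihc$tumor_id)))
  } else {
    skipped <- c(skipped, "biomarkers")
    say("score", "skipped: no IHC input")
  }

  # call
  mlpa <- NULL
  if (!is.null(mlpa_peaks)) {
    calls <- mlpa_call(mlpa_peaks, mlpa_panel %||% default_panel())
    mlpa <- list(calls = calls, summary = summarize_mlpa(calls))
    say("call", sprintf("called %d samples", dplyr::n_distinct(calls$sample_id)))
  } else {
    skipped <- c(skipped, "mlpa")
    say("call", "skipped: no MLPA input")
  }
  aberrations <- NULL
  if (!is.null(cnv) || !is.null(variants)) {
    triaged <- if (!is.null(variants)) {
      classify_pathogenicity(frequency_filter(variants))
    } else NULL
    aberrations <- build_matrix(triaged, cnv, pathway_map)
    say("call", sprintf("aberration matrix: %d events", nrow(aberrations$events)))
  } else {
    skipped <- c(skipped, "aberrations")
  }

  # classify
  annotated <- classify_risk(cohort)
  risk <- list(
    nih = dplyr::count(annotated, .data$nih_risk),
    nccn = dplyr::count(annotated, .data$nccn_risk)
  )
  say("classify", sprintf("classified %d tumors", nrow(annotated)))

  # associate
  associations <- NULL
  if (!is.null(biomarkers)) {
    ann <- dplyr::left_join(annotated, biomarkers$groups, by = "tumor_id")
    marker_ihc <- biomarkers$scores %>%
      dplyr::filter(.data$assay == "ihc") %>%
      dplyr::select("tumor_id", "marker", "level") %>%
      tidyr::pivot_wider(names_from = "marker", values_from = "level")
    ann <- dplyr::left_join(ann, marker_ihc, by = "tumor_id")
    assoc_one <- function(marker_col) {
      d <- ann[!is.na(ann$nccn_joint), ]
      tab <- crosstab(d, "nccn_joint", marker_col, quiet = TRUE)
      list(table = tab, test = categorical_test(tab))
    }
    associations <- list(
      gh2ax_vs_joint_risk = assoc_one("gH2AX"),
      bp1_vs_joint_risk = assoc_one("TP53BP1")
    )
    say("associate", "tested marker classes against joint risk groups")
  } else {
    skipped <- c(skipped, "associations")
    say("associate", "skipped: needs biomarker scores")
  }

  # survive
  surv <- NULL
  has_fu <- !is.na(cohort$followup_months) & !is.na(cohort$relapse_event)
  if (any(has_fu) && !is.null(biomarkers)) {
    ann2 <- dplyr::left_join(annotated, biomarkers$groups, by = "tumor_id")
    design <- table4_design(ann2)
    km_all <- km_fit(design$time, design$event)
    lr <- tryCatch(
      logrank(design$time, design$event,
              ifelse(design$dual_any_high == 1, "any_high", "double_low")),
      gistddr_error = function(e) NULL
    )
    covs <- c("nccn_low", "nccn_moderate", "nccn_high", "kit_ex11_del",
              "epithelioid_mixed", "non_gastric", "dual_any_high")
    cox <- tryCatch(cox_fit(design, covs), gistddr_error = function(e) NULL)
    surv <- list(km = km_all, logrank_dual = lr, cox = cox, design = design)
    say("survive", sprintf("fit DFS models on %d records (%d events)",
                           nrow(design), sum(design$event)))
  } else {
    skipped <- c(skipped, "survival")
    say("survive", "skipped: needs follow-up and biomarker groups")
  }

  structure(
    list(risk = risk, biomarkers = biomarkers, mlpa = mlpa,
         aberrations = aberrations, associations = associations,
         survival = surv, skipped = skipped, log = log,
         annotated_cohort = annotated),
    class = "gistddr_report"
  )
}

#' @export
print.gistddr_report <- function(x, ...) {
  cat("<gistddr_report>\n")
  for (line in x$log) cat(" ", line, "\n")
  if (length(x$skipped) > 0) {
    cat("  skipped blocks:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
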