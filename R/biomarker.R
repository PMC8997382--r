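#' Immunohistochemistry H-score
#'
#' The H-score combines staining intensity and the percentage of stained
#' tumor cells: \eqn{\sum_i P_i (i + 1)} where `i` is the nuclear staining
#' intensity (0 to 3+) and `P_i` the percentage of tumor cells at that
#' intensity. Because the weight is `i + 1`, the score ranges from 100
#' (all cells unstained) to 400 (all cells 3+), not the conventional
#' 0--300; `weighting = "conventional"` switches to \eqn{\sum_i P_i\, i}
#' for sensitivity checks.
#'
#' @param p0,p1,p2,p3 Percentages of tumor cells at intensities 0..3
#'   (each in \[0, 100\], summing to 100; vectorized).
#' @param weighting `"shifted"` (default, weights `i + 1`) or
#'   `"conventional"` (weights `i`).
#' @return Numeric H-score(s).
#' @export
#' @examples
#' h_score(50, 20, 20, 10) # 190
h_score <- function(p0, p1, p2, p3, weighting = c("shifted", "conventional")) {
  weighting <- match.arg(weighting)
  p <- cbind(p0, p1, p2, p3)
  if (any(p < 0 | p > 100)) {
    stop_gistddr("intensity percentages must lie in [0, 100]",
                 class = "gistddr_validation_error")
  }
  tot <- rowSums(p)
  if (any(abs(tot - 100) > 1e-9)) {
    stop_gistddr("intensity percentages must sum to 100",
                 class = "gistddr_validation_error")
  }
  w <- if (weighting == "shifted") 1:4 else 0:3
  as.numeric(p %*% w)
}

#' Score an IHC intensity table
#'
#' @param ihc Tibble with columns `tumor_id`, `marker`, `p0`, `p1`, `p2`,
#'   `p3` (one consensus intensity distribution per tumor and marker).
#' @inheritParams h_score
#' @return Tibble `tumor_id`, `marker`, `h_score`.
#' @export
score_ihc <- function(ihc, weighting = c("shifted", "conventional")) {
  weighting <- match.arg(weighting)
  assert_columns(ihc, c("tumor_id", "marker", "p0", "p1", "p2", "p3"), "IHC table")
  dplyr::transmute(
    ihc,
    tumor_id = as.character(.data$tumor_id),
    marker = .data$marker,
    h_score = h_score(.data$p0, .data$p1, .data$p2, .data$p3, weighting = weighting)
  )
}

#' Immunofluorescence focus positivity of one nucleus
#'
#' A nucleus counts as positive when it exhibits at least one concrete
#' focus whose short axis strictly exceeds the threshold (default 1.0 um);
#' faint or hazy staining, encoded as sub-threshold foci, never counts.
#'
#' @param focus_short_axes Numeric vector of focus short-axis lengths in um
#'   for one nucleus; empty means no foci.
#' @param min_short_axis_um Positivity threshold (strict `>`), default 1.0.
#' @return Logical scalar.
#' @export
if_cell_positive <- function(focus_short_axes, min_short_axis_um = 1.0) {
  focus_short_axes <- focus_short_axes[!is.na(focus_short_axes)]
  if (any(focus_short_axes < 0)) {
    stop_gistddr("focus short-axis lengths must be non-negative",
                 class = "gistddr_validation_error")
  }
  any(focus_short_axes > min_short_axis_um)
}

#' Immunofluorescence expression percentage
#'
#' Percentage of nuclei exhibiting at least one supra-threshold focus,
#' computed over a minimum of 100 scored cells per sample.
#'
#' @param profiles Tibble in long format with columns `nucleus_id` and
#'   `focus_short_axis_um` (one row per focus; nuclei without foci appear
#'   once with `NA` in the focus column).
#' @inheritParams if_cell_positive
#' @return One-row tibble with `percent_positive` and `n_cells_scored`.
#' @export
if_expression_percent <- function(profiles, min_short_axis_um = 1.0) {
  assert_columns(profiles, c("nucleus_id", "focus_short_axis_um"), "IF profile table")
  by_cell <- dplyr::summarise(
    dplyr::group_by(profiles, .data$nucleus_id),
    positive = if_cell_positive(.data$focus_short_axis_um, min_short_axis_um),
    .groups = "drop"
  )
  n <- nrow(by_cell)
  if (n < 100) {
    stop_gistddr(sprintf("IF scoring requires at least 100 cells, got %d", n),
                 class = "gistddr_insufficient_cells_error")
  }
  tibble::tibble(
    percent_positive = 100 * sum(by_cell$positive) / n,
    n_cells_scored = n
  )
}

#' Score an IF foci table
#'
#' @param if_foci Long-format tibble with columns `tumor_id`, `marker`,
#'   `nucleus_id`, `focus_short_axis_um`.
#' @inheritParams if_cell_positive
#' @return Tibble `tumor_id`, `marker`, `percent_positive`, `n_cells_scored`.
#' @export
score_if <- function(if_foci, min_short_axis_um = 1.0) {
  assert_columns(if_foci, c("tumor_id", "marker", "nucleus_id", "focus_short_axis_um"),
                 "IF table")
  if_foci %>%
    dplyr::group_by(tumor_id = as.character(.data$tumor_id), marker = .data$marker) %>%
    dplyr::group_modify(~ if_expression_percent(.x, min_short_axis_um)) %>%
    dplyr::ungroup()
}

#' Dichotomize scores at the cohort median
#'
#' Splits per-tumor scores at their sample median (mean of the middle two
#' for even n). Ties at the cutoff go to `low` (`value <= median`), so an
#' odd-sized cohort with a unique median places the median tumor in the low
#' group; the cutoff used is recorded alongside each class.
#'
#' @param scores Tibble with columns `tumor_id` and a score column.
#' @param value Name of the score column (default `"h_score"`).
#' @return Tibble `tumor_id`, `level` (`low`/`high`), `cutoff`.
#' @export
#' @examples
#' dichotomize_at_median(tibble::tibble(tumor_id = 1:4, h_score = c(1, 2, 3, 4)))
dichotomize_at_median <- function(scores, value = "h_score") {
  assert_columns(scores, c("tumor_id", value), "score table")
  x <- scores[[value]]
  if (length(x) < 2) {
    stop_gistddr("median dichotomization needs at least 2 tumors",
                 class = "gistddr_validation_error")
  }
  cutoff <- stats::median(x)
  if (all(x == x[1])) {
    rlang::warn("all scores identical; every tumor classified low",
                class = "gistddr_degenerate_warning")
  }
  tibble::tibble(
    tumor_id = as.character(scores$tumor_id),
    level = ifelse(x <= cutoff, "low", "high"),
    cutoff = cutoff
  )
}

#' Dual-marker expression group
#'
#' Combines the median-dichotomized classes of gamma-H2AX and 53BP1 into
#' the three-level group (`neither_high`, `one_high`, `both_high`) and its
#' two-level collapse (`double_low` vs `any_high`) used for the
#' disease-free-survival comparisons.
#'
#' @param level_gh2ax,level_53bp1 Character vectors of `low`/`high` classes
#'   (vectorized, aligned).
#' @return Tibble with columns `group3` and `group2`; `NA` rows where either
#'   marker class is missing.
#' @export
dual_group <- function(level_gh2ax, level_53bp1) {
  n_high <- (level_gh2ax == "high") + (level_53bp1 == "high")
  group3 <- dplyr::case_match(n_high,
                              0 ~ "neither_high",
                              1 ~ "one_high",
                              2 ~ "both_high")
  tibble::tibble(
    group3 = group3,
    group2 = ifelse(is.na(group3), NA_character_,
                    ifelse(group3 == "neither_high", "double_low", "any_high"))
  )
}

#' Full biomarker scoring stage
#'
#' Scores IHC and (optionally) IF tables, dichotomizes each marker at the
#' cohort median per assay, and forms the dual-marker groups from the IHC
#' classes.
#'
#' @param ihc IHC intensity table (see [score_ihc()]).
#' @param if_foci Optional IF foci table (see [score_if()]).
#' @inheritParams score_ihc
#' @return A list with tibbles `scores` (long: tumor, marker, assay, value,
#'   level, cutoff) and `groups` (tumor_id, group3, group2).
#' @export
score_biomarkers <- function(ihc, if_foci = NULL,
                             weighting = c("shifted", "conventional")) {
  weighting <- match.arg(weighting)
  ihc_scores <- score_ihc(ihc, weighting) %>%
    dplyr::rename(value = "h_score") %>%
    dplyr::mutate(assay = "ihc")
  scores <- ihc_scores
  if (!is.null(if_foci)) {
    if_scores <- score_if(if_foci) %>%
      dplyr::transmute(.data$tumor_id, .data$marker, value = .data$percent_positive,
                       assay = "if")
    scores <- dplyr::bind_rows(scores, if_scores)
  }
  classed <- scores %>%
    dplyr::group_by(.data$marker, .data$assay) %>%
    dplyr::group_modify(function(d, key) {
      cls <- dichotomize_at_median(d, value = "value")
      dplyr::left_join(d, cls, by = "tumor_id")
    }) %>%
    dplyr::ungroup()

  ihc_wide <- classed %>%
    dplyr::filter(.data$assay == "ihc") %>%
    dplyr::select("tumor_id", "marker", "level") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "level")
  groups <- dplyr::bind_cols(
    ihc_wide["tumor_id"],
    dual_group(ihc_wide[["gH2AX"]], ihc_wide[["TP53BP1"]])
  )
  list(scores = classed, groups = groups)
}
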