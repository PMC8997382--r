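#' Load a risk rule table
#'
#' The NIH consensus and NCCN (AFIP) stratification rules are shipped as
#' editable YAML grids under `inst/extdata` ("rules as data"), so the encoded
#' guideline edition is auditable and swappable without touching code.
#'
#' @param scheme `"nih"` or `"nccn"`.
#' @param path Optional path to an alternative YAML rule file.
#' @return A list with breakpoints and the level grid.
#' @export
load_risk_table <- function(scheme = c("nih", "nccn"), path = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(path)) {
    path <- system.file("extdata", paste0("risk_", scheme, ".yaml"),
                        package = "gistddr", mustWork = TRUE)
  }
  tbl <- yaml::read_yaml(path)
  if (!identical(tbl$scheme, scheme)) {
    stop_gistddr(sprintf("rule file at %s encodes scheme '%s', not '%s'",
                         path, tbl$scheme, scheme),
                 class = "gistddr_config_error")
  }
  tbl
}

# Bin index with upper-inclusive breaks: value <= breaks[1] -> 1, etc.
risk_bin <- function(x, breaks) {
  findInterval(x, breaks, left.open = TRUE) + 1L
}

#' NIH consensus risk level
#'
#' Deterministic lookup of tumor size and mitotic count in the encoded NIH
#' consensus grid. The table is total: every positive size and non-negative
#' count maps to a level.
#'
#' @param size_cm Tumor size in cm (positive; vectorized).
#' @param mitotic_count Mitoses per 50 HPF (non-negative; vectorized).
#' @param table Rule table from [load_risk_table()]; loaded on demand.
#' @return Character vector of levels among
#'   `very_low`, `low`, `intermediate`, `high`.
#' @export
#' @examples
#' nih_risk(c(1.5, 12, 4), c(2, 2, 8))
nih_risk <- function(size_cm, mitotic_count, table = NULL) {
  table <- table %||% load_risk_table("nih")
  stopifnot(all(size_cm > 0), all(mitotic_count >= 0))
  grid <- do.call(rbind, table$levels)
  i <- risk_bin(size_cm, table$size_breaks_cm)
  j <- risk_bin(mitotic_count, table$mitosis_breaks_per50hpf)
  grid[cbind(i, j)]
}

#' NCCN (AFIP) risk level
#'
#' Site-specific lookup in the encoded AFIP grid; non-gastric sites use the
#' small-intestine column. Cells the source series could not estimate return
#' `insufficient_data`.
#'
#' @param site Schema site labels (or already-binarized
#'   `gastric`/`non_gastric`); vectorized.
#' @inheritParams nih_risk
#' @return Character vector of levels among `none`, `very_low`, `low`,
#'   `moderate`, `high`, `insufficient_data`.
#' @export
#' @examples
#' nccn_risk(c("gastric", "intestinal", "gastric"), c(1.8, 11, 4), c(3, 2, 9))
nccn_risk <- function(site, size_cm, mitotic_count, table = NULL) {
  table <- table %||% load_risk_table("nccn")
  stopifnot(all(size_cm > 0), all(mitotic_count >= 0))
  n <- max(length(site), length(size_cm), length(mitotic_count))
  site <- rep_len(site, n)
  size_cm <- rep_len(size_cm, n)
  mitotic_count <- rep_len(mitotic_count, n)
  column <- binarize_site(site)
  i <- risk_bin(size_cm, table$size_breaks_cm)
  j <- risk_bin(mitotic_count, table$mitosis_breaks_per50hpf)
  purrr::map_chr(seq_along(i), function(k) {
    table$levels[[column[k]]][[i[k]]][[j[k]]]
  })
}

#' Joint risk group
#'
#' Collapses risk levels into the two-group comparison used in the
#' association and survival analyses: `none`, `very_low` and `low` form one
#' joint group; `moderate`/`intermediate` and `high` the other.
#' Unassessable levels (`not_assessable`, `insufficient_data`) return `NA`.
#'
#' @param level Character vector of NIH or NCCN risk levels.
#' @return Character vector with values `none_verylow_low`, `moderate_high`
#'   or `NA`.
#' @export
joint_group <- function(level) {
  dplyr::case_match(
    level,
    c("none", "very_low", "low") ~ "none_verylow_low",
    c("moderate", "intermediate", "high") ~ "moderate_high",
    .default = NA_character_
  )
}

#' Classify a cohort under both risk schemes
#'
#' Adds `nih_risk`, `nccn_risk` and joint-group columns to a cohort.
#' Biopsy, recurrence and metastasis specimens are not amenable to
#' resection-based risk stratification and are coded `not_assessable`.
#'
#' @param cohort A validated cohort tibble.
#' @return The cohort with columns `nih_risk`, `nccn_risk`,
#'   `nih_joint`, `nccn_joint` appended.
#' @export
classify_risk <- function(cohort) {
  validate_cohort(cohort)
  assessable <- cohort$specimen == "primary_resection"
  out <- dplyr::mutate(
    cohort,
    nih_risk = ifelse(assessable,
                      nih_risk(.data$size_cm, .data$mitotic_count),
                      "not_assessable"),
    nccn_risk = ifelse(assessable,
                       nccn_risk(.data$site, .data$size_cm, .data$mitotic_count),
                       "not_assessable")
  )
  dplyr::mutate(out,
                nih_joint = joint_group(.data$nih_risk),
                nccn_joint = joint_group(.data$nccn_risk))
}
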