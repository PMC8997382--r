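#' Clinicopathologic cohort tables
#'
#' A cohort is an ordinary tibble with one row per tumor and a fixed schema:
#' `tumor_id` (unique character), `age` (years), `sex` (`male`/`female`),
#' `site` (`gastric`/`intestinal`/`omental`/`other`), `size_cm` (positive),
#' `mitotic_count` (non-negative integer per 50 high-power fields),
#' `histology` (`spindle`/`epithelioid`/`mixed`), `specimen`
#' (`primary_resection`/`biopsy`/`recurrence`/`metastasis`), `genotype`
#' (`kit_ex11_5prime_del`/`other_mutant`/`wild_type`/`unknown`), and the
#' optional follow-up pair `followup_months` (non-negative) and
#' `relapse_event` (logical), which must be present or absent together
#' within a row.
#'
#' @name cohort-schema
NULL

cohort_levels <- list(
  sex       = c("male", "female"),
  site      = c("gastric", "intestinal", "omental", "other"),
  histology = c("spindle", "epithelioid", "mixed"),
  specimen  = c("primary_resection", "biopsy", "recurrence", "metastasis"),
  genotype  = c("kit_ex11_5prime_del", "other_mutant", "wild_type", "unknown")
)

cohort_columns <- c(
  "tumor_id", "age", "sex", "site", "size_cm", "mitotic_count",
  "histology", "specimen", "genotype", "followup_months", "relapse_event"
)

#' Validate a cohort tibble
#'
#' Checks every row against the cohort schema: categorical fields must come
#' from their closed vocabularies (no silent coercion), `size_cm > 0`,
#' `mitotic_count >= 0`, `age` in \[0, 120\], unique `tumor_id`, and the
#' follow-up pair present or absent together. All violations are collected
#' and reported at once, each naming the offending `tumor_id`.
#'
#' @param cohort A tibble in the cohort schema.
#' @return The validated cohort, invisibly unchanged.
#' @export
validate_cohort <- function(cohort) {
  assert_columns(cohort, setdiff(cohort_columns, c("followup_months", "relapse_event")),
                 what = "cohort")
  if (!"followup_months" %in% names(cohort)) cohort$followup_months <- NA_real_
  if (!"relapse_event" %in% names(cohort)) cohort$relapse_event <- NA

  problems <- character(0)
  note <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      ids <- cohort$tumor_id[which(bad)]
      problems <<- c(problems, sprintf("%s (tumor_id: %s)", msg,
                                       paste(ids, collapse = ", ")))
    }
  }

  if (anyDuplicated(cohort$tumor_id) > 0) {
    dup <- unique(cohort$tumor_id[duplicated(cohort$tumor_id)])
    problems <- c(problems, sprintf("duplicated tumor_id: %s",
                                    paste(dup, collapse = ", ")))
  }
  for (fld in names(cohort_levels)) {
    note(!is.na(cohort[[fld]]) & !cohort[[fld]] %in% cohort_levels[[fld]],
         sprintf("invalid %s value", fld))
    note(is.na(cohort[[fld]]), sprintf("missing %s", fld))
  }
  note(!is.na(cohort$size_cm) & cohort$size_cm <= 0, "size_cm must be > 0")
  note(is.na(cohort$size_cm), "missing size_cm")
  note(!is.na(cohort$mitotic_count) & cohort$mitotic_count < 0,
       "mitotic_count must be >= 0")
  note(is.na(cohort$mitotic_count), "missing mitotic_count")
  note(!is.na(cohort$age) & (cohort$age < 0 | cohort$age > 120),
       "age outside [0, 120]")
  note(xor(is.na(cohort$followup_months), is.na(cohort$relapse_event)),
       "followup_months and relapse_event must be present together")
  note(!is.na(cohort$followup_months) & cohort$followup_months < 0,
       "followup_months must be >= 0")

  if (length(problems) > 0) {
    stop_gistddr(
      c("cohort validation failed:", stats::setNames(problems, rep("x", length(problems)))),
      class = "gistddr_validation_error"
    )
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, header-mandatory cohort file (empty cell =
#' missing), optionally applying a schema mapping, and validates every row.
#' Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param schema Optional schema mapping: a list with elements `rename`
#'   (named character vector, `new_name = "file_column"`) and `synonyms`
#'   (named list per field mapping file category labels to schema labels,
#'   e.g. `list(sex = c(M = "male", F = "female"))`).
#' @return A validated cohort tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(synth_cohort(n = 5, seed = 1), f)
#' read_cohort(f)
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_gistddr(sprintf("cohort file not found: %s", path),
                 class = "gistddr_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema$rename)) {
    for (new in names(schema$rename)) {
      old <- schema$rename[[new]]
      assert_columns(raw, old, what = "cohort file")
      names(raw)[names(raw) == old] <- new
    }
  }
  assert_columns(raw, setdiff(cohort_columns, c("followup_months", "relapse_event")),
                 what = "cohort file")
  if (!is.null(schema$synonyms)) {
    for (fld in names(schema$synonyms)) {
      syn <- schema$synonyms[[fld]]
      hit <- raw[[fld]] %in% names(syn)
      raw[[fld]][hit] <- unname(syn[raw[[fld]][hit]])
    }
  }
  cohort <- tibble::as_tibble(raw)
  cohort$tumor_id <- as.character(cohort$tumor_id)
  cohort$age <- as.numeric(cohort$age)
  cohort$size_cm <- as.numeric(cohort$size_cm)
  cohort$mitotic_count <- as.numeric(cohort$mitotic_count)
  if (!"followup_months" %in% names(cohort)) cohort$followup_months <- NA_real_
  if (!"relapse_event" %in% names(cohort)) cohort$relapse_event <- NA
  cohort$followup_months <- as.numeric(cohort$followup_months)
  cohort$relapse_event <- as.logical(cohort$relapse_event)
  validate_cohort(cohort)
  cohort[, cohort_columns]
}

#' Write a cohort CSV
#'
#' Writes the cohort in the interchange dialect read by [read_cohort()]
#' (comma separator, header row, `.` decimal point, empty cell for missing).
#' `read_cohort(write_cohort(x, f))` reproduces `x` field for field.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort[, cohort_columns], path, na = "")
  invisible(path)
}

#' Binarize tumor site
#'
#' All association and survival analyses compare gastric against non-gastric
#' tumors; intestinal, omental and other sites collapse to `non_gastric`.
#'
#' @param site Character vector of schema site labels.
#' @return Character vector with levels `gastric` / `non_gastric`.
#' @export
binarize_site <- function(site) {
  ifelse(site == "gastric", "gastric", "non_gastric")
}
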