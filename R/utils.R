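# Shared internal helpers.

# Round half away from zero at `digits` decimals, so printed prevalences match
# clinical-report convention (75.55 -> 75.6) rather than banker's rounding.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# A percentage on the reporting scale: 100 * num/den, one decimal, half-up.
report_percent <- function(num, den, digits = 1) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

stop_gistddr <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "gistddr_error"), ...)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_gistddr(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "gistddr_schema_error"
    )
  }
  invisible(df)
}

# Deterministic per-module substreams from one master seed, so adding a module
# never perturbs the draws of another.
substream_seed <- function(seed, stream) {
  offsets <- c(
    cohort = 101L, biomarker = 211L, mlpa = 307L, ifcells = 401L,
    variants = 503L, survival = 601L, misc = 701L
  )
  off <- offsets[[stream]]
  (as.integer(seed) * 1009L + off) %% 2147483562L
}

`%||%` <- rlang::`%||%`
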