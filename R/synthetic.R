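#' Synthetic study generator
#'
#' Seeded generators producing cohorts, biomarker tables, MLPA peak tables
#' and variant tables with the statistical structure the downstream
#' analyses assume: correlated biomarker pairs (Gaussian copula), a latent
#' per-tumor instability score driving mitotic activity, risk and hazard,
#' heterozygous-deletion prevalences with RB1 enrichment in non-gastric
#' high-risk tumors, and proportional-hazards disease-free survival. One
#' master seed expands into per-module substreams, so generating one table
#' never perturbs the draws of another.
#'
#' @name synthetic-study
NULL

run_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generator configuration
#'
#' Central defaults for the synthetic study. Correlations are the observed
#' assay concordances (IHC vs IF 0.722 for gamma-H2AX and 0.696 for 53BP1;
#' between markers 0.700 by IHC and 0.594 by IF); heterozygous-deletion
#' prevalences are the MLPA cohort rates (CHEK2 0.756, BRCA2 0.122, RB1
#' 0.098); the survival log-hazards are the magnitudes of the multivariate
#' hazard ratios (14.612 NCCN high, 2.518 moderate, 2.05 low, 2.12 KIT
#' exon-11 deletion, 1.8 epithelioid histology).
#'
#' @param n Number of tumors.
#' @param seed Master integer seed.
#' @param ... Overrides for any default listed below.
#' @return A config list.
#' @export
synth_config <- function(n = 285, seed = 1, ...) {
  cfg <- list(
    n = n, seed = seed,
    gastric_fraction = 188 / 285,
    # log-size (cm): median ~5.8 cm, ~40% at or under 5 cm
    size_meanlog = 1.75, size_sdlog = 0.7, size_z_load = 0.45,
    # mitoses per 50 HPF: negative binomial, mean rising with instability Z
    mitosis_intercept = 0.8, mitosis_z_slope = 0.9, mitosis_dispersion = 1.5,
    # biomarker copula (order: gH2AX IHC, gH2AX IF, 53BP1 IHC, 53BP1 IF)
    rho_ihc_if_gh2ax = 0.722, rho_ihc_if_53bp1 = 0.696,
    rho_markers_ihc = 0.700, rho_markers_if = 0.594, rho_cross = 0.55,
    biomarker_z_share = 0.2,
    hscore_center = 250, hscore_sd = 55,
    if_center = 45, if_sd = 18,
    # heterozygous-deletion prevalences
    chek2_prev = 0.756, brca2_prev = 0.122, rb1_prev = 0.098,
    rb1_enriched_prob = 0.45, rb1_background_prob = 0.01,
    brca2_given_rb1 = 0.5,
    # age: carriers of CHEK2/BRCA2 deletions present older
    age_base = 58, age_sd = 11, age_carrier_shift = 8,
    # genotype mix
    p_kit_ex11_del = 83 / 285, p_other_mutant = 0.55,
    # histology
    p_epithelioid_mixed = 0.27,
    # disease-free survival: Weibull baseline, censoring window in months
    weibull_shape = 1.1, weibull_scale = 1400,
    loghr_nccn_low = log(2.05), loghr_nccn_moderate = log(2.518),
    loghr_nccn_high = log(14.612),
    loghr_kit_ex11_del = log(2.12), loghr_epithelioid = log(1.8),
    censor_min = 1, censor_max = 234
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_gistddr(sprintf("unknown config field(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "gistddr_config_error")
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$n >= 2)
  cfg
}

biomarker_corr <- function(cfg) {
  c_target <- diag(4)
  dimnames(c_target) <- list(c("g_ihc", "g_if", "b_ihc", "b_if"),
                             c("g_ihc", "g_if", "b_ihc", "b_if"))
  c_target["g_ihc", "g_if"] <- c_target["g_if", "g_ihc"] <- cfg$rho_ihc_if_gh2ax
  c_target["b_ihc", "b_if"] <- c_target["b_if", "b_ihc"] <- cfg$rho_ihc_if_53bp1
  c_target["g_ihc", "b_ihc"] <- c_target["b_ihc", "g_ihc"] <- cfg$rho_markers_ihc
  c_target["g_if", "b_if"] <- c_target["b_if", "g_if"] <- cfg$rho_markers_if
  c_target["g_ihc", "b_if"] <- c_target["b_if", "g_ihc"] <- cfg$rho_cross
  c_target["g_if", "b_ihc"] <- c_target["b_ihc", "g_if"] <- cfg$rho_cross
  a2 <- cfg$biomarker_z_share
  resid <- (c_target - a2) / (1 - a2)
  diag(resid) <- 1
  ev <- eigen(resid, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_gistddr("biomarker correlation matrix is not positive definite",
                 class = "gistddr_config_error")
  }
  list(target = c_target, resid = resid, a = sqrt(a2))
}

#' Generate the synthetic study
#'
#' Draws the full study from one seed: a validated cohort tibble, the
#' latent truth table (instability score, deletion flags, true biomarker
#' scores, linear predictor), and an IHC intensity table whose H-scores
#' reproduce the generated truth exactly.
#'
#' @param config A [synth_config()] list.
#' @return List with `cohort`, `truth`, `ihc`, and `if_percent` (per-tumor
#'   true IF positivity percentages).
#' @export
synth_study <- function(config = synth_config()) {
  cfg <- config
  n <- cfg$n
  corr <- biomarker_corr(cfg)

  run_seeded(substream_seed(cfg$seed, "cohort"), {
    z <- rnorm(n)
    site <- ifelse(runif(n) < cfg$gastric_fraction, "gastric",
                   sample(c("intestinal", "omental", "other"), n, TRUE,
                          prob = c(0.85, 0.1, 0.05)))
    size <- exp(cfg$size_meanlog + cfg$size_sdlog *
                  (cfg$size_z_load * z +
                     sqrt(1 - cfg$size_z_load^2) * rnorm(n)))
    mitoses <- rnbinom(n, mu = exp(cfg$mitosis_intercept + cfg$mitosis_z_slope * z),
                       size = cfg$mitosis_dispersion)
    histology <- ifelse(runif(n) < cfg$p_epithelioid_mixed,
                        ifelse(runif(n) < 0.8, "epithelioid", "mixed"),
                        "spindle")
    genotype <- sample(c("kit_ex11_5prime_del", "other_mutant", "wild_type"),
                       n, TRUE,
                       prob = c(cfg$p_kit_ex11_del, cfg$p_other_mutant,
                                1 - cfg$p_kit_ex11_del - cfg$p_other_mutant))

    nccn <- nccn_risk(site, size, mitoses)
    joint <- joint_group(nccn)

    # gene dosage truth
    chek2_del <- runif(n) < cfg$chek2_prev
    rb1_del <- runif(n) < ifelse(binarize_site(site) == "non_gastric" &
                                   !is.na(joint) & joint == "moderate_high",
                                 cfg$rb1_enriched_prob, cfg$rb1_background_prob)
    p_rb1 <- mean(rb1_del)
    brca2_base <- max(0, (cfg$brca2_prev - p_rb1 * cfg$brca2_given_rb1) /
                        max(1e-12, 1 - p_rb1))
    brca2_del <- runif(n) < ifelse(rb1_del, cfg$brca2_given_rb1, brca2_base)

    age <- round(cfg$age_base + cfg$age_carrier_shift * (chek2_del | brca2_del) +
                   rnorm(n, 0, cfg$age_sd))
    age <- pmin(pmax(age, 18), 100)

    # biomarkers: shared instability loading plus copula residual
    chol_r <- chol(corr$resid)
    u <- matrix(rnorm(n * 4), n, 4) %*% chol_r
    v <- corr$a * z + sqrt(1 - corr$a^2) * u
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    g_ihc <- clip(cfg$hscore_center + cfg$hscore_sd * v[, 1], 100, 400)
    g_if  <- clip(cfg$if_center + cfg$if_sd * v[, 2], 0, 100)
    b_ihc <- clip(cfg$hscore_center + cfg$hscore_sd * v[, 3], 100, 400)
    b_if  <- clip(cfg$if_center + cfg$if_sd * v[, 4], 0, 100)

    # proportional-hazards DFS with uniform censoring
    lp <- cfg$loghr_nccn_low * (nccn == "low") +
      cfg$loghr_nccn_moderate * (nccn == "moderate") +
      cfg$loghr_nccn_high * (nccn == "high") +
      cfg$loghr_kit_ex11_del * (genotype == "kit_ex11_5prime_del") +
      cfg$loghr_epithelioid * (histology %in% c("epithelioid", "mixed"))
    uu <- runif(n)
    t_event <- cfg$weibull_scale * (-log(uu) / exp(lp))^(1 / cfg$weibull_shape)
    t_cens <- runif(n, cfg$censor_min, cfg$censor_max)
    followup <- pmin(t_event, t_cens)
    event <- t_event <= t_cens

    ids <- sprintf("S%04d", seq_len(n))
    cohort <- tibble::tibble(
      tumor_id = ids, age = as.numeric(age), sex = sample(c("male", "female"), n, TRUE),
      site = site, size_cm = size, mitotic_count = as.numeric(mitoses),
      histology = histology, specimen = "primary_resection", genotype = genotype,
      followup_months = followup, relapse_event = event
    )
    validate_cohort(cohort)

    truth <- tibble::tibble(
      tumor_id = ids, z = z, chek2_hetdel = chek2_del, brca2_hetdel = brca2_del,
      rb1_hetdel = rb1_del, gh2ax_hscore = g_ihc, gh2ax_if = g_if,
      bp1_hscore = b_ihc, bp1_if = b_if, linear_predictor = lp,
      nccn_risk = nccn
    )
    ihc <- dplyr::bind_rows(
      synth_ihc_from_hscore(ids, "gH2AX", g_ihc),
      synth_ihc_from_hscore(ids, "TP53BP1", b_ihc)
    )
    if_percent <- tibble::tibble(
      tumor_id = rep(ids, 2),
      marker = rep(c("gH2AX", "TP53BP1"), each = n),
      percent_positive = c(g_if, b_if)
    )
    list(cohort = cohort, truth = truth, ihc = ihc, if_percent = if_percent)
  })
}

# Exact inversion of the H-score: place mass on two adjacent intensities.
synth_ihc_from_hscore <- function(ids, marker, hscores) {
  h <- pmin(pmax(hscores, 100), 400) - 100
  i <- pmin(floor(h / 100), 2)
  frac <- h / 100 - i
  p <- matrix(0, length(h), 4)
  p[cbind(seq_along(h), i + 1)] <- 100 * (1 - frac)
  p[cbind(seq_along(h), i + 2)] <- 100 * frac
  tibble::tibble(tumor_id = ids, marker = marker,
                 p0 = p[, 1], p1 = p[, 2], p2 = p[, 3], p3 = p[, 4])
}

#' Generate a cohort tibble only
#'
#' Convenience wrapper around [synth_study()] returning just the validated
#' cohort table.
#'
#' @param n Number of tumors.
#' @param seed Master seed.
#' @param ... Further [synth_config()] overrides.
#' @return A cohort tibble.
#' @export
synth_cohort <- function(n = 285, seed = 1, ...) {
  synth_study(synth_config(n = n, seed = seed, ...))$cohort
}

#' Default MLPA probe panel
#'
#' A synthetic panel in the shape of the commercial RB1 and BRCA2/CHEK2
#' probe mixes: several exon probes for RB1 and BRCA2, probes for CHEK2
#' exons 1 and 9 only, and four reference probes targeting other
#' chromosomes with differing amplicon sizes.
#'
#' @return A probe panel tibble.
#' @export
default_panel <- function() {
  tibble::tibble(
    probe_id = c(paste0("RB1_e", c(2, 8, 14, 19, 23)),
                 paste0("BRCA2_e", c(2, 9, 11, 18, 24)),
                 "CHEK2_e1", "CHEK2_e9",
                 paste0("REF_", 1:4)),
    gene = c(rep("RB1", 5), rep("BRCA2", 5), rep("CHEK2", 2), rep(NA, 4)),
    exon = c("e2", "e8", "e14", "e19", "e23",
             "e2", "e9", "e11", "e18", "e24", "e1", "e9", rep(NA, 4)),
    amplicon_size = c(130, 142, 154, 166, 178, 190, 202, 214, 226, 238,
                      250, 262, 120, 160, 220, 280),
    is_reference = c(rep(FALSE, 12), rep(TRUE, 4))
  )
}

#' Generate MLPA peak tables from planted copy numbers
#'
#' Each probe's expected dosage quotient is `copy_number / 2`; peak areas
#' are the product of a probe-specific baseline (decaying with amplicon
#' size, exercising the size adjustment), the dosage factor, a random
#' per-sample scale (exercising scale invariance), and multiplicative
#' log-normal noise at coefficient of variation `noise_cv`. Ligations are
#' emitted in duplicate; reference-normal samples carry two copies
#' throughout.
#'
#' @param copy_truth Tibble `sample_id`, `gene`, `copy_number`.
#' @param panel Probe panel (default [default_panel()]).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param n_reference Number of reference-normal samples.
#' @param n_replicates Ligation replicates per sample.
#' @return A long peak table consumable by [compute_dq()].
#' @export
synth_mlpa_peaks <- function(copy_truth, panel = default_panel(), noise_cv = 0.05,
                             seed = 1, n_reference = 3, n_replicates = 2) {
  validate_panel(panel)
  assert_columns(copy_truth, c("sample_id", "gene", "copy_number"), "copy truth")
  sdlog <- sqrt(log(1 + noise_cv^2))
  base_area <- 1500 * exp(-(panel$amplicon_size - 120) / 250)
  names(base_area) <- panel$probe_id

  run_seeded(substream_seed(seed, "mlpa"), {
    samples <- tibble::tibble(
      sample_id = c(unique(copy_truth$sample_id), paste0("NORM_", seq_len(n_reference))),
      role = c(rep("tumor", dplyr::n_distinct(copy_truth$sample_id)),
               rep("reference_normal", n_reference))
    )
    grid <- tidyr::expand_grid(samples, replicate = seq_len(n_replicates),
                               probe_id = panel$probe_id)
    grid <- dplyr::left_join(grid, dplyr::select(panel, "probe_id", "gene"),
                             by = "probe_id")
    grid <- dplyr::left_join(grid, copy_truth, by = c("sample_id", "gene"))
    grid$copy_number[grid$role == "reference_normal"] <- 2
    grid$copy_number[is.na(grid$gene)] <- 2          # reference probes
    grid$copy_number[is.na(grid$copy_number)] <- 2   # genes without planted truth
    scale_by_sample <- stats::setNames(exp(rnorm(nrow(samples), 0, 0.3)),
                                       samples$sample_id)
    noise <- if (noise_cv > 0) rlnorm(nrow(grid), 0, sdlog) else 1
    grid$peak_area <- base_area[grid$probe_id] * (grid$copy_number / 2) *
      scale_by_sample[grid$sample_id] * noise
    dplyr::select(grid, "sample_id", "role", "replicate", "probe_id", "peak_area")
  })
}

#' Generate immunofluorescence nucleus profiles
#'
#' Inverts the focus-positivity rule: each of `n_cells` nuclei is positive
#' with probability `percent_positive / 100`; positive nuclei receive one
#' to three foci with short axes drawn above the 1.0 um threshold, negative
#' nuclei receive either no foci or only sub-threshold (faint/hazy) ones.
#'
#' @param percent_positive True positivity percentage in \[0, 100\].
#' @param n_cells Number of nuclei (at least 100).
#' @param seed Integer seed.
#' @return Long tibble `nucleus_id`, `focus_short_axis_um` consumable by
#'   [if_expression_percent()].
#' @export
synth_if_cells <- function(percent_positive, n_cells = 150, seed = 1) {
  if (n_cells < 100) {
    stop_gistddr("n_cells must be at least 100", class = "gistddr_config_error")
  }
  stopifnot(percent_positive >= 0, percent_positive <= 100)
  run_seeded(substream_seed(seed, "ifcells"), {
    positive <- runif(n_cells) < percent_positive / 100
    purrr::map_dfr(seq_len(n_cells), function(i) {
      if (positive[i]) {
        k <- sample(1:3, 1)
        axes <- c(runif(1, 1.05, 2.5), runif(k - 1, 0.3, 2.5))
      } else if (runif(1) < 0.5) {
        axes <- runif(sample(1:2, 1), 0.1, 0.95)
      } else {
        axes <- NA_real_
      }
      tibble::tibble(nucleus_id = sprintf("c%04d", i), focus_short_axis_um = axes)
    })
  })
}

#' Default gene-to-pathway map
#'
#' Pathway blocks for the aberration matrix: primary GIST drivers, DNA
#' damage-sensing, homologous recombination, Fanconi anemia, nucleotide
#' excision repair, non-homologous end joining, and RB1.
#'
#' @return Tibble `gene`, `pathway`.
#' @export
default_pathway_map <- function() {
  tibble::tribble(
    ~gene, ~pathway,
    "KIT", "driver", "PDGFRA", "driver", "NF1", "driver", "SDHC", "driver",
    "CHEK2", "damage_sensing", "BLM", "damage_sensing", "ATM", "damage_sensing",
    "CHEK1", "damage_sensing", "ATR", "damage_sensing",
    "RAD51", "homologous_recombination", "RAD51B", "homologous_recombination",
    "MRE11", "homologous_recombination", "BRCA1", "homologous_recombination",
    "RAD52", "homologous_recombination", "RAD50", "homologous_recombination",
    "RAD54L", "homologous_recombination",
    "BRCA2", "fanconi_anemia", "PALB2", "fanconi_anemia",
    "FANCA", "fanconi_anemia", "FANCD2", "fanconi_anemia",
    "FANCG", "fanconi_anemia", "FANCL", "fanconi_anemia",
    "ERCC3", "NER", "ERCC5", "NER", "RECQL4", "NER",
    "PRKDC", "NHEJ",
    "RB1", "RB1"
  )
}

#' Generate annotated variant and CNV tables
#'
#' Emulates the composition of a small NGS aberration screen:
#' heterozygous deletions concentrated in damage-sensing genes, sporadic
#' non-recurrent missense variants across pathways, and planted anchor
#' samples carrying one amplification (copy number 7) and one gain (copy
#' number 4).
#'
#' @param n_samples Number of tumors.
#' @param seed Integer seed.
#' @param hetdel_probs Named per-gene heterozygous-deletion probabilities.
#' @param snv_rate Expected sporadic missense variants per sample.
#' @return List of tibbles `variants` and `cnv`.
#' @export
synth_variants <- function(n_samples = 16, seed = 1,
                           hetdel_probs = c(CHEK2 = 0.375, BLM = 0.3125,
                                            ATM = 0.25, RB1 = 0.25,
                                            CHEK1 = 0.1875, RAD51 = 0.1875,
                                            BRCA2 = 0.125, ATR = 0.0625),
                           snv_rate = 1.0) {
  run_seeded(substream_seed(seed, "variants"), {
    ids <- sprintf("N%03d", seq_len(n_samples))
    cnv <- purrr::map_dfr(names(hetdel_probs), function(gene) {
      hit <- runif(n_samples) < hetdel_probs[[gene]]
      tibble::tibble(sample_id = ids[hit], gene = gene, copy_number = 1L)
    })
    # planted anchors: one amplification and one gain of a driver locus
    cnv <- dplyr::bind_rows(
      cnv,
      tibble::tibble(sample_id = ids[1], gene = "SDHC", copy_number = 7L),
      tibble::tibble(sample_id = ids[min(2, n_samples)], gene = "SDHC",
                     copy_number = 4L)
    )
    pool <- setdiff(default_pathway_map()$gene, c("KIT", "PDGFRA"))
    n_snv <- stats::rpois(1, snv_rate * n_samples)
    variants <- if (n_snv > 0) {
      tibble::tibble(
        sample_id = sample(ids, n_snv, TRUE),
        gene = sample(pool, n_snv, TRUE),
        hgvs_p = sprintf("p.X%dY", sample(100:900, n_snv, TRUE)),
        effect = "missense",
        af = runif(n_snv, 0.05, 0.6),
        popfreq_max = 0,
        cosmic_id = NA_character_,
        oncokb_class = NA_character_,
        sift_call = sample(c("tolerated", "deleterious"), n_snv, TRUE,
                           prob = c(0.8, 0.2)),
        polyphen_call = sample(c("benign", "possibly_damaging"), n_snv, TRUE,
                               prob = c(0.7, 0.3)),
        grantham_score = runif(n_snv, 5, 120)
      )
    } else {
      tibble::tibble(sample_id = character(), gene = character(),
                     hgvs_p = character(), effect = character(), af = numeric(),
                     popfreq_max = numeric(), cosmic_id = character(),
                     oncokb_class = character(), sift_call = character(),
                     polyphen_call = character(), grantham_score = numeric())
    }
    list(variants = variants, cnv = cnv, samples = ids)
  })
}
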