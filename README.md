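# gistddr

DNA-damage-repair (DDR) gene dosage, γ-H2AX/53BP1 biomarker scoring, risk
stratification and disease-free-survival analysis for gastrointestinal
stromal tumors (GISTs).

Most GISTs are driven by KIT/PDGFRA mutations, but aberrations of the DDR
machinery — above all heterozygous deletions (HetDels) of damage-sensing
genes such as *CHEK2*, and rarer losses of *RB1* and *BRCA2* — accumulate
during progression. Two nuclear biomarkers of double-strand-break response,
γ-H2AX and 53BP1, can be read out either by immunofluorescence (IF foci
counting) or by the far more practical immunohistochemistry (IHC H-score),
and their joint expression carries prognostic information. `gistddr`
implements the full analytic chain that links these layers, for
biostatisticians and molecular pathologists who want each step as a tested,
reusable function:

- **MLPA dosage quotients** — per-sample normalization of probe peak areas
  by size-adjusted reference probes, tumor-over-pooled-reference dosage
  quotients (DQ), and copy-state calling: median DQ across exon probes for
  *RB1*/*BRCA2*, any-probe mode for *CHEK2* (exons 1 and 9 only), with
  DQ ≤ 0.7 ⇒ HetDel, DQ ≥ 1.3 ⇒ duplication, median DQ ≈ 0 ⇒ HomDel.
- **Biomarker scoring** — the H-score ΣPᵢ(i+1) over staining intensities
  i ∈ 0..3 (range 100–400), the IF positivity rule (≥1 concrete focus with
  short axis > 1.0 µm, ≥100 cells per sample), cohort-median
  dichotomization, and the dual-marker groups (double-low vs any-high).
- **Risk stratification** — the NIH consensus and NCCN-referenced AFIP
  rule tables, shipped as editable YAML grids, plus the joint
  none/very-low/low vs moderate/high grouping.
- **Variant triage** — allele-fraction (≥5%) and population-frequency
  screens, ordered pathogenicity rules (COSMIC/truncating ⇒ deleterious;
  OncoKB/SIFT/PolyPhen/Grantham ⇒ probably damaging; possibly damaging ⇒
  VUS), CNV-to-state mapping, and oncoprint-style gene × sample matrices.
- **Statistics from first principles** — Fisher exact (hypergeometric
  enumeration, two-sided small-p rule), Pearson chi-square, midrank
  Mann–Whitney U with exact enumeration for small untied samples, Pearson
  correlation; Kaplan–Meier, log-rank, and a Newton–Raphson Cox
  proportional-hazards fit with Efron ties. Base R supplies only
  distribution tails; `survival` and `stats` serve as independent
  cross-checks in the test suite.
- **A seeded synthetic-cohort generator** reproducing the statistical
  structure the analyses assume: Gaussian-copula biomarker pairs
  (IHC↔IF r ≈ 0.72/0.70; between markers 0.70 IHC / 0.59 IF), HetDel
  prevalences (CHEK2 0.756, BRCA2 0.122, RB1 0.098, RB1 enriched in
  non-gastric high-risk tumors), and proportional-hazards DFS with hazard
  ratios of the reported magnitude (14.612 NCCN-high, 2.12 KIT-exon-11
  deletion, 1.8 epithelioid).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for curves, forests and
oncoprints.

## Worked example

```r
library(gistddr)
library(dplyr)

study <- synth_study(synth_config(n = 285, seed = 2024))
scored <- score_biomarkers(study$ihc)
annotated <- classify_risk(study$cohort) |>
  left_join(scored$groups, by = "tumor_id")

d <- annotated |> filter(!is.na(nccn_joint), !is.na(group2))
tab <- crosstab(d, "nccn_joint", "group2", quiet = TRUE)
tab
#>                    any_high double_low
#>   moderate_high          91         35
#>   none_verylow_low       88         71
categorical_test(tab)
#> Pearson chi-square: statistic = 8.57055, p = 0.003416 (approximate)
```

Tumors at moderate/high risk are significantly depleted of double-low
biomarker expressers — the association the dual-marker grouping exists to
capture. The assay concordance and the multivariate DFS model:

```r
pearson_r(study$truth$gh2ax_hscore, study$truth$gh2ax_if)
#> Pearson correlation: statistic = 0.671832, p = 9.035e-39 (approximate)

design <- table4_design(annotated)
fit <- cox_fit(design, c("nccn_low", "nccn_moderate", "nccn_high",
                         "kit_ex11_del", "epithelioid_mixed",
                         "non_gastric", "dual_any_high"))
tidy(fit)
#>   term              estimate     hr    se ci_lower ci_upper p.value
#> 1 nccn_low             0.069  1.07  0.49     0.41      2.80   0.888
#> 2 nccn_moderate        1.22   3.38  0.466    1.36      8.41   0.009
#> 3 nccn_high            2.78  16.2   0.421    7.10     37.0    0
#> 4 kit_ex11_del         0.806  2.24  0.263    1.34      3.74   0.002
#> 5 epithelioid_mixed    0.684  1.98  0.256    1.2       3.27   0.007
#> 6 non_gastric         -0.187  0.83  0.258    0.501     1.38   0.469
#> 7 dual_any_high       -0.458  0.633 0.256    0.383     1.04   0.074
```

The high NCCN level, the KIT exon-11 5′ deletion and epithelioid histology
come out as independent adverse factors, with hazard ratios close to the
generating values (16.2 vs 14.6, 2.24 vs 2.12, 1.98 vs 1.8) — the
remaining gap is sampling noise at n = 285.

The package also ships encoded report tables (a 41-sample MLPA call table,
a 16-sample NGS aberration table, biomarker/survival count tables) and a
harness that recomputes their printed summaries:

```r
reproduce_printed()
#> # A tibble: 14 × 6  — e.g.
#>  1 chek2_mlpa_prevalence_pct  mlpa_prevale…  75.6   75.6     0     pass
#>  2 rb1_mlpa_prevalence_pct    mlpa_prevale…   9.8    9.8     0     pass
#> 10 fisher_location_rb1_p      fisher_locat…   0.013  0.0135  0.001 pass
```

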