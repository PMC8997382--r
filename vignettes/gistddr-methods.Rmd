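---
title: "Methods: dosage calling, biomarker scoring, and survival modelling in gistddr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage calling, biomarker scoring, and survival modelling in gistddr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistddr)
library(dplyr)
```

`gistddr` chains five analysis stages — MLPA dosage calling, γ-H2AX/53BP1
biomarker scoring, rule-based risk stratification, association testing, and
disease-free-survival (DFS) modelling — and pairs them with a seeded
synthetic-cohort generator so every stage can be exercised end to end
without patient data. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic cohorts do and do
not establish.

## MLPA dosage quotients

Multiplex ligation-dependent probe amplification reports relative gene
dosage through probe peak areas. Within each sample the area of every probe
is divided by the mean of the sample's *size-adjusted* reference-probe
areas (probes targeting loci on other chromosomes). Amplicon length biases
raw peak area, so each reference probe is first divided by a per-probe
scaling factor: its mean area across the reference-normal samples. This is
a deliberate design choice — a deterministic, data-driven equalization
rather than a fitted size-response curve, which would add a model where the
data provide a direct estimate. The normalization is scale invariant: any
per-sample multiplicative factor (DNA input, PCR efficiency) cancels.

The dosage quotient of a probe is the normalized tumor signal divided by
the pooled reference (the per-probe mean over normalized reference-normal
samples). Ligations run in duplicate; replicate DQs are averaged, and a
probe whose replicates spread by more than `replicate_tol = 0.3` is flagged
discordant and excluded — the assay gives no principled way to choose
between two inconsistent ligations, so neither is trusted.

Calling thresholds (all configurable):

| parameter | default | meaning |
|---|---|---|
| deletion cut | 0.7 | DQ at or below ⇒ heterozygous deletion |
| duplication cut | 1.3 | DQ at or above ⇒ heterozygous duplication |
| `homdel_tol` | 0.2 | median DQ at or below ⇒ homozygous deletion ("at or near zero") |

*RB1* and *BRCA2* carry several exon probes and are called on the **median**
DQ; *CHEK2* panels carry probes only for the representative exons 1 and 9,
so a single aberrant probe calls the gene (**any-probe** mode). When an
any-probe pattern shows both a deletion and a duplication probe, the
deletion wins and the call is flagged `mixed_pattern`: the deletion is the
clinically reported event, and silently averaging the two would fabricate a
normal. The any-probe mode has no homozygous arm — with two probes a single
zero is indistinguishable from probe failure.

## Biomarker scoring

The IHC H-score is $\sum_i P_i (i+1)$, where $i \in \{0,1,2,3\}$ is nuclear
staining intensity and $P_i$ the percentage of tumor cells at that
intensity. The shifted weight $(i+1)$ makes the range 100–400 rather than
the conventional 0–300; the package implements the shifted form as its
default because that is the score the downstream cutoffs were defined on,
and offers `weighting = "conventional"` for sensitivity checks only.

An IF-stained nucleus is positive when it exhibits at least one concrete
focus with short axis strictly greater than 1.0 µm; faint or hazy staining
(encoded as sub-threshold foci) never counts, and the boundary itself is
negative. Expression percentages require at least 100 scored cells. A cell
is positive on ≥1 supra-threshold focus — "exhibits foci" is read as
presence, not a count threshold; this is an interpretation and is recorded
here.

Each marker × assay is dichotomized at its cohort median (mean of the
middle two values for even n). Ties at the cutoff go to **low**: an odd
cohort with a unique median then places the median tumor in the low group.
The tie direction is arbitrary in principle; fixing it, and storing the
cutoff alongside every class, keeps the dichotomization reproducible. The
dual-marker grouping (neither/one/both high; double-low vs any-high) is
formed from the IHC classes, IHC being the assay available on every sample.

## Risk stratification

Neither rule table is an invention of this package: the NIH consensus grid
(size × mitoses) and the NCCN-referenced AFIP grid (site × size × mitoses)
are encoded as YAML under `inst/extdata`, cell by cell from the published
tables, with the encoded edition named in the file. Rules-as-data keeps the
classifier auditable and lets a different guideline edition be swapped in
without touching code. Two boundary conventions are fixed and documented in
the files: size and mitosis bins are upper-inclusive (≤2, ≤5, ≤10 cm;
≤5, ≤10 mitoses/50 HPF), closing the gaps the published tables leave
between "<5" and "6–10"; and the gastric ≤2 cm / >5 mitoses cell — too
rare in the source series to estimate — is `insufficient_data`, while its
non-gastric counterpart maps to high. Non-gastric, non-intestinal sites
(omental, other) use the small-intestine column, matching the gastric vs
non-gastric binarization used in all association tables. Biopsy, recurrence
and metastasis specimens are not amenable to resection-based
stratification and are coded `not_assessable`.

## Association statistics

The tests are implemented from their defining formulas, with base R
supplying only distribution tails; `fisher.test`, `chisq.test`,
`wilcox.test`/enumeration and `cor.test` act as independent oracles in the
test suite, never as the implementation.

- **Fisher exact (2×2)**: two-sided p by the "small-p" rule — the sum of
  hypergeometric point probabilities not exceeding the observed one, with a
  `1e-7` relative slack so floating-point noise cannot split exact ties.
  Definitions of the two-sided Fisher p differ across software; the rule
  used is stated precisely for that reason. A zero margin yields p = 1 and
  an undefined odds ratio.
- **Chi-square**: $\sum (O-E)^2/E$, no continuity correction.
- **Test selection** mirrors the reported analysis plan: a 2×2 table with
  any expected count below 5 goes to Fisher, everything else to chi-square;
  ordinal factors are tested as unordered categories (no trend test is part
  of the plan). Raw p-values are reported without multiplicity correction,
  and the report says so.
- **Rank-sum**: U via midranks (so $U_a + U_b = n_1 n_2$ holds under ties);
  exact two-sided p by full enumeration when $n_1+n_2 \le 12$ without ties,
  otherwise a normal approximation with tie-adjusted variance and
  continuity correction. The enumeration bound keeps the exact path under
  a thousand assignments — past that the approximation is already within
  0.02 of exact on tie-free data, which the suite asserts.
- **Pearson correlation**: the covariance formula with the t-distributed
  significance test on n − 2 degrees of freedom.

## Survival machinery

The Kaplan–Meier estimator, log-rank test and Cox model are implemented
from the estimating equations. Cox fitting maximizes the **Efron**
partial likelihood by Newton–Raphson (with step-halving), converging when
the largest score component drops below `1e-8`, capped at 50 iterations.
Efron is chosen over Breslow because it is the better tie approximation
and is exactly equivalent when ties are absent — preserving the classical
identity, asserted to `1e-6` in the suite, that the score test at β = 0
with a single untied binary covariate equals the log-rank chi-square.
Confidence intervals are Wald, $\exp(\hat\beta \pm 1.96\,\mathrm{se})$, at
a fixed 95% level. Monotone likelihood (complete separation) is detected
by coefficient escape (|β| > 15) and flagged as divergence with no
estimates reported, rather than returning a meaningless large number.
Records with zero follow-up are moved to half the smallest positive time
with a warning — the product-limit estimator needs positive time, and
observed follow-up in this setting starts at one month.

The multivariate DFS design contains the NCCN level (reference
none/very-low), the KIT exon-11 5′-deletion genotype, epithelioid/mixed
histology, non-gastric location, and the dual-marker group. Tumor size and
mitotic count are deliberately excluded: both are component factors of the
NCCN scheme, and including them alongside it would condition the risk
coefficients on their own ingredients. All listed covariates enter
simultaneously; collinearity shows up in the reported standard errors
rather than being resolved by silent exclusion.

## The synthetic-cohort generator

`synth_study()` draws, from one master seed, a cohort plus truth tables.
One integer seed expands into fixed per-module substreams, so generating
an MLPA table never perturbs the cohort draw. The generator encodes the
study conditions the analyses assume:

- a standard-normal **latent instability score** Z per tumor drives
  mitotic activity (negative-binomial, mean $e^{0.8 + 0.9Z}$, dispersion
  1.5), tumor size (log-normal, meanlog 1.75, sdlog 0.7, Z-loading 0.45 —
  median ≈ 5.8 cm with ~40% at or under 5 cm), and, through them, risk;
- the four biomarker readouts (two markers × two assays) are a Gaussian
  copula: each is $aZ + \sqrt{1-a^2}\,u$ with $a^2 = 0.2$ and residual
  correlations back-solved so the *total* correlations hit the observed
  assay concordances (0.722 and 0.696 IHC↔IF; 0.700 between markers by
  IHC, 0.594 by IF; unobserved cross-pairs set to 0.55, the weakest value
  keeping the matrix well-conditioned). Marginals are linear maps onto the
  H-score range (center 250, sd 55) and IF percentage (center 45, sd 18),
  clipped to their domains; linear maps preserve Pearson correlations and
  the clipping touches well under 1% of draws;
- HetDel prevalences are CHEK2 0.756, BRCA2 0.122, RB1 0.098, with RB1
  generated conditional on non-gastric site and moderate/high joint risk
  (enriched 0.45 vs background 0.01) and BRCA2 given RB1 raised to 0.5 to
  produce the rare co-deletions; CHEK2/BRCA2 carriers present about 8
  years older (base 58 ± 11);
- DFS follows a Weibull baseline (shape 1.1, scale 1400 months — about
  97% event-free at five years in the reference stratum) under
  proportional hazards with log-hazards ln 2.05 / ln 2.518 / ln 14.612 for
  the NCCN low/moderate/high levels, ln 2.12 for the KIT exon-11 deletion
  and ln 1.8 for epithelioid/mixed histology, censored uniformly on
  1–234 months (roughly the observed follow-up window), which yields on
  the order of a quarter of tumors relapsing;
- the MLPA peak generator inverts the dosage pipeline (expected DQ =
  copies/2, probe baselines decaying with amplicon size to exercise the
  size adjustment, a random per-sample scale to exercise scale invariance,
  log-normal noise at a configurable coefficient of variation), and the IF
  cell generator inverts the focus rule (positives get ≥1 focus above
  1.0 µm, negatives only sub-threshold ones).

What passing tests on these cohorts show: the pipeline recovers planted
truths — copy states exactly at zero noise, correlations within Fisher-z
bands, log-hazards within ±0.15 on replicate means, the configured
dual-marker × risk association at conventional significance. What they do
not show: performance on real stained tissue. The generator has no
inter-observer scoring noise, no spatial heterogeneity within a block, no
assay failures, and its copula is the *minimal* dependence structure
consistent with the reported correlations, not an estimate of the real
joint distribution. Defaults are calibration anchors, not estimates.

## Problem sizes and tolerances in the test suite

The suite runs at sizes chosen to make each assertion sharp while staying
lightweight: 500 noiseless and 200 noisy samples for the dosage oracle
(the false-HetDel bound of 2% at cv 0.05 sits ~7 normal sds from the 0.7
threshold); 2 000 replicates per test for type-I error, which bounds the
Monte-Carlo sd of an α̂ near 0.05 at about 0.005 against the accepted
[0.03, 0.07] band; a 10 000-shuffle permutation null for the log-rank
comparison (MC sd ≈ 0.005 on p ≈ 0.5 scale, asserted within 0.02); and 12
replicates of n = 2 000 for hazard recovery, putting the replicate-mean sd
near 0.06 on the log scale against the ±0.15 band. A single n = 2 000
draw has se ≈ 0.2–0.27 on the sparse risk coefficients — at the realistic
event rates the generator emulates, single-draw recovery at ±0.15 would
fail by noise alone about half the time, which is why recovery is defined
on the replicate mean.

## Known limitations

- Pathogenicity triage is rule-based on pre-annotated columns; it does not
  query COSMIC/OncoKB/ClinVar and inherits whatever the annotations got
  wrong. The "damaging" operationalization (OncoKB oncogenic OR SIFT
  deleterious OR PolyPhen probably-damaging OR Grantham > 100) is the most
  inclusive reading of a platform list that specifies no combination
  logic; the fired rule is logged per variant so any other policy can be
  audited against it.
- The population-frequency ceiling for the germline screen (0.01) is a
  configurable convention; the screening database is named in the inputs
  but its cutoff is not fixed by them.
- The gain/amplification boundary (gain 3–5, amplification ≥6) brackets
  the two anchor observations (copy number 4 = gain, 7 = amplification)
  symmetrically and is configurable; no calibration data exist between
  them.
- No trend tests, no competing risks, no time-varying covariates, no
  treatment modelling; DFS is the single endpoint.
- The encoded NIH/NCCN grids are one edition each; users tracking a newer
  guideline should supply their own YAML via `load_risk_table(path=)`.
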