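---
title: "Methods: combined polygenic and phenotypic breast-cancer risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined polygenic and phenotypic breast-cancer risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsband)
```

## The problem

Case-control studies of breast-cancer risk combine a polygenic risk score
(PRS) built from dozens of GWAS-derived susceptibility SNPs with established
phenotypic risk factors — mammographic density, reproductive history,
menopause status, family history — into a single multivariable logistic
model, and then ask two questions: how well does the combined score
discriminate cases from controls (cross-validated AUC), and how strongly
does it stratify women into low- and high-risk groups (odds ratios of
extreme risk deciles against the middle of the distribution)?

`prsband` implements that full analysis chain for a cohort of the design we
emulate — 642 healthy women and 455 cases, ages 30–70, genotyped on a
candidate panel of 123 SNPs — together with a synthetic cohort generator, so
every stage is testable without access to patient data.

## The generative model

The generator is a prospective logistic disease model with retrospective
ascertainment:

* **Genotypes.** Each SNP is biallelic with effect-allele frequency drawn
  uniformly from a configurable range (default 0.05–0.5) and genotypes drawn
  as Binomial(2, p) — Hardy–Weinberg equilibrium, no linkage disequilibrium
  (a stated non-goal). Drawn per-allele odds ratios have |log OR| between
  0.06 and 0.30 with random sign, so every OR falls outside the near-null
  filter zone (0.95, 1.05) unless near-null SNPs are injected deliberately
  for filter tests.
* **Phenotypes.** Five categorical factors are drawn independently from
  control-arm category frequencies that mimic the emulated cohort's
  marginals (e.g. mammographic density 15.4 / 18.1 / 28.8 / 28.2 / 9.5
  percent across the five Boyd categories). Age is drawn by 5-year bin from
  the control-arm bin distribution, then uniformly within the bin — only
  binned age is used downstream. Centre is a two-level label with a
  configurable intercept shift.
* **Risk.** The linear predictor is
  `baseline + Σ_k w_k x_k + Σ_f log OR_f(category) + interactions +
  centre shift`, and the outcome is Bernoulli(expit(·)). Interaction terms
  contribute `coef × (idx_a − E idx_a) × (idx_b − E idx_b)` on centred
  0-based category indices (age uses the bin index). Centring makes the
  term mean-zero and orthogonal to the main effects under independence;
  without centring an index-product interaction is almost entirely absorbed
  by the main effects and cannot create the discrimination gap between the
  interaction and no-interaction models that this design exhibits.
* **Ascertainment.** A population large enough to contain the target counts
  is simulated and exactly 455 cases and 642 controls are drawn uniformly
  without replacement. Retrospective sampling of this kind preserves odds
  ratios (the quantity every downstream model estimates) but not absolute
  risk, which is why predicted probabilities are documented as relative
  scores.

`expected_predictor_shift()` returns the closed-form expectation of the
non-intercept part of the linear predictor, so callers can centre the
baseline and keep the simulated prevalence near a chosen value (we use 12%,
the screening-population prevalence assumed in the emulated design's sample
size calculation).

### Default interaction strengths

The default age×density and age×menopause coefficients (0.13 and 0.32 per
centred index product, `default_interaction_terms()`) were fixed once, by
calibration against the interaction evidence this study design reports: at
n = 1097 they yield likelihood-ratio chi-squares near 8 and near 70
(two-sided p ≈ 4e-3 and ≈ 1e-16) and a cross-validated AUC advantage of
about 0.04 for the interaction model. A single Gaussian-ish interaction
term cannot simultaneously match an LRT of that size and the full printed
AUC gap of 0.06; we prioritised the interaction-test magnitudes and accept
the slightly smaller gap, since the direction of the contrast is what the
property tests assert.

### What the generator does not emulate

Linkage disequilibrium, genotyping batch effects, correlation between
phenotypic factors (age-dependent menopause status in particular: real
premenopausal women are young, simulated ones are not), population
admixture beyond an optional two-subpopulation mode used in PC tests, and
tumour subtypes. Passing tests therefore demonstrate correctness of the
estimation machinery under the stated generative assumptions, not
robustness to the confounding structure of real cohorts.

## Panel filtering and QC

`filter_snp_panel()` removes SNPs with OR strictly inside (0.95, 1.05) — the
boundary values are retained, matching the strict inequality of the rule —
plus SNPs flagged as platform genotyping failures or duplicate-control
errors; a 123-SNP panel with 28 near-null and 3 failed SNPs retains exactly
92. `qc_samples()` and `qc_snps()` apply strict `< 0.95` call-rate
thresholds per sample and per SNP. Both QC steps are idempotent.

## PRS: weights, normalization, missingness

The score is `PRS_i = Σ_k w_k x_ik` with `x` the effect-allele count
(0/1/2). The weights are `log(OR_k)`. The field's convention — and the per-SD
odds-ratio scale the results are reported on — requires log-odds weights; a
`weights = "or"` switch reproduces the literal sum of raw odds ratios for
comparison, but nothing downstream uses it.

Two normalizations are always produced: division by the control-sample
median (typical women sit near 1; this is the headline "normalized" scale)
and standardization by the control mean and SD, which is the scale on which
the per-SD odds ratio is estimated. Missing genotypes default to
expected-dosage imputation (`2·eaf`), keeping scores comparable across
samples; drop-to-zero and hard-fail policies are selectable.

Genotype principal components (default 5) are computed from the
mean-imputed, centred, unit-variance-scaled dosage matrix via SVD; a
`2p(1−p)` scaling is available. Component signs are fixed by making each
component's largest-magnitude loading positive, and ties in explained
variance resolve by column order — decompositions are deterministic.

## Association and model building

* Univariable screens: `outcome ~ factor + age_bin + centre`, maximum
  likelihood, Wald 95% CI and two-sided p, selection at p < 0.05.
  Standardized coefficients are `coefficient × SD(factor)`.
* The PRS fit follows the design's own convention — age and five PCs, no
  centre adjustment (a documented asymmetry; `adjust_centre = TRUE`
  harmonizes it) — and adds 5% tail contrasts against the 40–60% band of
  the PRS distribution, implemented as indicator logistic regressions.
* Interactions are assessed by likelihood-ratio tests of nested fits; the
  statistic is floored at zero and a constant interaction column returns
  LRT = 0 by construction. Age inside interaction terms is the ordinal bin
  index, matching its main-effect encoding (bin index rather than bin
  midpoint: the two are affinely related, so fits are equivalent; the index
  is the convention we fixed).
* The final model forces family history and age at menarche in regardless
  of significance, as is conventional for established risk factors, and
  forces in the parents of any retained interaction term so the models stay
  nested.
* Global model significance is a Wald chi-square on all non-intercept
  coefficients; per-term Wald tests are also reported. The covariance is
  the inverse observed information at the MLE.
* Hosmer–Lemeshow uses deciles of predicted probability with ties to the
  lower group; coincident cut points merge groups with a warning; df =
  groups − 2.

Degenerate inputs fail loudly and distinctly: rank deficiency,
(quasi-)complete separation (no Firth fallback — a stated non-goal) and
non-convergence each raise their own error.

## Discrimination and stratification

The AUC is the Mann–Whitney probability with ties credited 0.5, computed
from average ranks and verified in tests against an O(n²) pair-counting
oracle and an independent ROC implementation. Cross-validated AUC repeats
1000 uniform 90/10 train/test splits (configurable); the split sequence is
a deterministic function of the seed, so two model variants evaluated at
the same seed share splits and can be compared by a paired two-sided
Wilcoxon signed-rank test on per-replicate differences (approximate, since
replicates share observations; a paired t is available). The 95% CI of the
CV distribution is its 2.5/97.5 percentile interval; a cross-validation
reading was chosen over a bootstrap-over-cohort one, which is available as
a manual alternative.

Risk stratification cuts the cohort's predicted risks at empirical
quantiles 10/20/40/60/80/90% — computed over cases and controls together,
which makes "% of controls / % of cases per band" the natural report — into
seven bands with the 40–60% band as reference. Ties at a cut point fall to
the lower band. Band odds ratios come from indicator logistic regressions
against the reference band; empty bands are reported with undefined OR
rather than dropped.

## Calibrated recovery study

The per-SD odds ratio of 1.41 and the PRS-only AUC are checked by a
calibration loop (`prs_calibration_study()`): panel weights are rescaled so
that the population SD of the raw PRS under HWE,
`sqrt(Σ w² · 2p(1−p))`, equals `log(1.41)` exactly — making the generative
log-odds per 1 SD of the PRS equal `log(1.41)` by construction — and the
per-SD OR and the Mann–Whitney AUC are then re-estimated in each of 100
ascertained 455/642 cohorts. For a normal score with per-SD log-odds δ the
implied AUC is Φ(δ/√2) ≈ 0.60 at δ = log(1.41), which is what the raw
(unadjusted) PRS AUC of the study converges to; age- and PC-adjusted
estimates in real cohorts sit slightly higher.

## Problem sizes and numerical choices

Simulation-based tests use the cohort size of the emulated design
(n = 1097) where the claim is about that design, and 3000–20 000 where the
claim is asymptotic (coverage, calibration, null uniformity); replicate
counts are 20–200 per property and 100 for the calibration study. These
sizes are the package's own choice of where the Monte Carlo error becomes
negligible relative to the tolerances asserted. All randomness flows from
explicit integer seeds; identical configurations give byte-identical
results.

## Known limitations

The generator's independence assumptions (SNP–SNP, SNP–phenotype,
phenotype–phenotype, age–menopause) are idealisations; the Spearman
independence screen over controls is therefore expected to be null on
simulated data by construction. Predicted probabilities inherit the
case-control intercept and must not be read as absolute 5-year risks.
Printed per-band percentages in reports of this design depend on
cohort-specific risk distributions; only the ordering and sign pattern of
the band odds ratios is treated as reproducible.
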