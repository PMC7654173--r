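# prsband

Combined genotype + phenotype breast-cancer risk evaluation for
case-control cohorts: a 92-SNP polygenic risk score (PRS) with panel
filtering and call-rate QC, odds-ratio encoding of phenotypic risk factors,
multivariable logistic models with age interactions, cross-validated AUC,
and risk stratification into decile bands against the 40–60% reference
band. A synthetic cohort generator (Hardy–Weinberg genotypes, prospective
logistic disease model, retrospective ascertainment) stands in for patient
data, so the entire pipeline is reproducible and testable.

The package is aimed at biostatisticians and epidemiologists building or
auditing combined risk models of this design.

## The model

For woman *i* with effect-allele counts *x<sub>ik</sub>* ∈ {0,1,2} over a
panel of SNPs with per-allele odds ratios OR<sub>k</sub>,

    PRS_i = Σ_k log(OR_k) · x_ik

normalized by the control-sample median and standardized by the control
mean/SD. Categorical risk factors (mammographic density, age at first
delivery, menopause status, age at menarche, family history) are encoded as
the odds ratio of each woman's category from externally supplied lookup
tables; age enters as the ordinal 5-year bin index. The final model is a
multivariable logistic regression

    logit P(case) = β₀ + β·(encoded factors) + β_PRS·PRS_std
                    + γ₁·(age × density) + γ₂·(age × menopause)
                    + age + centre

with interaction terms retained when their likelihood-ratio test passes
p < 0.05. Discrimination is the Mann–Whitney AUC over 1000 random 90/10
train/test splits; stratification cuts predicted risk at quantiles
10/20/40/60/80/90% and estimates each band's odds ratio against the 40–60%
reference band.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort (642 controls + 455 cases, 123-SNP candidate panel) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + panel fixture
Rscript analysis/02_qc_prs.R            # filtering, QC, PRS, PCs
Rscript analysis/03_association.R       # univariable screens, LRTs
Rscript analysis/04_risk_model.R        # multivariable model
Rscript analysis/05_evaluation.R        # CV-AUC + stratification
Rscript analysis/06_calibration_study.R # calibrated PRS recovery
```

Step 2 prints the panel-filter worked example — 92 of 123 SNPs retained (28
near-null, 3 genotyping failures removed). Steps 4–5 print, for one
simulated cohort:

```
Hosmer-Lemeshow: chi2 = 7.82 (df 8), p = 0.451
CV-AUC without interactions: 0.765 (95% CI 0.682-0.847)
CV-AUC with interactions:    0.806 (95% CI 0.726-0.881)

    band n_controls n_cases pct_controls pct_cases     or      p
1   <10%        103       7        16.04      1.54  0.123 4.4e-07
...
7   >90%         12       98        1.87     21.54 14.763 1.3e-15
```

i.e. the calibration test does not reject the fitted model, the interaction
model discriminates better than the main-effects model, and the decile
bands separate risk by two orders of magnitude between the bottom and top
band. Step 6 prints the calibrated recovery study:

```
mean OR per SD: 1.406 (per-replicate SD 0.089)
mean PRS AUC:   0.594 (per-replicate SD 0.017)
```

— the per-SD odds ratio of the standardized PRS re-estimated from 100
ascertained cohorts whose generative per-SD effect is 1.41, and the
Mann–Whitney AUC of the PRS alone.

See `vignettes/risk-model-methods.Rmd` for the generative model, every
tunable parameter, and the numerical conventions (tie handling, band
boundaries, missing-genotype policy).

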