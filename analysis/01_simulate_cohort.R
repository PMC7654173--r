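#!/usr/bin/env Rscript
# Step 1 - build the study's synthetic stand-in cohort.
#
# The real cohort (642 healthy women, 455 breast-cancer cases, ages 30-70,
# genotyped on a 123-SNP candidate panel) is not distributable, so the
# analysis runs on a generative stand-in with the same structure: a 123-SNP
# panel carrying 28 near-null SNPs (OR strictly inside 0.95-1.05) and 3
# platform genotyping failures, Hardy-Weinberg genotypes, Table-1-style
# control category frequencies for the five phenotypic risk factors, age x
# density and age x menopause interaction effects, and retrospective
# ascertainment of 455 cases and 642 controls from a prospective logistic
# disease model.

library(prsband)

out_dir <- "results/cohort"
seed <- 20260921

sim <- simulation_config(
  n_snps = 123, seed = seed,
  interaction_terms = default_interaction_terms(),
  n_cases = 455, n_controls = 642
)
panel <- generate_snp_panel(sim, n_near_null = 28, n_failed = 3)
sim$baseline_log_odds <- sim$baseline_log_odds -
  expected_predictor_shift(panel, sim)

pop <- simulate_population(panel, sim, n = 8000)
cat(sprintf("population: %d women, %.1f%% cases\n",
            length(pop$outcome), 100 * mean(pop$outcome)))

cohort <- ascertain_case_control(pop, sim$n_cases, sim$n_controls, seed = seed)
paths <- write_fixture(cohort, panel, out_dir)
cat(sprintf("cohort: %d cases + %d controls written to %s\n",
            sum(cohort$phenotypes$outcome == 1),
            sum(cohort$phenotypes$outcome == 0), out_dir))
cat("files:", paste(basename(unlist(paths)), collapse = ", "), "\n")
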