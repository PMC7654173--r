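# Calibrated genotype-only simulation replicates: the generative per-SD
# effect of the PRS is fixed to a target odds ratio, a case-control cohort is
# ascertained, and the per-SD OR and the Mann-Whitney AUC of the
# standardized PRS are re-estimated.

#' One calibrated PRS simulation replicate
#'
#' Generates a SNP panel (MAF uniform on `maf_range`, HWE genotypes),
#' rescales the per-allele weights so the population per-SD log-odds of the
#' PRS equals `log(per_sd_or)` (see [calibrate_panel_per_sd()]), centres the
#' baseline so the population prevalence is near `prevalence`, simulates a
#' population, retrospectively ascertains `n_cases` cases and `n_controls`
#' controls, standardizes the PRS by the control mean and SD, and estimates
#' the per-SD odds ratio by logistic regression and the discrimination of
#' the score by the Mann-Whitney AUC. Phenotype effects are switched off so
#' the replicate isolates the genetic score.
#'
#' @param seed Integer seed for the replicate.
#' @param per_sd_or Target generative odds ratio per 1 SD of the PRS.
#' @param n_snps Panel size.
#' @param maf_range Effect-allele frequency range.
#' @param n_cases,n_controls Ascertained counts.
#' @param prevalence Population disease prevalence before ascertainment.
#' @param n_population Simulated population size.
#' @return List with `or_per_sd`, `auc`, and `n` (cohort size).
#' @export
prs_calibration_replicate <- function(seed, per_sd_or = 1.41,
                                      n_snps = 92,
                                      maf_range = c(0.05, 0.5),
                                      n_cases = 455, n_controls = 642,
                                      prevalence = 0.12,
                                      n_population = 6000) {
  specs <- default_phenotype_specs()
  for (nm in names(specs)) specs[[nm]]$log_or[] <- 0
  config <- simulation_config(
    n_snps = n_snps, maf_range = maf_range, phenotype_specs = specs,
    baseline_log_odds = stats::qlogis(prevalence),
    n_cases = n_cases, n_controls = n_controls, seed = seed
  )
  panel <- generate_snp_panel(config)
  panel <- calibrate_panel_per_sd(panel, log(per_sd_or))
  config$baseline_log_odds <- config$baseline_log_odds -
    expected_predictor_shift(panel, config)
  pop <- simulate_population(panel, config, n_population)
  cohort <- ascertain_case_control(pop, n_cases, n_controls, seed = seed + 7L)
  raw <- compute_prs(cohort$genotypes, panel)
  prs <- normalize_prs(raw, cohort$phenotypes$sample_id[cohort$phenotypes$outcome == 0])
  df <- data.frame(outcome = cohort$phenotypes$outcome,
                   prs_std = prs$standardized)
  fit <- univariable_fit(df, "prs_std", covariates = NULL)
  list(or_per_sd = fit$or,
       auc = auc(prs$standardized, df$outcome),
       n = nrow(df))
}

#' Calibrated PRS simulation study
#'
#' Averages the re-estimated per-SD odds ratio and the PRS AUC over
#' `n_replicates` independent seeded replicates of
#' [prs_calibration_replicate()].
#'
#' @param n_replicates Number of replicates (>= 100 for stable means).
#' @param seed Master seed; replicate seeds are drawn from it.
#' @param ... Passed to [prs_calibration_replicate()].
#' @return List with `mean_or_per_sd`, `mean_auc`, `n_replicates`, `n` and
#'   the per-replicate vectors.
#' @export
prs_calibration_study <- function(n_replicates = 100, seed = 1L, ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 10L, n_replicates)
  reps <- lapply(seeds, prs_calibration_replicate, ...)
  ors <- vapply(reps, `[[`, numeric(1), "or_per_sd")
  aucs <- vapply(reps, `[[`, numeric(1), "auc")
  list(mean_or_per_sd = mean(ors), mean_auc = mean(aucs),
       n_replicates = n_replicates, n = reps[[1]]$n,
       or_per_sd = ors, auc = aucs)
}
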