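# End-to-end pipeline: QC -> PRS -> encoding -> univariable screen ->
# interaction LRTs -> multivariable fit -> calibration -> CV-AUC ->
# decile-band stratification.

#' Expected linear-predictor shift of a generative model
#'
#' Closed-form expectation of the non-intercept part of the simulated linear
#' predictor (genetic term under HWE, phenotype main effects under the
#' control-category frequencies, interaction terms under factor independence,
#' centre shift). Subtracting it from `baseline_log_odds` keeps the simulated
#' prevalence near `plogis(baseline_log_odds)`.
#'
#' @param panel The `snp_panel` driving the disease model.
#' @param config The [simulation_config()].
#' @return Scalar expected shift in log-odds.
#' @export
expected_predictor_shift <- function(panel, config) {
  shift <- sum(panel$weight * 2 * panel$eaf)
  for (nm in names(config$phenotype_specs)) {
    sp <- config$phenotype_specs[[nm]]
    shift <- shift + sum(sp$control_freqs * sp$log_or)
  }
  # centred-index interaction terms have expectation 0 under independence
  shift + config$centre_effect * (config$n_centres - 1) / 2
}

#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [simulation_config()], optionally with
#' panel-composition and population-size settings) or `paths` (named list
#' with `panel`, `genotypes`, `phenotypes`) must be given.
#'
#' @param simulation A [simulation_config()] or `NULL`.
#' @param paths Named list of input paths or `NULL`.
#' @param n_near_null,n_failed Panel composition injected at simulation time
#'   (the analysis panel is what survives [filter_snp_panel()]).
#' @param n_population Simulated population size before ascertainment.
#' @param encodings Named list of [factor_encoding()] tables.
#' @param sample_call_rate,snp_call_rate QC thresholds in (0, 1].
#' @param selection_p Univariable/interaction inclusion threshold
#'   (two-sided).
#' @param forced_factors Factors kept in the multivariable model regardless
#'   of univariable significance.
#' @param interaction_candidates List of candidate interaction pairs
#'   (column names; age enters as `age_bin`).
#' @param n_perm,train_frac CV-AUC settings.
#' @param output_dir Optional directory for result files.
#' @param seed Master seed for ascertainment, CV splits and any simulation.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            n_near_null = 0, n_failed = 0,
                            n_population = 8000,
                            encodings = example_encodings(),
                            sample_call_rate = 0.95, snp_call_rate = 0.95,
                            selection_p = 0.05,
                            forced_factors = c("family_enc", "menarche_enc"),
                            interaction_candidates = list(
                              c("age_bin", "density_enc"),
                              c("age_bin", "menopause_enc")),
                            n_perm = 1000, train_frac = 0.9,
                            output_dir = NULL, seed = 1L) {
  if (is.null(simulation) == is.null(paths)) {
    stop("exactly one of `simulation` or `paths` must be supplied",
         call. = FALSE)
  }
  for (th in c(sample_call_rate, snp_call_rate)) {
    if (th <= 0 || th > 1) stop("QC thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    simulation = simulation, paths = paths, n_near_null = n_near_null,
    n_failed = n_failed, n_population = n_population, encodings = encodings,
    sample_call_rate = sample_call_rate, snp_call_rate = snp_call_rate,
    selection_p = selection_p, forced_factors = forced_factors,
    interaction_candidates = interaction_candidates,
    n_perm = n_perm, train_frac = train_frac,
    output_dir = output_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full risk-evaluation pipeline
#'
#' Executes, in order: input acquisition (simulation or files), panel
#' filtering, sample and SNP call-rate QC, PRS computation with
#' control-median normalization and control-SD standardization, genotype
#' principal components, OR encoding and age binning, univariable screens
#' with selection at the configured p threshold (family history and menarche
#' forced in), PRS association with 5% tail contrasts, interaction LRTs with
#' inclusion at the same threshold, multivariable fits with and without the
#' retained interactions, Hosmer-Lemeshow calibration, cross-validated AUC
#' for both model variants on shared splits with a paired comparison, and
#' decile-band stratification of the predicted risk against the 40-60%
#' reference band. When `output_dir` is set, results are written as
#' TSV/CSV/JSON plus a run manifest.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list) with every intermediate and final object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) message(sprintf(...))

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    panel_full <- generate_snp_panel(sim, n_near_null = config$n_near_null,
                                     n_failed = config$n_failed)
    sim$baseline_log_odds <- sim$baseline_log_odds -
      expected_predictor_shift(panel_full, sim)
    pop <- simulate_population(panel_full, sim, config$n_population)
    cohort <- ascertain_case_control(pop, sim$n_cases, sim$n_controls,
                                     seed = config$seed)
    panel <- panel_full
  } else {
    inp <- read_inputs(config$paths$panel, config$paths$genotypes,
                       config$paths$phenotypes)
    panel <- inp$panel
    cohort <- inp$cohort
    log_msg("input: %d samples reconciled, %d dropped",
            nrow(cohort$phenotypes), inp$n_dropped)
  }

  panel <- filter_snp_panel(panel)
  log_msg("panel filter: %d SNPs retained, %d removed",
          nrow(panel), nrow(attr(panel, "removed")))

  gt <- cohort$genotypes[, intersect(colnames(cohort$genotypes), panel$rsid),
                         drop = FALSE]
  gt <- qc_samples(gt, config$sample_call_rate)
  gt <- qc_snps(gt, config$snp_call_rate, panel = panel)
  panel <- panel[panel$rsid %in% colnames(gt), , drop = FALSE]
  keep <- cohort$phenotypes$sample_id %in% rownames(gt)
  phen <- cohort$phenotypes[keep, , drop = FALSE]

  raw <- compute_prs(gt, panel)
  prs <- normalize_prs(raw, phen$sample_id[phen$outcome == 0])
  pcs <- genotype_pcs(gt, k = min(5, min(dim(gt)) - 1))

  df <- encode_cohort(phen, config$encodings)
  df$prs_std <- prs$standardized[match(df$sample_id, prs$sample_id)]
  df$prs_norm <- prs$normalized[match(df$sample_id, prs$sample_id)]

  factor_cols <- paste0(names(config$encodings), "_enc")
  screens <- do.call(rbind, lapply(factor_cols, function(cl)
    univariable_fit(df, cl)))
  selected <- screens$factor[screens$p < config$selection_p]
  mains <- union(union(selected, config$forced_factors), "prs_std")
  mains <- intersect(c(factor_cols, "prs_std"), mains)  # deterministic order
  log_msg("univariable screen: selected %s; forced %s",
          paste(selected, collapse = ", "),
          paste(config$forced_factors, collapse = ", "))

  prs_assoc <- prs_association(df, prs, pcs)

  lrts <- lapply(config$interaction_candidates, function(pair) {
    res <- interaction_lrt(df, pair[1], pair[2])
    res$pair <- pair
    res
  })
  kept_inter <- Filter(function(r) r$p < config$selection_p, lrts)
  interactions <- lapply(kept_inter, function(r) r$pair)
  log_msg("interaction LRTs: %d of %d candidates retained",
          length(interactions), length(lrts))
  # a retained interaction forces its non-covariate parents into the model
  parents <- setdiff(unique(unlist(interactions)), c("age_bin", "centre_num"))
  mains <- intersect(c(factor_cols, "prs_std"), union(mains, parents))

  spec_base <- model_spec(mains, interactions = list())
  spec_int <- model_spec(mains, interactions = interactions)
  fit_base <- fit_multivariable(build_design(df, spec_base), df$outcome)
  fit_int <- fit_multivariable(build_design(df, spec_int), df$outcome)
  hl <- hosmer_lemeshow(fit_int$fitted, df$outcome)

  cv_base <- cv_auc(df, spec_base, n_perm = config$n_perm,
                    train_frac = config$train_frac, seed = config$seed)
  cv_int <- if (length(interactions)) {
    cv_auc(df, spec_int, n_perm = config$n_perm,
           train_frac = config$train_frac, seed = config$seed)
  } else NULL
  auc_cmp <- if (!is.null(cv_int)) compare_auc(cv_int, cv_base) else NULL

  final_fit <- if (length(interactions)) fit_int else fit_base
  final_spec <- if (length(interactions)) spec_int else spec_base
  risk <- predict_risk(final_fit, df, final_spec)
  bands <- stratify_bands(risk$probability)
  strat <- band_odds_ratios(bands, df$outcome)

  bundle <- list(
    config = config, panel = panel, cohort = df, prs = prs, pcs = pcs,
    screens = screens, selected = selected, prs_association = prs_assoc,
    interaction_tests = lrts, interactions = interactions,
    fit_base = fit_base, fit_interaction = fit_int,
    hosmer_lemeshow = hl, cv_base = cv_base, cv_interaction = cv_int,
    auc_comparison = auc_cmp, risk = risk, bands = bands,
    stratification = strat,
    manifest = list(seed = config$seed, n = nrow(df),
                    n_snps = nrow(panel),
                    package_version = as.character(utils::packageVersion("prsband")))
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(bundle)
  bundle
}

# Serialize the bundle's tables and summaries under config$output_dir.
write_pipeline_outputs <- function(bundle) {
  dir <- bundle$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$screens, file.path(dir, "univariable.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$stratification,
                     file.path(dir, "stratification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$prs[, c("sample_id", "raw", "normalized",
                                    "standardized")],
                     file.path(dir, "prs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fit <- bundle$fit_interaction
  jsonlite::write_json(list(
    coefficients = as.list(fit$coefficients),
    global_wald = fit$global_wald,
    hosmer_lemeshow = bundle$hosmer_lemeshow[c("statistic", "df", "p")],
    cv_auc = list(
      base = list(median = bundle$cv_base$median, ci = bundle$cv_base$ci),
      interaction = if (!is.null(bundle$cv_interaction))
        list(median = bundle$cv_interaction$median,
             ci = bundle$cv_interaction$ci),
      comparison_p = if (!is.null(bundle$auc_comparison))
        bundle$auc_comparison$p
    ),
    manifest = bundle$manifest
  ), file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}
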