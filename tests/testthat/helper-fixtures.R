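# Small in-code fixtures shared across test files.

# Hand-built panel with explicit ORs and statuses.
make_panel <- function(or_values, eaf = rep(0.3, length(or_values)),
                       status = rep("ok", length(or_values))) {
  n <- length(or_values)
  snp_panel(data.frame(
    rsid = sprintf("rs%04d", seq_len(n)),
    effect_allele = rep("A", n), other_allele = rep("G", n),
    or_value = or_values, eaf = eaf, status = status,
    stringsAsFactors = FALSE
  ))
}

# Deterministic genotype matrix with optional missing entries.
make_genotypes <- function(n_samples, rsids, seed = 1, missing = 0) {
  set.seed(seed)
  m <- matrix(sample(0:2, n_samples * length(rsids), replace = TRUE),
              nrow = n_samples,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)), rsids))
  if (missing > 0) {
    idx <- sample(length(m), missing)
    m[idx] <- NA
  }
  m
}

# Minimal encoded cohort for model-level tests: continuous risk factors and
# a Bernoulli outcome from a known logistic model.
make_logistic_cohort <- function(n, beta, intercept = -1, seed = 1) {
  set.seed(seed)
  k <- length(beta)
  X <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  lp <- intercept + drop(X %*% beta)
  df <- as.data.frame(X)
  df$outcome <- stats::rbinom(n, 1, stats::plogis(lp))
  df$age_bin <- sample(0:7, n, replace = TRUE)
  df$centre_num <- sample(0:1, n, replace = TRUE)
  df
}

# Fully simulated, encoded cohort via the generator, small and fast.
make_sim_cohort <- function(seed = 1, n_cases = 455, n_controls = 642,
                            interactions = list(), n_snps = 20,
                            n_population = 6000) {
  cfg <- simulation_config(n_snps = n_snps, seed = seed,
                           interaction_terms = interactions,
                           n_cases = n_cases, n_controls = n_controls)
  panel <- generate_snp_panel(cfg)
  cfg$baseline_log_odds <- cfg$baseline_log_odds -
    expected_predictor_shift(panel, cfg)
  pop <- simulate_population(panel, cfg, n_population)
  cohort <- ascertain_case_control(pop, n_cases, n_controls, seed = seed)
  list(cohort = cohort, panel = panel, config = cfg)
}
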