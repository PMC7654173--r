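# Generator: panel composition, Hardy-Weinberg structure, the prospective
# disease model and retrospective ascertainment.

test_that("panel generation honours size, effect bounds and injected composition", {
  cfg <- simulation_config(n_snps = 92, seed = 1)
  panel <- generate_snp_panel(cfg)
  expect_s3_class(panel, "snp_panel")
  expect_equal(nrow(panel), 92)
  expect_true(all(panel$or_value <= 0.95 | panel$or_value >= 1.05))
  expect_equal(panel$weight, log(panel$or_value))

  cfg123 <- simulation_config(n_snps = 123, seed = 2)
  p123 <- generate_snp_panel(cfg123, n_near_null = 28, n_failed = 3)
  expect_equal(sum(p123$or_value > 0.95 & p123$or_value < 1.05), 28)
  expect_equal(sum(p123$status == "genotyping_failure"), 3)

  expect_identical(generate_snp_panel(cfg), generate_snp_panel(cfg))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulation_config(age_bin_probs = rep(0.2, 8)), "summing to 1")
  bad_specs <- default_phenotype_specs()
  bad_specs$density$control_freqs <- rep(0.1, 5)
  expect_error(simulation_config(phenotype_specs = bad_specs), "density")
})

test_that("control genotype frequencies follow Hardy-Weinberg at MAF 0.3", {
  maf <- 0.3
  cfg <- simulation_config(n_snps = 1, maf_range = c(maf, maf),
                           per_allele_log_or = 0, seed = 3)
  panel <- generate_snp_panel(cfg)
  n <- 20000
  pop <- simulate_population(panel, cfg, n)
  obs <- tabulate(pop$genotypes[, 1] + 1, nbins = 3) / n
  expected <- stats::dbinom(0:2, 2, maf)  # (0.49, 0.42, 0.09)
  expect_equal(expected, c(0.49, 0.42, 0.09))
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(obs - expected) < 4 * se))
})

test_that("with all effects zero the case fraction matches the baseline", {
  specs <- default_phenotype_specs()
  for (nm in names(specs)) specs[[nm]]$log_or[] <- 0
  cfg <- simulation_config(n_snps = 1, per_allele_log_or = 0,
                           phenotype_specs = specs,
                           baseline_log_odds = stats::qlogis(0.12), seed = 4)
  panel <- generate_snp_panel(cfg)
  n <- 50000
  pop <- simulate_population(panel, cfg, n)
  se <- sqrt(0.12 * 0.88 / n)
  expect_lt(abs(mean(pop$outcome) - 0.12), 3 * se)
})

test_that("population fits recover injected effects and ascertainment preserves the OR", {
  true_b <- 0.4
  n_pop <- 20000
  n_rep <- 100
  covered <- logical(n_rep)
  asc_est <- numeric(n_rep)
  specs <- default_phenotype_specs()
  for (nm in names(specs)) specs[[nm]]$log_or[] <- 0
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(n_snps = 1, maf_range = c(0.3, 0.3),
                             per_allele_log_or = true_b,
                             phenotype_specs = specs,
                             baseline_log_odds = stats::qlogis(0.15),
                             seed = 100 + r)
    panel <- generate_snp_panel(cfg)
    cfg$baseline_log_odds <- cfg$baseline_log_odds -
      expected_predictor_shift(panel, cfg)
    pop <- simulate_population(panel, cfg, n_pop)
    d <- data.frame(outcome = pop$outcome, g = pop$genotypes[, 1])
    fit <- suppressWarnings(glm(outcome ~ g, data = d, family = binomial()))
    est <- coef(fit)["g"]
    se <- sqrt(diag(vcov(fit))["g"])
    covered[r] <- abs(est - true_b) < 1.96 * se

    cohort <- ascertain_case_control(pop, 455, 642, seed = r)
    dc <- data.frame(outcome = cohort$phenotypes$outcome,
                     g = cohort$genotypes[, 1])
    asc_est[r] <- coef(suppressWarnings(
      glm(outcome ~ g, data = dc, family = binomial())))["g"]
  }
  expect_gte(mean(covered), 0.9)
  # retrospective sampling leaves the log-OR unbiased
  expect_lt(abs(mean(asc_est) - true_b), 0.03)
})

test_that("ascertainment returns exact counts and errors on shortfall", {
  sc <- make_sim_cohort(seed = 9, n_cases = 100, n_controls = 150,
                        n_population = 2500)
  phen <- sc$cohort$phenotypes
  expect_equal(nrow(phen), 250)
  expect_equal(sum(phen$outcome == 1), 100)
  expect_equal(sum(phen$outcome == 0), 150)
  expect_equal(rownames(sc$cohort$genotypes), phen$sample_id)

  cfg <- sc$config
  pop <- simulate_population(sc$panel, cfg, 200)
  expect_error(ascertain_case_control(pop, 100000, 10, seed = 1),
               "short by")
})

test_that("the generator is deterministic under a fixed configuration", {
  cfg <- simulation_config(n_snps = 5, seed = 11,
                           interaction_terms = default_interaction_terms())
  panel <- generate_snp_panel(cfg)
  p1 <- simulate_population(panel, cfg, 500)
  p2 <- simulate_population(panel, cfg, 500)
  expect_identical(p1, p2)
  c1 <- ascertain_case_control(p1, 30, 40, seed = 2)
  c2 <- ascertain_case_control(p2, 30, 40, seed = 2)
  expect_identical(c1, c2)
})

test_that("panel per-SD calibration hits the target exactly in closed form", {
  cfg <- simulation_config(n_snps = 92, seed = 12)
  panel <- calibrate_panel_per_sd(generate_snp_panel(cfg), log(1.41))
  sd_prs <- sqrt(sum(panel$weight^2 * 2 * panel$eaf * (1 - panel$eaf)))
  expect_equal(sd_prs, log(1.41), tolerance = 1e-12)
})
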