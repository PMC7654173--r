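# AUC, cross-validated AUC, paired AUC comparison and decile-band
# stratification.

brute_force_auc <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(controls))
}

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:5, rep(1, 5)), "both classes")

  set.seed(61)
  for (r in 1:20) {
    s <- sample(1:8, 20, replace = TRUE)  # heavy ties
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_identical(auc(s, y), brute_force_auc(s, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  s <- rnorm(200)
  y <- rbinom(200, 1, plogis(s))
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("cross-validated AUC is deterministic and centred at 0.5 under noise", {
  df <- make_logistic_cohort(600, beta = 0, seed = 63)
  df$noise <- rnorm(600)
  spec <- model_spec("noise", covariates = character(0))
  cv1 <- cv_auc(df, spec, n_perm = 100, seed = 7)
  cv2 <- cv_auc(df, spec, n_perm = 100, seed = 7)
  expect_identical(cv1, cv2)
  expect_lt(abs(cv1$median - 0.5), 0.03)
  expect_true(all(cv1$aucs >= 0 & cv1$aucs <= 1))
  expect_equal(cv1$ci, unname(quantile(cv1$aucs, c(0.025, 0.975))))
})

test_that("cv_auc median approaches the generative AUC as n grows", {
  spec <- model_spec("x1", covariates = character(0))
  meds <- vapply(c(400, 3000), function(n) {
    df <- make_logistic_cohort(n, beta = 1, intercept = 0, seed = 64)
    cv_auc(df, spec, n_perm = 60, seed = 5)$median
  }, numeric(1))
  # single standardized predictor with beta 1: population AUC = Phi(delta/sqrt(2))
  target <- pnorm(1 / sqrt(2))
  expect_lt(abs(meds[2] - target), abs(meds[1] - target) + 0.02)
  expect_lt(abs(meds[2] - target), 0.03)
})

test_that("paired AUC comparison handles identity, dominance and pairing checks", {
  mk <- function(aucs, seed = 1) {
    structure(list(aucs = aucs, median = median(aucs),
                   ci = quantile(aucs, c(0.025, 0.975), names = FALSE),
                   n_perm = length(aucs), train_frac = 0.9, seed = seed),
              class = "cv_result")
  }
  a <- mk(rep(0.7, 100))
  expect_equal(compare_auc(a, a)$p, 1)
  set.seed(65)
  b <- mk(runif(100, 0.55, 0.65))
  expect_lt(compare_auc(mk(runif(100, 0.7, 0.8)), b)$p, 0.001)
  expect_error(compare_auc(a, mk(rep(0.6, 100), seed = 2)), "not paired")
})

test_that("decile bands partition the cohort with ties to the lower band", {
  bands <- stratify_bands(1:100)
  expect_equal(as.integer(table(bands)), c(10, 10, 20, 20, 20, 10, 10))
  # the reference band captures ranks 41-60
  expect_true(all(which(bands == "40-60%") == 41:60))
  expect_equal(length(bands), 100)
  expect_false(anyNA(bands))
  expect_error(stratify_bands(rep(1, 50)), "distinct")
})

test_that("band odds ratios reproduce closed-form two-band values", {
  mk_bands <- function(n_band, n_ref) {
    factor(rep(c("band", "40-60%"), c(n_band, n_ref)),
           levels = c("band", "40-60%"))
  }
  # 30 cases/60 controls vs 50/100: identical odds -> OR 1
  b1 <- mk_bands(90, 150)
  y1 <- c(rep(1, 30), rep(0, 60), rep(1, 50), rep(0, 100))
  r1 <- band_odds_ratios(b1, y1)
  expect_equal(r1$or[r1$band == "band"], 1, tolerance = 1e-6)
  # 3 cases/60 controls vs 50/100 -> OR (3/60)/(50/100) = 0.1
  b2 <- mk_bands(63, 150)
  y2 <- c(rep(1, 3), rep(0, 60), rep(1, 50), rep(0, 100))
  r2 <- band_odds_ratios(b2, y2)
  expect_equal(r2$or[r2$band == "band"], 0.1, tolerance = 1e-6)
  expect_equal(r2$or[r2$band == "40-60%"], 1)
  # column percentages sum to 100
  expect_equal(sum(r2$pct_controls), 100, tolerance = 0.1)
  expect_equal(sum(r2$pct_cases), 100, tolerance = 0.1)
})

test_that("band ORs rise monotonically under a monotone generative risk", {
  n_rep <- 20
  good <- 0
  delta <- qnorm(0.8) * sqrt(2)  # discrimination of a strong combined model
  for (r in seq_len(n_rep)) {
    set.seed(660 + r)
    n <- 1097
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(qlogis(0.415) + delta * s))
    if (length(unique(y)) < 2) next
    rep_tab <- band_odds_ratios(stratify_bands(s), y)
    ors <- rep_tab$or
    if (!anyNA(ors) && all(diff(ors) > -1e-12) &&
        ors[1] < 1 && ors[length(ors)] > 1) good <- good + 1
  }
  expect_gte(good, 0.9 * n_rep)
})
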