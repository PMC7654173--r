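# Design construction, multivariable fitting, Hosmer-Lemeshow calibration
# and risk prediction.

test_that("the design matrix has the specified columns in deterministic order", {
  df <- make_logistic_cohort(50, beta = rep(0.1, 6), seed = 51)
  spec <- model_spec(paste0("x", 1:6),
                     interactions = list(c("age_bin", "x1"),
                                         c("age_bin", "x2")))
  X <- build_design(df, spec)
  expect_equal(ncol(X), 1 + 6 + 2 + 2)
  expect_equal(colnames(X)[1], "(Intercept)")
  expect_equal(X[, "age_bin:x1"], X[, "age_bin"] * X[, "x1"],
               ignore_attr = TRUE)
  expect_identical(X, build_design(df, spec))
  expect_error(build_design(df, model_spec(c("x1", "nope"))), "nope")
  expect_error(model_spec("x1", interactions = list(c("x1", "zz"))),
               "reference included")
})

test_that("multivariable fits recover known coefficients with nominal coverage", {
  true_b <- c(0.5, -0.4, 0.3)
  n_rep <- 60
  covered <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    df <- make_logistic_cohort(4000, beta = true_b, seed = 500 + r)
    spec <- model_spec(paste0("x", 1:3), covariates = character(0))
    X <- build_design(df, spec)
    fit <- fit_multivariable(X, df$outcome)
    for (j in 1:3) {
      w <- fit$wald[fit$wald$term == paste0("x", j), ]
      covered[r, j] <- abs(w$estimate - true_b[j]) < 1.96 * w$se
    }
  }
  expect_gte(mean(covered), 0.9)
})

test_that("duplicating every row leaves the point estimates unchanged", {
  df <- make_logistic_cohort(500, beta = c(0.4, -0.2), seed = 52)
  spec <- model_spec(c("x1", "x2"), covariates = character(0))
  X <- build_design(df, spec)
  f1 <- fit_multivariable(X, df$outcome)
  f2 <- fit_multivariable(X[rep(1:500, 2), ], rep(df$outcome, 2))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("rank deficiency and separation raise distinct errors", {
  df <- make_logistic_cohort(200, beta = 0.3, seed = 53)
  df$x2 <- 2 * df$x1
  X <- build_design(df, model_spec(c("x1", "x2"), covariates = character(0)))
  expect_error(fit_multivariable(X, df$outcome), "rank deficient")

  y <- c(rep(0, 50), rep(1, 50))
  X2 <- cbind(`(Intercept)` = 1, x = c(seq(-2, -0.1, length.out = 50),
                                       seq(0.1, 2, length.out = 50)))
  expect_error(fit_multivariable(X2, y), "separation")
})

test_that("the global Wald test is reported and p is uniform under the null", {
  ps <- numeric(40)
  for (r in 1:40) {
    df <- make_logistic_cohort(400, beta = c(0, 0), seed = 540 + r)
    X <- build_design(df, model_spec(c("x1", "x2"), covariates = character(0)))
    ps[r] <- fit_multivariable(X, df$outcome)$global_wald$p
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Hosmer-Lemeshow matches a hand-computed oracle on a tiny grouping", {
  # 3 groups x 4 observations with fixed probabilities
  probs <- c(0.1, 0.1, 0.2, 0.2, 0.45, 0.45, 0.5, 0.5, 0.8, 0.8, 0.9, 0.9)
  y <- c(0, 0, 1, 0, 1, 0, 1, 0, 1, 1, 1, 0)
  hl <- hosmer_lemeshow(probs, y, groups = 3)
  # independent oracle: explicit sum over groups and both outcomes
  grp <- rep(1:3, each = 4)
  stat <- 0
  for (g in 1:3) {
    o1 <- sum(y[grp == g]); e1 <- sum(probs[grp == g])
    o0 <- 4 - o1; e0 <- 4 - e1
    stat <- stat + (o1 - e1)^2 / e1 + (o0 - e0)^2 / e0
  }
  expect_equal(hl$statistic, stat, tolerance = 1e-9)
  expect_equal(hl$df, 1)
  expect_gte(hl$statistic, 0)
})

test_that("Hosmer-Lemeshow is non-significant when the model is correctly specified", {
  ok <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    df <- make_logistic_cohort(4000, beta = c(0.8, -0.5), seed = 560 + r)
    spec <- model_spec(c("x1", "x2"), covariates = character(0))
    X <- build_design(df, spec)
    fit <- fit_multivariable(X, df$outcome)
    if (hosmer_lemeshow(fit$fitted, df$outcome)$p > 0.01) ok <- ok + 1
  }
  expect_gte(ok, ceiling(0.95 * n_rep))
})

test_that("predicted risk is the logistic transform of the linear predictor", {
  df <- make_logistic_cohort(300, beta = c(0.6, 0.2), seed = 57)
  spec <- model_spec(c("x1", "x2"), covariates = character(0))
  X <- build_design(df, spec)
  fit <- fit_multivariable(X, df$outcome)
  pr <- predict_risk(fit, df, spec)
  expect_true(all(pr$probability > 0 & pr$probability < 1))
  expect_equal(pr$probability, plogis(pr$linear_predictor))

  # all-zero covariates give expit(intercept)
  zero <- df[1, ]; zero$x1 <- 0; zero$x2 <- 0
  expect_equal(predict_risk(fit, zero, spec)$probability,
               plogis(unname(fit$coefficients["(Intercept)"])))

  # monotone in a positive-coefficient column
  j <- which.max(fit$coefficients[c("x1", "x2")])
  up <- df; up[[names(j)]] <- up[[names(j)]] + 1
  expect_true(all(predict_risk(fit, up, spec)$probability >
                    pr$probability - 1e-12 |
                    fit$coefficients[names(j)] < 0))
})

test_that("an interaction model never has lower log-likelihood than its nested base", {
  for (r in 1:5) {
    df <- make_logistic_cohort(600, beta = c(0.3, 0.2), seed = 580 + r)
    base <- model_spec(c("x1", "x2"), covariates = character(0))
    full <- model_spec(c("x1", "x2"),
                       interactions = list(c("x1", "x2")),
                       covariates = character(0))
    f0 <- fit_multivariable(build_design(df, base), df$outcome)
    f1 <- fit_multivariable(build_design(df, full), df$outcome)
    expect_gte(f1$loglik, f0$loglik - 1e-8)
  }
})
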