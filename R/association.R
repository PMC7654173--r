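# Univariable logistic screens, PRS association, interaction LRTs and
# control-only Spearman independence checks.

# Maximum-likelihood logistic fit with separation / convergence guards.
fit_logistic <- function(df, formula) {
  fit <- suppressWarnings(stats::glm(formula, data = df, family = stats::binomial()))
  if (any(is.na(stats::coef(fit)))) {
    stop("design is rank deficient: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  p <- stats::fitted(fit)
  if (any(p > 1 - 1e-10) || any(p < 1e-10)) {
    stop("(quasi-)complete separation detected; simplify the model or pool categories",
         call. = FALSE)
  }
  if (!fit$converged) stop("logistic regression did not converge", call. = FALSE)
  fit
}

wald_row <- function(fit, term) {
  est <- stats::coef(fit)[term]
  se <- sqrt(diag(stats::vcov(fit))[term])
  z <- est / se
  c(est = unname(est), se = unname(se),
    p = unname(2 * stats::pnorm(-abs(z))))
}

#' Univariable logistic screen of one risk factor
#'
#' Fits `outcome ~ factor + age_bin + centre` by maximum likelihood and
#' returns the per-unit odds ratio with Wald 95% CI and two-sided p, plus the
#' standardized coefficient (coefficient times the sample SD of the factor).
#'
#' @param cohort Encoded cohort data frame (see [encode_cohort()]); must have
#'   `outcome` coded 0/1.
#' @param factor_col Name of the encoded factor column.
#' @param covariates Adjustment columns (default `age_bin` and `centre_num`);
#'   use `NULL` for an unadjusted fit.
#' @return One-row data frame of class `fit_result`: `factor`, `or`,
#'   `ci_low`, `ci_high`, `p`, `std_beta`, `n`.
#' @export
univariable_fit <- function(cohort, factor_col,
                            covariates = c("age_bin", "centre_num")) {
  x <- cohort[[factor_col]]
  if (is.null(x)) stop("factor column not found: ", factor_col, call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("factor must take >= 2 distinct values", call. = FALSE)
  }
  rhs <- paste(c(factor_col, covariates), collapse = " + ")
  fit <- fit_logistic(cohort, stats::as.formula(paste("outcome ~", rhs)))
  w <- wald_row(fit, factor_col)
  structure(data.frame(
    factor = factor_col,
    or = exp(w["est"]),
    ci_low = exp(w["est"] - 1.96 * w["se"]),
    ci_high = exp(w["est"] + 1.96 * w["se"]),
    p = w["p"],
    std_beta = w["est"] * stats::sd(x),
    n = nrow(cohort),
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("fit_result", "data.frame"))
}

#' PRS association with tail contrasts
#'
#' Fits `outcome ~ standardized PRS + age_bin + PC1..PCk` and reports the
#' odds ratio per 1 SD of the PRS. Additionally contrasts the distribution
#' tails against the middle of the PRS distribution by indicator logistic
#' regression: bottom `tail` fraction vs the 40-60% band, and top `tail`
#' fraction vs the same band.
#'
#' @param cohort Encoded cohort data frame with an `outcome` column.
#' @param prs A `prs_result` aligned by `sample_id`, or a numeric vector of
#'   standardized scores in cohort order.
#' @param pcs Samples x k PC matrix from [genotype_pcs()], or `NULL` for no
#'   PC adjustment.
#' @param adjust_centre Also adjust for centre (off by default: the PRS model
#'   adjusts for age and principal components only).
#' @param tail Tail fraction for the extreme contrasts (default 0.05).
#' @param reference Quantile band used as reference, default `c(0.4, 0.6)`.
#' @return List with `fit` (a `fit_result` for the per-SD OR), `low_tail` and
#'   `high_tail` (fit_results of the indicator contrasts).
#' @export
prs_association <- function(cohort, prs, pcs = NULL, adjust_centre = FALSE,
                            tail = 0.05, reference = c(0.4, 0.6)) {
  s <- if (inherits(prs, "prs_result")) {
    prs$standardized[match(cohort$sample_id, prs$sample_id)]
  } else prs
  if (anyNA(s)) stop("PRS missing for some cohort samples", call. = FALSE)
  df <- cohort
  df$prs_std <- s
  covs <- "age_bin"
  if (!is.null(pcs)) {
    k <- ncol(pcs)
    pcs_m <- pcs[match(cohort$sample_id, rownames(pcs)), , drop = FALSE]
    for (j in seq_len(k)) df[[paste0("PC", j)]] <- pcs_m[, j]
    covs <- c(covs, paste0("PC", seq_len(k)))
  }
  if (adjust_centre) covs <- c(covs, "centre_num")
  main <- univariable_fit(df, "prs_std", covariates = covs)
  main$factor <- "prs_per_sd"

  q <- stats::quantile(s, c(tail, reference, 1 - tail), names = FALSE)
  tail_fit <- function(in_tail, label) {
    in_ref <- s > q[2] & s <= q[3]
    sub <- df[in_tail | in_ref, , drop = FALSE]
    sub$tail_ind <- as.numeric(in_tail[in_tail | in_ref])
    ft <- univariable_fit(sub, "tail_ind", covariates = NULL)
    ft$factor <- label
    ft
  }
  list(
    fit = main,
    low_tail = tail_fit(s <= q[1], sprintf("bottom_%d%%_vs_ref", round(100 * tail))),
    high_tail = tail_fit(s > q[4], sprintf("top_%d%%_vs_ref", round(100 * tail)))
  )
}

#' Likelihood-ratio test for an interaction term
#'
#' Compares `outcome ~ a + b + a:b + covariates` against the nested model
#' without `a:b`; the statistic `2 * (llik_full - llik_reduced)` (floored at
#' 0) is referred to a chi-square with df equal to the added parameters.
#'
#' @param cohort Encoded cohort data frame.
#' @param factor_a,factor_b Names of the two encoded columns.
#' @param covariates Adjustment columns for both models.
#' @return List with `lrt`, `df`, `p`, and the two log-likelihoods.
#' @export
interaction_lrt <- function(cohort, factor_a, factor_b,
                            covariates = c("age_bin", "centre_num")) {
  covariates <- setdiff(covariates, c(factor_a, factor_b))
  base <- paste(c(factor_a, factor_b, covariates), collapse = " + ")
  f_red <- stats::as.formula(paste("outcome ~", base))
  f_full <- stats::as.formula(
    paste("outcome ~", base, "+", factor_a, ":", factor_b))
  red <- fit_logistic(cohort, f_red)
  # constant interaction column collapses to the reduced fit
  inter <- cohort[[factor_a]] * cohort[[factor_b]]
  if (length(unique(inter)) < 2 ||
      qr(cbind(1, cohort[[factor_a]], cohort[[factor_b]], inter))$rank < 4) {
    return(list(lrt = 0, df = 1L, p = 1,
                loglik_full = as.numeric(stats::logLik(red)),
                loglik_reduced = as.numeric(stats::logLik(red))))
  }
  full <- fit_logistic(cohort, f_full)
  df <- length(stats::coef(full)) - length(stats::coef(red))
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(red))))
  list(lrt = lrt, df = df,
       p = stats::pchisq(lrt, df, lower.tail = FALSE),
       loglik_full = as.numeric(stats::logLik(full)),
       loglik_reduced = as.numeric(stats::logLik(red)))
}

#' Spearman independence screen over controls
#'
#' Pairwise Spearman rank correlations (average ranks for ties) of the given
#' variables over unaffected controls only, with two-sided p-values, used to
#' confirm independence of the PRS and the phenotypic risk factors.
#'
#' @param cohort Encoded cohort data frame with `outcome`.
#' @param vars Names of numeric columns to correlate.
#' @return List of matrices `rho` and `p`; pairs involving a constant
#'   variable are `NA`.
#' @export
spearman_independence <- function(cohort, vars) {
  ctrl <- cohort[cohort$outcome == 0, vars, drop = FALSE]
  if (nrow(ctrl) < 3) stop("need >= 3 controls", call. = FALSE)
  k <- length(vars)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    p[i, i] <- 0
    for (j in seq_len(k)) {
      if (j <= i) next
      xi <- ctrl[[vars[i]]]
      xj <- ctrl[[vars[j]]]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next  # rho undefined
      ct <- suppressWarnings(
        stats::cor.test(xi, xj, method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}
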