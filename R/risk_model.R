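# The final multivariable logistic model: design construction, fitting with
# Wald diagnostics, Hosmer-Lemeshow calibration, and per-woman prediction.

#' Multivariable model specification
#'
#' Names the encoded main effects, the interaction pairs and the covariates
#' of the final model. Age inside interaction terms is the same ordinal
#' age-bin index used as the main-effect covariate.
#'
#' @param main_effects Encoded column names (significant univariable factors
#'   plus the standardized PRS; family history and menarche are conventionally
#'   forced in regardless of significance).
#' @param interactions List of length-2 character vectors, each naming two
#'   columns whose elementwise product enters the design (e.g.
#'   `c("age_bin", "density_enc")`).
#' @param covariates Adjustment columns.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(main_effects,
                       interactions = list(),
                       covariates = c("age_bin", "centre_num")) {
  parents <- unique(c(main_effects, covariates))
  for (pair in interactions) {
    if (length(pair) != 2 || !all(pair %in% parents)) {
      stop("interaction terms must reference included main effects/covariates",
           call. = FALSE)
    }
  }
  structure(list(main_effects = main_effects, interactions = interactions,
                 covariates = covariates), class = "model_spec")
}

#' Build the design matrix for a model specification
#'
#' Columns, in deterministic order: intercept, main effects, elementwise
#' product interaction columns (`a:b`), covariates.
#'
#' @param cohort Encoded cohort data frame.
#' @param spec A [model_spec()].
#' @return Numeric matrix with named columns.
#' @export
build_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- unique(c(spec$main_effects, spec$covariates))
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) {
    stop("cohort lacks model columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(cohort)))
  for (cl in spec$main_effects) X <- cbind(X, stats::setNames(cohort[cl], cl))
  for (pair in spec$interactions) {
    nm <- paste(pair, collapse = ":")
    X <- cbind(X, stats::setNames(
      data.frame(cohort[[pair[1]]] * cohort[[pair[2]]]), nm))
  }
  for (cl in spec$covariates) X <- cbind(X, stats::setNames(cohort[cl], cl))
  as.matrix(X)
}

#' Fit the multivariable logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a design
#' matrix, with per-coefficient Wald z tests and a global Wald chi-square on
#' all non-intercept coefficients. Rank deficiency, separation and
#' non-convergence raise distinct errors.
#'
#' @param design Design matrix from [build_design()] (first column intercept).
#' @param outcome Binary 0/1 vector.
#' @return Object of class `risk_model_fit`: coefficients, covariance,
#'   log-likelihood, per-term Wald table, global Wald test, fitted
#'   probabilities.
#' @export
fit_multivariable <- function(design, outcome) {
  stopifnot(is.matrix(design), length(outcome) == nrow(design))
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, outcome, family = stats::binomial()))
  p <- fit$fitted.values
  if (any(p > 1 - 1e-10) || any(p < 1e-10)) {
    stop("(quasi-)complete separation detected", call. = FALSE)
  }
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  # observed-information covariance: (X' W X)^-1 at the MLE
  W <- p * (1 - p)
  V <- solve(crossprod(design * sqrt(W)))
  dimnames(V) <- list(colnames(design), colnames(design))
  b <- stats::setNames(fit$coefficients, colnames(design))
  se <- sqrt(diag(V))
  z <- b / se
  wald <- data.frame(
    term = names(b), estimate = unname(b), se = unname(se), z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))), stringsAsFactors = FALSE
  )
  free <- setdiff(names(b), "(Intercept)")
  bs <- b[free]
  gw <- drop(t(bs) %*% solve(V[free, free, drop = FALSE]) %*% bs)
  ll <- sum(stats::dbinom(outcome, 1, p, log = TRUE))
  structure(list(
    coefficients = b, vcov = V, loglik = ll, wald = wald,
    global_wald = list(chisq = gw, df = length(free),
                       p = stats::pchisq(gw, length(free), lower.tail = FALSE)),
    fitted = p, design_columns = colnames(design), converged = TRUE
  ), class = "risk_model_fit")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Partitions women into groups by deciles (default) of predicted
#' probability, with ties at a cut point assigned to the lower group, and
#' computes the calibration chi-square `sum over groups and outcomes of
#' (observed - expected)^2 / expected` on `groups - 2` degrees of freedom.
#' Cut points that coincide (heavily tied predictions) merge groups with a
#' warning.
#'
#' @param probs Predicted probabilities.
#' @param outcome Binary 0/1 vector.
#' @param groups Number of groups (>= 3), default 10 (deciles).
#' @return List with `statistic`, `df`, `p`, `groups` and the per-group
#'   observed/expected table.
#' @export
hosmer_lemeshow <- function(probs, outcome, groups = 10) {
  stopifnot(length(probs) == length(outcome), groups >= 3)
  qs <- stats::quantile(probs, seq(0, 1, length.out = groups + 1),
                        names = FALSE)
  brk <- unique(qs)
  if (length(brk) < groups + 1) {
    warning("tied predicted probabilities: merged ",
            groups + 1 - length(brk), " group boundary(ies)")
  }
  g <- cut(probs, breaks = brk, include.lowest = TRUE, right = TRUE)
  obs1 <- tapply(outcome, g, sum)
  n_g <- tapply(outcome, g, length)
  exp1 <- tapply(probs, g, sum)
  obs0 <- n_g - obs1
  exp0 <- n_g - exp1
  stat <- sum((obs1 - exp1)^2 / exp1 + (obs0 - exp0)^2 / exp0)
  df <- length(levels(g)) - 2
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       groups = length(levels(g)),
       table = data.frame(n = as.integer(n_g), observed = as.integer(obs1),
                          expected = as.numeric(exp1)))
}

#' Predict per-woman risk scores
#'
#' Linear predictor and fitted probability for each woman under a fitted
#' model. In a case-control design the intercept reflects ascertainment, so
#' the probability is a relative risk score suitable for ranking and band
#' stratification, not an absolute 5-year risk.
#'
#' @param fit A `risk_model_fit`.
#' @param cohort Encoded cohort data frame, or a design matrix whose columns
#'   match the fit.
#' @param spec The [model_spec()] used at fit time (required when `cohort`
#'   is a data frame).
#' @return Data frame with `linear_predictor` and `probability`.
#' @export
predict_risk <- function(fit, cohort, spec = NULL) {
  stopifnot(inherits(fit, "risk_model_fit"))
  X <- if (is.matrix(cohort)) cohort else {
    if (is.null(spec)) stop("`spec` required with a data-frame cohort", call. = FALSE)
    build_design(cohort, spec)
  }
  if (!identical(colnames(X), fit$design_columns)) {
    stop("design columns do not match the fitted model", call. = FALSE)
  }
  lp <- drop(X %*% fit$coefficients)
  data.frame(linear_predictor = lp, probability = stats::plogis(lp))
}
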