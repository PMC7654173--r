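# Discrimination and stratification: Mann-Whitney AUC, cross-validated AUC
# over repeated 90/10 splits, paired AUC comparison, and decile-band odds
# ratios against the 40-60% reference band.

#' Mann-Whitney AUC
#'
#' Probability that a random case scores above a random control, with ties
#' credited 0.5 — computed from average ranks, equivalent to exhaustive pair
#' counting.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary 0/1 vector (1 = case).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)  # average ranks handle ties as 0.5 credit
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC over repeated random splits
#'
#' For each of `n_perm` replicates: draw a uniform random `train_frac` /
#' `1 - train_frac` split, fit the model specification on the training set,
#' and compute the Mann-Whitney AUC of its predictions on the held-out set.
#' Splits whose test half lacks one of the classes are redrawn (with a
#' warning); `stratified = TRUE` splits within class instead.
#'
#' @param cohort Encoded cohort data frame with `outcome`.
#' @param spec A [model_spec()].
#' @param n_perm Number of repeated splits (1000 in the emulated protocol;
#'   smaller values for quick checks).
#' @param train_frac Training fraction (default 0.9).
#' @param seed Integer seed; the replicate split sequence is fully
#'   reproducible, so two specs evaluated at the same seed share splits.
#' @param stratified Split within outcome class.
#' @return Object of class `cv_result`: `aucs`, `median`, percentile 95%
#'   `ci`, `n_perm`, `train_frac`, `seed`.
#' @export
cv_auc <- function(cohort, spec, n_perm = 1000, train_frac = 0.9, seed = 1L,
                   stratified = FALSE) {
  X <- build_design(cohort, spec)
  y <- cohort$outcome
  n <- nrow(X)
  n_train <- round(train_frac * n)
  set.seed(seed)
  aucs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    for (try in seq_len(100)) {
      tr <- if (stratified) {
        c(sample(which(y == 1), round(train_frac * sum(y == 1))),
          sample(which(y == 0), round(train_frac * sum(y == 0))))
      } else sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      if (length(unique(y[te])) == 2) break
      if (try == 100) {
        stop("could not draw a test split with both classes; use stratified = TRUE",
             call. = FALSE)
      }
      warning("test split with a single class redrawn")
    }
    fit <- fit_multivariable(X[tr, , drop = FALSE], y[tr])
    lp <- drop(X[te, , drop = FALSE] %*% fit$coefficients)
    aucs[b] <- auc(lp, y[te])
  }
  structure(list(
    aucs = aucs, median = stats::median(aucs),
    ci = stats::quantile(aucs, c(0.025, 0.975), names = FALSE),
    n_perm = n_perm, train_frac = train_frac, seed = seed
  ), class = "cv_result")
}

#' Paired comparison of two cross-validated AUC distributions
#'
#' Two-sided paired test on per-replicate AUC differences between two models
#' evaluated on the same replicate splits (same cohort, same seed, same
#' `n_perm`). Wilcoxon signed-rank by default; paired t optional. Replicates
#' share observations, so the p-value is approximate.
#'
#' @param cv_a,cv_b `cv_result` objects paired by seed.
#' @param method `"wilcoxon"` or `"t"`.
#' @return List with `p`, `median_diff` and the method used.
#' @export
compare_auc <- function(cv_a, cv_b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  stopifnot(inherits(cv_a, "cv_result"), inherits(cv_b, "cv_result"))
  if (cv_a$n_perm != cv_b$n_perm || cv_a$seed != cv_b$seed ||
      cv_a$train_frac != cv_b$train_frac) {
    stop("CV results are not paired (seed/n_perm/train_frac differ)",
         call. = FALSE)
  }
  d <- cv_a$aucs - cv_b$aucs
  p <- if (all(d == 0)) 1 else if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
  } else {
    stats::t.test(d)$p.value
  }
  list(p = p, median_diff = stats::median(d), method = method)
}

BAND_LABELS <- c("<10%", "10-20%", "20-40%", "40-60%", "60-80%", "80-90%", ">90%")

#' Stratify risk scores into quantile bands
#'
#' Cuts the cohort's risk scores at empirical quantiles 10/20/40/60/80/90%
#' (computed over the full cohort, cases and controls together) into seven
#' bands: the two extreme deciles, two flanking 20% bands on each side, and
#' the 40-60% reference band. Ties at a cut point fall to the lower band.
#'
#' @param scores Finite numeric risk scores.
#' @param probs Cut quantiles, default `c(.1, .2, .4, .6, .8, .9)`.
#' @param labels Band labels, default the decile-band layout.
#' @return Factor of band memberships with levels in increasing-risk order.
#' @export
stratify_bands <- function(scores,
                           probs = c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9),
                           labels = BAND_LABELS) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  qs <- stats::quantile(scores, probs, names = FALSE)
  brk <- c(min(scores), qs, max(scores))
  if (anyDuplicated(brk)) {
    stop("too few distinct scores to form the requested bands", call. = FALSE)
  }
  cut(scores, breaks = brk, labels = labels,
      include.lowest = TRUE, right = TRUE)
}

#' Band odds ratios against the reference band
#'
#' Indicator logistic regression of outcome on band membership with the
#' 40-60% band as reference: per-band odds ratio, Wald 95% CI and two-sided
#' p, together with the percentage of all controls and of all cases falling
#' in each band. An empty band is reported with an undefined OR rather than
#' dropped.
#'
#' @param bands Factor from [stratify_bands()].
#' @param outcomes Binary 0/1 vector.
#' @param reference Reference band label (default `"40-60%"`).
#' @return Data frame of class `stratification_report`: `band`, `n_controls`,
#'   `n_cases`, `pct_controls`, `pct_cases`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
band_odds_ratios <- function(bands, outcomes, reference = "40-60%") {
  stopifnot(length(bands) == length(outcomes))
  if (!reference %in% levels(bands)) {
    stop("reference band not among the band levels", call. = FALSE)
  }
  ref_out <- outcomes[bands == reference]
  if (length(unique(ref_out)) < 2) {
    stop("reference band must contain both cases and controls", call. = FALSE)
  }
  lv <- levels(bands)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  rows <- lapply(lv, function(b) {
    in_b <- bands == b
    c1 <- sum(outcomes[in_b] == 1)
    c0 <- sum(outcomes[in_b] == 0)
    row <- data.frame(
      band = b, n_controls = c0, n_cases = c1,
      pct_controls = 100 * c0 / n0, pct_cases = 100 * c1 / n1,
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
      stringsAsFactors = FALSE
    )
    if (b == reference) {
      row$or <- 1
      return(row)
    }
    if (c0 + c1 == 0) return(row)  # empty band: OR undefined
    sub <- in_b | bands == reference
    d <- data.frame(outcome = outcomes[sub], ind = as.numeric(in_b[sub]))
    ft <- tryCatch(univariable_fit(d, "ind", covariates = NULL),
                   error = function(e) NULL)
    if (!is.null(ft)) {
      row$or <- ft$or
      row$ci_low <- ft$ci_low
      row$ci_high <- ft$ci_high
      row$p <- ft$p
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stratification_report", "data.frame")
  out
}
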