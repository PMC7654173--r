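# SNP panel container, panel filtering, call-rate QC, PRS computation and
# normalization, and genotype principal components.

#' SNP weight panel
#'
#' Validates and classes a data frame of per-SNP effects: rsID, effect and
#' other allele, per-allele odds ratio, effect-allele frequency and a QC
#' status flag. The log-odds weight column is derived as `log(or_value)`.
#'
#' @param df Data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `or_value`, `eaf`, and optionally `status` (default `"ok"`).
#' @return Data frame of class `snp_panel` with an added `weight` column.
#' @export
snp_panel <- function(df) {
  need <- c("rsid", "effect_allele", "other_allele", "or_value", "eaf")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$rsid)) stop("panel rsids must be unique", call. = FALSE)
  if (any(df$or_value <= 0)) stop("panel ORs must be > 0", call. = FALSE)
  if (any(df$eaf <= 0 | df$eaf >= 1)) {
    stop("effect-allele frequencies must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(df$status)) df$status <- "ok"
  ok <- c("ok", "near_null", "genotyping_failure", "duplicate_error")
  if (!all(df$status %in% ok)) {
    stop("unknown panel status values: ",
         paste(setdiff(unique(df$status), ok), collapse = ", "), call. = FALSE)
  }
  df$weight <- log(df$or_value)
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' Filter a SNP panel
#'
#' Removes SNPs whose odds ratio lies strictly inside the near-null zone
#' (0.95, 1.05) and SNPs flagged `genotyping_failure` or `duplicate_error`.
#' A 123-SNP panel with 28 near-null and 3 failed SNPs retains 92.
#'
#' @param panel A `snp_panel`.
#' @param near_null_bounds Open interval of ORs treated as near-null;
#'   boundary values are retained (strict inequality).
#' @return The retained `snp_panel`, with a `removed` attribute: data frame of
#'   dropped rsids and reasons.
#' @export
filter_snp_panel <- function(panel, near_null_bounds = c(0.95, 1.05)) {
  stopifnot(inherits(panel, "snp_panel"))
  near <- panel$or_value > near_null_bounds[1] &
    panel$or_value < near_null_bounds[2]
  bad_status <- panel$status %in% c("genotyping_failure", "duplicate_error")
  drop <- near | bad_status
  if (all(drop)) stop("no SNPs retained; PRS undefined", call. = FALSE)
  removed <- data.frame(
    rsid = panel$rsid[drop],
    reason = ifelse(bad_status[drop], panel$status[drop], "near_null"),
    stringsAsFactors = FALSE
  )
  out <- panel[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Drop samples by genotype call rate
#'
#' Discards samples whose fraction of non-missing calls over the panel is
#' below `threshold` (default 0.95, strict `<`).
#'
#' @param gt Samples x SNPs genotype matrix with values 0/1/2/`NA`.
#' @param threshold Minimum call-rate fraction to keep a sample.
#' @return The retained matrix with a `dropped_samples` attribute (data frame
#'   of sample id and call rate).
#' @export
qc_samples <- function(gt, threshold = 0.95) {
  stopifnot(is.matrix(gt), nrow(gt) > 0)
  rate <- rowMeans(!is.na(gt))
  drop <- rate < threshold
  if (all(drop)) stop("all samples fail the call-rate threshold", call. = FALSE)
  out <- gt[!drop, , drop = FALSE]
  attr(out, "dropped_samples") <- data.frame(
    sample_id = rownames(gt)[drop], call_rate = unname(rate[drop]),
    stringsAsFactors = FALSE
  )
  out
}

#' Drop SNPs by genotyping rate and duplicate-control errors
#'
#' Discards SNPs whose per-SNP call rate is below `threshold` (strict `<`)
#' and SNPs the panel flags as `duplicate_error` (errors observed in control
#' duplicates), regardless of call rate.
#'
#' @param gt Samples x SNPs genotype matrix.
#' @param threshold Minimum genotyping-rate fraction to keep a SNP.
#' @param panel Optional `snp_panel` supplying `duplicate_error` flags.
#' @return The retained matrix with a `dropped_snps` attribute.
#' @export
qc_snps <- function(gt, threshold = 0.95, panel = NULL) {
  stopifnot(is.matrix(gt), ncol(gt) > 0)
  rate <- colMeans(!is.na(gt))
  drop <- rate < threshold
  reason <- ifelse(drop, "call_rate", NA_character_)
  if (!is.null(panel)) {
    dup <- panel$rsid[panel$status == "duplicate_error"]
    hit <- colnames(gt) %in% dup
    reason[hit & !drop] <- "duplicate_error"
    drop <- drop | hit
  }
  if (all(drop)) stop("all SNPs fail QC", call. = FALSE)
  out <- gt[, !drop, drop = FALSE]
  attr(out, "dropped_snps") <- data.frame(
    rsid = colnames(gt)[drop], call_rate = unname(rate[drop]),
    reason = reason[drop], stringsAsFactors = FALSE
  )
  out
}

#' Compute raw polygenic risk scores
#'
#' Per-sample weighted sum of effect-allele counts,
#' `PRS_i = sum_k w_k x_ik`, with `w_k = log(OR_k)` by default. Missing
#' genotypes are handled by `missing_policy`: `"expected"` substitutes the
#' Hardy-Weinberg expected dosage `2 * eaf`, `"zero"` substitutes 0, and
#' `"fail"` errors on any missing call.
#'
#' @param gt Samples x SNPs genotype matrix (values 0/1/2/`NA`).
#' @param panel A `snp_panel`; every panel SNP must be a column of `gt`.
#' @param missing_policy One of `"expected"`, `"zero"`, `"fail"`.
#' @param weights `"log_or"` (default) or `"or"` to sum raw odds ratios
#'   instead of log odds ratios (a literal reading kept for comparison only).
#' @return Named numeric vector of raw scores, one per sample.
#' @export
compute_prs <- function(gt, panel,
                        missing_policy = c("expected", "zero", "fail"),
                        weights = c("log_or", "or")) {
  stopifnot(is.matrix(gt), inherits(panel, "snp_panel"))
  missing_policy <- match.arg(missing_policy)
  weights <- match.arg(weights)
  absent <- setdiff(panel$rsid, colnames(gt))
  if (length(absent)) {
    stop("panel SNPs absent from genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x <- gt[, panel$rsid, drop = FALSE]
  if (anyNA(x)) {
    if (missing_policy == "fail") {
      stop("missing genotypes present with missing_policy = 'fail'",
           call. = FALSE)
    }
    fill <- if (missing_policy == "expected") 2 * panel$eaf else
      rep(0, nrow(panel))
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- fill[na_idx[, 2]]
  }
  w <- if (weights == "log_or") panel$weight else panel$or_value
  drop(x %*% w)
}

#' Normalize and standardize PRS over controls
#'
#' Two scales are always produced: `normalized` divides the raw score by the
#' control-sample median (typical women sit near 1), and `standardized`
#' centres and scales by the control mean and SD (the scale on which per-SD
#' odds ratios are estimated).
#'
#' @param raw Named numeric vector of raw scores.
#' @param control_ids Sample ids of the controls (>= 2 with finite scores).
#' @return Object of class `prs_result`: data frame with `sample_id`, `raw`,
#'   `normalized`, `standardized`; control median/mean/SD kept as attributes.
#' @export
normalize_prs <- function(raw, control_ids) {
  ctrl <- raw[names(raw) %in% control_ids]
  ctrl <- ctrl[is.finite(ctrl)]
  if (length(ctrl) < 2) stop("need >= 2 controls with finite scores", call. = FALSE)
  med <- stats::median(ctrl)
  if (med == 0) {
    stop("control median PRS is 0; use the standardized scale", call. = FALSE)
  }
  mu <- mean(ctrl)
  sdev <- stats::sd(ctrl)
  if (sdev == 0) stop("control PRS has zero variance", call. = FALSE)
  out <- data.frame(
    sample_id = names(raw), raw = unname(raw),
    normalized = unname(raw / med),
    standardized = unname((raw - mu) / sdev),
    stringsAsFactors = FALSE
  )
  attr(out, "control_median") <- med
  attr(out, "control_mean") <- mu
  attr(out, "control_sd") <- sdev
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Genotype principal components
#'
#' Principal-component coordinates of the dosage matrix for population
#' structure adjustment: missing values are mean-imputed per SNP, columns are
#' centred and scaled (unit variance by default, `2p(1-p)` optional),
#' zero-variance columns are dropped, and each component's sign is fixed so
#' its largest-magnitude loading is positive.
#'
#' @param gt Samples x SNPs genotype matrix.
#' @param k Number of leading components to return.
#' @param scaling `"unit"` (unit variance) or `"hwe"` (`sqrt(2 p (1-p))` with
#'   `p` the observed allele frequency).
#' @return Samples x `k` matrix of PC coordinates, columns `PC1..PCk` ordered
#'   by decreasing explained variance.
#' @export
genotype_pcs <- function(gt, k = 5, scaling = c("unit", "hwe")) {
  stopifnot(is.matrix(gt))
  scaling <- match.arg(scaling)
  x <- gt
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- mu[na_idx[, 2]]
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  s <- if (scaling == "unit") apply(x, 2, stats::sd) else {
    p <- colMeans(gt, na.rm = TRUE) / 2
    sqrt(2 * p * (1 - p))
  }
  keep <- s > 0
  x <- sweep(x[, keep, drop = FALSE], 2, s[keep], "/")
  if (k > min(dim(x)) - 1) {
    stop(sprintf("k = %d exceeds the usable rank of the matrix", k),
         call. = FALSE)
  }
  dec <- svd(x, nu = k, nv = k)
  scores <- dec$u %*% diag(dec$d[seq_len(k)], k, k)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    v <- dec$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(gt), paste0("PC", seq_len(k)))
  scores
}
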