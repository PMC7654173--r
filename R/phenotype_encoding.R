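# Odds-ratio encoding of categorical risk factors and 5-year age binning.

AGE_BIN_LABELS <- c("30-35", "35-40", "40-45", "45-50",
                    "50-55", "55-60", "60-65", ">65")

#' Factor encoding table
#'
#' An ordered category -> odds-ratio lookup for one phenotypic risk factor.
#' The reference category carries OR 1.
#'
#' @param factor_name Name of the factor.
#' @param categories Ordered category labels.
#' @param or_values Per-category odds ratio (> 0); the reference must be 1.
#' @param reference Label of the reference category.
#' @return Data frame of class `factor_encoding`.
#' @export
factor_encoding <- function(factor_name, categories, or_values,
                            reference = categories[1]) {
  if (length(categories) != length(or_values)) {
    stop("categories and or_values must align", call. = FALSE)
  }
  if (anyDuplicated(categories)) {
    stop("category labels must be unique", call. = FALSE)
  }
  if (any(or_values <= 0)) stop("ORs must be > 0", call. = FALSE)
  if (!reference %in% categories) {
    stop("reference category not among the labels", call. = FALSE)
  }
  if (abs(or_values[match(reference, categories)] - 1) > 1e-12) {
    stop("reference category must have OR 1", call. = FALSE)
  }
  structure(data.frame(
    factor = factor_name, category = categories, or_value = or_values,
    is_reference = categories == reference, stringsAsFactors = FALSE
  ), class = c("factor_encoding", "data.frame"))
}

#' Example encoding tables for the five risk factors
#'
#' Synthetic example OR lookup tables for mammographic density, age at first
#' delivery, menopause status, age at menarche and family history, with
#' category labels matching [default_phenotype_specs()]. The values are
#' plausible, documented placeholders for the external literature-derived
#' tables a real analysis must supply; they are NOT published estimates.
#'
#' @return Named list of `factor_encoding` objects.
#' @export
example_encodings <- function() {
  sp <- default_phenotype_specs()
  # example ORs grow with the generator's default per-category effects
  mk <- function(nm) {
    factor_encoding(nm, sp[[nm]]$categories, exp(sp[[nm]]$log_or))
  }
  out <- lapply(names(sp), mk)
  names(out) <- names(sp)
  out
}

#' Encode categories as quantitative OR values
#'
#' Maps each woman's category label to its odds ratio from the encoding
#' table; the reference category maps to 1.
#'
#' @param categories Character vector of observed labels.
#' @param encoding A [factor_encoding()] covering every observed label.
#' @param missing `"error"` to reject `NA` labels, or a category label (e.g.
#'   `"Null"`) to substitute for them.
#' @return Numeric vector of encoded values.
#' @export
encode_factor <- function(categories, encoding, missing = "error") {
  stopifnot(inherits(encoding, "factor_encoding"))
  x <- as.character(categories)
  if (anyNA(x)) {
    if (identical(missing, "error")) {
      stop("missing category labels present", call. = FALSE)
    }
    x[is.na(x)] <- missing
  }
  i <- match(x, encoding$category)
  if (anyNA(i)) {
    stop("unknown category label(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  encoding$or_value[i]
}

#' Bin age into 5-year periods
#'
#' Half-open bins \[30,35), \[35,40), ..., \[60,65), with the top bin \[65,70\]
#' closed. Ages outside 30-70 are clamped with a warning. Returns the 0-based
#' bin index used as the ordinal age covariate, plus the printed label.
#'
#' @param age Numeric vector of ages in years.
#' @return Data frame with `index` (0-7) and `label`.
#' @export
bin_age <- function(age) {
  if (!is.numeric(age)) stop("age must be numeric", call. = FALSE)
  if (anyNA(age)) stop("age contains missing values", call. = FALSE)
  if (any(age < 30 | age > 70)) {
    warning("ages outside [30, 70] clamped to the cohort range")
    age <- pmin(pmax(age, 30), 70)
  }
  idx <- pmin(floor((age - 30) / 5), 7)
  data.frame(index = as.integer(idx), label = AGE_BIN_LABELS[idx + 1],
             stringsAsFactors = FALSE)
}

#' Validate phenotype completeness
#'
#' Flags rows with missing factor values (women with incomplete phenotypic
#' data are excluded from analysis); categories explicitly defined as their
#' own level (e.g. menarche "Null") are complete data, not missingness.
#'
#' @param phenotypes Data frame of per-woman categories.
#' @param factor_cols Columns to check (default: all `*_cat` columns).
#' @param exclude If `TRUE`, drop flagged rows; otherwise report only.
#' @return List with `data` (possibly filtered), `flagged` (row indices) and
#'   `n_excluded`.
#' @export
validate_phenotypes <- function(phenotypes,
                                factor_cols = grep("_cat$", names(phenotypes),
                                                   value = TRUE),
                                exclude = FALSE) {
  miss <- rep(FALSE, nrow(phenotypes))
  for (cl in factor_cols) {
    v <- phenotypes[[cl]]
    miss <- miss | is.na(v) | (!is.na(v) & v == "")
  }
  flagged <- which(miss)
  data <- if (exclude && length(flagged)) {
    out <- phenotypes[-flagged, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else phenotypes
  list(data = data, flagged = flagged, n_excluded = if (exclude) length(flagged) else 0L)
}

#' Encode a cohort for modelling
#'
#' Adds the ordinal age-bin index, a numeric centre indicator and the
#' quantitative OR encoding of each factor to a cohort's phenotype table.
#'
#' @param cohort A `cohort` (from [ascertain_case_control()]) or its
#'   phenotype data frame.
#' @param encodings Named list of [factor_encoding()] objects; names must
#'   match the `*_cat` column prefixes.
#' @return The phenotype data frame with `age_bin`, `age_bin_label`,
#'   `centre_num` and one `<factor>_enc` column per encoding.
#' @export
encode_cohort <- function(cohort, encodings = example_encodings()) {
  df <- if (inherits(cohort, "cohort")) cohort$phenotypes else cohort
  ab <- bin_age(df$age)
  df$age_bin <- ab$index
  df$age_bin_label <- ab$label
  df$centre_num <- as.integer(factor(df$centre)) - 1L
  for (nm in names(encodings)) {
    col <- paste0(nm, "_cat")
    if (!col %in% names(df)) {
      stop("cohort lacks column ", col, call. = FALSE)
    }
    df[[paste0(nm, "_enc")]] <- encode_factor(df[[col]], encodings[[nm]])
  }
  df
}
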